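#' Build / validate a run configuration
#'
#' Configuration for the two end-to-end workflows. Accepts a YAML file path
#' or a named list; defaults are filled in, thresholds validated, and every
#' referenced input path checked for existence.
#'
#' @param config YAML path or named list
#' @return validated config list (class `run_config`)
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    poses = NULL, receptor = NULL, anchors = NULL,
    traj = NULL, reference = NULL, target = NULL, times = NULL, dt = 1,
    out_dir = ".",
    pose_selection = "backbone",
    peptide_selection = "chain P",
    align_selection = "chain S",
    membrane_normal = c(0, 0, 1),
    cluster_cutoff = 1.5,
    hbond_dmax = 3.5, cation_pi_dmax = 6.0, cation_pi_angle_max = 45,
    water_cutoff = 3.5,
    rmsd_switch = 2.0, min_persist_fraction = 0.8, smoothing_window = 5L,
    seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  for (thr in c("cluster_cutoff", "hbond_dmax", "cation_pi_dmax",
                "water_cutoff", "rmsd_switch", "min_persist_fraction",
                "smoothing_window"))
    if (!is.numeric(cfg[[thr]]) || cfg[[thr]] <= 0)
      stop(sprintf("config: threshold '%s' must be positive", thr))
  for (p in c("poses", "receptor", "anchors", "traj", "reference", "target",
              "times"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(sprintf("config: input path '%s' does not exist (%s)", cfg[[p]], p))
  class(cfg) <- "run_config"
  cfg
}

config_criteria <- function(cfg) {
  interaction_criteria(hbond_dmax = cfg$hbond_dmax,
                       cation_pi_dmax = cfg$cation_pi_dmax,
                       cation_pi_angle_max = cfg$cation_pi_angle_max,
                       water_cutoff = cfg$water_cutoff)
}

#' Run the pose pipeline: cluster, fingerprint, classify, inter-pose screw
#'
#' Reads a multi-model pose PDB, a receptor PDB and a numbering anchor CSV;
#' clusters the poses by single linkage at the configured cutoff, computes
#' the contact fingerprint and state label of each cluster representative,
#' and the screw parameters between every pair of representatives (axis
#' fitted on the first of each pair). Writes `clusters.tsv`, `states.tsv`
#' and `screws.csv` into the output directory.
#'
#' @param config see [run_config()]; requires `poses`, `receptor`, `anchors`
#' @return (invisibly) list with `clusters`, `states`, `screws`, and the
#'   echoed thresholds
#' @export
run_pose_pipeline <- function(config) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  for (need in c("poses", "receptor", "anchors"))
    if (is.null(cfg[[need]]))
      stop("pose pipeline config requires '", need, "'")
  poses <- read_structure(cfg$poses)
  if (inherits(poses, "structure_model")) poses <- list(poses)
  ps <- pose_set(poses)
  receptor <- read_structure(cfg$receptor)
  numbering <- assign_generic_numbers(receptor, read_anchors(cfg$anchors))
  criteria <- config_criteria(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (length(ps$poses) >= 2L) {
    D <- pairwise_rmsd_matrix(ps, selection = cfg$pose_selection)
    cl <- single_linkage_cluster(D, cfg$cluster_cutoff)
  } else {
    cl <- structure(list(assignment = 1L, sizes = 1L, representative = 1L,
                         members = list(1L), cutoff = cfg$cluster_cutoff),
                    class = "cluster_result")
  }
  clusters <- as.data.frame(cl)
  clusters$cutoff_A <- cfg$cluster_cutoff

  states <- do.call(rbind, lapply(seq_along(cl$representative), function(r) {
    rep_pose <- ps$poses[[cl$representative[r]]]
    fp <- contact_fingerprint(receptor, rep_pose, numbering, criteria)
    cls <- classify_pose(fp)
    data.frame(rank = r, representative = cl$representative[r],
               state = cls$state,
               register_shift = if (is.na(cls$register_shift)) NA_integer_
                                else cls$register_shift,
               n_contacts = nrow(fp))
  }))

  screws <- NULL
  if (length(cl$representative) >= 2L) {
    pairs <- utils::combn(seq_along(cl$representative), 2L)
    screws <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      pa <- ps$poses[[cl$representative[i]]]
      pb <- ps$poses[[cl$representative[j]]]
      axis <- fit_helix_axis(pa)
      sp <- screw_about_axis(pa, pb, axis, selection = cfg$pose_selection)
      cbind(data.frame(rank_a = i, rank_b = j), as.data.frame(sp))
    }))
  }

  utils::write.table(clusters, file.path(cfg$out_dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(states, file.path(cfg$out_dir, "states.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(screws))
    utils::write.csv(screws, file.path(cfg$out_dir, "screws.csv"),
                     row.names = FALSE)
  invisible(list(clusters = clusters, states = states, screws = screws,
                 thresholds = list(cluster_cutoff = cfg$cluster_cutoff,
                                   hbond_dmax = cfg$hbond_dmax,
                                   cation_pi_dmax = cfg$cation_pi_dmax)))
}

#' Run the trajectory pipeline: align, metrics, switch call, interface report
#'
#' Reads a multi-model PDB trajectory with its time sidecar, a reference
#' (start) pose and a target (switched) pose; aligns all frames on the
#' alignment selection, computes rotation / RMSD-to-target / tilt series with
#' running averages, calls the switch event, and (when receptor atoms are in
#' the frames) reports bridging-water counts for the first and last frame.
#' Writes `series.csv`, `switch.json` and `waters.json`.
#'
#' @param config see [run_config()]; requires `traj`, `reference`, `target`
#' @return (invisibly) list with the metric series, `switch_event`, water
#'   counts, and echoed thresholds
#' @export
run_traj_pipeline <- function(config) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  for (need in c("traj", "reference", "target"))
    if (is.null(cfg[[need]]))
      stop("trajectory pipeline config requires '", need, "'")
  traj <- read_trajectory(cfg$traj, times_csv = cfg$times, dt = cfg$dt)
  reference <- read_structure(cfg$reference)
  target <- read_structure(cfg$target)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  traj <- align_frames(traj, reference, cfg$align_selection)
  hel <- paste0("(", cfg$peptide_selection, ") and backbone")
  rot <- running_average(rotation_series(traj, hel, reference),
                         cfg$smoothing_window)
  rms <- running_average(rmsd_series(traj, hel, target), cfg$smoothing_window)
  tlt <- running_average(tilt_series(traj, cfg$peptide_selection,
                                     cfg$membrane_normal),
                         cfg$smoothing_window)
  ev <- detect_switch(rot, rms,
                      thresholds = list(rmsd_switch = cfg$rmsd_switch,
                                        min_persist_fraction = cfg$min_persist_fraction,
                                        window = cfg$smoothing_window))
  waters <- NULL
  first <- traj$frames[[1L]]
  if (any(selection_mask(first, "water"))) {
    other <- sprintf("not water and not ( %s )", cfg$peptide_selection)
    n0 <- count_interface_waters(first, cfg$peptide_selection, other,
                                 cutoff = cfg$water_cutoff)$count
    n1 <- count_interface_waters(traj$frames[[length(traj$frames)]],
                                 cfg$peptide_selection, other,
                                 cutoff = cfg$water_cutoff)$count
    waters <- list(first_frame = n0, last_frame = n1,
                   cutoff_A = cfg$water_cutoff)
    jsonlite::write_json(waters, file.path(cfg$out_dir, "waters.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_series_csv(list(rot, rms, tlt), file.path(cfg$out_dir, "series.csv"))
  write_switch_event(ev, file.path(cfg$out_dir, "switch.json"))
  invisible(list(rotation = rot, rmsd = rms, tilt = tlt, switch = ev,
                 waters = waters,
                 thresholds = list(rmsd_switch = cfg$rmsd_switch,
                                   min_persist_fraction = cfg$min_persist_fraction,
                                   smoothing_window = cfg$smoothing_window)))
}

#' Generate synthetic inputs from a spec file
#'
#' Reads a YAML generator spec (`type`: "switch_trajectory", "pose_set" or
#' "interface_scene" plus the fields of the matching spec constructor),
#' runs the generator and writes its outputs (multi-model PDB + ground-truth
#' CSV) into `out_dir`.
#'
#' @param spec YAML path or list
#' @param out_dir output directory
#' @return (invisibly) the generated object
#' @export
run_simulate <- function(spec, out_dir = ".") {
  if (is.character(spec) && length(spec) == 1L) {
    if (!file.exists(spec)) stop("spec file not found: ", spec)
    spec <- yaml::read_yaml(spec)
  }
  stopifnot(is.list(spec))
  type <- spec$type %||% stop("generator spec needs a 'type' field")
  spec$type <- NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("simulate: type=", type, " seed=", spec$seed %||% "default")
  if (type == "switch_trajectory") {
    sim <- make_switch_trajectory(do.call(switch_trajectory_spec, spec))
    write_structure(sim$trajectory, file.path(out_dir, "trajectory.pdb"))
    write_structure(sim$start_pose, file.path(out_dir, "reference.pdb"))
    write_structure(sim$target_pose, file.path(out_dir, "target.pdb"))
    utils::write.csv(data.frame(frame = seq_along(sim$trajectory$times),
                                time_ns = sim$trajectory$times),
                     file.path(out_dir, "times.csv"), row.names = FALSE)
    utils::write.csv(sim$ground_truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    return(invisible(sim))
  }
  if (type == "pose_set") {
    gen <- do.call(make_pose_set, spec)
    write_structure(gen$poses$poses, file.path(out_dir, "poses.pdb"))
    utils::write.csv(data.frame(pose = seq_along(gen$labels),
                                planted_cluster = gen$labels),
                     file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    return(invisible(gen))
  }
  if (type == "interface_scene") {
    scn <- make_interface_scene(do.call(interface_scene_spec, spec))
    write_structure(scn$scene, file.path(out_dir, "scene.pdb"))
    write_structure(scn$receptor, file.path(out_dir, "receptor.pdb"))
    write_structure(scn$peptide, file.path(out_dir, "peptide.pdb"))
    utils::write.csv(scn$anchors, file.path(out_dir, "anchors.csv"),
                     row.names = FALSE)
    utils::write.csv(scn$expected_fingerprint,
                     file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    return(invisible(scn))
  }
  stop("unknown generator type: ", type)
}
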