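#' Specification of a planted switch trajectory
#'
#' The generator emulates the helix-switch: a rigid screw motion of the
#' peptide helix inside a fixed crevice scaffold, ramped in time by a logistic
#' profile (the switch is fast and then stable), plus i.i.d. Gaussian
#' coordinate noise. Defaults mirror the reported switch magnitude (60 degree
#' rotation, 1.5 A translation) and the GsalphaCT transition time scale
#' (onset within ~50 ns of a 100 ns run).
#'
#' @param helix a [helix_spec()] for the mobile peptide (default 11-mer)
#' @param theta_target planted total rotation (degrees, default 60)
#' @param slide_target planted total axial translation (A, default 1.5)
#' @param tilt_target planted change of tilt relative to the membrane plane
#'   (degrees, default 0), ramped with the same logistic
#' @param onset_time logistic midpoint (ns, default 50)
#' @param ramp_width logistic width (ns, default 1: switch-like)
#' @param dt frame spacing (ns, default 1)
#' @param n_frames number of frames (default 101, i.e. 0..100 ns)
#' @param noise_sigma per-coordinate Gaussian noise (A, default 0.3)
#' @param seed RNG seed (integer)
#' @export
switch_trajectory_spec <- function(helix = helix_spec(start_res_seq = 382L,
                                                      chain_id = "P"),
                                   theta_target = 60, slide_target = 1.5,
                                   tilt_target = 0,
                                   onset_time = 50, ramp_width = 1,
                                   dt = 1, n_frames = 101L,
                                   noise_sigma = 0.3, seed = 1L) {
  duration <- dt * (n_frames - 1L)
  if (onset_time < 0 || onset_time > duration)
    stop("onset_time must lie within [0, duration]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_frames < 2L) stop("need at least 2 frames")
  list(helix = helix, theta_target = theta_target, slide_target = slide_target,
       tilt_target = tilt_target,
       onset_time = onset_time, ramp_width = ramp_width, dt = dt,
       n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
       seed = as.integer(seed))
}

## Static crevice scaffold: two staggered rings of CA pseudo-atoms around the
## helix. Purely a frame anchor for alignment, not a receptor model.
make_scaffold <- function(center, axis_dir, radius = 12, n_ring = 12L) {
  e1 <- unit(cross3(axis_dir, if (abs(axis_dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- cross3(axis_dir, e1)
  rows <- list()
  k <- 0L
  for (lev in c(-6, 6)) for (i in seq_len(n_ring)) {
    k <- k + 1L
    ang <- 2 * pi * (i - 1L + (lev > 0) * 0.5) / n_ring
    p <- center + lev * axis_dir + radius * (cos(ang) * e1 + sin(ang) * e2)
    rows[[k]] <- data.frame(name = "CA", res_name = "GLY", chain_id = "S",
                            res_seq = k, x = p[1L], y = p[2L], z = p[3L],
                            element = "C", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a trajectory with a planted helix-switch
#'
#' Frame t carries the helix screw-transformed by
#' `theta(t) = theta_target * logistic((t - onset) / ramp_width)` and
#' `d(t) = slide_target * logistic(...)` about its own fitted axis, embedded
#' in a static scaffold, with seeded i.i.d. Gaussian noise on every
#' coordinate. The returned ground truth holds the planted theta(t), d(t)
#' per frame; generators are pure functions of spec + seed.
#'
#' @param spec a [switch_trajectory_spec()]
#' @return list of class `switch_sim`: `trajectory`, `ground_truth`
#'   (data.frame frame/time_ns/theta_deg/slide_A), `start_pose` and
#'   `target_pose` (noise-free helix at theta 0 and theta_target, embedded
#'   with the scaffold), `axis` (fitted on the start helix), `helix_selection`
#' @export
make_switch_trajectory <- function(spec = switch_trajectory_spec()) {
  helix <- build_ideal_helix(spec$helix)
  # canonical pose: helix axis along +x (lying in the membrane plane, the
  # z axis being the membrane normal), axis through the origin
  ax0 <- fit_helix_axis(helix)
  u <- ax0$direction
  v <- cross3(u, c(1, 0, 0))
  Rm <- if (vnorm(v) < 1e-9) diag(3) else
    rotation_about(v, rad2deg(acos(pmin(1, pmax(-1, u[1L])))))
  helix <- apply_transform(helix, rigid_transform(Rm, -as.numeric(Rm %*% ax0$point)))
  axis <- fit_helix_axis(helix)
  scaf <- make_scaffold(axis$point, axis$direction)
  embed <- function(hel) {
    m <- hel
    m$atoms <- rbind(hel$atoms[names(hel$atoms)],
                     structure_model(scaf, validate = FALSE)$atoms)
    rownames(m$atoms) <- NULL
    m$atoms$serial <- seq_len(nrow(m$atoms))
    m
  }
  times <- (seq_len(spec$n_frames) - 1L) * spec$dt
  ramp <- stats::plogis((times - spec$onset_time) / spec$ramp_width)
  theta <- spec$theta_target * ramp
  slide <- spec$slide_target * ramp
  tilt <- spec$tilt_target * ramp
  # tilting rotates the in-plane (x) helix axis about the in-plane y axis,
  # lifting it out of the membrane plane by the tilt angle
  place <- function(th, sl, ti) {
    hel <- apply_screw(helix, axis, angle_deg = th, slide = sl)
    if (ti != 0)
      hel <- apply_transform(hel, rigid_transform(rotation_about(c(0, 1, 0), -ti)))
    hel
  }
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    fr <- embed(place(theta[i], slide[i], tilt[i]))
    if (spec$noise_sigma > 0) {
      X <- coords(fr)
      fr <- set_coords(fr, X + matrix(stats::rnorm(length(X), 0, spec$noise_sigma),
                                      ncol = 3L))
    }
    fr$model_id <- i
    frames[[i]] <- fr
  }
  structure(list(
    trajectory = trajectory(frames, times),
    ground_truth = data.frame(frame = seq_len(spec$n_frames), time_ns = times,
                              theta_deg = theta, slide_A = slide,
                              tilt_deg = tilt),
    start_pose = embed(helix),
    target_pose = embed(place(spec$theta_target, spec$slide_target,
                              spec$tilt_target)),
    axis = axis,
    helix_selection = sprintf("chain %s", spec$helix$chain_id),
    spec = spec), class = "switch_sim")
}

#' Generate a docking-like pose set with planted cluster structure
#'
#' Cluster centers are distinct screw placements of the ideal helix about its
#' own axis, spaced so that adjacent centers differ by about `center_spacing`
#' in backbone RMSD; members are a center plus i.i.d. Gaussian jitter. Pose
#' order is shuffled (seeded); the planted labels are returned for recovery
#' scoring.
#'
#' @param k_centers number of planted clusters
#' @param sizes per-cluster pose counts (length `k_centers`)
#' @param jitter_sigma per-coordinate member jitter (A)
#' @param center_spacing target adjacent-center backbone RMSD (A)
#' @param seed RNG seed
#' @param helix a [helix_spec()]
#' @return list: `poses` (a `pose_set`), `labels` (planted cluster index per
#'   pose, 1 = first planted center), `centers` (list of structure models)
#' @export
make_pose_set <- function(k_centers = 3L, sizes = c(11L, 6L, 13L),
                          jitter_sigma = 0.15, center_spacing = 3.0,
                          seed = 1L,
                          helix = helix_spec(start_res_seq = 382L, chain_id = "P")) {
  if (length(sizes) != k_centers) stop("sizes must have length k_centers")
  if (center_spacing <= 0) stop("center_spacing must be positive")
  base <- build_ideal_helix(helix)
  axis <- fit_helix_axis(base)
  bb <- coords(select_atoms(base, "backbone"))
  z <- as.numeric(sweep(bb, 2L, axis$point) %*% axis$direction)
  V <- sweep(bb, 2L, axis$point) - outer(z, axis$direction)
  r_rms <- sqrt(mean(rowSums(V^2)))
  # adjacent-center rotation giving chord RMSD ~ center_spacing
  dtheta <- rad2deg(2 * asin(min(1, center_spacing / (2 * r_rms))))
  centers <- lapply(seq_len(k_centers), function(k)
    apply_screw(base, axis, angle_deg = (k - 1L) * dtheta, slide = 0))
  set.seed(seed)
  labels <- rep(seq_len(k_centers), sizes)
  perm <- sample(length(labels))
  labels <- labels[perm]
  poses <- lapply(seq_along(labels), function(i) {
    ctr <- centers[[labels[i]]]
    X <- coords(ctr)
    p <- set_coords(ctr, X + matrix(stats::rnorm(length(X), 0, jitter_sigma),
                                    ncol = 3L))
    p$model_id <- i
    p
  })
  list(poses = pose_set(poses, labels = labels), labels = labels,
       centers = centers, axis = axis, planted_dtheta = dtheta)
}
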