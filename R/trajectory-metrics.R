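#' Time-series metric container
#'
#' Per-frame metric trace (rotation, RMSD, distance, tilt) with optional
#' running-average smoothing, as plotted for switch trajectories: raw trace
#' with the running average drawn on top.
#'
#' @param name metric name
#' @param times time axis (ns), strictly increasing
#' @param values per-frame values
#' @param units unit string ("degrees", "A", ...)
#' @param smoothed optional smoothed values (same length)
#' @param params list of parameters (window etc.)
#' @export
time_series_metric <- function(name, times, values, units,
                               smoothed = NULL, params = list()) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(smoothed) && length(smoothed) != length(values))
    stop("smoothed values must match the series length")
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values), units = units,
                 smoothed = smoothed, params = params),
            class = "time_series_metric")
}

#' @export
print.time_series_metric <- function(x, ...) {
  cat(sprintf("<time_series_metric> %s [%s]: %d frames, range %.3g..%.3g\n",
              x$name, x$units, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.time_series_metric <- function(x, ...) {
  data.frame(metric = x$name, time_ns = x$times, value = x$values,
             smoothed = if (is.null(x$smoothed)) NA_real_ else x$smoothed)
}

#' Superpose every trajectory frame onto a reference
#'
#' Removes global motion by Kabsch-fitting each frame onto the reference on
#' an alignment selection (by default the non-peptide part: the receptor or
#' scaffold backbone), so downstream peptide metrics are receptor-frame
#' quantities. Pure transformation: atom identity is untouched.
#'
#' @param traj a `trajectory`
#' @param reference structure_model sharing atom identity with the frames
#' @param align_selection selection expression for the fit atoms
#' @return aligned `trajectory`
#' @export
align_frames <- function(traj, reference, align_selection = "backbone") {
  stopifnot(inherits(traj, "trajectory"), inherits(reference, "structure_model"))
  ref_mask <- selection_mask(reference, align_selection)
  if (!any(ref_mask)) stop("alignment selection matches no atoms in the reference")
  ref_xyz <- coords(reference)[ref_mask, , drop = FALSE]
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    mask <- selection_mask(fr, align_selection)
    if (sum(mask) != sum(ref_mask))
      stop(sprintf("alignment selection resolves %d atoms in frame %d but %d in the reference",
                   sum(mask), i, sum(ref_mask)))
    fit <- kabsch_superpose(coords(fr)[mask, , drop = FALSE], ref_xyz)
    traj$frames[[i]] <- apply_transform(fr, fit$transform)
  }
  traj
}

#' Helix rotation angle series about a fixed reference axis
#'
#' The axis is fitted once on the reference pose helix C-alphas and held
#' fixed; each frame's angle is the restricted screw rotation carrying the
#' reference helix onto the frame about that axis. With `per_frame_axis =
#' TRUE` the axis is re-fitted per frame instead (documented alternative).
#'
#' @param traj aligned `trajectory`
#' @param helix_selection selection of the helix atoms used for the screw fit
#' @param reference_pose structure_model of the reference pose
#' @param per_frame_axis re-fit the axis on each frame's C-alphas
#' @return `time_series_metric` in degrees
#' @export
rotation_series <- function(traj, helix_selection, reference_pose,
                            per_frame_axis = FALSE) {
  ref_sel <- select_atoms(reference_pose, helix_selection)
  if (isTRUE(attr(ref_sel, "empty_selection"))) stop("helix selection is empty")
  ref_ca <- select_atoms(reference_pose,
                         paste0("(", helix_selection, ") and name CA"))
  axis <- fit_helix_axis(coords(ref_ca))
  vals <- vapply(seq_along(traj$frames), function(i) {
    fr_sel <- select_atoms(traj$frames[[i]], helix_selection)
    ax <- if (per_frame_axis)
      fit_helix_axis(coords(select_atoms(traj$frames[[i]],
                                         paste0("(", helix_selection, ") and name CA"))))
    else axis
    screw_about_axis(ref_sel, fr_sel, ax, selection = NULL)$angle_deg
  }, numeric(1L))
  time_series_metric("rotation", traj$times, vals, "degrees",
                     params = list(per_frame_axis = per_frame_axis))
}

#' RMSD series relative to a reference pose
#'
#' Frames are assumed receptor-aligned; the RMSD is computed without
#' re-superposing the selection, because the peptide's position within the
#' crevice is the signal (RMSD relative to the position in the target
#' structure).
#'
#' @param traj aligned `trajectory`
#' @param selection selection expression (e.g. peptide backbone)
#' @param reference_pose structure_model resolving the same selection
#' @return `time_series_metric` in Angstrom
#' @export
rmsd_series <- function(traj, selection, reference_pose) {
  ref <- select_atoms(reference_pose, selection)
  if (isTRUE(attr(ref, "empty_selection"))) stop("selection is empty in the reference")
  ref_xyz <- coords(ref)
  vals <- vapply(seq_along(traj$frames), function(i) {
    x <- coords(select_atoms(traj$frames[[i]], selection))
    if (nrow(x) != nrow(ref_xyz))
      stop(sprintf("selection resolves %d atoms in frame %d but %d in the reference",
                   nrow(x), i, nrow(ref_xyz)))
    rmsd(x, ref_xyz, superpose = FALSE)
  }, numeric(1L))
  time_series_metric("rmsd", traj$times, vals, "A")
}

group_reference_point <- function(model, group_spec, mode) {
  sel <- select_atoms(model, group_spec)
  if (isTRUE(attr(sel, "empty_selection")))
    stop("group selection matches no atoms: ", group_spec)
  X <- coords(sel)
  switch(mode,
         centroid = colMeans(X),
         atom = {
           if (nrow(X) != 1L)
             stop("mode 'atom' needs a selection resolving exactly one atom")
           X[1L, ]
         },
         stop("unknown distance mode: ", mode))
}

#' Distance series between two atom groups
#'
#' Per-frame Euclidean distance between group reference points: group
#' centroids (e.g. the six ring atoms of a tyrosine give the ring centroid),
#' single atoms, or the minimum inter-group distance.
#'
#' @param traj `trajectory`
#' @param group_a,group_b selection expressions
#' @param mode "centroid", "min", or "atom"
#' @return `time_series_metric` in Angstrom
#' @export
distance_series <- function(traj, group_a, group_b, mode = "centroid") {
  vals <- vapply(seq_along(traj$frames), function(i) {
    fr <- traj$frames[[i]]
    if (mode == "min") {
      XA <- coords(select_atoms(fr, group_a))
      XB <- coords(select_atoms(fr, group_b))
      if (!nrow(XA) || !nrow(XB)) stop("empty group in frame ", i)
      min(vapply(seq_len(nrow(XA)),
                 function(k) min(sqrt(rowSums(sweep(XB, 2L, XA[k, ])^2))),
                 numeric(1L)))
    } else {
      pa <- group_reference_point(fr, group_a, mode)
      pb <- group_reference_point(fr, group_b, mode)
      vnorm(pa - pb)
    }
  }, numeric(1L))
  time_series_metric("distance", traj$times, vals, "A",
                     params = list(mode = mode, group_a = group_a, group_b = group_b))
}

#' Centered running average of a metric series
#'
#' Centered moving mean with an odd window; edges use shrunken windows so no
#' padding values are invented.
#'
#' @param series `time_series_metric` (or plain numeric vector)
#' @param window odd window length in frames, >= 1
#' @return the series with `$smoothed` filled (or a numeric vector)
#' @export
running_average <- function(series, window = 5L) {
  x <- if (inherits(series, "time_series_metric")) series$values else as.numeric(series)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(x)
  if (window > n) stop("window longer than the series")
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n),
               function(i) mean(x[max(1L, i - h):min(n, i + h)]),
               numeric(1L))
  if (inherits(series, "time_series_metric")) {
    series$smoothed <- sm
    series$params$window <- window
    series
  } else sm
}

#' Per-frame helix tilt series relative to a membrane normal
#'
#' @param traj `trajectory`
#' @param helix_selection selection whose CA atoms define the per-frame axis
#' @param membrane_normal unit vector (default z, the usual membrane normal
#'   convention for membrane simulations)
#' @return `time_series_metric` in degrees
#' @export
tilt_series <- function(traj, helix_selection, membrane_normal = c(0, 0, 1)) {
  vals <- vapply(seq_along(traj$frames), function(i) {
    ca <- select_atoms(traj$frames[[i]],
                       paste0("(", helix_selection, ") and name CA"))
    tilt_angle(fit_helix_axis(coords(ca)), membrane_normal)
  }, numeric(1L))
  time_series_metric("tilt", traj$times, vals, "degrees")
}

#' Write metric series as a tidy CSV
#' @param series a `time_series_metric` or list of them
#' @param path output CSV path
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "time_series_metric")) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
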