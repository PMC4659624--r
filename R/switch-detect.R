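#' Detect a helix-switch event from metric traces
#'
#' A switch is called when the smoothed RMSD-to-target trace drops below the
#' switch threshold at some onset time and stays below it for at least a
#' persistence fraction of the remaining frames -- the operational reading of
#' "adopts a conformation maintained for the remainder of the simulation".
#' The rotation trace is carried along to report the final rotation level.
#'
#' @param rotation `time_series_metric` of helix rotation (degrees)
#' @param rmsd `time_series_metric` of RMSD to the target (switched) pose (A)
#' @param thresholds list: `rmsd_switch` (A, default 2.0), `min_persist_fraction`
#'   (default 0.8), `window` (smoothing window in frames, default 5)
#' @param final_fingerprint optional `contact_fingerprint` of the last frame,
#'   classified against `states` to label the final state
#' @param states state definitions for the final-state call
#' @return object of class `switch_event`: `detected`, `onset_time` (ns),
#'   `onset_frame`, `final_rotation` (mean smoothed rotation after onset),
#'   `final_state`, `criteria`
#' @export
detect_switch <- function(rotation, rmsd,
                          thresholds = list(rmsd_switch = 2.0,
                                            min_persist_fraction = 0.8,
                                            window = 5L),
                          final_fingerprint = NULL, states = default_states()) {
  stopifnot(inherits(rotation, "time_series_metric"),
            inherits(rmsd, "time_series_metric"))
  if (length(rotation$values) != length(rmsd$values) ||
      max(abs(rotation$times - rmsd$times)) > 1e-9)
    stop("rotation and rmsd series must share one time grid")
  thr <- utils::modifyList(list(rmsd_switch = 2.0, min_persist_fraction = 0.8,
                                window = 5L), thresholds)
  n <- length(rmsd$values)
  if (n < thr$window) stop("series shorter than the smoothing window")
  sm_rmsd <- running_average(rmsd$values, thr$window)
  sm_rot <- running_average(rotation$values, thr$window)
  below <- sm_rmsd < thr$rmsd_switch
  onset_frame <- NA_integer_
  for (t in which(below)) {
    persist <- mean(below[t:n])
    if (persist >= thr$min_persist_fraction) {
      onset_frame <- t
      break
    }
  }
  detected <- !is.na(onset_frame)
  final_state <- NA_character_
  if (!is.null(final_fingerprint))
    final_state <- classify_pose(final_fingerprint, states)$state
  structure(list(detected = detected,
                 onset_time = if (detected) rmsd$times[onset_frame] else NA_real_,
                 onset_frame = onset_frame,
                 final_rotation = if (detected)
                   mean(sm_rot[onset_frame:n]) else NA_real_,
                 final_state = final_state,
                 criteria = thr),
            class = "switch_event")
}

#' @export
print.switch_event <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<switch_event> detected at %.3g ns (frame %d), final rotation %.1f deg\n",
                x$onset_time, x$onset_frame, x$final_rotation))
  else cat("<switch_event> no switch detected\n")
  invisible(x)
}

#' Write a switch event as JSON
#' @param event switch_event
#' @param path output path
#' @export
write_switch_event <- function(event, path) {
  jsonlite::write_json(unclass(event), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
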