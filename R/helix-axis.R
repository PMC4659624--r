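#' Fit a helix axis through ordered C-alpha positions
#'
#' Exploits the defining symmetry of a helix: successive residues are related
#' by one fixed screw motion. The C-alpha trace shifted by one residue is
#' Kabsch-superposed onto itself and the resulting transform is
#' Chasles-decomposed; its axis is the helix axis, its angle the per-residue
#' twist and its slide the per-residue rise. This is exact for ideal helical
#' points of any length >= 5 (a centroid-line fit is biased for short
#' helices, where a 4-residue window does not fully cancel the ~100
#' degree/residue winding) and degrades gracefully under coordinate noise.
#' The direction is oriented N-terminus to C-terminus; twist follows the
#' right-hand rule about that direction.
#'
#' @param ca_coords ordered n x 3 C-alpha coordinates (N->C), n >= 5, or a
#'   structure_model whose CA atoms are used in order
#' @param max_fit_rmsd sanity bound (Angstrom) on the residual of the
#'   one-residue screw fit; exceeding it sets the `suspect` flag rather than
#'   failing
#' @return object of class `helix_axis` with fields `point` (on the axis,
#'   near the helix centroid), `direction` (unit, N->C), `rise_per_residue`
#'   (A), `twist_per_residue` (degrees), `fit_rmsd` (A), `suspect` (logical)
#' @export
fit_helix_axis <- function(ca_coords, max_fit_rmsd = 1.0) {
  if (inherits(ca_coords, "structure_model"))
    ca_coords <- coords(select_atoms(ca_coords, "name CA"))
  X <- as_coord_matrix(ca_coords)
  n <- nrow(X)
  if (n < 5L) stop("helix axis fit needs at least 5 C-alpha positions")
  fit <- kabsch_superpose(X[seq_len(n - 1L), , drop = FALSE],
                          X[2L:n, , drop = FALSE])
  sp <- chasles_decompose(fit$transform)
  u <- sp$axis_direction
  twist <- sp$angle_deg
  rise <- sp$slide
  if (sum((X[n, ] - X[1L, ]) * u) < 0) {
    u <- -u
    twist <- -twist
    rise <- -rise
  }
  # put the reported axis point next to the helix, not near the origin
  cm <- colMeans(X)
  p0 <- sp$axis_point + sum((cm - sp$axis_point) * u) * u
  structure(list(point = p0, direction = u,
                 rise_per_residue = rise, twist_per_residue = twist,
                 fit_rmsd = fit$rmsd, suspect = fit$rmsd > max_fit_rmsd),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("<helix_axis> rise %.3f A/res, twist %.2f deg/res, fit rmsd %.3f A%s\n",
              x$rise_per_residue, x$twist_per_residue, x$fit_rmsd,
              if (isTRUE(x$suspect)) " [suspect fit]" else ""))
  invisible(x)
}

#' Transform a helix axis by a rigid motion
#' @param axis helix_axis
#' @param transform rigid_transform
#' @export
transform_axis <- function(axis, transform) {
  axis$point <- as.numeric(apply_transform(matrix(axis$point, 1L), transform))
  axis$direction <- as.numeric(transform$rotation %*% axis$direction)
  axis
}

#' Tilt of a helix axis relative to a reference plane
#'
#' Angle between the axis direction and the plane orthogonal to
#' `reference_normal` (the membrane plane when the normal is the membrane
#' normal), in degrees within [-90, 90], positive when the axis leans toward
#' the normal.
#'
#' @param axis a `helix_axis` (or unit 3-vector direction)
#' @param reference_normal unit 3-vector (membrane normal; z by convention)
#' @export
tilt_angle <- function(axis, reference_normal = c(0, 0, 1)) {
  u <- if (inherits(axis, "helix_axis")) axis$direction else unit(axis)
  if (vnorm(reference_normal) < .Machine$double.eps)
    stop("reference normal must be a non-zero vector")
  nrm <- unit(reference_normal)
  rad2deg(asin(pmin(1, pmax(-1, sum(u * nrm)))))
}
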