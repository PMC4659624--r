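#' Screw parameters constructor
#'
#' A screw motion: rotation by `angle_deg` about an axis plus translation
#' `slide` along it (Chasles form of a rigid displacement).
#'
#' @param axis_point point on the screw axis
#' @param axis_direction unit direction of the axis
#' @param angle_deg rotation angle, degrees, in (-180, 180]
#' @param slide translation along the axis, Angstrom
#' @param residual_rmsd RMSD left after applying the screw (A), when fitted
#' @export
screw_params <- function(axis_point, axis_direction, angle_deg, slide,
                         residual_rmsd = NA_real_) {
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = unit(as.numeric(axis_direction)),
                 angle_deg = wrap_angle(angle_deg),
                 slide = as.numeric(slide),
                 residual_rmsd = residual_rmsd),
            class = "screw_params")
}

#' @export
print.screw_params <- function(x, ...) {
  cat(sprintf("<screw_params> angle %.3f deg, slide %.3f A, residual %.4g A\n",
              x$angle_deg, x$slide, x$residual_rmsd))
  invisible(x)
}

#' Serialize screw parameters to a one-row data.frame (CSV-ready)
#' @param sp screw_params
#' @export
as.data.frame.screw_params <- function(x, ...) {
  data.frame(angle_deg = x$angle_deg, slide_A = x$slide,
             residual_A = x$residual_rmsd,
             axis_px = x$axis_point[1L], axis_py = x$axis_point[2L],
             axis_pz = x$axis_point[3L],
             axis_dx = x$axis_direction[1L], axis_dy = x$axis_direction[2L],
             axis_dz = x$axis_direction[3L])
}

#' Apply a screw motion to coordinates or a structure model
#'
#' Rotates by the screw angle about the screw axis, then translates along it.
#' @param x coordinates, structure_model, or trajectory
#' @param screw screw_params (or a helix_axis plus explicit angle/slide)
#' @param angle_deg,slide override/supply angle and slide when `screw` is a
#'   `helix_axis`
#' @export
apply_screw <- function(x, screw, angle_deg = NULL, slide = NULL) {
  if (inherits(screw, "helix_axis")) {
    if (is.null(angle_deg) || is.null(slide))
      stop("angle_deg and slide are required when passing a helix_axis")
    screw <- screw_params(screw$point, screw$direction, angle_deg, slide)
  } else {
    if (!is.null(angle_deg)) screw$angle_deg <- angle_deg
    if (!is.null(slide)) screw$slide <- slide
  }
  apply_transform(x, screw_to_transform(screw))
}

#' Convert screw parameters to the equivalent rigid transform
#' @param screw screw_params
#' @export
screw_to_transform <- function(screw) {
  stopifnot(inherits(screw, "screw_params"))
  Rm <- rotation_about(screw$axis_direction, screw$angle_deg)
  p <- screw$axis_point
  tr <- p - as.numeric(Rm %*% p) + screw$slide * screw$axis_direction
  rigid_transform(Rm, tr)
}

#' Fit the restricted screw motion between two poses about a fixed helix axis
#'
#' Finds the rotation angle about `axis` and the translation along it that
#' best (least-squares) carry pose A onto pose B, within the restricted motion
#' family \{rotate theta about axis, slide d along axis\}. Closed form: the
#' slide is the mean axial displacement, and the angle is the atan2 of summed
#' cross/dot products of the axis-perpendicular components, with sign by the
#' right-hand rule about the N->C axis direction. This is the operational
#' quantity behind "rotation about the helix axis" traces and inter-pose
#' switch magnitudes.
#'
#' @param pose_a,pose_b structure models (or n x 3 coordinate matrices) with
#'   matching atom order
#' @param axis `helix_axis` fitted on pose A (held fixed)
#' @param selection optional selection expression applied to both poses
#'   (default "backbone")
#' @return `screw_params` with the fitted angle (degrees), slide (A), and the
#'   residual RMSD after applying the fitted screw to pose A
#' @export
screw_about_axis <- function(pose_a, pose_b, axis, selection = "backbone") {
  stopifnot(inherits(axis, "helix_axis"))
  if (inherits(pose_a, "structure_model") && !is.null(selection)) {
    pose_a <- select_atoms(pose_a, selection)
    if (isTRUE(attr(pose_a, "empty_selection"))) stop("selection matches no atoms in pose A")
  }
  if (inherits(pose_b, "structure_model") && !is.null(selection)) {
    pose_b <- select_atoms(pose_b, selection)
    if (isTRUE(attr(pose_b, "empty_selection"))) stop("selection matches no atoms in pose B")
  }
  A <- as_coord_matrix(pose_a)
  B <- as_coord_matrix(pose_b)
  if (nrow(A) != nrow(B))
    stop(sprintf("atom counts differ between poses (%d vs %d)", nrow(A), nrow(B)))
  u <- axis$direction
  p <- axis$point
  za <- as.numeric(sweep(A, 2L, p) %*% u)
  zb <- as.numeric(sweep(B, 2L, p) %*% u)
  d <- mean(zb - za)
  Va <- sweep(A, 2L, p) - outer(za, u)
  Vb <- sweep(B, 2L, p) - outer(zb, u)
  if (max(rowSums(Va^2)) < 1e-12)
    stop("all atoms lie on the axis: rotation angle is undefined")
  cr <- Va[, c(2, 3, 1)] * Vb[, c(3, 1, 2)] - Va[, c(3, 1, 2)] * Vb[, c(2, 3, 1)]
  s <- sum(as.numeric(cr %*% u))
  c_ <- sum(Va * Vb)
  theta <- rad2deg(atan2(s, c_))
  sp <- screw_params(p, u, theta, d)
  sp$residual_rmsd <- rmsd(apply_transform(A, screw_to_transform(sp)), B)
  sp
}

#' Chasles decomposition of a rigid transform into its screw form
#'
#' Every proper rigid displacement is a rotation about a unique axis plus a
#' translation along that axis. For near-zero rotation (|angle| < 0.1 degree)
#' the motion is reported as a pure translation: angle 0, axis along the
#' translation vector.
#'
#' @param transform a `rigid_transform`
#' @return `screw_params` (residual_rmsd is 0 by construction)
#' @export
chasles_decompose <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rm <- transform$rotation
  tv <- transform$translation
  cos_th <- pmin(1, pmax(-1, (sum(diag(Rm)) - 1) / 2))
  theta <- acos(cos_th)
  if (rad2deg(theta) < 0.1) {
    u <- if (vnorm(tv) > 1e-12) unit(tv) else c(0, 0, 1)
    return(screw_params(c(0, 0, 0), u, 0, vnorm(tv), residual_rmsd = 0))
  }
  if (abs(pi - theta) > 1e-6) {
    u <- c(Rm[3L, 2L] - Rm[2L, 3L],
           Rm[1L, 3L] - Rm[3L, 1L],
           Rm[2L, 1L] - Rm[1L, 2L]) / (2 * sin(theta))
  } else {
    # angle ~180: axis from the dominant column of (R + I)/2
    M <- (Rm + diag(3)) / 2
    j <- which.max(diag(M))
    u <- M[, j] / sqrt(M[j, j])
  }
  u <- unit(u)
  slide <- sum(tv * u)
  t_perp <- tv - slide * u
  # point on the axis: c = 1/2 * (t_perp + cot(theta/2) * u x t_perp)
  p <- 0.5 * (t_perp + cross3(u, t_perp) / tan(theta / 2))
  screw_params(p, u, rad2deg(theta), slide, residual_rmsd = 0)
}
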