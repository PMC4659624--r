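#' Rigid transform constructor
#'
#' A proper rigid-body motion `x -> R x + t`. The rotation is checked for
#' orthonormality and determinant +1.
#'
#' @param rotation 3x3 proper rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be proper (det +1); reflections are not rigid motions")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))))
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A\n",
              ang, vnorm(x$translation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure model
#'
#' @param x n x 3 coordinate matrix, `structure_model`, or `trajectory`
#' @param transform a `rigid_transform`
#' @return object of the same kind with transformed coordinates
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "structure_model"))
    return(set_coords(x, apply_transform(coords(x), transform)))
  if (inherits(x, "trajectory")) {
    x$frames <- lapply(x$frames, apply_transform, transform = transform)
    return(x)
  }
  x <- as.matrix(x)
  sweep(x %*% t(transform$rotation), 2L, -transform$translation)
}

#' Compose two rigid transforms (apply `a` first, then `b`)
#' @param b,a rigid transforms
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform rigid_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

as_coord_matrix <- function(x) {
  if (inherits(x, "structure_model")) return(coords(x))
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  x
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of a mobile point set onto a reference,
#' solved by singular value decomposition with the reflection excluded, so the
#' returned rotation is always proper. Optional per-point weights give the
#' weighted-RMSD optimum.
#'
#' @param mobile n x 3 coordinates (or structure_model) to be moved
#' @param reference n x 3 coordinates (or structure_model) to match
#' @param weights optional non-negative per-point weights
#' @return list with `transform` (a `rigid_transform` mapping mobile onto
#'   reference) and `rmsd` (Angstrom, weighted when weights are given)
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as_coord_matrix(mobile)
  Q <- as_coord_matrix(reference)
  if (nrow(P) != nrow(Q))
    stop(sprintf("point counts differ (%d vs %d)", nrow(P), nrow(Q)))
  if (nrow(P) < 3L) stop("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(P)) else as.numeric(weights)
  if (length(w) != nrow(P) || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  pbar <- colSums(P * w)
  qbar <- colSums(Q * w)
  Pc <- sweep(P, 2L, pbar)
  Qc <- sweep(Q, 2L, qbar)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  # collinear (or coincident) points leave the rotation about the line free
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-12))
    stop("degenerate input: points are (near-)collinear, rotation is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(Rm, qbar - as.numeric(Rm %*% pbar))
  moved <- apply_transform(P, tr)
  rms <- sqrt(sum(w * rowSums((moved - Q)^2)))
  list(transform = tr, rmsd = rms)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b n x 3 coordinate matrices or structure models (paired by order)
#' @param superpose if TRUE, optimally superpose `a` onto `b` first (Kabsch);
#'   if FALSE (default) compute in the current frame
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  A <- as_coord_matrix(a)
  B <- as_coord_matrix(b)
  if (nrow(A) != nrow(B))
    stop(sprintf("point counts differ (%d vs %d)", nrow(A), nrow(B)))
  if (nrow(A) < 1L) stop("rmsd needs at least one point")
  if (superpose) return(kabsch_superpose(A, B)$rmsd)
  sqrt(mean(rowSums((A - B)^2)))
}
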