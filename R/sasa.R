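#' Default van der Waals radii by element (Angstrom)
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

## Deterministic, nearly uniform sphere quadrature: golden-spiral points.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by counting quadrature points on each atom's solvent-expanded
#' sphere that are not buried inside any neighbor's expanded sphere. The point
#' set is a deterministic golden-spiral lattice, so results are exactly
#' reproducible for a given `n_points`.
#'
#' @param model structure_model
#' @param probe probe radius (A), default 1.4 (water)
#' @param n_points quadrature points per atom, >= 100 (default 960)
#' @param radii named element->radius table (A); see [default_radii()]
#' @param fallback_radius radius used for elements missing from `radii`;
#'   `NA` (default) makes an unknown element an error
#' @return numeric vector of per-atom areas (A^2); `sum()` gives the total
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L, radii = default_radii(),
                 fallback_radius = NA_real_) {
  stopifnot(inherits(model, "structure_model"))
  if (n_points < 100L) stop("n_points must be at least 100")
  el <- toupper(model$atoms$element)
  r <- unname(radii[el])
  if (any(is.na(r))) {
    if (is.na(fallback_radius))
      stop("no radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "),
           " (supply a radii entry or fallback_radius)")
    r[is.na(r)] <- fallback_radius
  }
  X <- coords(model)
  re <- r + probe
  n <- nrow(X)
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(X))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    sp <- sweep(pts * re[i], 2L, X[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(sp, 2L, X[j, ])^2)
        free <- free & dj2 > re[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    } else {
      acc <- n_points
    }
    out[i] <- 4 * pi * re[i]^2 * acc / n_points
  }
  out
}

#' Buried interface area between two binding partners
#'
#' Half the SASA lost on complex formation:
#' `(sasa(a) + sasa(b) - sasa(a+b)) / 2`. The apolar component restricts the
#' per-atom sums to carbon and sulfur atoms (the hydrophobic-patch area). The
#' total burial (factor-2 convention) is reported alongside.
#'
#' @param a,b structure models with disjoint atom sets
#' @param ... passed to [sasa()] (`probe`, `n_points`, `radii`, ...)
#' @return list: `buried_area`, `apolar_buried_area` (half-burial, A^2) and
#'   `total_buried_area`, `total_apolar_buried_area` (factor-2 convention)
#' @export
buried_interface_area <- function(a, b, ...) {
  key_a <- paste(a$atoms$chain_id, a$atoms$res_seq, a$atoms$ins_code, a$atoms$name)
  key_b <- paste(b$atoms$chain_id, b$atoms$res_seq, b$atoms$ins_code, b$atoms$name)
  if (length(intersect(key_a, key_b)))
    stop("partners share atoms; buried area needs disjoint atom sets")
  ab <- a
  ab$atoms <- rbind(a$atoms, b$atoms)
  rownames(ab$atoms) <- NULL
  sa <- sasa(a, ...)
  sb <- sasa(b, ...)
  sab <- sasa(ab, ...)
  apol_a <- toupper(a$atoms$element) %in% c("C", "S")
  apol_b <- toupper(b$atoms$element) %in% c("C", "S")
  apol_ab <- c(apol_a, apol_b)
  total <- sum(sa) + sum(sb) - sum(sab)
  total_apolar <- sum(sa[apol_a]) + sum(sb[apol_b]) - sum(sab[apol_ab])
  list(buried_area = total / 2,
       apolar_buried_area = total_apolar / 2,
       total_buried_area = total,
       total_apolar_buried_area = total_apolar)
}
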