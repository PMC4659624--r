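# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# random structure with unique atom identities and PDB-representable coords
random_structure <- function(n = 20L, seed = 1L, chains = c("A", "B")) {
  set.seed(seed)
  names_pool <- c("N", "CA", "C", "O", "CB", "CG", "CD", "NE2", "OE1", "OH")
  res_pool <- c("ALA", "GLN", "TYR", "GLU", "ARG", "GLY", "HOH")
  atoms <- data.frame(
    name = sample(names_pool, n, replace = TRUE),
    res_name = sample(res_pool, n, replace = TRUE),
    chain_id = sample(chains, n, replace = TRUE),
    res_seq = sample.int(50L, n, replace = TRUE),
    x = round(runif(n, -50, 50), 3),
    y = round(runif(n, -50, 50), 3),
    z = round(runif(n, -50, 50), 3),
    stringsAsFactors = FALSE)
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms$element <- substr(atoms$name, 1L, 1L)
  structure_model(atoms)
}

# per-atom predicate evaluation of a conjunction of simple terms; the
# brute-force counterpart of the selection parser for "t1 and t2 and ..."
oracle_select_mask <- function(model, terms) {
  a <- model$atoms
  mask <- rep(TRUE, nrow(a))
  for (t in terms) {
    mask <- mask & switch(t$kind,
      backbone = a$name %in% c("N", "CA", "C", "O"),
      heavy = toupper(a$element) != "H",
      water = a$res_name %in% c("HOH", "WAT", "SOL"),
      chain = a$chain_id %in% t$args,
      name = a$name %in% t$args,
      resid = a$res_seq %in% t$args)
  }
  mask
}

# union-find connected components at a distance cutoff
oracle_components <- function(D, cutoff) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, 1L)
}

# uniformly sampled unit quaternions, reusable across clouds
oracle_quaternions <- function(n_rot, seed = 1L) {
  set.seed(seed)
  qn <- matrix(rnorm(4L * n_rot), ncol = 4L)
  qn / sqrt(rowSums(qn^2))
}

# brute-force minimum RMSD over uniformly sampled unit quaternions (with
# optimal translation folded in analytically)
oracle_min_rmsd <- function(P, Q, n_rot = 200000L, seed = 1L, qn = NULL) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  M <- crossprod(Qc, Pc)  # 3x3; trace(R M) is the alignment gain
  if (is.null(qn)) qn <- oracle_quaternions(n_rot, seed)
  w <- qn[, 1L]; x <- qn[, 2L]; y <- qn[, 3L]; z <- qn[, 4L]
  tr <- (1 - 2 * (y^2 + z^2)) * M[1L, 1L] +
        2 * (x * y - w * z) * M[2L, 1L] +
        2 * (x * z + w * y) * M[3L, 1L] +
        2 * (x * y + w * z) * M[1L, 2L] +
        (1 - 2 * (x^2 + z^2)) * M[2L, 2L] +
        2 * (y * z - w * x) * M[3L, 2L] +
        2 * (x * z - w * y) * M[1L, 3L] +
        2 * (y * z + w * x) * M[2L, 3L] +
        (1 - 2 * (x^2 + y^2)) * M[3L, 3L]
  ss <- sum(Pc^2) + sum(Qc^2)
  sqrt(pmax(0, (ss - 2 * max(tr)) / nrow(P)))
}

# exposed area of two overlapping solvent-expanded spheres (analytic caps)
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  if (d <= abs(r1 - r2)) {
    # one sphere engulfed by the other
    if (r1 > r2) return(c(4 * pi * r1^2, 0))
    return(c(0, 4 * pi * r2^2))
  }
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1,
    4 * pi * r2^2 - 2 * pi * r2 * h2)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

random_rigid <- function(seed = NULL, max_t = 20) {
  Rm <- random_rotation(seed)
  rigid_transform(Rm, runif(3L, -max_t, max_t))
}
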