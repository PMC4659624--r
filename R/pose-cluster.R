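#' Construct a pose set
#'
#' An ordered collection of peptide poses (structure models) with identical
#' atom composition, e.g. the output of a docking run read from a multi-model
#' PDB file.
#'
#' @param poses list of `structure_model` with identical atom identity
#' @param labels optional per-pose tags
#' @export
pose_set <- function(poses, labels = NULL) {
  if (inherits(poses, "structure_model")) poses <- list(poses)
  if (!length(poses)) stop("a pose set needs at least one pose")
  for (i in seq_along(poses))
    if (!same_atom_identity(poses[[1L]], poses[[i]]))
      stop(sprintf("pose %d does not match the atom identity of pose 1", i))
  if (!is.null(labels) && length(labels) != length(poses))
    stop("labels must match the number of poses")
  structure(list(poses = poses, labels = labels), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses x %d atoms\n",
              length(x$poses), n_atoms(x$poses[[1L]])))
  invisible(x)
}

#' Pairwise RMSD matrix over a pose set
#'
#' By default no re-superposition is performed: docking poses share the
#' receptor frame, so in-frame RMSD is the meaningful clustering distance.
#'
#' @param poses a `pose_set` or list of structure models
#' @param selection selection expression (default "backbone")
#' @param superpose optimally superpose each pair first
#' @return symmetric matrix of RMSD values (A) with zero diagonal
#' @export
pairwise_rmsd_matrix <- function(poses, selection = "backbone", superpose = FALSE) {
  if (inherits(poses, "pose_set")) poses <- poses$poses
  if (length(poses) < 2L) stop("need at least 2 poses for a distance matrix")
  xs <- lapply(poses, function(p) {
    if (!is.null(selection)) {
      p <- select_atoms(p, selection)
      if (isTRUE(attr(p, "empty_selection"))) stop("selection matches no atoms")
    }
    coords(p)
  })
  n <- length(xs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- rmsd(xs[[i]], xs[[j]], superpose = superpose)
  }
  D
}

#' Single-linkage clustering at a fixed cutoff
#'
#' Clusters are the connected components of the graph whose edges join pose
#' pairs with distance <= cutoff -- the single-linkage partition at that cut
#' height, matching the behavior of fixed-cutoff clustering of docking poses.
#' Clusters are ranked by descending size (the paper's "first cluster" is the
#' most occupied one), ties broken by the lowest member index. Each cluster's
#' representative is the member with minimal summed distance to the rest of
#' its cluster.
#'
#' @param dist square symmetric distance matrix, zero diagonal
#' @param cutoff linkage cutoff (A), > 0
#' @return object of class `cluster_result`: `assignment` (per-pose cluster
#'   rank), `sizes` (descending), `representative` (per-cluster pose index),
#'   `members` (list of index vectors)
#' @export
single_linkage_cluster <- function(dist, cutoff) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n != ncol(dist)) stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(dist < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(dist)) > 1e-8)) stop("distance matrix must have a zero diagonal")
  stopifnot_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0) stop("cutoff must be positive")

  adj <- dist <= cutoff
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes_raw <- tabulate(comp)
  first_member <- vapply(seq_len(cid), function(k) min(which(comp == k)), 1L)
  rank_order <- order(-sizes_raw, first_member)
  rank_of <- integer(cid)
  rank_of[rank_order] <- seq_len(cid)
  assignment <- rank_of[comp]
  members <- lapply(seq_len(cid), function(r) which(assignment == r))
  representative <- vapply(members, function(idx) {
    if (length(idx) == 1L) return(idx)
    sums <- rowSums(dist[idx, idx, drop = FALSE])
    idx[which.min(sums)]
  }, 1L)
  structure(list(assignment = assignment,
                 sizes = lengths(members),
                 representative = representative,
                 members = members,
                 cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at cutoff %.2f A; sizes: %s\n",
              length(x$sizes), x$cutoff, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Tabulate a cluster result (rank, size, representative)
#' @param x cluster_result
#' @export
as.data.frame.cluster_result <- function(x, ...) {
  data.frame(rank = seq_along(x$sizes), size = x$sizes,
             representative = x$representative)
}
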