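#' Construct a structure model
#'
#' A `structure_model` is the universal coordinate container of the package:
#' one model (a receptor, a peptide pose, or a single trajectory frame) as an
#' ordered table of atom records. Coordinates are in Angstrom throughout.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`, `res_name`,
#'   `chain_id`, `res_seq`, `ins_code`, `x`, `y`, `z`, `occupancy`, `b_factor`,
#'   `element`. Missing bookkeeping columns are filled with defaults.
#' @param model_id integer model number (1 for single-model structures).
#' @param validate check invariants (finite coordinates, non-empty elements,
#'   unique `(chain_id, res_seq, ins_code, name)` keys).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("a structure model must contain at least one atom")
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = "", ins_code = "",
                   occupancy = 1, b_factor = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  needed <- c("serial", "name", "altloc", "res_name", "chain_id", "res_seq",
              "ins_code", "x", "y", "z", "occupancy", "b_factor", "element")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[needed]
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  m <- structure(list(model_id = as.integer(model_id), atoms = atoms),
                 class = "structure_model")
  if (validate) validate_structure_model(m)
  m
}

validate_structure_model <- function(m) {
  a <- m$atoms
  if (any(!nzchar(a$element)))
    stop("every atom needs a non-empty element symbol")
  xyz <- as.matrix(a[c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure model")
  key <- paste(a$chain_id, a$res_seq, a$ins_code, a$name, a$altloc, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain_id, res_seq, name) within one model")
  invisible(m)
}

## Crude element from a PDB atom name: strip digits/primes, first letter,
## honoring two-letter cases that matter for proteins and waters.
guess_element <- function(name) {
  nm <- toupper(gsub("[ 0-9']", "", name))
  el <- substr(nm, 1L, 1L)
  el[nm %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA2")] <- substr(nm[nm %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA2")], 1L, 2L)
  el
}

#' Number of atoms in a structure model
#' @param m structure_model
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Coordinate matrix of a structure model
#' @param m structure_model
#' @return numeric n x 3 matrix (Angstrom)
#' @export
coords <- function(m) {
  x <- as.matrix(m$atoms[c("x", "y", "z")])
  dimnames(x) <- NULL
  x
}

#' Replace the coordinates of a structure model
#' @param m structure_model
#' @param xyz n x 3 matrix matching the atom count
#' @export
set_coords <- function(m, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(m) || ncol(xyz) != 3L)
    stop("replacement coordinates must be an n_atoms x 3 matrix")
  m$atoms$x <- xyz[, 1L]
  m$atoms$y <- xyz[, 2L]
  m$atoms$z <- xyz[, 3L]
  m
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> model %d: %d atoms, %d residues, chains [%s]\n",
              x$model_id, nrow(a),
              length(unique(paste(a$chain_id, a$res_seq, a$ins_code))),
              paste(unique(a$chain_id), collapse = ",")))
  invisible(x)
}

same_atom_identity <- function(a, b) {
  ka <- paste(a$atoms$chain_id, a$atoms$res_seq, a$atoms$ins_code, a$atoms$name)
  kb <- paste(b$atoms$chain_id, b$atoms$res_seq, b$atoms$ins_code, b$atoms$name)
  identical(ka, kb)
}

#' Construct a trajectory
#'
#' An ordered series of frames with identical atom composition plus a strictly
#' increasing time axis in nanoseconds. Multi-model PDB is the on-disk format;
#' times come from a sidecar table or a uniform time step.
#'
#' @param frames list of `structure_model`, identical atom identity
#' @param times numeric vector of times (ns), strictly increasing, same length
#' @return object of class `trajectory`
#' @export
trajectory <- function(frames, times = NULL) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times and frames must have equal length")
  if (any(diff(times) <= 0)) stop("trajectory times must be strictly increasing")
  n0 <- n_atoms(frames[[1L]])
  for (i in seq_along(frames)) {
    if (n_atoms(frames[[i]]) != n0 || !same_atom_identity(frames[[1L]], frames[[i]]))
      stop(sprintf("frame %d does not match the atom identity of frame 1", i))
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              length(x$frames), n_atoms(x$frames[[1L]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)
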