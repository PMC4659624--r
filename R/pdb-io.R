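#' Read a structure (or trajectory frames) from a PDB file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records from a fixed-width PDB file.
#' Waters (HOH/WAT/SOL) are retained as ordinary atoms; insertion codes are
#' kept in the `ins_code` column. Multi-model files double as the trajectory
#' format. For alternate locations only the highest-occupancy conformer is
#' kept (ties broken by altloc letter order) and the choice is reported via
#' `message()`.
#'
#' @param path PDB file path
#' @param model_index optional integer: return only that model
#' @return a `structure_model`, or a list of them for multi-model input
#' @export
read_structure <- function(path, model_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  models <- list()
  cur_rows <- integer(0)
  cur_id <- NA_integer_
  n_seen <- 0L
  flush_model <- function() {
    if (!length(cur_rows)) return(invisible(NULL))
    n_seen <<- n_seen + 1L
    id <- if (is.na(cur_id)) n_seen else cur_id
    models[[length(models) + 1L]] <<- parse_atom_lines(lines[cur_rows], cur_rows, id)
    cur_rows <<- integer(0)
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush_model()
      cur_id <- suppressWarnings(as.integer(substr(lines[i], 11L, 14L)))
    } else if (r == "ENDMDL") {
      if (!length(cur_rows))
        stop(sprintf("empty model (no atoms) ending at line %d", i))
      flush_model()
      cur_id <- NA_integer_
    } else if (r %in% c("ATOM  ", "HETATM")) {
      cur_rows <- c(cur_rows, i)
    }
  }
  flush_model()
  if (!length(models)) stop("no ATOM/HETATM records found in ", path)
  if (!is.null(model_index)) {
    if (model_index < 1L || model_index > length(models))
      stop(sprintf("model_index %d out of range (file has %d model(s))",
                   model_index, length(models)))
    return(models[[model_index]])
  }
  if (length(models) == 1L) models[[1L]] else models
}

parse_atom_lines <- function(ln, line_no, model_id) {
  ln <- formatC(ln, width = 80L, flag = "-")
  num <- function(from, to, what) {
    s <- trimws(substr(ln, from, to))
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!nzchar(s) | is.na(v))
    if (length(bad))
      stop(sprintf("malformed PDB record at line %d: unreadable %s field '%s'",
                   line_no[bad[1L]], what, s[bad[1L]]))
    v
  }
  occ_raw <- trimws(substr(ln, 55L, 60L))
  bfc_raw <- trimws(substr(ln, 61L, 66L))
  atoms <- data.frame(
    serial = as.integer(num(7L, 11L, "serial")),
    name = trimws(substr(ln, 13L, 16L)),
    altloc = trimws(substr(ln, 17L, 17L)),
    res_name = trimws(substr(ln, 18L, 20L)),
    chain_id = substr(ln, 22L, 22L),
    res_seq = as.integer(num(23L, 26L, "residue number")),
    ins_code = trimws(substr(ln, 27L, 27L)),
    x = num(31L, 38L, "x coordinate"),
    y = num(39L, 46L, "y coordinate"),
    z = num(47L, 54L, "z coordinate"),
    occupancy = ifelse(nzchar(occ_raw), suppressWarnings(as.numeric(occ_raw)), 1),
    b_factor = ifelse(nzchar(bfc_raw), suppressWarnings(as.numeric(bfc_raw)), 0),
    element = trimws(substr(ln, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$occupancy))) atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (any(is.na(atoms$b_factor))) atoms$b_factor[is.na(atoms$b_factor)] <- 0
  blank_el <- !nzchar(atoms$element)
  if (any(blank_el)) atoms$element[blank_el] <- guess_element(atoms$name[blank_el])
  atoms <- resolve_altloc(atoms)
  structure_model(atoms, model_id = model_id)
}

## Keep the highest-occupancy alternate conformer per atom; ties broken by
## altloc letter order. Author numbering is never touched.
resolve_altloc <- function(atoms) {
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$ins_code, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt & duplicated(key) | has_alt & key %in% key[duplicated(key)]])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- order(-atoms$occupancy[idx], atoms$altloc[idx])
    keep[idx[-ord[1L]]] <- FALSE
    message(sprintf("altloc: kept conformer '%s' (occ %.2f) for %s",
                    atoms$altloc[idx[ord[1L]]], atoms$occupancy[idx[ord[1L]]], k))
  }
  atoms[keep, , drop = FALSE]
}

#' Write one or more structure models as a PDB file
#'
#' Output is bit-stable for identical input. A list of models is written as
#' MODEL/ENDMDL blocks (the trajectory format).
#'
#' @param model a `structure_model`, a list of them, or a `trajectory`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  if (inherits(model, "trajectory")) model <- model$frames
  if (inherits(model, "structure_model")) model <- list(model)
  if (!length(model)) stop("nothing to write: empty model list")
  multi <- length(model) > 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(model)) {
    m <- model[[i]]
    if (!inherits(m, "structure_model")) stop("can only write structure_model objects")
    if (n_atoms(m) == 0L) stop("refusing to write an empty atom list")
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_atom_lines(m$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(a) {
  xyz <- as.matrix(a[c("x", "y", "z")])
  if (any(abs(xyz) > 9999.999))
    stop("coordinate out of PDB fixed-width range (|x| must be < 9999.999)")
  if (any(nchar(a$name) > 4L)) stop("atom name longer than 4 characters")
  nm <- ifelse(nchar(a$name) >= 4L, a$name, sprintf(" %-3s", a$name))
  rec <- ifelse(a$res_name %in% c("HOH", "WAT", "SOL"), "HETATM", "ATOM  ")
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm,
          substr(paste0(a$altloc, " "), 1L, 1L),
          a$res_name, a$chain_id, a$res_seq,
          substr(paste0(a$ins_code, " "), 1L, 1L),
          xyz[, 1L], xyz[, 2L], xyz[, 3L], a$occupancy, a$b_factor,
          formatC(a$element, width = 2L))
}

#' Read a trajectory from a multi-model PDB plus a time axis
#'
#' @param path multi-model PDB
#' @param times_csv optional CSV with columns `frame`, `time_ns`
#' @param dt uniform time step (ns) used when no sidecar table is given
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, times_csv = NULL, dt = 1) {
  frames <- read_structure(path)
  if (inherits(frames, "structure_model")) frames <- list(frames)
  if (!is.null(times_csv)) {
    tt <- utils::read.csv(times_csv)
    if (!all(c("frame", "time_ns") %in% names(tt)))
      stop("times sidecar must have columns 'frame' and 'time_ns'")
    tt <- tt[order(tt$frame), ]
    if (nrow(tt) != length(frames))
      stop(sprintf("times table has %d rows but trajectory has %d frames",
                   nrow(tt), length(frames)))
    times <- tt$time_ns
  } else {
    times <- (seq_along(frames) - 1) * dt
  }
  trajectory(frames, times)
}
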