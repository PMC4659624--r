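#' Select atoms from a structure model
#'
#' A small selection language for addressing atoms the way the analyses need
#' to ("backbone of the 11-mer", "heavy atoms of chain R"). Grammar:
#'
#' * keywords: `all`, `backbone` (N, CA, C, O), `heavy` (element != H),
#'   `water` (HOH/WAT/SOL), `protein` (standard residue names)
#' * `chain A B ...`
#' * `resid 382-392 400 ...` (ranges with `-` or `:`)
#' * `name CA CB ...`
#' * combinators: `and`, `or`, `not`, parentheses
#'
#' Selection preserves atom order and never modifies its input. An empty
#' result is allowed but flagged: the returned model carries
#' `attr(, "empty_selection") = TRUE` and has zero rows in `$atoms`.
#'
#' @param model structure_model
#' @param expr selection expression string
#' @return structure_model subset (possibly with zero atoms, flagged)
#' @export
select_atoms <- function(model, expr) {
  stopifnot(inherits(model, "structure_model"))
  mask <- selection_mask(model, expr)
  sub <- model
  sub$atoms <- model$atoms[mask, , drop = FALSE]
  rownames(sub$atoms) <- NULL
  if (!any(mask)) attr(sub, "empty_selection") <- TRUE
  sub
}

#' Logical atom mask for a selection expression
#' @param model structure_model
#' @param expr selection expression (see [select_atoms()])
#' @return logical vector over atoms
#' @export
selection_mask <- function(model, expr) {
  toks <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, model)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection syntax error near '%s'", st$toks[st$pos]))
  mask
}

tokenize_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr)))
    stop("selection expression must be a non-empty string")
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "[[:space:]]+")[[1L]]
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

parse_or <- function(st, model) {
  m <- parse_and(st, model)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    m <- m | parse_and(st, model)
  }
  m
}

parse_and <- function(st, model) {
  m <- parse_unary(st, model)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    m <- m & parse_unary(st, model)
  }
  m
}

parse_unary <- function(st, model) {
  tok <- peek(st)
  if (is.na(tok)) stop("selection expression ended unexpectedly")
  if (tok == "not") {
    advance(st)
    return(!parse_unary(st, model))
  }
  parse_primary(st, model)
}

SELECTION_KEYWORDS <- c("all", "backbone", "heavy", "water", "protein")
RESERVED_TOKENS <- c(SELECTION_KEYWORDS, "and", "or", "not", "chain", "resid", "name", "(", ")")
PROTEIN_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL")
WATER_RESNAMES <- c("HOH", "WAT", "SOL")

parse_primary <- function(st, model) {
  a <- model$atoms
  tok <- peek(st)
  if (is.na(tok)) stop("selection expression ended unexpectedly")
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, model)
    if (is.na(peek(st)) || peek(st) != ")") stop("selection syntax error: missing ')'")
    advance(st)
    return(m)
  }
  if (tok %in% SELECTION_KEYWORDS) {
    advance(st)
    return(switch(tok,
      all = rep(TRUE, nrow(a)),
      backbone = a$name %in% c("N", "CA", "C", "O"),
      heavy = toupper(a$element) != "H",
      water = a$res_name %in% WATER_RESNAMES,
      protein = a$res_name %in% PROTEIN_RESNAMES))
  }
  if (tok %in% c("chain", "name", "resid")) {
    advance(st)
    args <- character(0)
    while (!is.na(peek(st)) && !(peek(st) %in% RESERVED_TOKENS)) {
      args <- c(args, peek(st))
      advance(st)
    }
    if (!length(args))
      stop(sprintf("selection syntax error: '%s' needs at least one argument", tok))
    if (tok == "chain") return(a$chain_id %in% args)
    if (tok == "name") return(a$name %in% args)
    resids <- integer(0)
    for (arg in args) {
      if (grepl("^-?[0-9]+[-:]-?[0-9]+$", arg)) {
        parts <- regmatches(arg, regexec("^(-?[0-9]+)[-:](-?[0-9]+)$", arg))[[1L]]
        resids <- c(resids, seq.int(as.integer(parts[2L]), as.integer(parts[3L])))
      } else if (grepl("^-?[0-9]+$", arg)) {
        resids <- c(resids, as.integer(arg))
      } else {
        stop(sprintf("selection syntax error: bad resid token '%s'", arg))
      }
    }
    return(a$res_seq %in% resids)
  }
  stop(sprintf("selection syntax error: unexpected token '%s'", tok))
}
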