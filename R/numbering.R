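#' Assign Ballesteros-Weinstein generic numbers by anchor propagation
#'
#' GPCR residues are addressed by generic labels "t.pp" (transmembrane helix
#' `t`, position `pp` relative to the most conserved residue `t.50`). The map
#' is propagated arithmetically from anchors: if residue `r` in a segment is
#' anchored at position `pp`, residue `r + k` of the same segment is `pp + k`.
#' No alignment is attempted; author numbering is authoritative.
#'
#' @param model structure_model whose residues are to be numbered
#' @param anchors data.frame with columns `chain`, `res_seq`, `bw_label`
#'   (e.g. "3.50"), `segment_start`, `segment_end` (author numbering of the
#'   helix segment the anchor propagates through)
#' @return object of class `bw_map`: a per-residue table plus lookup support
#' @export
assign_generic_numbers <- function(model, anchors) {
  stopifnot(inherits(model, "structure_model"), is.data.frame(anchors))
  need <- c("chain", "res_seq", "bw_label", "segment_start", "segment_end")
  if (!all(need %in% names(anchors)))
    stop("anchors table needs columns: ", paste(need, collapse = ", "))
  lab <- regmatches(anchors$bw_label,
                    regexec("^([0-9]+)\\.([0-9]+)$", as.character(anchors$bw_label)))
  bad <- vapply(lab, length, 1L) != 3L
  if (any(bad))
    stop("bad BW label(s): ", paste(anchors$bw_label[bad], collapse = ", "))
  tm <- vapply(lab, function(p) as.integer(p[2L]), 1L)
  pos <- vapply(lab, function(p) as.integer(p[3L]), 1L)

  rows <- list()
  seen <- list()  # segment key -> data.frame(res_seq, tm, pos) for conflict check
  for (i in seq_len(nrow(anchors))) {
    seg <- seq.int(anchors$segment_start[i], anchors$segment_end[i])
    if (!(anchors$res_seq[i] %in% seg))
      stop(sprintf("anchor residue %d lies outside its segment %d-%d",
                   anchors$res_seq[i], anchors$segment_start[i], anchors$segment_end[i]))
    offs <- seg - anchors$res_seq[i]
    key <- paste(anchors$chain[i], anchors$segment_start[i], anchors$segment_end[i])
    seg_map <- data.frame(chain_id = as.character(anchors$chain[i]),
                          res_seq = seg, tm = tm[i], pos = pos[i] + offs,
                          stringsAsFactors = FALSE)
    if (!is.null(seen[[key]])) {
      prev <- seen[[key]]
      if (!identical(prev$pos, seg_map$pos) || !identical(prev$tm, seg_map$tm))
        stop(sprintf("conflicting anchors for segment %s: offsets disagree", key))
    }
    seen[[key]] <- seg_map
    rows[[length(rows) + 1L]] <- seg_map
  }
  full <- unique(do.call(rbind, rows))
  dupe <- duplicated(paste(full$chain_id, full$res_seq))
  if (any(dupe)) {
    # same residue reached from two different segments with different labels
    key2 <- paste(full$chain_id, full$res_seq)
    for (k in unique(key2[dupe])) {
      hit <- full[key2 == k, ]
      if (nrow(unique(hit[c("tm", "pos")])) > 1L)
        stop("residue ", k, " receives conflicting BW labels from overlapping segments")
    }
    full <- full[!dupe, ]
  }
  full$bw_label <- sprintf("%d.%d", full$tm, full$pos)
  structure(list(map = full, anchors = anchors), class = "bw_map")
}

#' Look up the BW label of a residue
#'
#' @param numbering a `bw_map`
#' @param chain chain identifier
#' @param res_seq author residue number
#' @param strict if TRUE (default) an unmapped residue is an error; if FALSE
#'   it returns `NA_character_`
#' @return BW label string, e.g. "3.50"
#' @export
bw_lookup <- function(numbering, chain, res_seq, strict = TRUE) {
  stopifnot(inherits(numbering, "bw_map"))
  hit <- numbering$map$bw_label[numbering$map$chain_id == chain &
                                numbering$map$res_seq == res_seq]
  if (!length(hit)) {
    if (strict)
      stop(sprintf("residue %s/%d is outside every numbered segment", chain, res_seq))
    return(NA_character_)
  }
  hit[1L]
}

#' Read a numbering anchor table from CSV
#'
#' Expected header: `chain,res_seq,bw_label,segment_start,segment_end`.
#' @param path CSV file
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("anchors file not found: ", path)
  utils::read.csv(path, colClasses = c(chain = "character", bw_label = "character"))
}

#' @export
print.bw_map <- function(x, ...) {
  cat(sprintf("<bw_map> %d residues in %d segment(s)\n",
              nrow(x$map), nrow(x$anchors)))
  invisible(x)
}
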