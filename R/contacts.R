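#' Contact fingerprint between a peptide and the receptor crevice
#'
#' Runs the hydrogen-bond, cation-pi and nonpolar detectors between receptor
#' and peptide and reports one record per interaction, with the receptor side
#' expressed in Ballesteros-Weinstein generic numbering where the map covers
#' it (unmapped receptor residues keep their raw author number and are
#' flagged). The fingerprint is the basis of functional-state assignment:
#' which peptide residue engages the conserved crevice positions (e.g. the
#' 3.50 arginine and the 3.54 main-chain carbonyl) encodes the binding
#' register.
#'
#' @param receptor structure_model of the receptor (fragment)
#' @param peptide structure_model of the peptide pose
#' @param numbering a `bw_map` for the receptor (optional; raw numbers used
#'   otherwise)
#' @param criteria see [interaction_criteria()]
#' @return object of class `contact_fingerprint`: data.frame with columns
#'   `peptide_res_seq`, `receptor_pos` (BW label or raw number as character),
#'   `receptor_res_seq`, `class` (hbond / cation_pi / nonpolar), `distance`,
#'   `mapped`; the peptide C-terminal residue number is kept as an attribute
#' @export
contact_fingerprint <- function(receptor, peptide, numbering = NULL,
                                criteria = interaction_criteria()) {
  stopifnot(inherits(receptor, "structure_model"),
            inherits(peptide, "structure_model"))
  hb <- detect_hbonds(receptor, peptide, criteria)
  cp <- detect_cation_pi(receptor, peptide, criteria)
  np <- detect_nonpolar(receptor, peptide, criteria)
  rows <- list()
  if (nrow(hb)) {
    pep_is_donor <- hb$direction == "b->a"
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_res_seq = ifelse(pep_is_donor, hb$donor_res_seq, hb$acceptor_res_seq),
      receptor_res_seq = ifelse(pep_is_donor, hb$acceptor_res_seq, hb$donor_res_seq),
      receptor_chain = ifelse(pep_is_donor, hb$acceptor_chain, hb$donor_chain),
      class = "hbond", distance = hb$distance, stringsAsFactors = FALSE)
  }
  if (nrow(cp)) {
    pep_is_cation <- cp$direction == "b->a"
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_res_seq = ifelse(pep_is_cation, cp$cation_res_seq, cp$ring_res_seq),
      receptor_res_seq = ifelse(pep_is_cation, cp$ring_res_seq, cp$cation_res_seq),
      receptor_chain = ifelse(pep_is_cation, cp$ring_chain, cp$cation_chain),
      class = "cation_pi", distance = cp$distance, stringsAsFactors = FALSE)
  }
  if (nrow(np)) {
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_res_seq = np$res_seq_b, receptor_res_seq = np$res_seq_a,
      receptor_chain = np$chain_a,
      class = "nonpolar", distance = np$distance, stringsAsFactors = FALSE)
  }
  fp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide_res_seq = integer(0), receptor_res_seq = integer(0),
               receptor_chain = character(0), class = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(fp)) {
    lab <- vapply(seq_len(nrow(fp)), function(i)
      if (is.null(numbering)) NA_character_ else
        bw_lookup(numbering, fp$receptor_chain[i], fp$receptor_res_seq[i],
                  strict = FALSE),
      character(1L))
    fp$mapped <- !is.na(lab)
    if (!is.null(numbering) && any(!fp$mapped))
      warning("contacting receptor residue(s) outside the numbered segments: ",
              paste(unique(fp$receptor_res_seq[!fp$mapped]), collapse = ", "))
    fp$receptor_pos <- ifelse(fp$mapped, lab, as.character(fp$receptor_res_seq))
  } else {
    fp$mapped <- logical(0)
    fp$receptor_pos <- character(0)
  }
  fp <- fp[c("peptide_res_seq", "receptor_pos", "receptor_res_seq",
             "class", "distance", "mapped")]
  rownames(fp) <- NULL
  pep_prot <- peptide$atoms[peptide$atoms$res_name %in% PROTEIN_RESNAMES, ]
  cterm <- if (nrow(pep_prot)) max(pep_prot$res_seq) else max(peptide$atoms$res_seq)
  structure(fp, class = c("contact_fingerprint", "data.frame"),
            peptide_cterm = cterm)
}

#' Functional-state definitions for the helix-switch register
#'
#' A state is a required contact register: which peptide residue (as an
#' offset from the peptide C-terminus, 0 = C-terminal residue) engages each
#' conserved receptor probe position. The defaults encode the two registers
#' of the switch: in the nucleotide-free-like state the penultimate residue
#' (offset -1) caps the 3.50 arginine and the residue at offset -8 hydrogen
#' bonds the 3.54 main-chain carbonyl; in the GDP-intermediate-like state
#' both contacts are shifted C-terminally by one residue (offsets 0 and -7).
#'
#' @return named list of state definitions (`name`, `register`)
#' @export
default_states <- function() {
  list(
    empty = list(name = "empty",
                 register = list("3.50" = -1L, "3.54" = -8L)),
    gdp_intermediate = list(name = "gdp_intermediate",
                            register = list("3.50" = 0L, "3.54" = -7L))
  )
}

#' Classify a pose from its contact fingerprint
#'
#' Computes, for every contact at a probe position used by the state
#' definitions, the peptide-residue offset from the C-terminus, and asks
#' whether a single uniform register shift relative to the reference (first)
#' state explains all of them. Returns the matching state and the shift
#' (0 for the reference register, +1 for a one-residue C-terminal shift).
#' Contradictory probes or an empty fingerprint give `"other"`, never a
#' silent pick.
#'
#' @param fp a `contact_fingerprint`
#' @param states list of state definitions (see [default_states()]); the
#'   first entry is the reference register for the shift
#' @return list: `state` (label), `register_shift` (integer or NA),
#'   `diagnostics` (per-probe observed offsets)
#' @export
classify_pose <- function(fp, states = default_states()) {
  stopifnot(inherits(fp, "contact_fingerprint"), length(states) >= 1L)
  cterm <- attr(fp, "peptide_cterm")
  ref <- states[[1L]]$register
  probes <- unique(unlist(lapply(states, function(s) names(s$register))))
  obs <- fp[fp$receptor_pos %in% probes, , drop = FALSE]
  diagnostics <- unique(data.frame(probe = obs$receptor_pos,
                                   offset = obs$peptide_res_seq - cterm,
                                   stringsAsFactors = FALSE))
  if (!nrow(obs))
    return(list(state = "other", register_shift = NA_integer_,
                diagnostics = diagnostics))
  shifts <- vapply(seq_len(nrow(diagnostics)), function(i) {
    p <- diagnostics$probe[i]
    if (is.null(ref[[p]])) return(NA_integer_)
    as.integer(diagnostics$offset[i] - ref[[p]])
  }, integer(1L))
  shifts <- shifts[!is.na(shifts)]
  if (!length(shifts) || length(unique(shifts)) != 1L)
    return(list(state = "other", register_shift = NA_integer_,
                diagnostics = diagnostics))
  s <- unique(shifts)
  for (st in states) {
    expected <- ref
    match_st <- all(vapply(names(st$register), function(p) {
      isTRUE(st$register[[p]] == ref[[p]] + s)
    }, logical(1L)))
    if (match_st)
      return(list(state = st$name, register_shift = s, diagnostics = diagnostics))
  }
  list(state = "other", register_shift = s, diagnostics = diagnostics)
}

#' Full interface report between two binding partners
#'
#' Buried and apolar buried interface area, hydrogen bonds, cation-pi
#' contacts, and (when a scene with waters is supplied) the bridging
#' interface-water count.
#'
#' @param a,b structure models of the two partners (no waters)
#' @param scene optional structure model containing both partners plus
#'   waters, used for the water count
#' @param sel_a,sel_b selections of the partners within `scene`
#' @param criteria see [interaction_criteria()]
#' @param ... passed to [sasa()]
#' @return object of class `interface_report`
#' @export
interface_report <- function(a, b, scene = NULL, sel_a = NULL, sel_b = NULL,
                             criteria = interaction_criteria(), ...) {
  burial <- buried_interface_area(a, b, ...)
  hb <- detect_hbonds(a, b, criteria)
  cp <- detect_cation_pi(a, b, criteria)
  nw <- NA_integer_
  if (!is.null(scene)) {
    if (is.null(sel_a) || is.null(sel_b))
      stop("sel_a and sel_b are required when a scene is supplied")
    nw <- count_interface_waters(scene, sel_a, sel_b,
                                 cutoff = criteria$water_cutoff)$count
  }
  structure(list(buried_area = burial$buried_area,
                 apolar_buried_area = burial$apolar_buried_area,
                 total_buried_area = burial$total_buried_area,
                 total_apolar_buried_area = burial$total_apolar_buried_area,
                 hbonds = hb, cation_pi = cp, n_interface_waters = nw,
                 criteria = criteria),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0("<interface_report> buried %.1f A^2 (apolar %.1f), ",
                     "%d H-bond(s), %d cation-pi, %s interface water(s)\n"),
              x$buried_area, x$apolar_buried_area, nrow(x$hbonds),
              nrow(x$cation_pi),
              if (is.na(x$n_interface_waters)) "NA" else x$n_interface_waters))
  invisible(x)
}

#' Write an interface report to JSON
#' @param report interface_report
#' @param path output path
#' @export
write_interface_report <- function(report, path) {
  jsonlite::write_json(
    list(buried_area = report$buried_area,
         apolar_buried_area = report$apolar_buried_area,
         total_buried_area = report$total_buried_area,
         total_apolar_buried_area = report$total_apolar_buried_area,
         n_hbonds = nrow(report$hbonds),
         n_cation_pi = nrow(report$cation_pi),
         n_interface_waters = report$n_interface_waters,
         hbonds = report$hbonds, cation_pi = report$cation_pi,
         criteria = report$criteria),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
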