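#' Default geometric interaction criteria
#'
#' Crystallographic "potential hydrogen bond" geometry without explicit
#' hydrogens: donor-heavy to acceptor distance cutoff with an
#' antecedent-donor-acceptor angle gate; when hydrogens are present the
#' D-H...A angle is used instead. Cation-pi contacts use the ring-centroid to
#' cation distance plus an angle gate between the ring normal and the
#' centroid->cation vector. Nonpolar contacts are C/S atom pairs within a
#' distance cutoff.
#'
#' @param hbond_dmax donor-acceptor heavy-atom cutoff (A)
#' @param hbond_h_angle_min minimal D-H...A angle (degrees) when H is present
#' @param hbond_ant_angle_min minimal antecedent-D...A angle (degrees)
#' @param cation_pi_dmax centroid-cation cutoff (A)
#' @param cation_pi_angle_max maximal angle between ring normal and
#'   centroid->cation vector (degrees)
#' @param nonpolar_dmax apolar C/S contact cutoff (A)
#' @param water_cutoff bridging-water cutoff (A)
#' @export
interaction_criteria <- function(hbond_dmax = 3.5, hbond_h_angle_min = 120,
                                 hbond_ant_angle_min = 90,
                                 cation_pi_dmax = 6.0, cation_pi_angle_max = 45,
                                 nonpolar_dmax = 4.5, water_cutoff = 3.5) {
  list(hbond_dmax = hbond_dmax, hbond_h_angle_min = hbond_h_angle_min,
       hbond_ant_angle_min = hbond_ant_angle_min,
       cation_pi_dmax = cation_pi_dmax, cation_pi_angle_max = cation_pi_angle_max,
       nonpolar_dmax = nonpolar_dmax, water_cutoff = water_cutoff)
}

## Donor atoms (with the bonded antecedent used for the no-hydrogen angle
## proxy) and acceptor atoms, by residue type. "*" applies to all residues.
HB_DONORS <- data.frame(
  res = c("*", "ARG", "ARG", "ARG", "LYS", "GLN", "ASN", "SER", "THR", "TYR",
          "TRP", "HIS", "HIS"),
  atom = c("N", "NE", "NH1", "NH2", "NZ", "NE2", "ND2", "OG", "OG1", "OH",
           "NE1", "ND1", "NE2"),
  antecedent = c("CA", "CZ", "CZ", "CZ", "CE", "CD", "CG", "CB", "CB", "CZ",
                 "CD1", "CG", "CD2"),
  stringsAsFactors = FALSE)

HB_ACCEPTORS <- data.frame(
  res = c("*", "*", "GLU", "GLU", "ASP", "ASP", "GLN", "ASN", "SER", "THR",
          "TYR", "HIS", "HIS", "HOH", "WAT", "SOL"),
  atom = c("O", "OXT", "OE1", "OE2", "OD1", "OD2", "OE1", "OD1", "OG", "OG1",
           "OH", "ND1", "NE2", "O", "O", "OW"),
  stringsAsFactors = FALSE)

atom_is_donor <- function(a) {
  m_specific <- match(paste(a$res_name, a$name), paste(HB_DONORS$res, HB_DONORS$atom))
  wild <- HB_DONORS$res == "*"
  m_wild <- match(a$name, HB_DONORS$atom[wild])
  is_water <- a$res_name %in% WATER_RESNAMES
  is_d <- (!is.na(m_specific) | !is.na(m_wild)) & !is_water
  ant <- ifelse(!is.na(m_specific), HB_DONORS$antecedent[m_specific],
                HB_DONORS$antecedent[wild][m_wild])
  list(is_donor = is_d, antecedent = ant)
}

atom_is_acceptor <- function(a) {
  m <- !is.na(match(paste(a$res_name, a$name), paste(HB_ACCEPTORS$res, HB_ACCEPTORS$atom)))
  wild <- HB_ACCEPTORS$res == "*"
  m | (a$name %in% HB_ACCEPTORS$atom[wild])
}

angle_deg <- function(v1, v2) {
  rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
}

#' Detect hydrogen bonds between two structures
#'
#' Scans donors of one partner against acceptors of the other (both
#' directions). Without explicit hydrogens the geometric criterion is
#' donor-acceptor distance <= `hbond_dmax` plus antecedent-donor-acceptor
#' angle >= `hbond_ant_angle_min`; with hydrogens, the D-H...A angle must be
#' >= `hbond_h_angle_min` for some hydrogen bonded to the donor.
#'
#' @param a,b structure models (disjoint atom sets)
#' @param criteria see [interaction_criteria()]
#' @return data.frame of hydrogen bonds: donor/acceptor chain, residue, atom,
#'   heavy-atom distance (A), angle used (degrees, NA when no geometry gate
#'   applied), and `direction` ("a->b" means the donor is in `a`)
#' @export
detect_hbonds <- function(a, b, criteria = interaction_criteria()) {
  out <- rbind(scan_hbonds(a, b, criteria, "a->b"),
               scan_hbonds(b, a, criteria, "b->a"))
  rownames(out) <- NULL
  out
}

scan_hbonds <- function(da, ab, criteria, direction) {
  empty <- data.frame(donor_chain = character(0), donor_res_seq = integer(0),
                      donor_res = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_res_seq = integer(0),
                      acceptor_res = character(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  A <- da$atoms; B <- ab$atoms
  don <- atom_is_donor(A)
  di <- which(don$is_donor)
  ai <- which(atom_is_acceptor(B))
  if (!length(di) || !length(ai)) return(empty)
  DA <- as.matrix(A[di, c("x", "y", "z")])
  AC <- as.matrix(B[ai, c("x", "y", "z")])
  rows <- list()
  for (k in seq_along(di)) {
    dists <- sqrt(rowSums(sweep(AC, 2L, DA[k, ])^2))
    hits <- which(dists <= criteria$hbond_dmax)
    if (!length(hits)) next
    i <- di[k]
    # explicit hydrogens bonded to this donor (same residue, H element, < 1.25 A)
    hsel <- which(A$chain_id == A$chain_id[i] & A$res_seq == A$res_seq[i] &
                  toupper(A$element) == "H")
    if (length(hsel)) {
      hxyz <- as.matrix(A[hsel, c("x", "y", "z")])
      hd <- sqrt(rowSums(sweep(hxyz, 2L, DA[k, ])^2))
      hsel <- hsel[hd < 1.25]
    }
    for (h in hits) {
      ang <- NA_real_
      ok <- TRUE
      if (length(hsel)) {
        angs <- vapply(hsel, function(hidx) {
          hp <- as.numeric(A[hidx, c("x", "y", "z")])
          angle_deg(DA[k, ] - hp, AC[h, ] - hp)
        }, numeric(1L))
        ang <- max(angs)
        ok <- ang >= criteria$hbond_h_angle_min
      } else {
        antn <- don$antecedent[i]
        j <- which(A$chain_id == A$chain_id[i] & A$res_seq == A$res_seq[i] &
                   A$name == antn)
        if (length(j)) {
          ap <- as.numeric(A[j[1L], c("x", "y", "z")])
          ang <- angle_deg(ap - DA[k, ], AC[h, ] - DA[k, ])
          ok <- ang >= criteria$hbond_ant_angle_min
        }
      }
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = A$chain_id[i], donor_res_seq = A$res_seq[i],
        donor_res = A$res_name[i], donor_atom = A$name[i],
        acceptor_chain = B$chain_id[ai[h]], acceptor_res_seq = B$res_seq[ai[h]],
        acceptor_res = B$res_name[ai[h]], acceptor_atom = B$name[ai[h]],
        distance = dists[h], angle = ang, direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

CATION_ATOMS <- list(ARG = "CZ", LYS = "NZ")

ring_geometry <- function(atoms, chain, res_seq, res_name) {
  want <- RING_ATOMS[[res_name]]
  idx <- match(want, atoms$name[atoms$chain_id == chain & atoms$res_seq == res_seq])
  sub <- atoms[atoms$chain_id == chain & atoms$res_seq == res_seq, ]
  pos <- sub[match(want, sub$name), c("x", "y", "z")]
  if (any(is.na(pos))) return(NULL)
  P <- as.matrix(pos)
  centroid <- colMeans(P)
  sv <- svd(sweep(P, 2L, centroid))
  list(centroid = centroid, normal = sv$v[, 3L])
}

#' Detect cation-pi contacts between two structures
#'
#' Cations are the Arg guanidinium (CZ) and Lys NZ; pi systems are Phe/Tyr
#' six-rings, the Trp indole six-ring, and the His five-ring. A contact is
#' reported when the ring-centroid to cation distance is within the cutoff
#' and the angle between the ring normal and the centroid->cation vector is
#' within the gate (the cation must sit over the ring face, not in-plane).
#'
#' @param a,b structure models; cations and rings are scanned on both sides
#' @param criteria see [interaction_criteria()]
#' @return data.frame: cation chain/residue, ring chain/residue, centroid
#'   distance (A), off-normal angle (degrees)
#' @export
detect_cation_pi <- function(a, b, criteria = interaction_criteria()) {
  out <- rbind(scan_cation_pi(a, b, criteria, "a->b"),
               scan_cation_pi(b, a, criteria, "b->a"))
  rownames(out) <- NULL
  out
}

scan_cation_pi <- function(cat_side, ring_side, criteria, direction) {
  empty <- data.frame(cation_chain = character(0), cation_res_seq = integer(0),
                      cation_res = character(0),
                      ring_chain = character(0), ring_res_seq = integer(0),
                      ring_res = character(0), distance = numeric(0),
                      angle = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  A <- cat_side$atoms; B <- ring_side$atoms
  cat_idx <- which(paste(A$res_name, A$name) %in%
                   paste(names(CATION_ATOMS), unlist(CATION_ATOMS)))
  ring_res <- unique(B[B$res_name %in% names(RING_ATOMS),
                       c("chain_id", "res_seq", "res_name")])
  if (!length(cat_idx) || !nrow(ring_res)) return(empty)
  rows <- list()
  for (r in seq_len(nrow(ring_res))) {
    g <- ring_geometry(B, ring_res$chain_id[r], ring_res$res_seq[r],
                       ring_res$res_name[r])
    if (is.null(g)) {
      warning(sprintf("residue %s/%d %s lacks ring atoms; skipped",
                      ring_res$chain_id[r], ring_res$res_seq[r],
                      ring_res$res_name[r]))
      next
    }
    for (i in cat_idx) {
      cp <- as.numeric(A[i, c("x", "y", "z")])
      v <- cp - g$centroid
      d <- vnorm(v)
      if (d > criteria$cation_pi_dmax) next
      ang <- angle_deg(g$normal, v)
      ang <- min(ang, 180 - ang)  # normal orientation is arbitrary
      if (ang > criteria$cation_pi_angle_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        cation_chain = A$chain_id[i], cation_res_seq = A$res_seq[i],
        cation_res = A$res_name[i],
        ring_chain = ring_res$chain_id[r], ring_res_seq = ring_res$res_seq[r],
        ring_res = ring_res$res_name[r], distance = d, angle = ang,
        direction = direction, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Detect nonpolar (apolar carbon/sulfur) contacts between two structures
#'
#' One record per residue pair in contact, carrying the minimal C/S-C/S
#' distance.
#' @param a,b structure models
#' @param criteria see [interaction_criteria()]
#' @export
detect_nonpolar <- function(a, b, criteria = interaction_criteria()) {
  A <- a$atoms[toupper(a$atoms$element) %in% c("C", "S"), , drop = FALSE]
  B <- b$atoms[toupper(b$atoms$element) %in% c("C", "S"), , drop = FALSE]
  empty <- data.frame(res_seq_a = integer(0), chain_a = character(0),
                      res_seq_b = integer(0), chain_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(A) || !nrow(B)) return(empty)
  XA <- as.matrix(A[c("x", "y", "z")])
  XB <- as.matrix(B[c("x", "y", "z")])
  rows <- list()
  for (i in seq_len(nrow(A))) {
    dd <- sqrt(rowSums(sweep(XB, 2L, XA[i, ])^2))
    hit <- which(dd <= criteria$nonpolar_dmax)
    for (h in hit)
      rows[[length(rows) + 1L]] <- data.frame(
        res_seq_a = A$res_seq[i], chain_a = A$chain_id[i],
        res_seq_b = B$res_seq[h], chain_b = B$chain_id[h],
        distance = dd[h], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  all <- do.call(rbind, rows)
  key <- paste(all$chain_a, all$res_seq_a, all$chain_b, all$res_seq_b)
  best <- tapply(seq_len(nrow(all)), key, function(ii) ii[which.min(all$distance[ii])])
  out <- all[sort(unlist(best)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count bridging interface waters
#'
#' A water counts as an interface water when its oxygen lies within `cutoff`
#' of at least one heavy atom of each partner selection.
#'
#' @param scene structure model containing both partners and the waters
#' @param sel_a,sel_b selection expressions for the two partners
#' @param cutoff distance cutoff (A), default 3.5
#' @return list: `count` and `water_ids` (chain/res_seq of bridging waters)
#' @export
count_interface_waters <- function(scene, sel_a, sel_b, cutoff = 3.5) {
  wat <- select_atoms(scene, "water and name O OW")
  if (isTRUE(attr(wat, "empty_selection"))) {
    message("scene contains no waters")
    return(list(count = 0L, water_ids = data.frame(chain_id = character(0),
                                                   res_seq = integer(0))))
  }
  pa <- select_atoms(scene, paste0("(", sel_a, ") and heavy and not water"))
  pb <- select_atoms(scene, paste0("(", sel_b, ") and heavy and not water"))
  if (isTRUE(attr(pa, "empty_selection")) || isTRUE(attr(pb, "empty_selection")))
    stop("a partner selection matches no heavy atoms")
  XW <- coords(wat); XA <- coords(pa); XB <- coords(pb)
  near <- function(X, x) any(rowSums(sweep(X, 2L, x)^2) <= cutoff^2)
  bridging <- vapply(seq_len(nrow(XW)),
                     function(i) near(XA, XW[i, ]) && near(XB, XW[i, ]),
                     logical(1L))
  ids <- wat$atoms[bridging, c("chain_id", "res_seq")]
  rownames(ids) <- NULL
  list(count = sum(bridging), water_ids = ids)
}
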