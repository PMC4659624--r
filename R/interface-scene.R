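## Interface scenes are built on an analytically parametric helix (exact
## cylindrical coordinates: twist 100 degrees, rise 1.5 A per residue) rather
## than the internal-coordinate builder. The exact one-residue screw symmetry
## is the point: side-chain functional atoms of the register residues are
## placed at identical cylindrical offsets, so screwing the peptide by
## (-100 degrees, -1.5 A) moves residue k+1 exactly into the slot residue k
## occupied, and one fixed receptor scaffold satisfies both binding
## registers. Geometry is minimal by design: the scaffold is an arginine
## probe at generic position 3.50 plus a main-chain carbonyl probe at 3.54,
## not a 7-transmembrane receptor.

SCENE_TWIST <- 100   # degrees/residue
SCENE_RISE <- 1.5    # A/residue

cyl <- function(r, az_deg, z) {
  a <- deg2rad(az_deg)
  c(r * cos(a), r * sin(a), z)
}

## per-residue backbone and generic side-chain offsets: (radius, d_azimuth, dz)
SCENE_BB_OFFSETS <- list(
  N = c(1.60, -25, -0.75), CA = c(2.30, 0, 0), C = c(1.70, 25, 0.70),
  O = c(2.00, 45, 0.60), CB = c(3.30, -15, -0.50))

## functional atoms of all register residues sit at the common slot F
SCENE_F <- c(6.5, 0, 0)

SCENE_SIDECHAINS <- list(
  GLN = list(CG = c(4.30, -8, -0.30), CD = c(5.30, -3, -0.10),
             OE1 = c(5.80, 10, 0.50), NE2 = SCENE_F),
  ARG = list(CG = c(4.30, -8, -0.30), CD = c(4.90, -5, -0.20),
             NE = c(5.00, -2, 0.10), CZ = c(5.17, 0, 0),
             NH1 = SCENE_F, NH2 = c(5.60, 12, 0.40)),
  GLU = list(CG = c(4.30, -8, -0.30), CD = c(5.25, -3, 0),
             OE1 = SCENE_F, OE2 = c(5.90, 13, 0.30)))

scene_element <- function(name) substr(name, 1L, 1L)

scene_residue_atoms <- function(res_i, res_name, az0, z0, chain_id, res_seq) {
  rows <- list()
  add <- function(name, off_or_xyz, cylindrical = TRUE) {
    p <- if (cylindrical)
      cyl(off_or_xyz[1L], az0 + off_or_xyz[2L], z0 + off_or_xyz[3L])
    else off_or_xyz
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, res_name = res_name, chain_id = chain_id,
      res_seq = res_seq, x = p[1L], y = p[2L], z = p[3L],
      element = scene_element(name), stringsAsFactors = FALSE)
  }
  for (nm in names(SCENE_BB_OFFSETS)) add(nm, SCENE_BB_OFFSETS[[nm]])
  if (res_name %in% names(SCENE_SIDECHAINS)) {
    for (nm in names(SCENE_SIDECHAINS[[res_name]]))
      add(nm, SCENE_SIDECHAINS[[res_name]][[nm]])
  } else if (res_name == "TYR") {
    # six-ring centered on the functional slot, plane perpendicular to the
    # radial direction (normal points away from the helix axis); CG sits at
    # the ring vertex nearest CB (the -z side)
    centroid <- cyl(SCENE_F[1L], az0, z0 + SCENE_F[3L])
    e_az <- unit(cross3(c(0, 0, 1), unit(centroid * c(1, 1, 0))))
    e_z <- c(0, 0, 1)
    ring <- c(CG = -90, CD1 = -30, CE1 = 30, CZ = 90, CE2 = 150, CD2 = 210)
    for (nm in names(ring)) {
      a <- deg2rad(ring[[nm]])
      add(nm, centroid + 1.39 * (cos(a) * e_az + sin(a) * e_z),
          cylindrical = FALSE)
    }
    add("OH", centroid + 2.77 * e_z, cylindrical = FALSE)
  }
  do.call(rbind, rows)
}

scene_peptide <- function(chain_id = "P", start_res_seq = 382L) {
  seqs <- c("ALA", "ALA", "GLN", "ARG", "ALA", "ALA", "ALA", "ALA", "ALA",
            "TYR", "GLU")
  rows <- lapply(seq_along(seqs), function(k)
    scene_residue_atoms(k, seqs[k], az0 = (k - 1L) * SCENE_TWIST,
                        z0 = (k - 1L) * SCENE_RISE,
                        chain_id = chain_id,
                        res_seq = start_res_seq + k - 1L))
  structure_model(do.call(rbind, rows))
}

## The two functional slots of the unshifted (empty-register) peptide:
## where Y391's ring centroid and Q384's NE2 sit.
scene_slot <- function(res_index) {  # 1-based residue index on the 11-mer
  c(az = (res_index - 1L) * SCENE_TWIST, z = (res_index - 1L) * SCENE_RISE)
}

scene_receptor <- function(chain_id = "R") {
  sY <- scene_slot(10L)  # Y391 slot: generic position 3.50 probe
  sQ <- scene_slot(3L)   # Q384 slot: generic position 3.54 carbonyl probe
  rows <- list()
  add <- function(name, res_name, res_seq, r, daz, dz, base) {
    p <- cyl(r, base[["az"]] + daz, base[["z"]] + dz)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, res_name = res_name, chain_id = chain_id,
      res_seq = res_seq, x = p[1L], y = p[2L], z = p[3L],
      element = scene_element(name), stringsAsFactors = FALSE)
  }
  # Arg probe at 3.50: guanidinium pointing down the ring normal so that the
  # cation sits over the ring face (empty register) and NH1 reaches the
  # carboxylate slot (shifted register)
  add("NH1", "ARG", 131L, 9.17, 0, 0, sY)
  add("CZ", "ARG", 131L, 10.50, 0, 0, sY)
  add("NH2", "ARG", 131L, 11.00, 6, -0.30, sY)
  add("NE", "ARG", 131L, 11.20, -6, 0.40, sY)
  add("CD", "ARG", 131L, 12.40, -8, 0.70, sY)
  add("CG", "ARG", 131L, 13.50, -6, 0.50, sY)
  add("CB", "ARG", 131L, 14.50, -3, 0.10, sY)
  add("CA", "ARG", 131L, 15.70, -2, -0.20, sY)
  add("N", "ARG", 131L, 16.30, -6, -0.70, sY)
  add("C", "ARG", 131L, 16.50, 2, 0.30, sY)
  add("O", "ARG", 131L, 16.20, 7, 0.70, sY)
  # connecting strand 132-134 (out of contact range by construction)
  ca131 <- c(15.70, sY[["az"]] - 2, sY[["z"]] - 0.20)
  ca135 <- c(11.90, sQ[["az"]] - 2 + 360, sQ[["z"]] + 0.10)  # unwrap azimuth
  for (k in 1:3) {
    f <- k / 4
    r <- (1 - f) * ca131[1L] + f * ca135[1L]
    az <- (1 - f) * ca131[2L] + f * ca135[2L]
    z <- (1 - f) * ca131[3L] + f * ca135[3L]
    rs <- 131L + k
    base <- c(az = az, z = z)
    add("N", "ALA", rs, r + 0.8, -4, 0.50, base)
    add("CA", "ALA", rs, r, 0, 0, base)
    add("C", "ALA", rs, r + 0.3, 4, -0.50, base)
    add("O", "ALA", rs, r + 1.2, 6, -0.70, base)
  }
  # Ile probe at 3.54: main-chain carbonyl acceptor facing the NE2/NH1 slot
  add("O", "ILE", 135L, 9.40, 0, 0, sQ)
  add("C", "ILE", 135L, 10.60, 0, 0, sQ)
  add("CA", "ILE", 135L, 11.90, -2, 0.10, sQ)
  add("N", "ILE", 135L, 12.60, -6, -0.30, sQ)
  add("CB", "ILE", 135L, 12.90, 2, 0.50, sQ)
  structure_model(do.call(rbind, rows))
}

scene_waters <- function(n_bridging, n_bulk, chain_id = "W") {
  rows <- list()
  add_water <- function(res_seq, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = "O", res_name = "HOH", chain_id = chain_id, res_seq = res_seq,
      x = p[1L], y = p[2L], z = p[3L], element = "O", stringsAsFactors = FALSE)
  }
  sQ <- scene_slot(3L)
  mid <- cyl((6.5 + 9.4) / 2, sQ[["az"]], sQ[["z"]])
  radial <- unit(mid * c(1, 1, 0))
  e1 <- unit(cross3(c(0, 0, 1), radial))
  e2 <- c(0, 0, 1)
  if (n_bridging > 0) {
    for (i in seq_len(n_bridging)) {
      a <- 2 * pi * (i - 1L) / max(n_bridging, 1L)
      add_water(i, mid + 2.0 * (cos(a) * e1 + sin(a) * e2))
    }
  }
  if (n_bulk > 0) {
    ctr <- c(0, 0, 7.5)
    for (i in seq_len(n_bulk)) {
      dir <- unit(stats::rnorm(3L))
      add_water(n_bridging + i, ctr + stats::runif(1L, 30, 40) * dir)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Interface-scene specification
#'
#' @param register "empty" (nucleotide-free-like contacts: penultimate
#'   tyrosine caps the 3.50 arginine, the -8 glutamine hydrogen bonds the
#'   3.54 carbonyl) or "gdp_intermediate" (both contacts shifted C-terminally
#'   by one residue: C-terminal glutamate to 3.50, the -7 arginine to 3.54)
#' @param n_bridging_waters waters bridging the two partners (default 3)
#' @param n_bulk_waters distant waters (default 20)
#' @param jitter_sigma per-coordinate Gaussian jitter (A, default 0.02)
#' @param global_motion apply a seeded random rigid motion to the whole scene
#' @param seed RNG seed
#' @export
interface_scene_spec <- function(register = c("empty", "gdp_intermediate"),
                                 n_bridging_waters = 3L, n_bulk_waters = 20L,
                                 jitter_sigma = 0.02, global_motion = TRUE,
                                 seed = 1L) {
  register <- match.arg(register)
  if (n_bridging_waters < 0 || n_bulk_waters < 0)
    stop("water counts must be >= 0")
  list(register = register, n_bridging_waters = as.integer(n_bridging_waters),
       n_bulk_waters = as.integer(n_bulk_waters),
       jitter_sigma = jitter_sigma, global_motion = isTRUE(global_motion),
       seed = as.integer(seed))
}

random_rigid_transform <- function(max_translation = 10) {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  Rm <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                 2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                 2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
               3L, 3L, byrow = TRUE)
  rigid_transform(Rm, stats::runif(3L, -max_translation, max_translation))
}

#' Generate a synthetic receptor-peptide interface scene
#'
#' Builds a minimal receptor scaffold (an arginine probe at generic position
#' 3.50 and a main-chain carbonyl probe at 3.54) plus an 11-mer peptide helix
#' placed so the requested register's contacts satisfy the default detector
#' criteria, bridging waters within the bridging cutoff of both partners, and
#' distant bulk waters. The peptide of the "gdp_intermediate" register is the
#' "empty" peptide screw-transformed by exactly (-100 degrees, -1.5 A) about
#' the helix axis -- the helix's own one-residue symmetry -- which shifts
#' every probe contact C-terminally by one residue.
#'
#' @param spec an [interface_scene_spec()]
#' @return list of class `interface_scene`: `scene` (peptide chain P +
#'   receptor chain R + waters chain W), `receptor`, `peptide`,
#'   `peptide_empty`, `peptide_intermediate` (consistently transformed),
#'   `anchors` (numbering anchor table for the receptor), `expected_fingerprint`
#'   (required register contacts), `planted_screw` (intermediate relative to
#'   empty: angle -100 degrees, slide -1.5 A), `spec`
#' @export
make_interface_scene <- function(spec = interface_scene_spec()) {
  set.seed(spec$seed)
  pep_empty <- scene_peptide()
  z_axis <- screw_params(c(0, 0, 0), c(0, 0, 1), -SCENE_TWIST, -SCENE_RISE)
  pep_inter <- apply_transform(pep_empty, screw_to_transform(z_axis))
  pep_inter$atoms$serial <- pep_empty$atoms$serial
  rec <- scene_receptor()
  wat <- scene_waters(spec$n_bridging_waters, spec$n_bulk_waters)
  jitter <- function(m) {
    if (spec$jitter_sigma <= 0) return(m)
    X <- coords(m)
    set_coords(m, X + matrix(stats::rnorm(length(X), 0, spec$jitter_sigma),
                             ncol = 3L))
  }
  pep_empty <- jitter(pep_empty)
  pep_inter <- jitter(pep_inter)
  rec <- jitter(rec)
  tr <- if (spec$global_motion) random_rigid_transform() else
    rigid_transform()
  pep_empty <- apply_transform(pep_empty, tr)
  pep_inter <- apply_transform(pep_inter, tr)
  rec <- apply_transform(rec, tr)
  pep <- if (spec$register == "empty") pep_empty else pep_inter
  pieces <- list(pep$atoms, rec$atoms)
  if (!is.null(wat)) {
    watm <- apply_transform(jitter(structure_model(wat)), tr)
    pieces <- c(pieces, list(watm$atoms))
  }
  scene_atoms <- do.call(rbind, pieces)
  scene_atoms$serial <- seq_len(nrow(scene_atoms))
  expected <- if (spec$register == "empty")
    data.frame(peptide_res_seq = c(391L, 384L),
               receptor_pos = c("3.50", "3.54"),
               class = c("cation_pi", "hbond"), stringsAsFactors = FALSE)
  else
    data.frame(peptide_res_seq = c(392L, 385L),
               receptor_pos = c("3.50", "3.54"),
               class = c("hbond", "hbond"), stringsAsFactors = FALSE)
  structure(list(
    scene = structure_model(scene_atoms),
    receptor = rec, peptide = pep,
    peptide_empty = pep_empty, peptide_intermediate = pep_inter,
    anchors = data.frame(chain = "R", res_seq = 131L, bw_label = "3.50",
                         segment_start = 131L, segment_end = 135L,
                         stringsAsFactors = FALSE),
    expected_fingerprint = expected,
    planted_screw = c(angle_deg = -SCENE_TWIST, slide_A = -SCENE_RISE),
    spec = spec), class = "interface_scene")
}

#' Generate a two-register docking pose set over one receptor
#'
#' Emulates the docking outcome behind the register-shift observation: a pose
#' set containing jittered copies of the "empty" and "gdp_intermediate"
#' placements of the peptide against a single receptor scaffold. The planted
#' inter-register screw is the helix's one-residue symmetry
#' (-100 degrees, -1.5 A).
#'
#' @param sizes poses per register, `c(empty, gdp_intermediate)`
#' @param jitter_sigma per-coordinate pose jitter (A)
#' @param seed RNG seed
#' @return list: `poses` (a `pose_set` with planted labels 1 = empty,
#'   2 = gdp_intermediate), `receptor`, `anchors`, `planted_screw`, `labels`
#' @export
make_register_pose_set <- function(sizes = c(11L, 6L), jitter_sigma = 0.05,
                                   seed = 1L) {
  scn <- make_interface_scene(interface_scene_spec(
    register = "empty", n_bridging_waters = 0L, n_bulk_waters = 0L,
    jitter_sigma = 0, global_motion = FALSE, seed = seed))
  set.seed(seed)
  labels <- rep(c(1L, 2L), sizes)
  perm <- sample(length(labels))
  labels <- labels[perm]
  poses <- lapply(seq_along(labels), function(i) {
    base <- if (labels[i] == 1L) scn$peptide_empty else scn$peptide_intermediate
    X <- coords(base)
    p <- set_coords(base, X + matrix(stats::rnorm(length(X), 0, jitter_sigma),
                                     ncol = 3L))
    p$model_id <- i
    p
  })
  list(poses = pose_set(poses, labels = labels), labels = labels,
       receptor = scn$receptor, anchors = scn$anchors,
       planted_screw = scn$planted_screw)
}
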