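## Canonical peptide internal coordinates (textbook values, force-field
## independent). Overridable through the spec.
default_internal_coords <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
       b_ca_cb = 1.521,
       a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
       a_ca_c_o = 120.5, a_n_ca_cb = 110.4)
}

## Place atom D given A, B, C with bond |C-D|, angle B-C-D (deg) and
## torsion A-B-C-D (deg): the standard internal-to-Cartesian (NeRF) step.
place_atom <- function(A, B, C, bond, angle, torsion) {
  bc <- unit(C - B)
  ab <- B - A
  n <- unit(cross3(ab, bc))
  m <- cross3(n, bc)
  ang <- deg2rad(180 - angle)
  tor <- deg2rad(torsion)
  d_local <- bond * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL")

#' Helix specification for the ideal-helix builder
#'
#' @param sequence one-letter sequence, length >= 5 (default poly-Ala 11-mer,
#'   the peptide length most simulations use)
#' @param phi,psi,omega backbone dihedrals in degrees. The defaults
#'   (-64 / -42 / 180) are calibrated so that, together with the standard
#'   bond geometry, the built helix realizes the canonical alpha-helix
#'   rise (~1.5 A/residue) and twist (~99 degrees/residue); textbook
#'   alpha-helical dihedrals near -57/-47 combined with the standard
#'   tau = 111.2 degree backbone angle yield a noticeably stretched helix
#'   (rise ~1.56 A).
#' @param start_res_seq author number of the first residue
#' @param chain_id chain identifier
#' @param internal bond length/angle table, see source for defaults
#' @export
helix_spec <- function(sequence = strrep("A", 11L), phi = -64, psi = -42,
                       omega = 180, start_res_seq = 1L, chain_id = "A",
                       internal = default_internal_coords()) {
  if (nchar(sequence) < 5L) stop("helix sequence must have at least 5 residues")
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  if (any(!letters1 %in% names(AA_1TO3)))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[!letters1 %in% names(AA_1TO3)]), collapse = ", "))
  list(sequence = sequence, phi = phi, psi = psi, omega = omega,
       start_res_seq = as.integer(start_res_seq), chain_id = chain_id,
       internal = internal)
}

#' Build an ideal alpha-helical peptide from internal coordinates
#'
#' Constructs backbone N/CA/C/O (plus CB for non-glycine) atoms residue by
#' residue from standard bond lengths, bond angles and the spec's phi/psi/
#' omega dihedrals. Deterministic. With the alpha-helical defaults the result
#' has the canonical helix geometry (rise ~1.5 A and twist ~100 degrees per
#' residue).
#'
#' @param spec a [helix_spec()]
#' @return `structure_model` with atoms in N->C order
#' @export
build_ideal_helix <- function(spec = helix_spec()) {
  ic <- spec$internal
  letters1 <- strsplit(toupper(spec$sequence), "")[[1L]]
  n <- length(letters1)
  N <- CA <- C <- vector("list", n)
  # first residue in a canonical local frame
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(ic$b_n_ca, 0, 0)
  ang <- deg2rad(180 - ic$a_n_ca_c)
  C[[1L]] <- CA[[1L]] + ic$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L) + 1L) {
    N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         ic$b_c_n, ic$a_ca_c_n, spec$psi)
    CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          ic$b_n_ca, ic$a_c_n_ca, spec$omega)
    C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                         ic$b_ca_c, ic$a_n_ca_c, spec$phi)
  }
  rows <- list()
  add <- function(res_i, name, xyz, element) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, res_name = AA_1TO3[[letters1[res_i]]],
      chain_id = spec$chain_id,
      res_seq = spec$start_res_seq + res_i - 1L,
      x = xyz[1L], y = xyz[2L], z = xyz[3L], element = element,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add(i, "N", N[[i]], "N")
    add(i, "CA", CA[[i]], "C")
    add(i, "C", C[[i]], "C")
    # carbonyl O anti to the following N (torsion psi + 180 about N-CA-C)
    O <- place_atom(N[[i]], CA[[i]], C[[i]], ic$b_c_o, ic$a_ca_c_o,
                    spec$psi + 180)
    add(i, "O", O, "O")
    if (letters1[i] != "G") {
      CB <- place_atom(C[[i]], N[[i]], CA[[i]], ic$b_ca_cb, ic$a_n_ca_cb,
                       -122.6)
      add(i, "CB", CB, "C")
    }
  }
  atoms <- do.call(rbind, rows)
  structure_model(atoms)
}
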