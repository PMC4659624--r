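atom_model <- function(xyz, element = "C", res_name = "ALA") {
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  structure_model(data.frame(
    name = paste0(element, seq_len(nrow(xyz))), res_name = res_name,
    chain_id = "A", res_seq = seq_len(nrow(xyz)),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], element = element))
}

test_that("sasa reproduces the closed forms for isolated and distant spheres", {
  lone <- atom_model(c(0, 0, 0))
  a <- sasa(lone, probe = 1.4, n_points = 960L)
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.01)
  two_far <- atom_model(c(0, 0, 0, 100, 0, 0))
  expect_equal(sum(sasa(two_far)), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  expect_error(sasa(lone, n_points = 50L), "at least 100")
  unknown <- atom_model(c(0, 0, 0), element = "X")
  expect_error(sasa(unknown), "no radius")
  expect_equal(sum(sasa(unknown, fallback_radius = 1.7)),
               4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("two overlapping spheres match the analytic cap formula", {
  r1 <- 1.7 + 1.4
  r2 <- 1.52 + 1.4
  for (d in c(1.5, 2.5, 3.5, 4.5, 5.5)) {
    m <- structure_model(data.frame(
      name = c("C1", "O1"), res_name = "ALA", chain_id = "A",
      res_seq = c(1L, 2L), x = c(0, d), y = 0, z = 0,
      element = c("C", "O")))
    got <- sasa(m, n_points = 960L)
    want <- oracle_two_sphere_area(r1, r2, d)
    expect_equal(got[1L], want[1L], tolerance = 0.02)
    expect_equal(got[2L], want[2L], tolerance = 0.02)
  }
})

test_that("sasa is invariant under rigid motion and converges with n_points", {
  scn <- make_interface_scene(interface_scene_spec(n_bulk_waters = 0L,
                                                   seed = 2L))
  pep <- scn$peptide
  ref <- sum(sasa(pep, n_points = 960L))
  drift <- vapply(1:20, function(seed) {
    moved <- apply_transform(pep, random_rigid(seed))
    abs(sum(sasa(moved, n_points = 960L)) - ref) / ref
  }, numeric(1L))
  # the fixed quadrature lattice leaves a small orientation dependence;
  # 960 points keep it below 0.75% on this fixture
  expect_lt(max(drift), 0.0075)
  # quadrature refinement converges toward the fine-grid value
  fine <- sum(sasa(pep, n_points = 3840L))
  errs <- vapply(c(240L, 960L), function(np)
    abs(sum(sasa(pep, n_points = np)) - fine), numeric(1L))
  expect_lt(errs[2L], errs[1L])
})

test_that("buried interface area is symmetric, zero at distance, and sane", {
  scn <- make_interface_scene(interface_scene_spec(n_bulk_waters = 0L,
                                                   n_bridging_waters = 0L,
                                                   seed = 3L))
  ab <- buried_interface_area(scn$receptor, scn$peptide, n_points = 480L)
  ba <- buried_interface_area(scn$peptide, scn$receptor, n_points = 480L)
  expect_equal(ab$buried_area, ba$buried_area, tolerance = 1e-12)
  expect_gt(ab$buried_area, 0)
  expect_gte(ab$apolar_buried_area, 0)
  expect_lte(ab$apolar_buried_area, ab$buried_area)
  expect_equal(ab$total_buried_area, 2 * ab$buried_area)

  pep_far <- set_coords(scn$peptide, coords(scn$peptide) + 100)
  far <- buried_interface_area(scn$receptor, pep_far, n_points = 480L)
  expect_equal(far$buried_area, 0, tolerance = 1e-9)
  expect_error(buried_interface_area(scn$peptide, scn$peptide), "disjoint")
})

test_that("buried area of a toy dimer matches the cap-overlap oracle", {
  # single-atom partners: burial must equal half the lost cap areas
  a <- atom_model(c(0, 0, 0))
  b <- atom_model(c(3, 0, 0), element = "O")
  got <- buried_interface_area(a, b, n_points = 1920L)
  iso <- c(4 * pi * 3.1^2, 4 * pi * 2.92^2)
  pair <- oracle_two_sphere_area(3.1, 2.92, 3)
  expect_equal(got$buried_area, sum(iso - pair) / 2, tolerance = 0.02)
})

test_that("hydrogen bond detection follows the geometric criteria", {
  # carbonyl O facing an amide N at 2.9 A with the antecedent behind
  donor <- structure_model(data.frame(
    name = c("CA", "N"), res_name = "ALA", chain_id = "A", res_seq = 1L,
    x = c(-1.2, 0), y = 0, z = 0, element = c("C", "N")))
  acc <- function(d) structure_model(data.frame(
    name = "O", res_name = "ALA", chain_id = "B", res_seq = 5L,
    x = d, y = 0, z = 0, element = "O"))
  hb <- detect_hbonds(donor, acc(2.9))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9)
  expect_identical(hb$donor_atom, "N")
  expect_equal(nrow(detect_hbonds(donor, acc(4.2))), 0L)
  # angle gate: acceptor on the same side as the antecedent
  behind <- structure_model(data.frame(
    name = "O", res_name = "ALA", chain_id = "B", res_seq = 5L,
    x = -2.9, y = 0, z = 0, element = "O"))
  expect_equal(nrow(detect_hbonds(donor, behind)), 0L)
})

test_that("explicit hydrogens switch the criterion to the D-H...A angle", {
  donor_h <- structure_model(data.frame(
    name = c("CA", "N", "H"), res_name = "ALA", chain_id = "A", res_seq = 1L,
    x = c(-1.2, 0, 1.0), y = 0, z = 0, element = c("C", "N", "H")))
  straight <- structure_model(data.frame(
    name = "O", res_name = "ALA", chain_id = "B", res_seq = 2L,
    x = 2.9, y = 0, z = 0, element = "O"))
  expect_equal(nrow(detect_hbonds(donor_h, straight)), 1L)
  # acceptor at 90 degrees from the N-H direction, still within distance
  bent <- structure_model(data.frame(
    name = "O", res_name = "ALA", chain_id = "B", res_seq = 2L,
    x = 0, y = 2.9, z = 0, element = "O"))
  expect_equal(nrow(detect_hbonds(donor_h, bent)), 0L)
})

test_that("hbond scan equals a brute-force all-pairs scan on random scenes", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15L
    mk <- function(chain) structure_model(data.frame(
      name = sample(c("N", "O", "CA"), n, replace = TRUE),
      res_name = "GLY", chain_id = chain, res_seq = seq_len(n),
      x = runif(n, 0, 12), y = runif(n, 0, 12), z = runif(n, 0, 12),
      element = NA_character_, stringsAsFactors = FALSE) |>
        transform(element = substr(name, 1L, 1L)))
    a <- mk("A"); b <- mk("B")
    hb <- detect_hbonds(a, b)
    # brute force with identical rules (backbone N donor with CA antecedent
    # when present, O acceptor)
    brute <- 0L
    for (i in which(a$atoms$name == "N")) for (j in which(b$atoms$name == "O")) {
      pi_ <- as.numeric(a$atoms[i, c("x", "y", "z")])
      pj <- as.numeric(b$atoms[j, c("x", "y", "z")])
      if (sqrt(sum((pi_ - pj)^2)) > 3.5) next
      ant <- which(a$atoms$res_seq == a$atoms$res_seq[i] & a$atoms$name == "CA")
      ok <- TRUE
      if (length(ant)) {
        pa <- as.numeric(a$atoms[ant[1L], c("x", "y", "z")])
        cosang <- sum((pa - pi_) * (pj - pi_)) /
          (sqrt(sum((pa - pi_)^2)) * sqrt(sum((pj - pi_)^2)))
        ok <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= 90
      }
      if (ok) brute <- brute + 1L
    }
    for (i in which(b$atoms$name == "N")) for (j in which(a$atoms$name == "O")) {
      pi_ <- as.numeric(b$atoms[i, c("x", "y", "z")])
      pj <- as.numeric(a$atoms[j, c("x", "y", "z")])
      if (sqrt(sum((pi_ - pj)^2)) > 3.5) next
      ant <- which(b$atoms$res_seq == b$atoms$res_seq[i] & b$atoms$name == "CA")
      ok <- TRUE
      if (length(ant)) {
        pa <- as.numeric(b$atoms[ant[1L], c("x", "y", "z")])
        cosang <- sum((pa - pi_) * (pj - pi_)) /
          (sqrt(sum((pa - pi_)^2)) * sqrt(sum((pj - pi_)^2)))
        ok <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= 90
      }
      if (ok) brute <- brute + 1L
    }
    expect_equal(nrow(hb), brute, info = paste("seed", seed))
  }
})

test_that("cation-pi detection respects distance and the angular gate", {
  ring <- function() {
    ang <- seq(0, 300, by = 60) * pi / 180
    structure_model(data.frame(
      name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      res_name = "TYR", chain_id = "A", res_seq = 1L,
      x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0, element = "C"))
  }
  arg_at <- function(p) structure_model(data.frame(
    name = "CZ", res_name = "ARG", chain_id = "B", res_seq = 9L,
    x = p[1L], y = p[2L], z = p[3L], element = "C"))
  hit <- detect_cation_pi(arg_at(c(0, 0, 4)), ring())
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 4, tolerance = 1e-9)
  # same distance but in-plane: rejected by the angular gate
  expect_equal(nrow(detect_cation_pi(arg_at(c(4, 0, 0)), ring())), 0L)
  # beyond the distance cutoff
  expect_equal(nrow(detect_cation_pi(arg_at(c(0, 0, 6.5)), ring())), 0L)
  # incomplete ring: skipped with a warning
  broken <- ring()
  broken$atoms <- broken$atoms[-2L, ]
  expect_warning(out <- detect_cation_pi(arg_at(c(0, 0, 4)), broken),
                 "ring atoms")
  expect_equal(nrow(out), 0L)
})

test_that("bridging waters are counted by the two-sided distance rule", {
  scn <- make_interface_scene(interface_scene_spec(n_bridging_waters = 3L,
                                                   n_bulk_waters = 50L,
                                                   seed = 17L))
  res <- count_interface_waters(scn$scene, "chain P", "chain R")
  expect_equal(res$count, 3L)
  expect_equal(nrow(res$water_ids), 3L)
  counts <- vapply(c(1.0, 2.0, 2.5, 3.5, 6),
                   function(co) count_interface_waters(scn$scene, "chain P",
                                                       "chain R", cutoff = co)$count,
                   integer(1L))
  expect_true(all(diff(counts) >= 0))
  # no waters: zero with a notice
  dry <- make_interface_scene(interface_scene_spec(n_bridging_waters = 0L,
                                                   n_bulk_waters = 0L, seed = 1L))
  expect_message(none <- count_interface_waters(dry$scene, "chain P", "chain R"),
                 "no waters")
  expect_equal(none$count, 0L)
})

test_that("interface report assembles burial, bonds and waters", {
  scn <- make_interface_scene(interface_scene_spec(seed = 23L))
  rep_ <- interface_report(scn$receptor, scn$peptide, scene = scn$scene,
                           sel_a = "chain P", sel_b = "chain R",
                           n_points = 480L)
  expect_s3_class(rep_, "interface_report")
  expect_gt(rep_$buried_area, 0)
  expect_gte(nrow(rep_$hbonds), 1L)
  expect_equal(rep_$n_interface_waters, 3L)
  f <- withr::local_tempfile(fileext = ".json")
  write_interface_report(rep_, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_interface_waters, 3L)
  expect_equal(back$buried_area, rep_$buried_area, tolerance = 1e-9)
})
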