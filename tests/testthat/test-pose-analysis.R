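test_that("pairwise RMSD matrix matches closed forms and the loop oracle", {
  h <- build_ideal_helix()
  shifted <- set_coords(h, sweep(coords(h), 2L, c(0, 0, -1)))
  D <- pairwise_rmsd_matrix(list(h, h, shifted), selection = "backbone")
  expect_equal(D[1L, 2L], 0)
  expect_equal(D[1L, 3L], 1.0, tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3L))

  set.seed(8)
  poses <- lapply(1:5, function(i)
    set_coords(h, coords(h) + matrix(rnorm(3L * n_atoms(h)), ncol = 3L)))
  D2 <- pairwise_rmsd_matrix(poses, selection = NULL)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D2[i, j], rmsd(coords(poses[[i]]), coords(poses[[j]])))
  expect_error(pairwise_rmsd_matrix(list(h), selection = NULL), "at least 2")
  expect_error(pairwise_rmsd_matrix(poses, selection = "water"), "no atoms")
})

test_that("single linkage at a cutoff equals connected components", {
  # chain a-b 1.0, b-c 1.0, a-c 2.0 at cutoff 1.5: one cluster of 3
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3L)
  cl <- single_linkage_cluster(D, 1.5)
  expect_equal(length(cl$sizes), 1L)
  expect_equal(cl$sizes, 3L)
  # everything apart: n singletons
  far <- matrix(5, 4L, 4L) - diag(5, 4L)
  expect_equal(single_linkage_cluster(far, 1.5)$sizes, rep(1L, 4L))

  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(4:30, 1L)
    X <- matrix(rnorm(2L * n, sd = 2), ncol = 2L)
    D <- as.matrix(dist(X))
    cutoff <- runif(1L, 0.3, 3)
    cl <- single_linkage_cluster(D, cutoff)
    comp <- oracle_components(D, cutoff)
    # same partition: equal label co-membership
    expect_identical(outer(cl$assignment, cl$assignment, "=="),
                     outer(comp, comp, "=="))
    expect_equal(sum(cl$sizes), n)
    expect_true(all(diff(cl$sizes) <= 0))
    for (r in seq_along(cl$sizes))
      expect_true(cl$assignment[cl$representative[r]] == r)
  }
})

test_that("cluster count is monotone non-increasing in the cutoff", {
  for (seed in 1:10) {
    set.seed(seed)
    D <- as.matrix(dist(matrix(rnorm(40L), ncol = 2L)))
    ks <- vapply(c(0.2, 0.5, 1, 2, 4),
                 function(co) length(single_linkage_cluster(D, co)$sizes), 1L)
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("degenerate distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2L)
  expect_error(single_linkage_cluster(D, 1), "symmetric")
  expect_error(single_linkage_cluster(matrix(c(0, -1, -1, 0), 2L), 1),
               "non-negative")
  expect_error(single_linkage_cluster(as.matrix(dist(1:3)), 0), "positive")
})

test_that("planted pose clusters are recovered for cutoffs between jitter and spacing", {
  for (seed in 1:12) {
    gen <- make_pose_set(k_centers = 3L, sizes = c(11L, 6L, 13L),
                         jitter_sigma = 0.15, center_spacing = 3.0,
                         seed = seed)
    D <- pairwise_rmsd_matrix(gen$poses, selection = "backbone")
    cl <- single_linkage_cluster(D, 1.5)
    expect_equal(sort(cl$sizes), sort(c(11L, 6L, 13L)))
    # recovered partition equals the planted labels
    expect_identical(outer(cl$assignment, cl$assignment, "=="),
                     outer(gen$labels, gen$labels, "=="))
  }
})

test_that("contact fingerprints equal a brute-force detector scan", {
  scn <- make_interface_scene(interface_scene_spec(seed = 13L))
  bw <- assign_generic_numbers(scn$receptor, scn$anchors)
  fp <- contact_fingerprint(scn$receptor, scn$peptide, bw)
  # brute force: every donor/acceptor heavy pair, every cation/ring pair
  A <- scn$receptor$atoms
  B <- scn$peptide$atoms
  crit <- interaction_criteria()
  n_hb_brute <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((as.numeric(A[i, c("x", "y", "z")]) -
                   as.numeric(B[j, c("x", "y", "z")]))^2))
    if (d > crit$hbond_dmax) next
    don_a <- paste(A$res_name[i], A$name[i]) %in%
      c("ARG NE", "ARG NH1", "ARG NH2", "GLN NE2", "TYR OH") ||
      (A$name[i] == "N" & A$res_name[i] != "HOH")
    acc_b <- B$name[j] %in% c("O", "OXT") ||
      paste(B$res_name[j], B$name[j]) %in%
        c("GLU OE1", "GLU OE2", "GLN OE1", "TYR OH")
    don_b <- paste(B$res_name[j], B$name[j]) %in%
      c("ARG NE", "ARG NH1", "ARG NH2", "GLN NE2", "TYR OH") ||
      (B$name[j] == "N" & B$res_name[j] != "HOH")
    acc_a <- A$name[i] %in% c("O", "OXT") ||
      paste(A$res_name[i], A$name[i]) %in%
        c("GLU OE1", "GLU OE2", "GLN OE1", "TYR OH")
    if ((don_a && acc_b) || (don_b && acc_a)) n_hb_brute <- n_hb_brute + 1L
  }
  # the detector additionally gates on the antecedent angle; every brute hit
  # here is face-on by construction, so counts must match
  expect_equal(nrow(fp[fp$class == "hbond", ]), n_hb_brute)
  got <- paste(fp$peptide_res_seq, fp$receptor_pos, fp$class)
  for (k in seq_len(nrow(scn$expected_fingerprint))) {
    want <- paste(scn$expected_fingerprint$peptide_res_seq[k],
                  scn$expected_fingerprint$receptor_pos[k],
                  scn$expected_fingerprint$class[k])
    expect_true(want %in% got, info = want)
  }
  # a peptide far away yields an empty fingerprint
  pep_far <- set_coords(scn$peptide, coords(scn$peptide) + 50)
  expect_equal(nrow(contact_fingerprint(scn$receptor, pep_far, bw)), 0L)
})

test_that("register classification separates the two states and flags others", {
  for (seed in 1:10) {
    for (reg in c("empty", "gdp_intermediate")) {
      scn <- make_interface_scene(interface_scene_spec(register = reg,
                                                       seed = seed))
      bw <- assign_generic_numbers(scn$receptor, scn$anchors)
      cls <- classify_pose(contact_fingerprint(scn$receptor, scn$peptide, bw))
      expect_identical(cls$state, reg)
      expect_equal(cls$register_shift, if (reg == "empty") 0L else 1L)
    }
  }
  # empty fingerprint: "other"
  scn <- make_interface_scene(interface_scene_spec(seed = 1L))
  bw <- assign_generic_numbers(scn$receptor, scn$anchors)
  pep_far <- set_coords(scn$peptide, coords(scn$peptide) + 50)
  far_cls <- classify_pose(contact_fingerprint(scn$receptor, pep_far, bw))
  expect_identical(far_cls$state, "other")
  # contradictory register: contacts that no uniform shift explains
  fp <- structure(data.frame(peptide_res_seq = c(392L, 384L),
                             receptor_pos = c("3.50", "3.54"),
                             receptor_res_seq = c(131L, 135L),
                             class = c("hbond", "hbond"),
                             distance = c(3, 3), mapped = TRUE),
                  class = c("contact_fingerprint", "data.frame"),
                  peptide_cterm = 392L)
  mixed <- classify_pose(fp)
  expect_identical(mixed$state, "other")
  expect_equal(nrow(mixed$diagnostics), 2L)
})
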