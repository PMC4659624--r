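test_that("frame alignment undoes planted global motions exactly", {
  sim <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                       slide_target = 0,
                                                       noise_sigma = 0,
                                                       n_frames = 6L,
                                                       onset_time = 2,
                                                       seed = 1L))
  ref <- sim$start_pose
  # translate each frame by a different offset: alignment must restore them
  traj <- sim$trajectory
  for (i in seq_along(traj$frames)) {
    traj$frames[[i]] <- apply_transform(traj$frames[[i]], random_rigid(i))
  }
  aligned <- align_frames(traj, ref, "chain S")
  for (i in seq_along(aligned$frames)) {
    expect_lt(rmsd(coords(aligned$frames[[i]]), coords(ref)), 1e-6)
  }
  # kabsch optimality: aligned selection RMSD never exceeds pre-alignment
  noisy <- make_switch_trajectory(switch_trajectory_spec(n_frames = 6L,
                                                         onset_time = 2,
                                                         seed = 2L))
  al <- align_frames(noisy$trajectory, noisy$start_pose, "chain S")
  for (i in seq_along(al$frames)) {
    sel <- "chain S"
    pre <- rmsd(coords(select_atoms(noisy$trajectory$frames[[i]], sel)),
                coords(select_atoms(noisy$start_pose, sel)))
    post <- rmsd(coords(select_atoms(al$frames[[i]], sel)),
                 coords(select_atoms(noisy$start_pose, sel)))
    expect_lte(post, pre + 1e-12)
  }
})

test_that("rotation series equals the planted ramp without noise", {
  sim <- make_switch_trajectory(switch_trajectory_spec(noise_sigma = 0,
                                                       seed = 3L))
  rot <- rotation_series(sim$trajectory, "chain P and backbone", sim$start_pose)
  expect_equal(rot$values, sim$ground_truth$theta_deg, tolerance = 1e-6)
  # static trajectory: constant zero
  still <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                         slide_target = 0,
                                                         noise_sigma = 0,
                                                         n_frames = 5L,
                                                         onset_time = 2,
                                                         seed = 4L))
  rot0 <- rotation_series(still$trajectory, "chain P and backbone",
                          still$start_pose)
  expect_equal(rot0$values, rep(0, 5L), tolerance = 1e-9)
})

test_that("smoothed rotation tracks the planted ramp under noise", {
  sim <- make_switch_trajectory(switch_trajectory_spec(noise_sigma = 0.3,
                                                       seed = 5L))
  rot <- running_average(rotation_series(sim$trajectory, "chain P and backbone",
                                         sim$start_pose), 5L)
  sm_truth <- running_average(sim$ground_truth$theta_deg, 5L)
  expect_lt(max(abs(rot$smoothed - sm_truth)), 5)
})

test_that("rmsd series reports in-frame displacement without re-superposition", {
  sim <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                       slide_target = 0,
                                                       noise_sigma = 0,
                                                       n_frames = 5L,
                                                       onset_time = 2,
                                                       seed = 6L))
  rs <- rmsd_series(sim$trajectory, "chain P and backbone", sim$start_pose)
  expect_equal(rs$values, rep(0, 5L), tolerance = 1e-12)
  # uniform 2 A shift of the reference: constant 2.0 exactly
  shifted_ref <- sim$start_pose
  mask <- selection_mask(shifted_ref, "chain P")
  X <- coords(shifted_ref)
  X[mask, 3L] <- X[mask, 3L] + 2
  shifted_ref <- set_coords(shifted_ref, X)
  rs2 <- rmsd_series(sim$trajectory, "chain P and backbone", shifted_ref)
  expect_equal(rs2$values, rep(2, 5L), tolerance = 1e-12)
})

test_that("distance series handles centroids, atoms and ring centers", {
  scn <- make_interface_scene(interface_scene_spec(seed = 6L,
                                                   global_motion = FALSE))
  frames <- list(scn$scene, scn$scene)
  tr <- trajectory(frames, times = c(0, 1))
  d <- distance_series(tr, "chain P and resid 391 and name CG CD1 CE1 CZ CE2 CD2",
                       "chain R and resid 131 and name CZ", mode = "centroid")
  # the arginine CZ was planted 4 A down the ring normal
  expect_equal(d$values, rep(4, 2L), tolerance = 0.15)
  # ring centroid equals the mean of the six ring-atom coordinates
  ring <- select_atoms(scn$scene,
                       "chain P and resid 391 and name CG CD1 CE1 CZ CE2 CD2")
  cz <- coords(select_atoms(scn$scene, "chain R and resid 131 and name CZ"))
  expect_equal(d$values[1L], vnorm(colMeans(coords(ring)) - cz[1L, ]),
               tolerance = 1e-12)
  expect_equal(distance_series(tr, "chain P and name CA", "chain P and name CA",
                               mode = "centroid")$values, c(0, 0))
  dmin <- distance_series(tr, "chain P", "chain R", mode = "min")
  expect_lte(dmin$values[1L], d$values[1L])
  expect_error(distance_series(tr, "chain P", "chain R", mode = "atom"),
               "exactly one atom")
})

test_that("running average matches the convolution oracle and keeps edges", {
  expect_equal(running_average(1:7, 1L), as.numeric(1:7))
  expect_equal(running_average(rep(3.5, 9L), 5L), rep(3.5, 9L))
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(40L)
    for (w in c(3L, 5L, 9L)) {
      got <- running_average(x, w)
      h <- (w - 1L) %/% 2L
      want <- vapply(seq_along(x), function(i)
        mean(x[max(1L, i - h):min(length(x), i + h)]), numeric(1L))
      expect_equal(got, want)
    }
  }
  expect_error(running_average(1:10, 4L), "odd")
  expect_error(running_average(1:3, 5L), "longer")
})

test_that("switch detection recovers planted onsets and rejects null runs", {
  hits <- vapply(1:5, function(seed) {
    sim <- make_switch_trajectory(switch_trajectory_spec(seed = seed))
    tr <- align_frames(sim$trajectory, sim$start_pose, "chain S")
    rot <- rotation_series(tr, "chain P and backbone", sim$start_pose)
    rs <- rmsd_series(tr, "chain P and backbone", sim$target_pose)
    ev <- detect_switch(rot, rs)
    expect_true(ev$detected)
    expect_gt(ev$final_rotation, 45)
    abs(ev$onset_time - 50)
  }, numeric(1L))
  expect_lte(stats::median(hits), 2)

  for (seed in 1:5) {
    null <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                          slide_target = 0,
                                                          seed = seed))
    target <- make_switch_trajectory(switch_trajectory_spec(noise_sigma = 0,
                                                            seed = seed))$target_pose
    tr <- align_frames(null$trajectory, null$start_pose, "chain S")
    ev <- detect_switch(rotation_series(tr, "chain P and backbone", null$start_pose),
                        rmsd_series(tr, "chain P and backbone", target))
    expect_false(ev$detected)
  }
})

test_that("switch detection is monotone in the rmsd threshold", {
  sim <- make_switch_trajectory(switch_trajectory_spec(seed = 31L))
  tr <- align_frames(sim$trajectory, sim$start_pose, "chain S")
  rot <- rotation_series(tr, "chain P and backbone", sim$start_pose)
  rs <- rmsd_series(tr, "chain P and backbone", sim$target_pose)
  detected <- vapply(c(0.8, 1.2, 2.0, 2.4),
                     function(thr) detect_switch(rot, rs,
                       thresholds = list(rmsd_switch = thr))$detected,
                     logical(1L))
  expect_true(all(diff(detected) >= 0))
  # an rmsd identically below threshold: detected at the first frame
  flat <- time_series_metric("rmsd", rs$times, rep(0, length(rs$times)), "A")
  ev0 <- detect_switch(rot, flat)
  expect_true(ev0$detected)
  expect_equal(ev0$onset_frame, 1L)
  expect_error(detect_switch(rot, time_series_metric("rmsd", 1:3, 1:3, "A")),
               "time grid")
})

test_that("tilt series recovers a planted re-tilt and flips sign with the normal", {
  sim <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                       slide_target = 0,
                                                       tilt_target = 10,
                                                       noise_sigma = 0,
                                                       seed = 7L))
  ts <- tilt_series(sim$trajectory, "chain P")
  expect_equal(ts$values[1L], 0, tolerance = 1e-6)
  expect_equal(ts$values[length(ts$values)], 10, tolerance = 1e-6)
  flipped <- tilt_series(sim$trajectory, "chain P", membrane_normal = c(0, 0, -1))
  expect_equal(flipped$values, -ts$values, tolerance = 1e-9)
  # static in-plane helix: constant zero
  still <- make_switch_trajectory(switch_trajectory_spec(theta_target = 0,
                                                         slide_target = 0,
                                                         noise_sigma = 0,
                                                         n_frames = 5L,
                                                         onset_time = 2,
                                                         seed = 8L))
  expect_equal(tilt_series(still$trajectory, "chain P")$values, rep(0, 5L),
               tolerance = 1e-6)
})

test_that("metric series survive a common rigid motion of frames and reference", {
  sim <- make_switch_trajectory(switch_trajectory_spec(n_frames = 21L,
                                                       onset_time = 10,
                                                       seed = 9L))
  rot0 <- rotation_series(sim$trajectory, "chain P and backbone", sim$start_pose)
  rms0 <- rmsd_series(sim$trajectory, "chain P and backbone", sim$target_pose)
  for (seed in c(2L, 12L)) {
    tr <- random_rigid(seed)
    traj2 <- sim$trajectory
    traj2$frames <- lapply(traj2$frames, apply_transform, transform = tr)
    ref2 <- apply_transform(sim$start_pose, tr)
    tgt2 <- apply_transform(sim$target_pose, tr)
    expect_equal(rotation_series(traj2, "chain P and backbone", ref2)$values,
                 rot0$values, tolerance = 1e-6)
    expect_equal(rmsd_series(traj2, "chain P and backbone", tgt2)$values,
                 rms0$values, tolerance = 1e-9)
  }
})
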