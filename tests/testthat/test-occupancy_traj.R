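# Trajectory statistics: permeation-event detection and site occupancy.

test_that("hand-built crossings are counted and excursions ignored", {
  traj <- make_hand_trajectory(n_cross = 3, n_excursion = 2)
  ev <- detect_permeation_events(traj)
  expect_identical(ev$outward, 3L)
  expect_identical(ev$inward, 0L)
  # time-mirroring swaps outward and inward
  rev_traj <- ion_trajectory(traj$positions[rev(seq_len(traj$n_frames)), ],
                             dt_ns = traj$dt_ns)
  ev_rev <- detect_permeation_events(rev_traj)
  expect_identical(ev_rev$outward, 0L)
  expect_identical(ev_rev$inward, 3L)
})

test_that("detector count equals the generator's drawn count exactly", {
  for (seed in 1:5) {
    traj <- generate_trajectory(rate = 20, duration = 2, seed = seed)
    ev <- detect_permeation_events(traj)
    expect_identical(ev$outward, attr(traj, "truth")$n_outward)
    expect_identical(ev$inward, attr(traj, "truth")$n_inward)
  }
})

test_that("event counts follow Poisson statistics at the prescribed rate", {
  counts <- vapply(1:8, function(seed) {
    detect_permeation_events(
      generate_trajectory(rate = 20, duration = 10, seed = seed))$outward
  }, integer(1))
  expect_true(all(abs(counts - 200) <= 3 * sqrt(200)))
})

test_that("zero rate yields no events and same seed identical trajectories", {
  traj0 <- generate_trajectory(rate = 0, duration = 1, distractor_rate = 2,
                               seed = 5)
  expect_identical(detect_permeation_events(traj0)$outward, 0L)
  a <- generate_trajectory(rate = 20, duration = 1, seed = 9)
  b <- generate_trajectory(rate = 20, duration = 1, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_error(generate_trajectory(rate = -1, duration = 1), "rate")
})

test_that("a single ion parked in S2 occupies S2 only", {
  sites <- site_definition()
  s2 <- sites$windows[sites$windows$site == "S2", ]
  pos <- matrix((s2$lo + s2$hi) / 2, nrow = 50, ncol = 1)
  occ <- site_occupancy_fractions(ion_trajectory(pos))
  expect_equal(unname(unclass(occ)), c(0, 1, 0, 0))
})

test_that("the generator reproduces a target occupancy profile", {
  # 1e5 frames; a moderate crossing rate keeps the ion-track matrix small
  # while still exercising the transiting-ion compensation
  target <- c(S1 = 0.58, S2 = 0.97, S3 = 0.65, S4 = 0.46)
  traj <- generate_trajectory(rate = 2, duration = 100,
                              occupancy_profile = target, seed = 3)
  occ <- site_occupancy_fractions(traj)
  expect_true(all(abs(occ - target) < 0.02))
  # Rb-like profile: S2 suppressed relative to the K+ profile
  rb <- generate_trajectory(rate = 5, duration = 10,
                            occupancy_profile = c(S1 = 0.5, S2 = 0.4,
                                                  S3 = 0.6, S4 = 0.7),
                            seed = 4)
  expect_lt(site_occupancy_fractions(rb)["S2"], occ["S2"])
})

test_that("occupancy recovery error shrinks roughly as 1/sqrt(frames)", {
  target <- c(S1 = 0.58, S2 = 0.97, S3 = 0.65, S4 = 0.46)
  err <- function(duration, seed) {
    traj <- generate_trajectory(rate = 0, duration = duration,
                                distractor_rate = 0,
                                occupancy_profile = target, seed = seed)
    mean(abs(site_occupancy_fractions(traj) - target))
  }
  e_small <- mean(vapply(1:6, function(s) err(1, s), numeric(1)))
  e_large <- mean(vapply(1:6, function(s) err(100, s), numeric(1)))
  # 100x the frames: expect about 10x smaller error; accept >= 4x
  expect_gt(e_small / e_large, 4)
})

test_that("expected total occupancy is the sum of site fractions", {
  expect_equal(expected_total_occupancy(c(0, 0, 0, 0)), 0)
  expect_equal(expected_total_occupancy(c(1, 1, 1, 1)), 4)
  # measured TRAAK site fractions give 2.66 simultaneous ions
  expect_equal(expected_total_occupancy(c(0.58, 0.97, 0.65, 0.46)), 2.66,
               tolerance = 1e-12)
})

test_that("degenerate trajectories are handled explicitly", {
  empty <- ion_trajectory(matrix(numeric(0), 0, 0))
  expect_warning(ev <- detect_permeation_events(empty), "empty")
  expect_identical(ev$outward, 0L)
  expect_error(site_occupancy_fractions(empty), "zero frames")
})
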