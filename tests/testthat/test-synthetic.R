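test_that("rate law without force decay gives exact linear growth", {
  strand <- noiseless_strand(re0 = 0.4, n_frames = 60L)
  ext <- extruder_config("one_sided_left", rate_left_0 = 2,
                         stall_force_pN = Inf, landing_position_kb = 30)
  truth <- simulate_extrusion(strand, ext)
  dt <- strand$frame_interval_s
  grow <- diff(truth$loop_kb)
  # 2 kb/s exactly, per Euler step, until a geometric stop would intervene
  expect_equal(grow, rep(2 * dt, length(grow)), tolerance = 1e-12)
})

test_that("symmetric two-sided extrusion keeps the loop position fixed", {
  strand <- noiseless_strand(re0 = 0.45, n_frames = 100L)
  ext <- extruder_config("two_sided", rate_left_0 = 1, rate_right_0 = 1,
                         stall_force_pN = 0.3, landing_position_kb = 24.25)
  truth <- simulate_extrusion(strand, ext)
  expect_equal(truth$loop_position_rel, rep(0.5, nrow(truth)),
               tolerance = 1e-12)
  expect_equal(truth$loop_position_kb, rep(24.25, nrow(truth)),
               tolerance = 1e-12)
})

test_that("final extension converges to the inverse-WLC stall point", {
  strand <- noiseless_strand(re0 = 0.5, n_frames = 800L)  # L=10, CL=20
  ext <- extruder_config("one_sided_left", rate_left_0 = 2,
                         stall_force_pN = 0.2, landing_position_kb = 30)
  truth <- simulate_extrusion(strand, ext)
  re_final <- relative_extension(10, wlc_params(contour_um = 20),
                                 utils::tail(truth$loop_kb, 1))
  x_stall <- oracle_wlc_inverse(0.2)
  # within one Euler step of the root of the Marko-Siggia inverse
  dre <- re_final - relative_extension(10, wlc_params(contour_um = 20),
                                       utils::tail(truth$loop_kb, 2)[1])
  expect_lt(abs(re_final - x_stall), max(abs(dre), 1e-3) + 1e-3)
  expect_equal(re_final, x_stall, tolerance = 0.01)
})

test_that("ground truth conserves DNA and grows monotonically", {
  for (fix in list(std_one_sided(), std_two_sided())) {
    truth <- fix$truth
    total <- truth$extruded_left_kb + truth$extruded_right_kb +
      truth$regionI_kb + truth$regionII_kb
    expect_equal(total, rep(48.5, nrow(truth)), tolerance = 1e-12)
    expect_true(all(diff(truth$loop_kb) >= -1e-12))
    expect_true(all(diff(truth$tension_pN) >= -1e-12))
    expect_equal(truth$loop_kb,
                 truth$extruded_left_kb + truth$extruded_right_kb)
  }
})

test_that("a strand without slack is rejected with a diagnostic", {
  expect_error(strand_config(end_to_end_um = 21, contour_um = 20), "slack")
  # slack in the config but not for the requested contour via explicit wlc
  strand <- noiseless_strand(re0 = 0.5)
  wlc_tight <- wlc_params(contour_um = 16.5)
  strand$end_to_end_um <- 18
  expect_error(simulate_extrusion(strand, extruder_config("one_sided_left"),
                                  wlc_tight), "slack")
})

test_that("extruder config enforces the one-sided/two-sided dichotomy", {
  expect_error(extruder_config("one_sided_left", rate_left_0 = 0,
                               rate_right_0 = 2), "one_sided_left")
  expect_error(extruder_config("two_sided", rate_left_0 = 1, rate_right_0 = 0),
               "two_sided")
  expect_error(extruder_config("one_sided_left", landing_position_kb = 50),
               "landing")
  expect_error(extruder_config("one_sided_left", stall_force_pN = 0))
})

test_that("noiseless render conserves photons frame by frame", {
  strand <- noiseless_strand(re0 = 0.45, n_frames = 50L)
  truth <- make_truth(strand, loop_kb = 0, pos_rel = 0.5, n_frames = 50L)
  kymo <- render_kymograph(truth, strand, noise = FALSE)
  # no loop: total intensity (above background) = 48.5 kb * intensity/kb
  sums <- rowSums(kymo) - ncol(kymo) * strand$background_level
  expect_equal(sums, rep(48.5 * strand$line_intensity_per_kb, 50),
               tolerance = 1e-9)
  # growing loop: photon total is invariant across frames
  fix <- std_one_sided()
  sums2 <- rowSums(fix$kymo) - ncol(fix$kymo) * fix$strand$background_level
  expect_equal(max(sums2) - min(sums2), 0, tolerance = 1e-6)
})

test_that("render rejects loop positions outside the anchors", {
  strand <- noiseless_strand(n_frames = 5L)
  bad <- make_truth(strand, loop_kb = 5, pos_rel = 1.2, n_frames = 5L)
  expect_error(render_kymograph(bad, strand), "outside anchors")
})

test_that("population generation is reproducible and validated", {
  a <- generate_population(5, seed = 99, n_frames = 30L)
  b <- generate_population(5, seed = 99, n_frames = 30L)
  expect_identical(lapply(a, function(e) e$truth),
                   lapply(b, function(e) e$truth))
  expect_identical(lapply(a, function(e) unclass(e$kymograph)),
                   lapply(b, function(e) unclass(e$kymograph)))
  expect_error(generate_population(0), "n_events")
  expect_error(generate_population(3, mixture = c(one_sided = 0.5)), "sum to 1")
  expect_error(generate_population(3, mixture = c(sideways = 1)), "mixture")
})

test_that("one-sided-only mixtures give symmetry scores at 1 by construction", {
  events <- generate_population(12, mixture = c(one_sided = 1), seed = 5,
                                noise = FALSE, n_frames = 40L)
  scores <- vapply(events, function(ev) {
    a <- utils::tail(ev$truth$extruded_left_kb, 1)
    b <- utils::tail(ev$truth$extruded_right_kb, 1)
    symmetry_score(a, b)
  }, numeric(1))
  expect_equal(scores, rep(1, 12))
})

test_that("a 20/80 two-sided mixture yields ~20% scores below 0.5", {
  events <- generate_population(100, seed = 31, noise = FALSE, n_frames = 40L)
  scores <- vapply(events, function(ev) {
    a <- utils::tail(ev$truth$extruded_left_kb, 1)
    b <- utils::tail(ev$truth$extruded_right_kb, 1)
    symmetry_score(a, b)
  }, numeric(1))
  frac <- mean(scores < 0.5)
  # binomial error band: 0.2 +/- 3*sqrt(0.2*0.8/100)
  expect_lt(abs(frac - 0.2), 0.12)
})
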