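region_trace <- function(rI, rII, pos = 0.4, n = 40) {
  data.frame(time_s = seq_len(n) * 0.15,
             loop_kb = 48.5 - rI - rII,
             regionI_kb = rI, regionII_kb = rII,
             loop_position_rel = pos, flag = "ok")
}

test_that("region changes are first-ten minus last-ten, with clipping", {
  rI <- c(rep(20, 10), seq(20, 10, length.out = 20), rep(10, 10))
  rII <- rep(14, 40)
  rc <- region_changes(region_trace(rI, rII))
  expect_equal(rc$a, 10)
  expect_equal(rc$b, 0)
  expect_false(rc$substantial_slippage)

  # region II gains 3 kb: clipped to zero, slippage flagged substantial
  rII2 <- c(rep(14, 10), seq(14, 17, length.out = 20), rep(17, 10))
  rc2 <- region_changes(region_trace(rI, rII2))
  expect_equal(rc2$b, 0)
  expect_equal(rc2$slippage_II_kb, 3)
  expect_true(rc2$substantial_slippage)
  # 1 kb of slippage is not substantial
  rII3 <- c(rep(14, 10), rep(15, 30))
  expect_false(region_changes(region_trace(rI, rII3))$substantial_slippage)
  expect_error(region_changes(region_trace(rI, rII)[1:15, ]), ">= 20")
})

test_that("symmetry score formula and degeneracies", {
  expect_equal(symmetry_score(10, 0), 1)
  expect_equal(symmetry_score(5, 5), 0)
  expect_equal(symmetry_score(6, 2), 0.5)
  expect_equal(symmetry_score(2, 6), 0.5)  # swap-invariant
  expect_error(symmetry_score(-1, 2), ">= 0")
  expect_warning(s <- symmetry_score(0, 0), "undefined")
  expect_true(is.na(s))
})

test_that("scores stay in [0, 1] for random clipped region changes", {
  set.seed(123)
  raw_a <- rnorm(500, 3, 4)  # mixed signs: slippage cases included
  raw_b <- rnorm(500, 3, 4)
  a <- pmax(raw_a, 0); b <- pmax(raw_b, 0)
  keep <- a + b > 0
  s <- symmetry_score(a[keep], b[keep])
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(symmetry_score(a[keep], b[keep]),
               symmetry_score(b[keep], a[keep]))
})

test_that("classification threshold assigns 0.5 to one-sided", {
  expect_identical(classify_symmetry(0.49), "two_sided")
  expect_identical(classify_symmetry(0.5), "one_sided")
  expect_identical(classify_symmetry(1), "one_sided")
  expect_identical(classify_symmetry(c(0, NA, 1)),
                   c("two_sided", NA, "one_sided"))
  expect_error(classify_symmetry(1.2), "outside")
})

test_that("noiseless simulations hit the symmetry-score anchors", {
  one <- std_one_sided()
  expect_equal(symmetry_score(region_changes(one$trace)), 1, tolerance = 1e-9)
  two <- std_two_sided()
  expect_equal(symmetry_score(region_changes(two$trace)), 0, tolerance = 1e-9)
})

test_that("displacement sign convention is center-positive", {
  pos_up <- c(rep(0.30, 10), seq(0.30, 0.45, length.out = 20), rep(0.45, 10))
  d1 <- loop_displacement(region_trace(rep(15, 40), rep(15, 40), pos_up))
  expect_equal(d1$displacement_rel, 0.15)
  expect_identical(d1$direction_class, "toward_center")

  pos_dn <- c(rep(0.30, 10), seq(0.30, 0.25, length.out = 20), rep(0.25, 10))
  d2 <- loop_displacement(region_trace(rep(15, 40), rep(15, 40), pos_dn))
  expect_equal(d2$displacement_rel, -0.05)
  expect_true(d2$static)
  expect_identical(d2$direction_class, "static")

  # starting right of center: moving right is moving to the boundary
  pos_r <- c(rep(0.70, 10), seq(0.70, 0.85, length.out = 20), rep(0.85, 10))
  d3 <- loop_displacement(region_trace(rep(15, 40), rep(15, 40), pos_r))
  expect_equal(d3$displacement_rel, -0.15)
  expect_identical(d3$direction_class, "toward_boundary")

  # starting exactly at the center: any net motion is towards a boundary
  pos_c <- c(rep(0.5, 10), seq(0.5, 0.62, length.out = 20), rep(0.62, 10))
  d4 <- loop_displacement(region_trace(rep(15, 40), rep(15, 40), pos_c))
  expect_lt(d4$displacement_rel, 0)
})

test_that("one-sided reeling from the short side moves to the boundary", {
  strand <- noiseless_strand(re0 = 0.45)
  ext <- extruder_config("one_sided_left", rate_left_0 = 2,
                         stall_force_pN = 0.3, landing_position_kb = 15)
  truth <- simulate_extrusion(strand, ext)
  tr <- track_trace(render_kymograph(truth, strand, noise = FALSE))
  d <- loop_displacement(tr)
  expect_lt(d$displacement_rel, 0)
  expect_identical(d$direction_class, "toward_boundary")
})

test_that("center bias counts mobile events with a Wilson interval", {
  disp <- c(0.2, 0.15, 0.1, 0.09, 0.3, -0.2, -0.1, -0.12, -0.3, -0.09)
  cb <- center_bias(disp)
  expect_equal(cb$fraction_toward_center, 0.5)
  expect_equal(cb$n_mobile, 10)
  expect_true(cb$conf_int["lower"] < 0.5 && cb$conf_int["upper"] > 0.5)
  expect_equal(center_bias(c(0.2, 0.5, 0.1))$fraction_toward_center, 1)
  expect_error(center_bias(c(0.01, -0.02)), "static")
})
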