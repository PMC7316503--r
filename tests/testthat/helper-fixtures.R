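# Shared fixtures: small simulated events, built once per test run.

.fixtures <- new.env(parent = emptyenv())

noiseless_strand <- function(re0 = 0.45, contour_um = 20, n_frames = 400L, ...) {
  strand_config(end_to_end_um = re0 * contour_um, contour_um = contour_um,
                n_frames = n_frames, background_level = 0, read_noise_sd = 0,
                ...)
}

# hand-built constant-state truth (e.g. a static loop) for render tests
make_truth <- function(strand, loop_kb, pos_rel, n_frames = strand$n_frames) {
  ckb <- strand$contour_kb
  df <- data.frame(frame = seq_len(n_frames),
                   time_s = (seq_len(n_frames) - 1) * strand$frame_interval_s,
                   loop_kb = loop_kb, extruded_left_kb = loop_kb / 2,
                   extruded_right_kb = loop_kb / 2,
                   regionI_kb = pos_rel * (ckb - loop_kb),
                   regionII_kb = (1 - pos_rel) * (ckb - loop_kb),
                   loop_position_kb = pos_rel * ckb,
                   loop_position_rel = pos_rel,
                   tension_pN = 0, stalled = FALSE)
  structure(df, class = c("ground_truth", "data.frame"), strand = strand,
            wlc = wlc_params(contour_um = strand$contour_um))
}

# a standard noiseless one-sided event, cached (used by several files)
std_one_sided <- function() {
  if (is.null(.fixtures$one_sided)) {
    strand <- noiseless_strand(re0 = 0.45)
    ext <- extruder_config("one_sided_left", rate_left_0 = 2,
                           stall_force_pN = 0.3, landing_position_kb = 24)
    truth <- simulate_extrusion(strand, ext)
    kymo <- render_kymograph(truth, strand, noise = FALSE)
    .fixtures$one_sided <- list(strand = strand, extruder = ext,
                                truth = truth, kymo = kymo,
                                trace = track_trace(kymo))
  }
  .fixtures$one_sided
}

# a standard noiseless symmetric two-sided event, cached
std_two_sided <- function() {
  if (is.null(.fixtures$two_sided)) {
    strand <- noiseless_strand(re0 = 0.45)
    ext <- extruder_config("two_sided", rate_left_0 = 1, rate_right_0 = 1,
                           stall_force_pN = 0.3, landing_position_kb = 24.25)
    truth <- simulate_extrusion(strand, ext)
    kymo <- render_kymograph(truth, strand, noise = FALSE)
    .fixtures$two_sided <- list(strand = strand, extruder = ext,
                                truth = truth, kymo = kymo,
                                trace = track_trace(kymo))
  }
  .fixtures$two_sided
}

# independent bisection inverse of the Marko-Siggia law (oracle, kept free of
# the package's wlc_extension)
oracle_wlc_inverse <- function(force, P = 50, kBT = 4.11) {
  f <- function(x) (kBT / P) * (1 / (4 * (1 - x)^2) - 0.25 + x) - force
  lo <- 0; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
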