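#' Strand and imaging configuration for the simulator
#'
#' Describes one doubly tethered lambda-DNA strand and the camera/optics used
#' to image it. The defaults emulate the reference assay: a 48.5 kb strand
#' bound at sub-contour extension, imaged at 100-300 ms frame intervals with a
#' diffraction-limited PSF at 0.16 um/px.
#'
#' @param end_to_end_um Tether-to-tether distance L in um (must leave slack:
#'   `end_to_end_um < contour_um`).
#' @param contour_kb Strand length in kb (48.5 for lambda DNA).
#' @param contour_um Effective (dye-corrected) contour length in um.
#' @param pixel_size_um Camera pixel size in um/px.
#' @param frame_interval_s Time between frames, s (assay range 0.1-0.3 s).
#' @param n_frames Number of frames to simulate.
#' @param psf_sigma_px Gaussian PSF sigma in px (1.3 px ~ diffraction limit
#'   for 561 nm at 0.16 um/px).
#' @param line_intensity_per_kb Integrated photons emitted per kb of DNA per
#'   frame.
#' @param background_level Constant background, photons/px.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @return A `strand_config` object.
#' @export
strand_config <- function(end_to_end_um = 10, contour_kb = 48.5,
                          contour_um = 20, pixel_size_um = 0.16,
                          frame_interval_s = 0.15, n_frames = 300L,
                          psf_sigma_px = 1.3, line_intensity_per_kb = 200,
                          background_level = 50, read_noise_sd = 5) {
  stopifnot(end_to_end_um > 0, contour_um > 0, pixel_size_um > 0,
            frame_interval_s > 0, n_frames >= 1, psf_sigma_px > 0,
            line_intensity_per_kb > 0, background_level >= 0,
            read_noise_sd >= 0, contour_kb > 0)
  if (end_to_end_um >= contour_um) {
    stop("strand has no slack: end_to_end_um (", end_to_end_um,
         ") >= contour_um (", contour_um, ")")
  }
  structure(list(end_to_end_um = end_to_end_um, contour_kb = contour_kb,
                 contour_um = contour_um, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 psf_sigma_px = psf_sigma_px,
                 line_intensity_per_kb = line_intensity_per_kb,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd),
            class = "strand_config")
}

#' Extruder configuration
#'
#' One loop-extruding factor: where it lands, how fast it reels DNA in from
#' each side at zero tension, and the tension at which it stalls. One-sided
#' modes must have exactly one non-zero rate.
#'
#' @param mode `"one_sided_left"` (reels from the left flank only),
#'   `"one_sided_right"`, or `"two_sided"`.
#' @param rate_left_0,rate_right_0 Zero-tension reeling rates, kb/s.
#' @param stall_force_pN Tension at which extrusion stops (may be `Inf`).
#' @param landing_position_kb Nucleation position along the strand, kb
#'   (0 < landing < contour).
#' @param start_frame First frame at which extrusion is active (1-based).
#' @param contour_kb Strand length used for validation.
#' @return An `extruder_config` object.
#' @export
extruder_config <- function(mode = c("one_sided_left", "one_sided_right",
                                     "two_sided"),
                            rate_left_0 = NULL, rate_right_0 = NULL,
                            stall_force_pN = 0.3,
                            landing_position_kb = 24.25, start_frame = 1L,
                            contour_kb = 48.5) {
  mode <- match.arg(mode)
  if (is.null(rate_left_0)) {
    rate_left_0 <- if (mode == "one_sided_right") 0 else 2
  }
  if (is.null(rate_right_0)) {
    rate_right_0 <- switch(mode, one_sided_left = 0, one_sided_right = 2,
                           two_sided = rate_left_0)
  }
  stopifnot(rate_left_0 >= 0, rate_right_0 >= 0, stall_force_pN > 0,
            start_frame >= 1)
  if (landing_position_kb <= 0 || landing_position_kb >= contour_kb) {
    stop("landing_position_kb must lie strictly inside (0, ", contour_kb, ")")
  }
  if (mode == "one_sided_left" && !(rate_left_0 > 0 && rate_right_0 == 0)) {
    stop("one_sided_left requires rate_left_0 > 0 and rate_right_0 == 0")
  }
  if (mode == "one_sided_right" && !(rate_right_0 > 0 && rate_left_0 == 0)) {
    stop("one_sided_right requires rate_right_0 > 0 and rate_left_0 == 0")
  }
  if (mode == "two_sided" && !(rate_left_0 > 0 && rate_right_0 > 0)) {
    stop("two_sided requires both rates > 0")
  }
  structure(list(mode = mode, rate_left_0 = rate_left_0,
                 rate_right_0 = rate_right_0,
                 stall_force_pN = stall_force_pN,
                 landing_position_kb = landing_position_kb,
                 start_frame = as.integer(start_frame)),
            class = "extruder_config")
}

#' Simulate one loop-extrusion event under worm-like-chain tension feedback
#'
#' Forward-Euler integration at the camera frame interval of
#' \deqn{dLoop/dt = r_L(F) + r_R(F), \quad r_i(F) = r_{i,0} \max(0, 1 - F/F_{stall})}
#' where the tension F is the WLC force at the current relative extension of
#' the non-looped DNA, `RE = L / (CL_phys (1 - loop_kb/CL_kb))`. Growth halts
#' when the tension reaches the stall force, when a reeled-in flank is
#' exhausted (the loop boundary reaches an anchor), or when the non-looped DNA
#' becomes taut (geometric stall, capped at RE = 0.999).
#'
#' The loop's genomic position drifts by the imbalance of left/right reeling;
#' its physical position along the tether axis is the fraction of non-looped
#' DNA to its left (the non-looped DNA is assumed uniformly stretched).
#'
#' @param strand A [strand_config()].
#' @param extruder An [extruder_config()].
#' @param wlc A [wlc_params()]; defaults to the strand's geometry with
#'   standard P and kBT.
#' @return A `ground_truth` data frame with one row per frame: `frame`,
#'   `time_s`, `loop_kb`, `extruded_left_kb`, `extruded_right_kb`,
#'   `regionI_kb`, `regionII_kb`, `loop_position_kb`, `loop_position_rel`,
#'   `tension_pN`, `stalled`. Configurations are attached as attributes.
#' @export
simulate_extrusion <- function(strand, extruder, wlc = NULL) {
  stopifnot(inherits(strand, "strand_config"), inherits(extruder, "extruder_config"))
  if (is.null(wlc)) {
    wlc <- wlc_params(contour_um = strand$contour_um,
                      contour_kb = strand$contour_kb)
  }
  ckb <- strand$contour_kb
  re0 <- relative_extension(strand$end_to_end_um, wlc, 0)
  if (re0 >= 1) {
    stop("strand without slack: baseline relative extension ", format(re0),
         " >= 1; loop extrusion is geometrically impossible")
  }
  if (extruder$landing_position_kb >= ckb) stop("landing position outside strand")
  dt <- strand$frame_interval_s
  n <- strand$n_frames
  # largest loop compatible with RE <= 0.999 (non-looped DNA taut)
  loop_cap <- ckb * (1 - strand$end_to_end_um / (wlc$contour_um * 0.999))

  ext_l <- ext_r <- loop <- 0
  rows <- vector("list", n)
  for (f in seq_len(n)) {
    regionI <- extruder$landing_position_kb - ext_l
    regionII <- (ckb - extruder$landing_position_kb) - ext_r
    re <- relative_extension(strand$end_to_end_um, wlc, loop)
    tension <- wlc_force(min(re, 1 - 1e-9), wlc)
    factor <- max(0, 1 - tension / extruder$stall_force_pN)
    active <- f >= extruder$start_frame
    dl <- if (active) extruder$rate_left_0 * factor * dt else 0
    dr <- if (active) extruder$rate_right_0 * factor * dt else 0
    dl <- min(dl, regionI)
    dr <- min(dr, regionII)
    if (loop + dl + dr > loop_cap) {
      scale <- max(0, (loop_cap - loop)) / (dl + dr)
      dl <- dl * scale
      dr <- dr * scale
    }
    stalled <- active && (dl + dr) <= 0 &&
      (extruder$rate_left_0 + extruder$rate_right_0) > 0
    rows[[f]] <- c(frame = f, time_s = (f - 1) * dt, loop_kb = loop,
                   extruded_left_kb = ext_l, extruded_right_kb = ext_r,
                   regionI_kb = regionI, regionII_kb = regionII,
                   loop_position_kb = extruder$landing_position_kb +
                     (ext_r - ext_l) / 2,
                   loop_position_rel = regionI / (regionI + regionII),
                   tension_pN = tension, stalled = as.numeric(stalled))
    ext_l <- ext_l + dl
    ext_r <- ext_r + dr
    loop <- loop + dl + dr
  }
  truth <- as.data.frame(do.call(rbind, rows))
  truth$stalled <- truth$stalled > 0
  structure(truth, class = c("ground_truth", "data.frame"),
            strand = strand, extruder = extruder, wlc = wlc)
}

# Spread kb densities onto the camera pixel grid for one frame.
# The non-looped DNA is uniform over the physical anchor span [aL, aR] (pixel
# units, fractional coverage at the ends); the loop is a Gaussian spot of
# width psf_sigma whose discrete mass is exactly loop_kb * intensity_per_kb.
render_profile <- function(loop_kb, pos_rel, strand, width_px, anchor_px) {
  aL <- anchor_px[1]; aR <- anchor_px[2]
  span <- aR - aL
  ipkb <- strand$line_intensity_per_kb
  px <- seq_len(width_px)
  cover <- pmax(0, pmin(px + 0.5, aR) - pmax(px - 0.5, aL))
  nonloop_kb <- strand$contour_kb - loop_kb
  profile <- nonloop_kb * ipkb * cover / span
  if (loop_kb > 0) {
    centre <- aL + pos_rel * span
    g <- exp(-(px - centre)^2 / (2 * strand$psf_sigma_px^2))
    profile <- profile + loop_kb * ipkb * g / sum(g)
  }
  profile
}

#' Render a simulated event as a noisy kymograph
#'
#' Forward model of the imaging: per frame, the non-looped DNA is spread
#' uniformly along the anchor-to-anchor axis and the loop is added as a
#' diffraction-limited Gaussian spot whose integrated intensity equals
#' `loop_kb * line_intensity_per_kb`. Poisson shot noise, then Gaussian read
#' noise, then a constant background offset are applied.
#'
#' @param truth A `ground_truth` from [simulate_extrusion()].
#' @param strand The [strand_config()] used for the simulation (defaults to
#'   the one stored in `truth`).
#' @param noise Apply shot and read noise? `FALSE` gives the noiseless
#'   expectation (background still added).
#' @param margin_px Dark margin left of the first and right of the last
#'   anchor, px.
#' @return A `kymograph`: a `n_frames x width` intensity matrix with
#'   attributes `pixel_size_um`, `frame_interval_s`, `anchor_px` (left/right,
#'   1-based column indices), `background_level` and
#'   `background_subtracted = FALSE`.
#' @export
render_kymograph <- function(truth, strand = attr(truth, "strand"),
                             noise = TRUE, margin_px = 10L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(strand, "strand_config"))
  if (nrow(truth) > strand$n_frames) stop("truth has more frames than strand config")
  if (any(truth$loop_position_rel < -1e-9 | truth$loop_position_rel > 1 + 1e-9,
          na.rm = TRUE)) {
    stop("loop position outside anchors")
  }
  span_px <- max(3L, round(strand$end_to_end_um / strand$pixel_size_um))
  aL <- margin_px + 1L
  aR <- aL + span_px
  width <- aR + margin_px
  mat <- matrix(0, nrow(truth), width)
  for (f in seq_len(nrow(truth))) {
    p <- render_profile(truth$loop_kb[f], truth$loop_position_rel[f],
                        strand, width, c(aL, aR))
    if (noise) {
      p <- stats::rpois(width, p) +
        stats::rnorm(width, 0, strand$read_noise_sd)
    }
    mat[f, ] <- p + strand$background_level
  }
  new_kymograph(mat, pixel_size_um = strand$pixel_size_um,
                frame_interval_s = strand$frame_interval_s,
                anchor_px = c(aL, aR),
                background_level = strand$background_level,
                background_subtracted = FALSE)
}

#' Render a simulated event as a movie stack
#'
#' Like [render_kymograph()] but produces 2-D frames: the 1-D intensity model
#' is spread across rows with a Gaussian cross-section of width `psf_sigma_px`
#' centred on the strand axis, then per-pixel noise and background are
#' applied. Feeding the result through [build_kymograph()] reproduces the
#' direct kymograph render up to noise.
#'
#' @inheritParams render_kymograph
#' @param height_px Frame height in px (strand axis at the middle row).
#' @return A `movie_stack`: list of frame matrices plus calibration
#'   attributes, including `strand_roi`.
#' @export
render_movie <- function(truth, strand = attr(truth, "strand"), noise = TRUE,
                         margin_px = 10L, height_px = 15L) {
  stopifnot(inherits(truth, "ground_truth"), height_px >= 3)
  span_px <- max(3L, round(strand$end_to_end_um / strand$pixel_size_um))
  aL <- margin_px + 1L
  aR <- aL + span_px
  width <- aR + margin_px
  centre_row <- (height_px + 1) / 2
  w <- exp(-(seq_len(height_px) - centre_row)^2 / (2 * strand$psf_sigma_px^2))
  w <- w / sum(w)
  frames <- vector("list", nrow(truth))
  for (f in seq_len(nrow(truth))) {
    p <- render_profile(truth$loop_kb[f], truth$loop_position_rel[f],
                        strand, width, c(aL, aR))
    fr <- outer(w, p)
    if (noise) {
      fr <- matrix(stats::rpois(length(fr), fr) +
                     stats::rnorm(length(fr), 0, strand$read_noise_sd),
                   nrow = height_px)
    }
    frames[[f]] <- fr + strand$background_level
  }
  structure(list(frames = frames,
                 pixel_size_um = strand$pixel_size_um,
                 frame_interval_s = strand$frame_interval_s,
                 strand_roi = list(rows = seq_len(height_px),
                                   cols = seq_len(width)),
                 anchor_px = c(aL, aR)),
            class = "movie_stack")
}

#' Generate a population of simulated looping events
#'
#' Samples extruder configurations from a mixture of templates and strand
#' geometries from the ranges the assay reports: baseline relative extension
#' 0.35-0.55 (all strands have "sufficient slack"), zero-tension rates
#' 1-3 kb/s, stall forces 0.15-0.6 pN, landing positions in the central 60%
#' of the strand. Reproducible under a fixed seed.
#'
#' @param n_events Number of events (> 0).
#' @param mixture Named fractions summing to 1 over
#'   `c("one_sided", "one_sided_left", "one_sided_right", "two_sided")`;
#'   `"one_sided"` picks left/right at random. Two-sided events draw both
#'   rates independently, so their symmetry scores fall in `[0, 0.5)`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise Render with shot/read noise?
#' @param n_frames Frames per event.
#' @param contour_um Effective contour length for all strands.
#' @return List of events; each has `$kymograph`, `$truth`, `$strand`,
#'   `$extruder`.
#' @export
generate_population <- function(n_events,
                                mixture = c(one_sided = 0.8, two_sided = 0.2),
                                seed = NULL, noise = TRUE, n_frames = 300L,
                                contour_um = 20) {
  if (n_events <= 0) stop("n_events must be > 0")
  allowed <- c("one_sided", "one_sided_left", "one_sided_right", "two_sided")
  if (is.null(names(mixture)) || !all(names(mixture) %in% allowed)) {
    stop("mixture names must be among: ", paste(allowed, collapse = ", "))
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  modes <- sample(names(mixture), n_events, replace = TRUE, prob = mixture)
  lapply(seq_len(n_events), function(i) {
    mode <- modes[i]
    if (mode == "one_sided") {
      mode <- sample(c("one_sided_left", "one_sided_right"), 1)
    }
    re0 <- stats::runif(1, 0.35, 0.55)
    # snap the tether distance to the camera pixel grid so the rendered
    # anchor span and the simulated geometry describe the same strand
    # (near stall the tension is very sensitive to sub-pixel length errors)
    px <- 0.16
    L <- round(re0 * contour_um / px) * px
    strand <- strand_config(end_to_end_um = L,
                            contour_um = contour_um, n_frames = n_frames)
    rl <- stats::runif(1, 1, 3)
    rr <- stats::runif(1, 1, 3)
    extruder <- extruder_config(
      mode = mode,
      rate_left_0 = switch(mode, one_sided_right = 0, two_sided = rl, rl),
      rate_right_0 = switch(mode, one_sided_left = 0, two_sided = rr, rl),
      stall_force_pN = stats::runif(1, 0.15, 0.6),
      landing_position_kb = stats::runif(1, 0.2, 0.8) * 48.5)
    truth <- simulate_extrusion(strand, extruder)
    kymo <- render_kymograph(truth, strand, noise = noise)
    list(kymograph = kymo, truth = truth, strand = strand, extruder = extruder)
  })
}
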