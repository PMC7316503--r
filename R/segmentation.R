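# Fractional-pixel integral of a profile over [lo, hi], pixel i covering
# (i - 0.5, i + 0.5). Continuous in lo/hi, which keeps the region partition
# free of pixel-quantization jumps as the fitted loop center moves.
frac_sum <- function(v, lo, hi) {
  n <- length(v)
  lo <- max(lo, 0.5); hi <- min(hi, n + 0.5)
  if (hi <= lo) return(0)
  i <- seq_len(n)
  w <- pmax(0, pmin(i + 0.5, hi) - pmax(i - 0.5, lo))
  sum(v * w)
}

#' Locate the loop on a background-subtracted profile
#'
#' The loop position is the intensity maximum within the anchor span (or
#' within a search window around the previous frame's center when tracking).
#' Ties break to the leftmost pixel. A profile whose maximum does not rise
#' above the local median by more than a noise floor carries no detectable
#' loop and is flagged.
#'
#' @param profile Background-subtracted intensity profile.
#' @param anchor_px Left/right anchor columns.
#' @param prev_center Previous frame's loop center (px) for seeded tracking,
#'   or `NULL` for a global search.
#' @param search_halfwidth Half-width of the seeded search window, px.
#' @return List with `center_px` and logical `has_loop`.
#' @export
locate_loop <- function(profile, anchor_px, prev_center = NULL,
                        search_halfwidth = 15L) {
  aL <- ceiling(anchor_px[1]); aR <- floor(anchor_px[2])
  span <- aL:aR
  if (!is.null(prev_center)) {
    lo <- max(aL, round(prev_center) - search_halfwidth)
    hi <- min(aR, round(prev_center) + search_halfwidth)
    span <- lo:hi
  }
  seg <- profile[span]
  center <- span[which.max(seg)]
  med <- stats::median(profile[aL:aR])
  floor_sd <- stats::mad(profile[aL:aR])
  # a real spot must clear both the noise floor and a 5% contrast floor over
  # the line level; otherwise the Gaussian fit is degenerate (amplitude ~ 0)
  has_loop <- (max(seg) - med) >
    max(3 * floor_sd, 0.05 * max(med, 0), 1e-9 * max(abs(profile)))
  list(center_px = center, has_loop = has_loop)
}

#' Fit a Gaussian to the loop spot
#'
#' Least-squares fit of `amplitude * exp(-(x - mu)^2 / (2 sigma^2)) + offset`
#' over a local window around `center_guess`. The window is +/-
#' `window_halfwidth` px initially and can be re-derived from a running sigma
#' estimate by the tracker. Convergence is declared at a relative cost change
#' below `rel_tol` (default 1e-8).
#'
#' @param profile Background-subtracted profile.
#' @param center_guess Initial center, px; must lie within the anchors.
#' @param anchor_px Left/right anchor columns.
#' @param window_halfwidth Fit window half-width, px.
#' @param sigma_guess Initial sigma, px.
#' @param rel_tol Relative cost-change convergence tolerance.
#' @return A `loop_fit` list: `center_px`, `sigma_px`, `amplitude`, `offset`,
#'   `converged`, `window` (the columns used).
#' @export
fit_loop_gaussian <- function(profile, center_guess, anchor_px,
                              window_halfwidth = 15L, sigma_guess = 2,
                              rel_tol = 1e-8) {
  aL <- ceiling(anchor_px[1]); aR <- floor(anchor_px[2])
  if (center_guess < anchor_px[1] || center_guess > anchor_px[2]) {
    stop("center_guess outside anchors")
  }
  # the anchor pixels themselves have partial strand coverage (a step the
  # Gaussian + constant-offset model cannot represent), so keep them out
  lo <- max(aL + 1L, floor(center_guess - window_halfwidth))
  hi <- min(aR - 1L, ceiling(center_guess + window_halfwidth))
  if (hi - lo < 4L) stop("fit window too small near anchor")
  win <- lo:hi
  x <- as.numeric(win)
  y <- profile[win]
  off0 <- min(y)
  amp0 <- max(y) - off0
  model <- function(p, x) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4]
  resid <- function(p) model(p, x) - y
  jac <- function(p) {
    e <- exp(-(x - p[2])^2 / (2 * p[3]^2))
    cbind(e,
          p[1] * e * (x - p[2]) / p[3]^2,
          p[1] * e * (x - p[2])^2 / p[3]^3,
          1)
  }
  fit <- lm_least_squares(c(amp0, center_guess, sigma_guess, off0),
                          resid, jac, rel_tol = rel_tol)
  p <- fit$par
  p[3] <- abs(p[3])
  converged <- fit$converged && is.finite(p[3]) && p[3] > 0 &&
    p[2] >= anchor_px[1] && p[2] <= anchor_px[2]
  structure(list(center_px = p[2], sigma_px = p[3], amplitude = p[1],
                 offset = p[4], converged = converged,
                 cost = fit$cost, window = win),
            class = "loop_fit")
}

#' Partition a profile into loop and flanking regions
#'
#' The loop region is the +/- 2 sigma window around the fitted Gaussian
#' center. The loop signal is the window sum minus the offset pass-through
#' (the non-looped DNA running underneath the spot), plus the fitted Gaussian
#' tail mass outside the window; that same tail mass is removed from the
#' flanking-region sums, so the three signals always add up to the total
#' strand signal. The offset pass-through is split equally between the two
#' flanking regions. All boundaries are integrated at fractional-pixel
#' resolution.
#'
#' @param profile Background-subtracted profile.
#' @param fit A converged `loop_fit`.
#' @param anchor_px Left/right anchor columns.
#' @param window_sigma Loop window half-width in sigmas (default 2).
#' @param boundary_margin_px Loop windows closer than this to an anchor are
#'   flagged `boundary_contact` (used by the stall-force filter).
#' @return A `region_partition` list: `loop_signal`, `regionI_signal`,
#'   `regionII_signal`, `total_signal`, `loop_window` (c(lo, hi) in px),
#'   `loop_position_rel`, `boundary_contact`.
#' @export
partition_regions <- function(profile, fit, anchor_px, window_sigma = 2,
                              boundary_margin_px = 3) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  aL <- anchor_px[1]; aR <- anchor_px[2]
  n <- length(profile)
  mu <- fit$center_px; sg <- fit$sigma_px
  wlo <- mu - window_sigma * sg
  whi <- mu + window_sigma * sg
  if (whi <= wlo) stop("empty loop window")
  i <- seq_len(n)
  gauss <- fit$amplitude * exp(-(i - mu)^2 / (2 * sg^2))
  # integrate the whole profile: outside the anchors it is ~0 after
  # background subtraction, and a spot parked at an anchor spills past it
  s_left <- frac_sum(profile, 0.5, wlo)
  s_right <- frac_sum(profile, whi, n + 0.5)
  s_win <- frac_sum(profile, wlo, whi)
  g_left <- frac_sum(gauss, 0.5, wlo)
  g_right <- frac_sum(gauss, whi, n + 0.5)
  # the offset (non-looped DNA running under the spot) only exists inside the
  # anchor span
  pass <- fit$offset * max(0, min(whi, aR + 0.5) - max(wlo, aL - 0.5))
  loop_sig <- s_win - pass + g_left + g_right
  regI <- s_left - g_left + pass / 2
  regII <- s_right - g_right + pass / 2
  total_raw <- s_left + s_win + s_right
  # a partition that needs a large clamp means the Gaussian fit does not
  # describe the spot (e.g. it absorbed the strand line): flag it
  inconsistent <- min(loop_sig, regI, regII) < -0.02 * total_raw
  loop_sig <- max(loop_sig, 0)
  regI <- max(regI, 0)
  regII <- max(regII, 0)
  structure(list(loop_signal = loop_sig, regionI_signal = regI,
                 regionII_signal = regII,
                 total_signal = loop_sig + regI + regII,
                 loop_window = c(wlo, whi),
                 loop_position_rel = (mu - aL) / (aR - aL),
                 boundary_contact = (wlo < aL + boundary_margin_px) ||
                   (whi > aR - boundary_margin_px),
                 inconsistent = inconsistent),
            class = "region_partition")
}

#' Convert region signals to kilobases
#'
#' Each region's DNA content is the total strand length (48.5 kb for lambda)
#' times its share of the total summed intensity; the three values therefore
#' sum to the strand length exactly.
#'
#' @param partition A `region_partition` (or list with the three `*_signal`
#'   fields).
#' @param total_strand_signal Total signal to normalize by; defaults to the
#'   sum of the three region signals.
#' @param contour_kb Strand length in kb.
#' @return The partition with `loop_kb`, `regionI_kb`, `regionII_kb` added.
#' @export
intensity_to_kb <- function(partition, total_strand_signal = NULL,
                            contour_kb = 48.5) {
  if (is.null(total_strand_signal)) {
    total_strand_signal <- partition$loop_signal + partition$regionI_signal +
      partition$regionII_signal
  }
  if (!is.finite(total_strand_signal) || total_strand_signal <= 0) {
    stop("total strand signal must be > 0")
  }
  partition$loop_kb <- contour_kb * partition$loop_signal / total_strand_signal
  partition$regionI_kb <- contour_kb * partition$regionI_signal / total_strand_signal
  partition$regionII_kb <- contour_kb * partition$regionII_signal / total_strand_signal
  partition
}

#' Track a looping event across a kymograph
#'
#' Runs the per-frame segmentation (locate, Gaussian fit, region partition,
#' kb conversion) over all frames. By default each frame's search is seeded
#' by the previous frame's center, which prevents jumps to transient noise
#' maxima; `mode = "global"` reproduces a plain per-frame argmax. Frames with
#' no detectable loop are recorded with `loop_kb = 0` and `NA` regions;
#' isolated failed fits are linearly interpolated, runs of failures are
#' dropped. Traces with more than 30% failed frames are rejected
#' (`attr(trace, "accepted") == FALSE`).
#'
#' @param kymo A `kymograph`. Raw kymographs are background-subtracted first.
#' @param mode `"seeded"` (default) or `"global"` loop search.
#' @param window_sigma Loop window half-width in sigmas.
#' @param boundary_margin_px Anchor margin for the boundary-contact flag.
#' @param kernel_px Median kernel if background subtraction is needed.
#' @param contour_kb Strand length in kb.
#' @return A `loop_trace` data frame: `frame`, `time_s`, `loop_kb`,
#'   `regionI_kb`, `regionII_kb`, `loop_position_rel`, `boundary_contact`,
#'   `flag` (`"ok"`, `"no_loop"`, `"fit_failed"`, `"interpolated"`).
#'   Attributes: `accepted`, `end_to_end_um`, `anchor_px`, `pixel_size_um`,
#'   `frame_interval_s`.
#' @export
track_trace <- function(kymo, mode = c("seeded", "global"), window_sigma = 2,
                        boundary_margin_px = 3, kernel_px = 51L,
                        contour_kb = 48.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(kymo, "kymograph"))
  if (nrow(kymo) < 20) stop("kymograph must have >= 20 frames")
  kymo <- subtract_kymograph(kymo, kernel_px)
  anchors <- attr(kymo, "anchor_px")
  dt <- attr(kymo, "frame_interval_s")
  n <- nrow(kymo)
  res <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
                    loop_kb = NA_real_, regionI_kb = NA_real_,
                    regionII_kb = NA_real_, loop_position_rel = NA_real_,
                    boundary_contact = FALSE, flag = "fit_failed",
                    stringsAsFactors = FALSE)
  prev_center <- NULL
  prev_sigma <- NULL
  for (f in seq_len(n)) {
    profile <- as.numeric(kymo[f, ])
    loc <- locate_loop(profile, anchors,
                       prev_center = if (mode == "seeded") prev_center else NULL)
    if (!loc$has_loop) {
      res$loop_kb[f] <- 0
      res$flag[f] <- "no_loop"
      next
    }
    hw <- if (!is.null(prev_sigma)) {
      min(25L, max(8L, ceiling(6 * prev_sigma)))
    } else 15L
    fit <- tryCatch(
      fit_loop_gaussian(profile, loc$center_px, anchors, window_halfwidth = hw),
      error = function(e) NULL)
    # sigma beyond half the window means the "spot" is the strand itself,
    # not a diffraction-limited loop: treat as a failed fit
    if (is.null(fit) || !fit$converged || fit$amplitude <= 0 ||
        fit$sigma_px > hw / 2) next
    part <- tryCatch(
      intensity_to_kb(
        partition_regions(profile, fit, anchors, window_sigma,
                          boundary_margin_px),
        contour_kb = contour_kb),
      error = function(e) NULL)
    if (is.null(part) || isTRUE(part$inconsistent)) next
    res$loop_kb[f] <- part$loop_kb
    res$regionI_kb[f] <- part$regionI_kb
    res$regionII_kb[f] <- part$regionII_kb
    res$loop_position_rel[f] <- part$loop_position_rel
    res$boundary_contact[f] <- part$boundary_contact
    res$flag[f] <- "ok"
    prev_center <- fit$center_px
    prev_sigma <- fit$sigma_px
  }
  # interpolate isolated failures between ok neighbours
  failed <- which(res$flag == "fit_failed")
  for (f in failed) {
    if (f > 1 && f < n && res$flag[f - 1] == "ok" && res$flag[f + 1] == "ok") {
      for (col in c("loop_kb", "regionI_kb", "regionII_kb",
                    "loop_position_rel")) {
        res[[col]][f] <- (res[[col]][f - 1] + res[[col]][f + 1]) / 2
      }
      res$flag[f] <- "interpolated"
    }
  }
  n_bad <- sum(res$flag == "fit_failed")
  accepted <- n_bad <= 0.3 * n
  structure(res, class = c("loop_trace", "data.frame"),
            accepted = accepted,
            anchor_px = anchors,
            pixel_size_um = attr(kymo, "pixel_size_um"),
            frame_interval_s = dt,
            end_to_end_um = (anchors[2] - anchors[1]) *
              attr(kymo, "pixel_size_um"))
}
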