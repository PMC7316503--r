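#' Fit saturating-exponential kinetics to a loop-growth trace
#'
#' Least-squares fit of
#' \deqn{loop(t) = L_f - (L_f - L_0) e^{-(t - t_0)/\tau}}
#' to the loop size over time. The initial extrusion rate is the derivative
#' at the event onset, `(L_f - L_0) / tau`. Convergence is declared only when
#' the relative change of the cost function falls below `rel_tol` (default
#' 1e-8); non-converged events are excluded from rate statistics downstream.
#'
#' The onset `t_0` is the first frame whose loop size exceeds 3x the
#' pre-event noise SD (estimated from frames with no detectable loop); for
#' traces that start mid-event it is the first accepted frame.
#'
#' @param trace A `loop_trace`, or a data frame with `time_s`, `loop_kb` and
#'   optionally `flag`.
#' @param rel_tol Relative cost-change tolerance for convergence.
#' @return An `exp_fit` list: `loop_initial_kb`, `loop_final_kb`, `tau_s`,
#'   `initial_rate_kbps`, `t0_s`, `cost`, `converged`, `n_points`.
#' @export
fit_exponential <- function(trace, rel_tol = 1e-8) {
  flag <- if (!is.null(trace$flag)) trace$flag else rep("ok", nrow(trace))
  ok <- flag %in% c("ok", "interpolated") & is.finite(trace$loop_kb)
  pre <- flag == "no_loop"
  noise_sd <- if (sum(pre) >= 3) stats::sd(trace$loop_kb[pre]) else 0
  idx <- which(ok & trace$loop_kb > 3 * noise_sd)
  if (length(idx) < 20) stop("need >= 20 frames of loop growth")
  start <- idx[1]
  use <- which(ok)
  use <- use[use >= start]
  t <- trace$time_s[use] - trace$time_s[start]
  y <- trace$loop_kb[use]

  non_degenerate <- (max(y) - min(y)) > max(1e-6, 3 * noise_sd)
  l0_0 <- y[1]
  lf_0 <- y[length(y)]
  tau_0 <- max(diff(range(t)) / 2, 1e-6)
  model <- function(p, t) p[2] - (p[2] - p[1]) * exp(-t / p[3])
  resid <- function(p) model(c(p[1], p[2], abs(p[3])), t) - y
  jac <- function(p) {
    e <- exp(-t / abs(p[3]))
    cbind(e, 1 - e,
          -sign(p[3]) * (p[2] - p[1]) * e * t / p[3]^2)
  }
  fit <- lm_least_squares(c(l0_0, lf_0, tau_0), resid, jac, rel_tol = rel_tol)
  p <- fit$par
  tau <- abs(p[3])
  converged <- fit$converged && non_degenerate && tau > 0 && p[2] > p[1]
  structure(list(loop_initial_kb = p[1], loop_final_kb = p[2], tau_s = tau,
                 initial_rate_kbps = (p[2] - p[1]) / tau,
                 t0_s = trace$time_s[start], cost = fit$cost,
                 converged = converged, n_points = length(y),
                 rel_cost_tolerance = rel_tol),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "exponential fit: L0 = %.2f kb, Lf = %.2f kb, tau = %.2f s, rate0 = %.2f kb/s (%s)\n",
    x$loop_initial_kb, x$loop_final_kb, x$tau_s, x$initial_rate_kbps,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extrusion rate versus DNA tension for one event
#'
#' Builds the per-time-point (tension, rate) curve: the rate comes from the
#' exponential fit, `rate(t) = rate_0 exp(-(t - t_0)/tau)`, and the tension
#' from the WLC force at the Savitzky-Golay-smoothed relative extension.
#' An alternative rate from the smoothed first derivative of the loop size is
#' returned alongside (`rate_savgol_kbps`); the two agree at onset for
#' well-behaved events. Frames whose smoothed relative extension reaches 1
#' are masked.
#'
#' @param trace A `loop_trace`.
#' @param fit A converged `exp_fit` for the same trace.
#' @param wlc A [wlc_params()].
#' @param end_to_end_um Strand end-to-end distance; defaults to the trace's.
#' @param savgol_window,savgol_order Smoothing parameters (defaults 63 / 2).
#' @return Data frame `time_s`, `loop_kb_smooth`, `rel_extension`,
#'   `tension_pN`, `rate_kbps`, `rate_savgol_kbps` (masked rows dropped).
#' @export
rate_vs_tension <- function(trace, fit, wlc = wlc_params(),
                            end_to_end_um = NULL, savgol_window = 63L,
                            savgol_order = 2L) {
  if (!isTRUE(fit$converged)) stop("exponential fit did not converge")
  if (is.null(end_to_end_um)) end_to_end_um <- attr(trace, "end_to_end_um")
  flag <- if (!is.null(trace$flag)) trace$flag else rep("ok", nrow(trace))
  ok <- flag %in% c("ok", "interpolated") & is.finite(trace$loop_kb) &
    trace$time_s >= fit$t0_s
  t <- trace$time_s[ok]
  dt <- stats::median(diff(t))
  loop_s <- smooth_trace(trace$loop_kb[ok], window = savgol_window,
                         order = savgol_order)
  dloop <- smooth_trace(trace$loop_kb[ok], window = savgol_window,
                        order = savgol_order, deriv = 1L, delta = dt)
  loop_s <- pmin(pmax(as.numeric(loop_s), 0), wlc$contour_kb * 0.999)
  re <- relative_extension(end_to_end_um, wlc, loop_s)
  keep <- re < 1
  data.frame(time_s = t[keep],
             loop_kb_smooth = loop_s[keep],
             rel_extension = re[keep],
             tension_pN = wlc_force(re[keep], wlc),
             rate_kbps = fit$initial_rate_kbps *
               exp(-(t[keep] - fit$t0_s) / fit$tau_s),
             rate_savgol_kbps = as.numeric(dloop)[keep])
}

#' Initial extrusion rate from the smoothed derivative
#'
#' Model-free alternative to the exponential fit: the Savitzky-Golay first
#' derivative of the loop size, evaluated at the event onset (first frame
#' whose loop size exceeds 3x the pre-event noise SD). For tension-limited
#' kinetics this estimates the true onset rate without assuming an
#' exponential form. The derivative is evaluated on the growth phase only
#' (up to the first frame reaching 90% of the robust steady-state loop
#' size): a fixed wide window spanning the stall plateau would bias the edge
#' derivative for fast events, so the window shrinks with the growth phase
#' when necessary.
#'
#' @param trace A `loop_trace` (or data frame with `time_s`, `loop_kb`,
#'   optionally `flag`).
#' @param window,order Savitzky-Golay parameters (defaults 63 / 2).
#' @return Onset rate in kb/s.
#' @export
initial_rate_savgol <- function(trace, window = 63L, order = 2L) {
  flag <- if (!is.null(trace$flag)) trace$flag else rep("ok", nrow(trace))
  ok <- flag %in% c("ok", "interpolated") & is.finite(trace$loop_kb)
  pre <- flag == "no_loop"
  noise_sd <- if (sum(pre) >= 3) stats::sd(trace$loop_kb[pre]) else 0
  idx <- which(ok & trace$loop_kb > 3 * noise_sd)
  if (length(idx) < 20) stop("need >= 20 frames of loop growth")
  use <- which(ok)
  use <- use[use >= idx[1]]
  y <- trace$loop_kb[use]
  plateau <- stats::quantile(y, 0.9)
  growth_end <- which(y >= 0.9 * plateau)[1]
  if (!is.na(growth_end)) {
    use <- use[seq_len(min(length(use), max(growth_end + 5L, 20L)))]
    y <- trace$loop_kb[use]
  }
  dt <- stats::median(diff(trace$time_s[use]))
  # resolve the kinetic timescale: a quadratic window wider than about half
  # the growth phase cannot follow the onset curvature of fast events
  w <- min(window, max(7L, floor(length(y) / 2)))
  if (w %% 2L == 0L) w <- w - 1L
  d <- smooth_trace(y, window = w, order = order, deriv = 1L, delta = dt)
  as.numeric(d)[1]
}

#' Pool rate-tension curves across events
#'
#' Bins the pooled (tension, rate) points into equal-count tension bins and
#' reports the bin-wise mean and standard deviation, the population summary
#' used to display the average decrease of extrusion rate with tension.
#'
#' @param curves List of data frames from [rate_vs_tension()] (>= 2), or a
#'   single pooled data frame with `tension_pN` and the rate column.
#' @param n_bins Number of equal-count bins (default 8).
#' @param value_col Rate column to pool (default `"rate_kbps"`; use
#'   `"rate_savgol_kbps"` for the model-free rates).
#' @return Data frame `tension_mid_pN`, `rate_mean_kbps`, `rate_sd_kbps`, `n`.
#' @export
pool_rate_tension <- function(curves, n_bins = 8L, value_col = "rate_kbps") {
  if (is.data.frame(curves)) curves <- list(curves)
  if (length(curves) < 2 && nrow(curves[[1]]) < 2) stop("need >= 2 curves or points")
  pooled <- do.call(rbind, lapply(curves, function(d) {
    data.frame(tension_pN = d$tension_pN, rate_kbps = d[[value_col]])
  }))
  pooled <- pooled[is.finite(pooled$tension_pN) & is.finite(pooled$rate_kbps), ]
  qs <- stats::quantile(pooled$tension_pN,
                        probs = seq(0, 1, length.out = n_bins + 1))
  qs <- unique(qs)
  if (length(qs) < 2) stop("degenerate tension distribution")
  bin <- cut(pooled$tension_pN, qs, include.lowest = TRUE)
  empty <- setdiff(levels(bin), unique(as.character(bin)))
  if (length(empty)) warning("dropping ", length(empty), " empty tension bins")
  agg <- lapply(split(pooled, bin, drop = TRUE), function(d) {
    data.frame(tension_mid_pN = mean(d$tension_pN),
               rate_mean_kbps = mean(d$rate_kbps),
               rate_sd_kbps = if (nrow(d) > 1) stats::sd(d$rate_kbps) else 0,
               n = nrow(d))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$tension_mid_pN), ]
}
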