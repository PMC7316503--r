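#' Savitzky-Golay smoothing and differentiation
#'
#' Local least-squares polynomial filter. Each output point is the value (or
#' `deriv`-th derivative) at the window center of a degree-`order` polynomial
#' fit to the surrounding `window` samples. The default (order 2, window 63)
#' matches the smoothing applied to loop-size traces before tension
#' conversion. Near the edges, where a centered window does not fit, the
#' polynomial fitted to the first/last full window is evaluated directly
#' (polynomial extrapolation), so a polynomial input of degree `<= order` is
#' reproduced exactly everywhere.
#'
#' @param y Numeric vector (regularly sampled).
#' @param window Odd window length. If `length(y) < window` the window is
#'   shrunk to the largest odd length `<= length(y)` and the result carries
#'   attribute `window_shrunk = TRUE`.
#' @param order Polynomial order (default 2); must be `< window`.
#' @param deriv Derivative order (0 = smoothing, 1 = first derivative, ...).
#' @param delta Sample spacing used to scale derivatives (e.g. the frame
#'   interval in seconds).
#' @return Numeric vector, same length as `y`; attributes `window_used` and
#'   `window_shrunk`.
#' @examples
#' t <- seq(0, 10, by = 0.1)
#' noisy <- t^2 + rnorm(length(t), sd = 0.5)
#' s <- savgol_filter(noisy, window = 21)
#' @export
savgol_filter <- function(y, window = 63L, order = 2L, deriv = 0L, delta = 1) {
  n <- length(y)
  if (n < 5) stop("need at least 5 points")
  stopifnot(order >= 0, deriv >= 0, deriv <= order, delta > 0)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  shrunk <- FALSE
  if (window > n) {
    window <- if (n %% 2L == 1L) n else n - 1L
    shrunk <- TRUE
  }
  if (window <= order) stop("window must exceed polynomial order")
  h <- (window - 1L) %/% 2L

  # pseudo-inverse of the Vandermonde on centered abscissa -h..h
  X <- outer(seq(-h, h), 0:order, `^`)
  Cmat <- solve(crossprod(X), t(X))          # (order+1) x window
  coef <- factorial(deriv) * Cmat[deriv + 1L, ]

  out <- numeric(n)
  if (n >= window) {
    for (i in seq(h + 1L, n - h)) {
      out[i] <- sum(coef * y[(i - h):(i + h)])
    }
  }
  if (h > 0L) {
    eval_poly <- function(beta, t) {
      s <- 0
      for (k in deriv:order) {
        s <- s + beta[k + 1L] * factorial(k) / factorial(k - deriv) * t^(k - deriv)
      }
      s
    }
    beta_head <- Cmat %*% y[1:window]
    beta_tail <- Cmat %*% y[(n - window + 1L):n]
    for (i in 1:h) {
      out[i] <- eval_poly(beta_head, i - (h + 1L))
      out[n - h + i] <- eval_poly(beta_tail, i)
    }
  }
  out <- out / delta^deriv
  attr(out, "window_used") <- window
  attr(out, "window_shrunk") <- shrunk
  out
}

#' Smooth a loop-size or extension trace
#'
#' Convenience wrapper around [savgol_filter()] with the trace-analysis
#' defaults (2nd-order polynomial, 63-point window). Short traces get the
#' largest odd window that fits, flagged via the `window_shrunk` attribute.
#'
#' @param values Numeric vector (e.g. `loop_kb` per frame).
#' @param window,order,deriv,delta Passed to [savgol_filter()].
#' @return Smoothed vector with `window_used` / `window_shrunk` attributes.
#' @export
smooth_trace <- function(values, window = 63L, order = 2L, deriv = 0L,
                         delta = 1) {
  savgol_filter(values, window = window, order = order, deriv = deriv,
                delta = delta)
}
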