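# Small dense Levenberg-Marquardt least squares used by the Gaussian and
# exponential fits. Convergence is declared when an accepted step changes the
# cost (sum of squared residuals) by less than `rel_tol` relative to the
# previous cost -- the same relative-cost criterion the per-event kinetics
# fits gate on.

lm_least_squares <- function(par, residual_fn, jacobian_fn = NULL,
                             max_iter = 200L, rel_tol = 1e-8,
                             lambda0 = 1e-3) {
  num_jacobian <- function(p) {
    r0 <- residual_fn(p)
    J <- matrix(0, length(r0), length(p))
    for (j in seq_along(p)) {
      h <- max(1e-7, abs(p[j]) * 1e-7)
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      J[, j] <- (residual_fn(pp) - residual_fn(pm)) / (2 * h)
    }
    J
  }
  jac <- if (is.null(jacobian_fn)) num_jacobian else jacobian_fn

  r <- residual_fn(par)
  cost <- sum(r * r)
  lambda <- lambda0
  converged <- FALSE
  rel_change <- NA_real_
  iter <- 0L
  n_small <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac(par)
    g <- crossprod(J, r)           # gradient/2
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:30) {
      A <- H + lambda * diag(diag(H) + 1e-12, nrow(H))
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        p_new <- par + as.numeric(delta)
        r_new <- residual_fn(p_new)
        c_new <- sum(r_new * r_new)
        if (is.finite(c_new) && c_new <= cost) {
          rel_change <- (cost - c_new) / max(cost, 1e-300)
          par <- p_new; r <- r_new; cost <- c_new
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          break
        }
      }
      lambda <- lambda * 4
    }
    if (!step_ok) {
      # could not improve: treat as converged if gradient is flat, else failed
      converged <- max(abs(g)) < 1e-10 * max(1, cost)
      break
    }
    if (cost < 1e-300) {
      converged <- TRUE
      break
    }
    # a single small-improvement step can be a damped stall far from the
    # optimum; require the relative-cost criterion on two consecutive
    # accepted steps (the second taken at reduced damping) before stopping
    if (rel_change < rel_tol) {
      n_small <- n_small + 1L
      if (n_small >= 2L) {
        converged <- TRUE
        break
      }
      lambda <- max(lambda / 100, 1e-12)
    } else {
      n_small <- 0L
    }
  }
  list(par = par, cost = cost, converged = converged,
       n_iter = iter, rel_change = rel_change)
}
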