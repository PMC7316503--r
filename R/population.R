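# Wilson 95% score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Looping probability of a condition
#'
#' The frequency at which loop extrusion occurs on strands with sufficient
#' slack: strands whose baseline relative extension is at or above the slack
#' threshold (default 0.6) cannot form a loop and are excluded from the
#' denominator.
#'
#' @param re0 Baseline relative extensions, one per strand, in `(0, 1]`.
#' @param looped Logical per strand: did a looping event occur?
#' @param condition Condition label (e.g. `"mock"`, `"condensin-depleted"`).
#' @param slack_threshold Strands with `re0 >=` this are excluded
#'   (default 0.6).
#' @return A `strand_census` list: `condition`, `n_strands_with_slack`,
#'   `n_looping`, `probability`, `conf_int` (Wilson 95%).
#' @export
extrusion_probability <- function(re0, looped, condition = "",
                                  slack_threshold = 0.6) {
  stopifnot(length(re0) == length(looped), is.logical(looped))
  if (any(re0 <= 0 | re0 > 1)) stop("re0 must lie in (0, 1]")
  eligible <- re0 < slack_threshold
  n <- sum(eligible)
  if (n == 0) stop("no strands with sufficient slack (re0 < ",
                   slack_threshold, ")")
  k <- sum(looped & eligible)
  structure(list(condition = condition, n_strands_with_slack = n,
                 n_looping = k, probability = k / n,
                 conf_int = wilson_interval(k, n)),
            class = "strand_census")
}

#' @export
print.strand_census <- function(x, ...) {
  cat(sprintf("%s: %d/%d strands looped (p = %.3f, 95%% CI %.3f-%.3f)\n",
              if (nzchar(x$condition)) x$condition else "census",
              x$n_looping, x$n_strands_with_slack, x$probability,
              x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Compare looping probabilities of two conditions
#'
#' Exact binomial comparison of two strand censuses. The default
#' (`method = "conditional"`) conditions on the total number of looping
#' events: under equal looping probabilities, the split of the `a + b` events
#' between the two conditions follows (conservatively) a binomial with
#' success probability `n_b / (n_a + n_b)`, and the treated count is tested
#' against it two-sided with [stats::binom.test()]. This controls the type-I
#' error at the nominal level. `method = "plugin"` instead tests the treated
#' count against the control's point-estimate probability; it is
#' anti-conservative for small censuses and is provided for comparison only.
#'
#' @param census_a Control [extrusion_probability()] census.
#' @param census_b Treated census.
#' @param method `"conditional"` (default) or `"plugin"`.
#' @param alpha Significance level for the star annotation (default 0.01).
#' @return A `condition_comparison` list: `p_value`, `significant`, `stars`,
#'   `method`, `conditions`.
#' @export
compare_conditions <- function(census_a, census_b,
                               method = c("conditional", "plugin"),
                               alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(census_a, "strand_census"),
            inherits(census_b, "strand_census"))
  ka <- census_a$n_looping; na <- census_a$n_strands_with_slack
  kb <- census_b$n_looping; nb <- census_b$n_strands_with_slack
  if (method == "conditional") {
    total <- ka + kb
    p_value <- if (total == 0) 1 else {
      stats::binom.test(kb, total, p = nb / (na + nb),
                        alternative = "two.sided")$p.value
    }
  } else {
    p0 <- census_a$probability
    p_value <- if (p0 <= 0 || p0 >= 1) {
      # degenerate control: any discordant treated count is impossible under
      # the plug-in null, handled exactly without division
      if ((p0 <= 0 && kb == 0) || (p0 >= 1 && kb == nb)) 1 else 0
    } else {
      stats::binom.test(kb, nb, p = p0, alternative = "two.sided")$p.value
    }
  }
  structure(list(p_value = p_value, significant = p_value < alpha,
                 stars = if (p_value < alpha) "**" else "ns",
                 method = method,
                 conditions = c(census_a$condition, census_b$condition)),
            class = "condition_comparison")
}

#' Cluster scattered points by proximity for error bars
#'
#' 1-D agglomerative clustering of the x values (e.g. baseline relative
#' extension): sorted points are split wherever the gap between neighbours
#' exceeds `gap`. Each cluster reports the mean x, mean y and SD of y
#' (singleton clusters get SD 0 and are flagged). Raw points are preserved.
#'
#' @param x Numeric vector (clustering axis), length >= 2.
#' @param y Numeric vector of values, same length.
#' @param gap Gap threshold in x units (default 0.05).
#' @return List with `clusters` (data frame `x_mean`, `y_mean`, `y_sd`, `n`,
#'   `singleton`) and `points` (the raw data with cluster ids).
#' @export
cluster_errorbars <- function(x, y, gap = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2, gap > 0)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cl <- cumsum(c(1, diff(xs) > gap))
  agg <- lapply(split(seq_along(xs), cl), function(i) {
    data.frame(x_mean = mean(xs[i]), y_mean = mean(ys[i]),
               y_sd = if (length(i) > 1) stats::sd(ys[i]) else 0,
               n = length(i), singleton = length(i) == 1)
  })
  clusters <- do.call(rbind, agg)
  rownames(clusters) <- NULL
  list(clusters = clusters,
       points = data.frame(x = xs, y = ys, cluster = cl))
}
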