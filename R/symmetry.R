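#' DNA extruded from each flanking region, with slippage clipping
#'
#' For each flanking region, the amount of DNA extruded into the loop over
#' the event is the mean of its first ten accepted time points minus the mean
#' of its last ten. A region that *gained* DNA did not feed the loop -- the
#' loop slipped DNA back out -- so its extruded amount is clipped to zero and
#' the gain recorded as slippage; slippage above 2 kb is flagged as
#' substantial.
#'
#' @param trace A `loop_trace` with `regionI_kb` / `regionII_kb` columns.
#' @param n_edge Number of leading/trailing accepted frames to average
#'   (default 10).
#' @param substantial_kb Slippage flag threshold in kb (default 2).
#' @return A `region_changes` list: `a` (kb extruded from region I, >= 0),
#'   `b` (region II), `slippage_I_kb`, `slippage_II_kb`,
#'   `substantial_slippage`.
#' @export
region_changes <- function(trace, n_edge = 10L, substantial_kb = 2) {
  ok <- which(!is.na(trace$regionI_kb) & !is.na(trace$regionII_kb))
  if (length(ok) < 2 * n_edge) {
    stop("need >= ", 2 * n_edge, " accepted frames with region values")
  }
  head_idx <- ok[seq_len(n_edge)]
  tail_idx <- ok[seq(length(ok) - n_edge + 1L, length(ok))]
  a_raw <- mean(trace$regionI_kb[head_idx]) - mean(trace$regionI_kb[tail_idx])
  b_raw <- mean(trace$regionII_kb[head_idx]) - mean(trace$regionII_kb[tail_idx])
  structure(list(a = max(a_raw, 0), b = max(b_raw, 0),
                 slippage_I_kb = max(-a_raw, 0),
                 slippage_II_kb = max(-b_raw, 0),
                 substantial_slippage = max(-a_raw, -b_raw, 0) > substantial_kb),
            class = "region_changes")
}

#' Symmetry score of a looping event
#'
#' \deqn{score = (\max(a, b) - \min(a, b)) / (a + b)}
#' over the non-negative amounts of DNA extruded from the two flanking
#' regions. 1 means all DNA came from one side (one-sided extrusion), 0 means
#' equal contributions (symmetric extrusion). Undefined when no DNA was
#' extruded (`a + b == 0`): returns `NA` with a warning, and such events are
#' rejected from symmetry statistics.
#'
#' @param a,b Non-negative extruded amounts (kb), e.g. from
#'   [region_changes()]; `a` may also be a `region_changes` object.
#' @return Score in `[0, 1]`, or `NA` if undefined.
#' @examples
#' symmetry_score(10, 0)  # 1: one-sided
#' symmetry_score(5, 5)   # 0: symmetric
#' @export
symmetry_score <- function(a, b = NULL) {
  if (inherits(a, "region_changes")) {
    b <- a$b
    a <- a$a
  }
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (any(a < 0 | b < 0)) stop("a and b must be >= 0 (clip slippage first)")
  out <- ifelse(a + b > 0, (pmax(a, b) - pmin(a, b)) / (a + b), NA_real_)
  if (anyNA(out)) warning("symmetry score undefined where a + b == 0")
  out
}

#' Classify extrusion symmetry
#'
#' Events with a symmetry score below 0.5 are two-sided; 0.5 and above are
#' one-sided (the threshold itself belongs to the one-sided class, since
#' two-sided is defined by "score less than 0.5").
#'
#' @param score Score(s) in `[0, 1]`.
#' @return Character vector `"one_sided"` / `"two_sided"` (`NA` passes
#'   through).
#' @export
classify_symmetry <- function(score) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) stop("score outside [0, 1]")
  ifelse(is.na(score), NA_character_,
         ifelse(score < 0.5, "two_sided", "one_sided"))
}

#' Loop displacement along the strand
#'
#' The change in relative loop position between the first and last ten
#' accepted time points, sign-oriented so that movement towards (or across)
#' the strand center is positive and movement towards the nearest boundary is
#' negative, regardless of which half the loop started in. Displacements with
#' magnitude below 0.08 are classified as static. A loop starting exactly at
#' the center can only move towards a boundary, so its displacement is
#' `-|change|`.
#'
#' @param trace A `loop_trace` with `loop_position_rel`.
#' @param n_edge Leading/trailing frames to average (default 10).
#' @param static_threshold Magnitude below which the loop is static
#'   (default 0.08, in relative-position units).
#' @return A `displacement_result` list: `displacement_rel`, `static`,
#'   `direction_class` (`"toward_center"`, `"toward_boundary"`, `"static"`),
#'   `start_rel`, `end_rel`.
#' @export
loop_displacement <- function(trace, n_edge = 10L, static_threshold = 0.08) {
  ok <- which(!is.na(trace$loop_position_rel))
  if (length(ok) < 2 * n_edge) {
    stop("need >= ", 2 * n_edge, " accepted frames with loop positions")
  }
  p0 <- mean(trace$loop_position_rel[ok[seq_len(n_edge)]])
  p1 <- mean(trace$loop_position_rel[ok[seq(length(ok) - n_edge + 1L,
                                            length(ok))]])
  disp <- if (p0 < 0.5) p1 - p0 else if (p0 > 0.5) p0 - p1 else -abs(p1 - p0)
  static <- abs(disp) < static_threshold
  structure(list(displacement_rel = disp, static = static,
                 direction_class = if (static) "static"
                                   else if (disp > 0) "toward_center"
                                   else "toward_boundary",
                 start_rel = p0, end_rel = p1),
            class = "displacement_result")
}

#' Fraction of mobile loops moving towards the strand center
#'
#' Among non-static events, the fraction whose displacement is positive
#' (towards or across the center), with a Wilson 95% confidence interval. A
#' value near 0.5 is the signature of randomly oriented one-sided extruders;
#' a strong boundary bias (< 0.5) is expected for symmetric extrusion
#' starting off-center.
#'
#' @param displacements List of `displacement_result`s, or a numeric vector
#'   of oriented displacements.
#' @param static_threshold Static cutoff applied to numeric input.
#' @return List `fraction_toward_center`, `n_mobile`, `n_static`,
#'   `conf_int` (Wilson 95%).
#' @export
center_bias <- function(displacements, static_threshold = 0.08) {
  if (is.list(displacements) && !is.data.frame(displacements)) {
    disp <- vapply(displacements, function(d) d$displacement_rel, numeric(1))
  } else {
    disp <- as.numeric(displacements)
  }
  mobile <- abs(disp) >= static_threshold
  if (!any(mobile)) stop("all events are static")
  k <- sum(disp[mobile] > 0)
  n <- sum(mobile)
  list(fraction_toward_center = k / n, n_mobile = n,
       n_static = sum(!mobile), conf_int = wilson_interval(k, n))
}
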