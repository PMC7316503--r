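#' Kymograph container
#'
#' A kymograph is a time x position intensity raster (rows = frames) plus the
#' calibration needed to interpret it: pixel size, frame interval and the
#' pixel positions of the two strand anchors.
#'
#' @param data Numeric matrix, rows = time points.
#' @param pixel_size_um um per pixel.
#' @param frame_interval_s Seconds per frame.
#' @param anchor_px Length-2 integer-ish vector, left/right anchor column
#'   (1-based), `anchor_px[1] < anchor_px[2]`.
#' @param background_level Optional known background (photons/px).
#' @param background_subtracted Has the background already been removed?
#' @return A `kymograph` object.
#' @export
new_kymograph <- function(data, pixel_size_um, frame_interval_s, anchor_px,
                          background_level = NA_real_,
                          background_subtracted = FALSE) {
  stopifnot(is.matrix(data), is.numeric(data),
            length(anchor_px) == 2, anchor_px[1] < anchor_px[2],
            pixel_size_um > 0, frame_interval_s > 0)
  structure(data, class = c("kymograph", "matrix", "array"),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            anchor_px = as.numeric(anchor_px),
            background_level = background_level,
            background_subtracted = background_subtracted)
}

#' @export
print.kymograph <- function(x, ...) {
  a <- attr(x, "anchor_px")
  cat("kymograph:", nrow(x), "frames x", ncol(x), "px;",
      attr(x, "pixel_size_um"), "um/px,",
      attr(x, "frame_interval_s"), "s/frame; anchors at px",
      a[1], "-", a[2],
      if (isTRUE(attr(x, "background_subtracted"))) "(background subtracted)" else "",
      "\n")
  invisible(x)
}

#' Project a movie frame onto the strand axis
#'
#' Sums intensities along the direction perpendicular to the DNA strand
#' inside the region of interest, yielding a 1-D intensity profile whose
#' length equals the ROI width. The strand axis is assumed horizontal within
#' the ROI.
#'
#' @param frame 2-D numeric matrix.
#' @param strand_roi List with integer vectors `rows` and `cols` (the band
#'   containing the strand); defaults to the whole frame.
#' @return Numeric profile of length `length(strand_roi$cols)`.
#' @export
project_frame <- function(frame, strand_roi = NULL) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (is.null(strand_roi)) {
    strand_roi <- list(rows = seq_len(nrow(frame)), cols = seq_len(ncol(frame)))
  }
  rows <- strand_roi$rows; cols <- strand_roi$cols
  if (length(rows) == 0 || length(cols) == 0) stop("empty ROI")
  if (min(rows) < 1 || max(rows) > nrow(frame) ||
      min(cols) < 1 || max(cols) > ncol(frame)) {
    stop("ROI outside frame bounds")
  }
  colSums(frame[rows, cols, drop = FALSE])
}

#' Subtract the background from an intensity profile
#'
#' Estimates a smooth baseline from the pixels *outside* the strand support
#' (the strand itself, loop spot included, must not be treated as background)
#' and subtracts it, clamping negative residues to zero. Support is detected
#' by thresholding against a robust background estimate from the dimmest
#' pixels; under the support the baseline is bridged by linear interpolation
#' and then smoothed with a running median of `kernel_px` points.
#'
#' @param profile Numeric intensity profile.
#' @param kernel_px Odd running-median kernel, `>= 3`, `<=` profile length.
#' @return Background-subtracted profile (non-negative); the estimated
#'   baseline is attached as attribute `baseline`.
#' @export
subtract_background <- function(profile, kernel_px = 51L) {
  n <- length(profile)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px %% 2L == 0L || kernel_px < 3L) stop("kernel_px must be odd, >= 3")
  if (kernel_px > n) stop("kernel larger than profile")
  dim_px <- profile <= stats::quantile(profile, 0.1)
  bg0 <- stats::median(profile[dim_px])
  noise <- stats::mad(profile[dim_px])
  thr <- bg0 + max(4 * noise, 0.02 * (max(profile) - bg0), 1e-12)
  support <- profile > thr
  if (!any(support) || all(support)) {
    baseline <- stats::runmed(profile, kernel_px, endrule = "median")
  } else {
    x_out <- which(!support)
    bridged <- stats::approx(x_out, profile[x_out], xout = seq_len(n),
                             rule = 2)$y
    baseline <- stats::runmed(bridged, kernel_px, endrule = "median")
  }
  out <- pmax(profile - baseline, 0)
  attr(out, "baseline") <- as.numeric(baseline)
  out
}

# Locate the strand anchors on a background-subtracted time-averaged profile:
# outermost columns whose intensity exceeds 20% of the strand median.
detect_anchors <- function(mean_profile) {
  m <- mean_profile
  strand_med <- stats::median(m[m > 0.2 * max(m)])
  support <- which(m > 0.2 * strand_med)
  if (length(support) < 3) stop("strand not detected (support < 3 px)")
  c(min(support), max(support))
}

#' Build a kymograph from a movie
#'
#' Projects each frame perpendicular to the strand, removes the background per
#' profile, concatenates the profiles into a time x position raster and
#' locates the strand anchors from the time-averaged profile.
#'
#' @param movie A `movie_stack` (see [render_movie()]) or a plain list of
#'   frame matrices.
#' @param kernel_px Running-median kernel passed to [subtract_background()].
#' @param strand_roi ROI override; defaults to the movie's own.
#' @param pixel_size_um,frame_interval_s Calibration overrides for plain-list
#'   input.
#' @return A background-subtracted `kymograph`.
#' @export
build_kymograph <- function(movie, kernel_px = 51L, strand_roi = NULL,
                            pixel_size_um = NULL, frame_interval_s = NULL) {
  if (inherits(movie, "movie_stack")) {
    frames <- movie$frames
    if (is.null(strand_roi)) strand_roi <- movie$strand_roi
    if (is.null(pixel_size_um)) pixel_size_um <- movie$pixel_size_um
    if (is.null(frame_interval_s)) frame_interval_s <- movie$frame_interval_s
  } else {
    frames <- movie
  }
  stopifnot(length(frames) >= 1, !is.null(pixel_size_um),
            !is.null(frame_interval_s))
  shapes <- vapply(frames, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("frames must all have the same shape")
  }
  kernel_eff <- min(kernel_px,
                    if (is.null(strand_roi)) shapes[2, 1] else length(strand_roi$cols))
  if (kernel_eff %% 2L == 0L) kernel_eff <- kernel_eff - 1L
  rows <- lapply(frames, function(fr) {
    as.numeric(subtract_background(project_frame(fr, strand_roi), kernel_eff))
  })
  mat <- do.call(rbind, rows)
  anchors <- detect_anchors(colMeans(mat))
  new_kymograph(mat, pixel_size_um = pixel_size_um,
                frame_interval_s = frame_interval_s, anchor_px = anchors,
                background_subtracted = TRUE)
}

# Ensure a kymograph is background-subtracted; subtract row-wise if not.
subtract_kymograph <- function(kymo, kernel_px = 51L) {
  if (isTRUE(attr(kymo, "background_subtracted"))) return(kymo)
  kernel_eff <- min(as.integer(kernel_px), ncol(kymo))
  if (kernel_eff %% 2L == 0L) kernel_eff <- kernel_eff - 1L
  mat <- t(apply(unclass(kymo), 1, function(p) {
    as.numeric(subtract_background(p, kernel_eff))
  }))
  new_kymograph(mat, pixel_size_um = attr(kymo, "pixel_size_um"),
                frame_interval_s = attr(kymo, "frame_interval_s"),
                anchor_px = attr(kymo, "anchor_px"),
                background_level = attr(kymo, "background_level"),
                background_subtracted = TRUE)
}
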