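#' Worm-like-chain parameter set
#'
#' Bundles the constants needed to convert relative DNA extension into tension:
#' the persistence length, the thermal energy, and the effective (dye-corrected)
#' contour length of the strand both in physical units and in kilobases.
#'
#' Intercalating dyes lengthen DNA, so the physical contour length used for the
#' extension/tension conversion is the *effective* contour length at the working
#' dye concentration (see [effective_contour_length()]), not the bare B-form
#' value of 16.49 um for the 48.5 kb lambda genome.
#'
#' @param persistence_nm Persistence length in nm. Default 50 nm, the standard
#'   value for double-stranded DNA at physiological ionic strength.
#' @param kBT_pN_nm Thermal energy in pN nm. Default 4.11 (about 296 K).
#' @param contour_um Effective contour length of the strand in um
#'   (dye-corrected). Must be at least the bare lambda contour of 16.49 um.
#' @param contour_kb Strand length in kb. Default 48.5 (lambda phage DNA).
#' @return An object of class `wlc_params`.
#' @examples
#' wlc <- wlc_params(contour_um = 20)
#' wlc_force(0.5, wlc)
#' @export
wlc_params <- function(persistence_nm = 50, kBT_pN_nm = 4.11,
                       contour_um = 20, contour_kb = 48.5) {
  stopifnot(is.numeric(persistence_nm), persistence_nm > 0,
            is.numeric(kBT_pN_nm), kBT_pN_nm > 0,
            is.numeric(contour_kb), contour_kb > 0)
  if (!is.numeric(contour_um) || contour_um < 16.49) {
    stop("contour_um must be >= 16.49 um (bare lambda-DNA contour length); ",
         "got ", format(contour_um))
  }
  structure(list(persistence_nm = persistence_nm,
                 kBT_pN_nm = kBT_pN_nm,
                 contour_um = contour_um,
                 contour_kb = contour_kb),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat("WLC parameters: P =", x$persistence_nm, "nm, kBT =", x$kBT_pN_nm,
      "pN nm, contour =", x$contour_um, "um /", x$contour_kb, "kb\n")
  invisible(x)
}

#' Worm-like-chain force at a given relative extension
#'
#' Marko-Siggia interpolation formula
#' \deqn{F(x) = (k_B T / P) [ 1/(4 (1 - x)^2) - 1/4 + x ]}
#' for the tension of a worm-like chain held at relative extension
#' \eqn{x = L / L_c}. Strictly increasing on `[0, 1)`; valid in the
#' inextensible regime (forces up to a few pN) relevant here.
#'
#' @param rel_extension Relative extension(s), in `[0, 1)`.
#' @param wlc A [wlc_params()] object.
#' @return Tension(s) in pN.
#' @examples
#' wlc_force(0.85, wlc_params())  # ~0.96 pN
#' @export
wlc_force <- function(rel_extension, wlc = wlc_params()) {
  x <- rel_extension
  if (!is.numeric(x) || any(!is.finite(x))) stop("rel_extension must be finite numeric")
  if (any(x < 0)) stop("rel_extension < 0")
  if (any(x >= 1)) stop("rel_extension >= 1: strand beyond contour length (overstretched)")
  (wlc$kBT_pN_nm / wlc$persistence_nm) * (1 / (4 * (1 - x)^2) - 0.25 + x)
}

#' Relative extension at a given worm-like-chain force
#'
#' Inverts [wlc_force()] by root bracketing on `[0, 1)`; the force law is
#' strictly monotone so the root is unique. Round-trip accuracy is 1e-9
#' relative or better.
#'
#' @param force Tension(s) in pN, `>= 0`.
#' @param wlc A [wlc_params()] object.
#' @return Relative extension(s) in `[0, 1)`.
#' @export
wlc_extension <- function(force, wlc = wlc_params()) {
  if (!is.numeric(force) || any(!is.finite(force))) stop("force must be finite numeric")
  if (any(force < 0)) stop("negative force")
  vapply(force, function(f) {
    if (f == 0) return(0)
    upper <- 1 - 1e-12
    if (wlc_force(upper, wlc) < f) stop("force beyond inextensible WLC range")
    stats::uniroot(function(x) wlc_force(x, wlc) - f,
                   lower = 0, upper = upper, tol = 1e-13)$root
  }, numeric(1))
}

#' Relative extension of the DNA outside the loop
#'
#' The observable that sets the tension on a doubly tethered strand carrying a
#' loop: the fixed end-to-end distance divided by the contour length of the
#' DNA *outside* the loop,
#' \deqn{RE = L / (CL_{phys} (1 - loop_{kb} / CL_{kb}))}
#' As the loop grows the non-looped contour shrinks and RE rises toward 1.
#'
#' @param end_to_end_um End-to-end (tether-to-tether) distance L in um.
#' @param wlc A [wlc_params()] object carrying the dye-corrected contour length.
#' @param loop_kb Amount of DNA in the loop, kb (scalar or vector).
#' @return Relative extension(s); values `>= 1` indicate the non-looped DNA is
#'   taut beyond its contour (flagged downstream, not an error here unless the
#'   denominator is non-positive).
#' @export
relative_extension <- function(end_to_end_um, wlc = wlc_params(), loop_kb = 0) {
  stopifnot(is.numeric(end_to_end_um), end_to_end_um > 0, is.numeric(loop_kb))
  if (any(loop_kb < 0)) stop("loop_kb < 0")
  denom <- wlc$contour_um * (1 - loop_kb / wlc$contour_kb)
  if (any(denom <= 0)) stop("loop_kb >= contour_kb: non-looped contour is empty")
  end_to_end_um / denom
}

#' Stall force of a looping event
#'
#' The tension at which extrusion stopped: the mean loop size over the last
#' `n_tail` time points is converted to a relative extension and then to a
#' single WLC force per event. Events whose loop window touched a strand
#' anchor near the end of the trace are excluded (the apparent stall is then a
#' geometric artifact, not a force measurement) and yield `NA` with a reason
#' attribute.
#'
#' @param trace A `loop_trace` (see [track_trace()]), or any data frame with
#'   columns `loop_kb` and `flag`.
#' @param wlc A [wlc_params()] object.
#' @param end_to_end_um End-to-end distance in um; defaults to the geometry
#'   stored in the trace.
#' @param n_tail Number of final accepted frames to average (default 10).
#' @return Stall force in pN, or `NA` (with attribute `reason`) for excluded
#'   events.
#' @export
stall_force <- function(trace, wlc = wlc_params(), end_to_end_um = NULL,
                        n_tail = 10) {
  if (is.null(end_to_end_um)) end_to_end_um <- attr(trace, "end_to_end_um")
  if (is.null(end_to_end_um)) stop("end_to_end_um not given and not stored in trace")
  ok <- trace$flag %in% c("ok", "interpolated") & is.finite(trace$loop_kb)
  if (sum(ok) < n_tail) stop("fewer than ", n_tail, " accepted frames")
  idx <- utils::tail(which(ok), n_tail)
  if (any(trace$boundary_contact[idx])) {
    out <- NA_real_
    attr(out, "reason") <- "boundary_contact"
    return(out)
  }
  loop_end <- mean(trace$loop_kb[idx])
  if (loop_end >= wlc$contour_kb * (1 - 1e-9)) {
    out <- NA_real_
    attr(out, "reason") <- "overstretched"
    return(out)
  }
  re <- relative_extension(end_to_end_um, wlc, loop_end)
  if (re >= 1) {
    out <- NA_real_
    attr(out, "reason") <- "overstretched"
    return(out)
  }
  wlc_force(re, wlc)
}

#' Effective contour length from a calibration stretch
#'
#' Intercalating dyes lengthen DNA in a concentration-dependent way. The
#' calibration holds the stretching force fixed (1.54 pN in the reference
#' protocol), measures the extension, and solves
#' `CL_eff = measured_extension / wlc_extension(force)` for the effective
#' contour length at that dye concentration.
#'
#' @param measured_extension_um Measured end-to-end extension in um.
#' @param force_pN Stretching force in pN (must be > 0).
#' @param wlc A [wlc_params()] object supplying P and kBT (its contour fields
#'   are ignored).
#' @return Effective contour length in um.
#' @export
effective_contour_length <- function(measured_extension_um, force_pN,
                                     wlc = wlc_params()) {
  stopifnot(is.numeric(measured_extension_um), is.numeric(force_pN))
  if (any(measured_extension_um <= 0)) stop("measured_extension_um <= 0")
  if (any(force_pN <= 0)) stop("force_pN <= 0")
  measured_extension_um / wlc_extension(force_pN, wlc)
}
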