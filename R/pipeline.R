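#' Default run configuration
#'
#' All analysis thresholds in one serializable list, so every run records the
#' constants it used: median-filter kernel, loop-window width in sigmas,
#' first/last-10 edge count, symmetry class threshold (0.5), static
#' displacement threshold (0.08), slack threshold (0.6), exponential-fit
#' relative cost tolerance (1e-8), Savitzky-Golay window/order (63/2), WLC
#' constants and strand geometry.
#'
#' @param ... Named overrides of any default field.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    median_kernel_px = 51L,
    loop_window_sigma = 2,
    boundary_margin_px = 3,
    n_edge_frames = 10L,
    symmetry_threshold = 0.5,
    static_threshold = 0.08,
    slack_threshold = 0.6,
    fit_rel_tol = 1e-8,
    savgol_window = 63L,
    savgol_order = 2L,
    substantial_slippage_kb = 2,
    track_mode = "seeded",
    persistence_nm = 50,
    kBT_pN_nm = 4.11,
    contour_um = 20,
    contour_kb = 48.5,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks physical and statistical consistency: positive constants, odd
#' median kernel, thresholds in range. Returns a character vector of
#' diagnostics (empty when the config is valid); schema violations are
#' errors, physically vacuous settings are returned as warnings in the
#' diagnostics.
#'
#' @param config A `run_config`.
#' @return Character vector of diagnostics (zero-length if clean).
#' @export
validate_config <- function(config) {
  diag <- character()
  must <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  must(is.list(config), "config must be a list")
  must(config$persistence_nm > 0, "persistence length must be > 0")
  must(config$kBT_pN_nm > 0, "kBT must be > 0")
  must(config$contour_um >= 16.49,
       "contour_um below the bare lambda contour (16.49 um)")
  must(config$median_kernel_px >= 3 && config$median_kernel_px %% 2 == 1,
       "median kernel must be odd and >= 3")
  must(config$loop_window_sigma > 0, "loop window width must be > 0")
  must(config$n_edge_frames >= 1, "n_edge_frames must be >= 1")
  must(config$fit_rel_tol > 0, "fit tolerance must be > 0")
  must(config$savgol_window %% 2 == 1 &&
         config$savgol_window > config$savgol_order,
       "Savitzky-Golay window must be odd and exceed the polynomial order")
  if (config$slack_threshold >= 1) {
    diag <- c(diag, "slack threshold >= 1: slack filter is vacuous")
  }
  if (config$static_threshold <= 0) {
    diag <- c(diag, "static threshold <= 0: every event will be mobile")
  }
  if (config$symmetry_threshold <= 0 || config$symmetry_threshold >= 1) {
    diag <- c(diag, "symmetry threshold outside (0, 1): one class is empty")
  }
  diag
}

#' Analyze one looping event
#'
#' Runs segmentation, kinetics, stall-force and symmetry analysis on a single
#' kymograph and returns a one-row event summary.
#'
#' @param kymo A `kymograph`.
#' @param config A `run_config`.
#' @param event_id Identifier for the output row.
#' @return List with `summary` (one-row data frame), `trace`, `fit`.
#' @export
analyze_event <- function(kymo, config = default_config(), event_id = "event") {
  wlc <- wlc_params(config$persistence_nm, config$kBT_pN_nm,
                    config$contour_um, config$contour_kb)
  trace <- track_trace(kymo, mode = config$track_mode,
                       window_sigma = config$loop_window_sigma,
                       boundary_margin_px = config$boundary_margin_px,
                       kernel_px = config$median_kernel_px,
                       contour_kb = config$contour_kb)
  if (!isTRUE(attr(trace, "accepted"))) {
    return(list(summary = data.frame(event_id = event_id, accepted = FALSE,
                                     rate0_kbps = NA_real_, tau_s = NA_real_,
                                     fit_converged = FALSE,
                                     stall_pN = NA_real_,
                                     stall_excluded = NA,
                                     a_kb = NA_real_, b_kb = NA_real_,
                                     score = NA_real_, class = NA_character_,
                                     slippage_kb = NA_real_,
                                     substantial_slippage = NA,
                                     displacement_rel = NA_real_,
                                     direction_class = NA_character_,
                                     re0 = NA_real_,
                                     stringsAsFactors = FALSE),
                trace = trace, fit = NULL))
  }
  fit <- tryCatch(fit_exponential(trace, rel_tol = config$fit_rel_tol),
                  error = function(e) NULL)
  sf <- stall_force(trace, wlc, n_tail = config$n_edge_frames)
  rc <- region_changes(trace, n_edge = config$n_edge_frames,
                       substantial_kb = config$substantial_slippage_kb)
  score <- suppressWarnings(symmetry_score(rc))
  disp <- loop_displacement(trace, n_edge = config$n_edge_frames,
                            static_threshold = config$static_threshold)
  re0 <- relative_extension(attr(trace, "end_to_end_um"), wlc, 0)
  list(summary = data.frame(
         event_id = event_id, accepted = TRUE,
         rate0_kbps = if (!is.null(fit) && fit$converged)
           fit$initial_rate_kbps else NA_real_,
         tau_s = if (!is.null(fit) && fit$converged) fit$tau_s else NA_real_,
         fit_converged = !is.null(fit) && fit$converged,
         stall_pN = as.numeric(sf),
         stall_excluded = is.na(sf),
         a_kb = rc$a, b_kb = rc$b, score = score,
         class = if (is.na(score)) NA_character_ else classify_symmetry(score),
         slippage_kb = max(rc$slippage_I_kb, rc$slippage_II_kb),
         substantial_slippage = rc$substantial_slippage,
         displacement_rel = disp$displacement_rel,
         direction_class = disp$direction_class,
         re0 = re0,
         stringsAsFactors = FALSE),
       trace = trace, fit = fit)
}

#' Run the full analysis pipeline over a batch of kymographs
#'
#' Analyzes every input event, writes per-event and population CSVs plus a
#' provenance record (full config, package version, seed, per-file status) to
#' the output directory. Identical inputs and config produce identical
#' outputs. Malformed inputs are reported per event without aborting the
#' batch.
#'
#' @param inputs A list of `kymograph` objects (e.g. from
#'   [generate_population()], `lapply(events, "[[", "kymograph")`), or a
#'   directory containing `<id>.tsv`/`<id>.json` pairs written by
#'   [write_kymograph()].
#' @param out_dir Output directory (created if missing).
#' @param config A `run_config`.
#' @return Invisibly, a list with `events` (data frame) and `failures`.
#' @export
run_pipeline <- function(inputs, out_dir, config = default_config()) {
  diags <- validate_config(config)
  for (d in diags) warning(d, call. = FALSE)
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    prefixes <- sub("\\.tsv$", "",
                    list.files(inputs, pattern = "\\.tsv$", full.names = TRUE))
    inputs <- lapply(prefixes, read_kymograph)
    names(inputs) <- basename(prefixes)
  }
  if (!length(inputs)) stop("no input kymographs")
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- sprintf("event_%03d", seq_along(inputs))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  failures <- list()
  for (id in names(inputs)) {
    res <- tryCatch(analyze_event(inputs[[id]], config, event_id = id),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      next
    }
    rows[[id]] <- res$summary
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    stop("all inputs failed: ",
         paste(names(failures), unlist(failures), sep = ": ", collapse = "; "))
  rownames(events) <- NULL
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)

  acc <- events[events$accepted & !is.na(events$score), , drop = FALSE]
  pop <- data.frame(
    n_events = nrow(events),
    n_accepted = sum(events$accepted),
    n_fit_converged = sum(events$fit_converged, na.rm = TRUE),
    mean_rate0_kbps = mean(events$rate0_kbps, na.rm = TRUE),
    mean_stall_pN = mean(events$stall_pN, na.rm = TRUE),
    n_stall_included = sum(!is.na(events$stall_pN)),
    frac_two_sided = if (nrow(acc)) mean(acc$class == "two_sided") else NA_real_,
    frac_static = mean(events$direction_class == "static", na.rm = TRUE))
  utils::write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(schema = "loopscope-provenance-1",
         package_version = as.character(utils::packageVersion("loopscope")),
         config = unclass(config),
         n_inputs = length(inputs),
         failures = failures,
         timestamp_omitted_for_determinism = TRUE),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(events = events, population = pop, failures = failures))
}

#' Write/read a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `read_config`: the `run_config` (round-trips losslessly).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, raw)
}
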