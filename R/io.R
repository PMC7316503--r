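#' Write a kymograph as a plain-text raster with a JSON sidecar
#'
#' The intensity matrix goes to `<prefix>.tsv` (tab-separated, one row per
#' frame, no headers) and the calibration (pixel size, frame interval, anchor
#' positions, background flags, schema version) to `<prefix>.json`.
#'
#' @param kymo A `kymograph`.
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_kymograph <- function(kymo, prefix) {
  stopifnot(inherits(kymo, "kymograph"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(unclass(kymo), tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(schema = "loopscope-kymograph-1",
               pixel_size_um = attr(kymo, "pixel_size_um"),
               frame_interval_s = attr(kymo, "frame_interval_s"),
               anchor_px = attr(kymo, "anchor_px"),
               background_level = attr(kymo, "background_level"),
               background_subtracted = isTRUE(attr(kymo, "background_subtracted")))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param prefix Path prefix (without extension).
#' @return A `kymograph`.
#' @export
read_kymograph <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(json)) {
    stop("missing ", tsv, " or ", json)
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!identical(meta$schema, "loopscope-kymograph-1")) {
    stop("unrecognized kymograph schema: ", meta$schema)
  }
  mat <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  new_kymograph(mat, pixel_size_um = meta$pixel_size_um,
                frame_interval_s = meta$frame_interval_s,
                anchor_px = meta$anchor_px,
                background_level = if (is.null(meta$background_level))
                  NA_real_ else meta$background_level,
                background_subtracted = isTRUE(meta$background_subtracted))
}

#' Write a ground-truth table as CSV with a JSON config sidecar
#'
#' @param truth A `ground_truth` from [simulate_extrusion()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  csv <- paste0(prefix, "_truth.csv")
  json <- paste0(prefix, "_config.json")
  utils::write.csv(as.data.frame(truth), csv, row.names = FALSE)
  cfg <- list(schema = "loopscope-simconfig-1",
              strand = unclass(attr(truth, "strand")),
              extruder = unclass(attr(truth, "extruder")),
              wlc = unclass(attr(truth, "wlc")))
  jsonlite::write_json(cfg, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Write a loop trace as tidy CSV
#'
#' One row per frame with the segmentation columns, plus the strand geometry
#' in a JSON sidecar.
#'
#' @param trace A `loop_trace`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "loop_trace"))
  csv <- paste0(prefix, "_trace.csv")
  json <- paste0(prefix, "_trace.json")
  utils::write.csv(as.data.frame(trace), csv, row.names = FALSE)
  meta <- list(schema = "loopscope-trace-1",
               accepted = isTRUE(attr(trace, "accepted")),
               anchor_px = attr(trace, "anchor_px"),
               pixel_size_um = attr(trace, "pixel_size_um"),
               frame_interval_s = attr(trace, "frame_interval_s"),
               end_to_end_um = attr(trace, "end_to_end_um"))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read/write a dye-calibration table
#'
#' Maps dye concentration (nM) to the effective contour length (um) measured
#' at the fixed calibration force. Plain CSV with columns `dye_nM`,
#' `contour_um`.
#'
#' @param path CSV path.
#' @param table Data frame with `dye_nM` and `contour_um` columns.
#' @return `read_dye_calibration`: the validated data frame.
#' @export
read_dye_calibration <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("dye_nM", "contour_um") %in% names(tab))) {
    stop("calibration table needs columns dye_nM, contour_um")
  }
  if (any(tab$contour_um < 16.49)) {
    stop("calibration contour lengths below the bare lambda contour (16.49 um)")
  }
  tab
}

#' @rdname read_dye_calibration
#' @export
write_dye_calibration <- function(table, path) {
  stopifnot(all(c("dye_nM", "contour_um") %in% names(table)))
  utils::write.csv(table[, c("dye_nM", "contour_um")], path, row.names = FALSE)
  invisible(path)
}
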