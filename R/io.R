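PEAK_AREA_COLUMNS <- c("sample_id", "marker", "transition", "area",
                       "replicate", "day", "sample_type",
                       "nominal_value", "nominal_unit")

#' Read a peak-area CSV
#'
#' The interchange dialect is comma-separated UTF-8 with a mandatory header,
#' dot decimal separator, and columns `sample_id, marker, transition, area,
#' replicate, day, sample_type, nominal_value, nominal_unit`. Concentration
#' nominal values are ug/g (mg/kg is numerically identical and accepted as a
#' unit alias on input).
#'
#' @param path CSV path.
#' @return Peak-area data frame.
#' @export
read_peak_areas <- function(path) {
  if (!file.exists(path)) stop("peak-area file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(PEAK_AREA_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("peak-area CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("area", "replicate", "day", "nominal_value")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & raw != "NA" & is.na(num))
    if (length(bad) > 0L) {
      # +1 for the header row so the line number matches the file
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   raw[bad[1L]], col, bad[1L] + 1L, path), call. = FALSE)
    }
    df[[col]] <- num
  }
  if (any(df$area < 0, na.rm = TRUE)) {
    stop("negative peak areas in ", path, call. = FALSE)
  }
  df$nominal_unit <- ifelse(df$nominal_unit == "mg/kg", "ug/g", df$nominal_unit)
  df[, PEAK_AREA_COLUMNS]
}

#' Write a peak-area CSV (with ground-truth sidecar)
#'
#' Writes the standard peak-area CSV; when the data frame carries a
#' `ground_truth` attribute (as all synthetic generators attach), it is
#' written alongside as `<path>.truth.json`.
#'
#' @param records Peak-area data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_peak_areas <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(PEAK_AREA_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[, PEAK_AREA_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  truth <- attr(records, "ground_truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

curve_to_list <- function(curve) {
  list(marker = curve$marker_code, transition = curve$transition,
       curve_kind = curve$curve_kind, weighting = curve$weighting,
       slope = curve$slope, intercept = curve$intercept,
       se_intercept = curve$se_intercept, r_squared = curve$r_squared,
       n_points = curve$n_points,
       lod = curve$lod, loq = curve$loq,
       lod_reported = signif(curve$lod, 2), loq_reported = signif(curve$loq, 2),
       ion_ratios = as.list(curve$ion_ratios),
       conversion = curve$provenance)
}

#' Write a calibration report (JSON)
#'
#' One entry per marker: slope, intercept, intercept SE, R-squared, LOD/LOQ
#' (full precision plus a 2-significant-figure reporting value) and the
#' conversion provenance. The report embeds a schema id and the seed when
#' one is supplied.
#'
#' @param curves Named list of `calibration_curve` objects.
#' @param path Output JSON path.
#' @param seed Optional seed recorded in the report.
#' @return The path, invisibly.
#' @export
write_calibration_report <- function(curves, path, seed = NULL) {
  out <- list(schema = "allerquant-calibration-report/1",
              seed = seed,
              curves = lapply(curves, curve_to_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a batch screening summary (CSV) and decisions (JSON)
#'
#' @param report A `screening_report`.
#' @param decisions Optional [comply_batch()] data frame merged into the
#'   summary.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_batch_summary <- function(report, path, decisions = NULL) {
  stopifnot(inherits(report, "screening_report"))
  out <- report$allergens[, c("sample_id", "allergen", "marker_code",
                              "conc", "status", "lod", "loq")]
  if (!is.null(decisions)) {
    out <- merge(out, decisions[, c("sample_id", "allergen",
                                    "dose_per_serving_mg", "action_level")],
                 by = c("sample_id", "allergen"), sort = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
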