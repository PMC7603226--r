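#' Fit calibration curves for all markers of a data set
#'
#' @param records Calibration peak-area data frame (spiked or incurred
#'   calibrants).
#' @param registry An `allergen_registry`.
#' @param curve_kind `"spiked"` or `"incurred"`.
#' @param chain Volumetric chain preset for spiked-level conversion.
#' @param weighting Passed to [build_curve()].
#' @return Named list of `calibration_curve` objects keyed by marker code.
#' @export
calibrate_all <- function(records, registry,
                          curve_kind = c("spiked", "incurred"),
                          chain = "extraction_spe",
                          weighting = c("none", "inverse_x")) {
  curve_kind <- match.arg(curve_kind)
  weighting <- match.arg(weighting)
  codes <- intersect(names(registry$markers), unique(records$marker))
  if (length(codes) == 0L) stop("no registry markers in records", call. = FALSE)
  curves <- lapply(codes, function(code) {
    conversion <- if (curve_kind == "spiked") {
      marker_context(registry, code, chain = chain)
    } else NULL
    build_curve(records, code, registry, curve_kind = curve_kind,
                conversion = conversion, weighting = weighting)
  })
  names(curves) <- codes
  curves
}

#' Run the simulate -> calibrate -> screen -> comply workflow
#'
#' End-to-end convenience wrapper: generates a synthetic calibration set and
#' a screening batch, fits per-marker curves, screens the lots, applies the
#' VITAL rules, and (optionally) writes the report artifacts.
#'
#' @param seed Seed for all randomness.
#' @param out_dir Optional output directory for the CSV/JSON artifacts.
#' @param cfg A [synthetic_config()] (rebuilt with `seed` when omitted).
#' @param curve_kind Which calibration to censor against (`"incurred"`
#'   reflects processed-food sensitivity and is the default; the report
#'   names the curve used).
#' @param n_lots,contaminated Passed to [generate_screening_batch()].
#' @param rules VITAL rules, see [default_vital_rules()].
#' @return List with `curves`, `screening` (a `screening_report`),
#'   `decisions`, `seed` and `curve_kind`.
#' @export
run_screening_pipeline <- function(seed = 1L, out_dir = NULL, cfg = NULL,
                                   curve_kind = c("incurred", "spiked"),
                                   n_lots = 10L, contaminated = numeric(0),
                                   rules = default_vital_rules()) {
  curve_kind <- match.arg(curve_kind)
  if (is.null(cfg)) cfg <- synthetic_config(seed = seed)
  cal <- generate_calibration(cfg, curve_kind, seed = seed)
  curves <- calibrate_all(cal, cfg$registry, curve_kind = curve_kind,
                          chain = cfg$chain)
  batch <- generate_screening_batch(cfg, n_lots = n_lots,
                                    contaminated = contaminated,
                                    seed = seed + 1L)
  screening <- screen_lots(batch, curves, cfg$registry)
  decisions <- comply_batch(screening, rules)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peak_areas(cal, file.path(out_dir, "calibration.csv"))
    write_peak_areas(batch, file.path(out_dir, "screening_batch.csv"))
    write_calibration_report(curves, file.path(out_dir, "calibration_report.json"),
                             seed = seed)
    write_batch_summary(screening, file.path(out_dir, "batch_summary.csv"),
                        decisions = decisions)
  }
  list(curves = curves, screening = screening, decisions = decisions,
       seed = seed, curve_kind = curve_kind)
}
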