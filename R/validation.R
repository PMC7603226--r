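#' Percent coefficient of variation
#'
#' @param values Numeric vector (>= 2 values) of peak areas or
#'   concentrations with non-zero mean.
#' @return 100 * sample standard deviation / mean.
#' @examples
#' cv_percent(c(9, 10, 11))  # 10
#' @export
cv_percent <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Intra/inter-day precision study with ANOVA day comparison
#'
#' Computes the per-day (intra-day) CV percent, the pooled inter-day CV
#' percent (CV over all observations across days), and a one-way
#' fixed-effects ANOVA comparing day means; the study passes when the ANOVA
#' p-value exceeds `alpha` (no significant day effect). A variance-components
#' inter-day estimator (between-day plus within-day) is available behind
#' `inter_day = "variance_components"`.
#'
#' @param data Data frame with columns `day` and `area` (or `value`).
#' @param alpha Significance level (default 0.05 for a 95 percent confidence
#'   level).
#' @param inter_day `"pooled"` (default) or `"variance_components"`.
#' @return Object of class `precision_report`: per-day CVs, inter-day CV,
#'   ANOVA F and p, `verdict` (TRUE when no significant difference) and a
#'   `degenerate` flag for zero-variance input (F undefined, verdict TRUE).
#' @export
precision_study <- function(data, alpha = 0.05,
                            inter_day = c("pooled", "variance_components")) {
  inter_day <- match.arg(inter_day)
  stopifnot(is.data.frame(data), "day" %in% names(data))
  value_col <- if ("area" %in% names(data)) "area" else "value"
  if (!value_col %in% names(data)) {
    stop("precision data need an 'area' or 'value' column", call. = FALSE)
  }
  v <- data[[value_col]]
  day <- factor(data$day)
  if (nlevels(day) < 2L) stop("precision study needs >= 2 days", call. = FALSE)
  counts <- table(day)
  if (any(counts < 2L)) {
    stop("each day needs >= 2 replicates (day ",
         paste(names(counts)[counts < 2], collapse = ", "), ")", call. = FALSE)
  }

  per_day <- vapply(split(v, day), cv_percent, numeric(1))

  if (inter_day == "pooled") {
    cv_inter <- cv_percent(v)
  } else {
    # between + within variance components (method-of-moments, balanced)
    fitv <- stats::aov(v ~ day)
    ms <- summary(fitv)[[1]][["Mean Sq"]]
    n_per <- mean(counts)
    var_between <- max(0, (ms[1] - ms[2]) / n_per)
    cv_inter <- 100 * sqrt(var_between + ms[2]) / mean(v)
  }

  degenerate <- stats::var(v) == 0
  if (degenerate) {
    f_stat <- NA_real_; p_val <- NA_real_; verdict <- TRUE
  } else {
    fit <- stats::aov(v ~ day)
    tab <- summary(fit)[[1]]
    f_stat <- tab[["F value"]][1]
    p_val <- tab[["Pr(>F)"]][1]
    verdict <- p_val > alpha
  }

  structure(list(cv_intra_day = per_day, cv_inter_day = cv_inter,
                 n_days = nlevels(day), n_per_day = as.integer(counts),
                 anova_f = f_stat, anova_p = p_val, alpha = alpha,
                 verdict = verdict, degenerate = degenerate,
                 inter_day_estimator = inter_day),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report> ", x$n_days, " days\n", sep = "")
  cat("  intra-day CV%:", paste(sprintf("%.2f", x$cv_intra_day), collapse = ", "),
      "\n  inter-day CV%:", sprintf("%.2f", x$cv_inter_day), "\n")
  if (x$degenerate) {
    cat("  ANOVA degenerate (zero variance); verdict: no significant difference\n")
  } else {
    cat(sprintf("  ANOVA F = %.3f, p = %.4f (alpha %.2f): %s\n",
                x$anova_f, x$anova_p, x$alpha,
                if (x$verdict) "no significant day difference"
                else "significant day difference"))
  }
  invisible(x)
}

#' Method recovery against a validated reference value
#'
#' Recovery is the percent ratio of measured to validated concentration,
#' computed per independent sample and then averaged (mean of ratios), with
#' the standard deviation over samples.
#'
#' @param measured Numeric vector of measured concentrations (ug/g) from
#'   independent samples.
#' @param validated Validated (certified) concentration, ug/g; > 0.
#' @param level_label Optional label (e.g. `"LOW"` / `"HIGH"`).
#' @return Object of class `recovery_report` with `recovery_pct`,
#'   `recovery_sd_pct`, per-sample ratios and inputs.
#' @export
recovery <- function(measured, validated, level_label = NA_character_) {
  stopifnot(is.numeric(measured), length(measured) >= 1L,
            is.numeric(validated), length(validated) == 1L)
  if (validated <= 0) stop("validated concentration must be > 0", call. = FALSE)
  if (any(measured < 0)) stop("measured concentrations must be >= 0", call. = FALSE)
  pct <- 100 * measured / validated
  structure(list(level_label = level_label,
                 measured_mean = mean(measured),
                 measured_sd = if (length(measured) > 1L) stats::sd(measured) else 0,
                 validated = validated,
                 recovery_pct = mean(pct),
                 recovery_sd_pct = if (length(pct) > 1L) stats::sd(pct) else 0,
                 per_sample_pct = pct),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report>%s %.1f +/- %.1f %% (measured %.3g vs validated %.3g ug/g, n %d)\n",
              if (is.na(x$level_label)) "" else paste0(" ", x$level_label),
              x$recovery_pct, x$recovery_sd_pct,
              x$measured_mean, x$validated, length(x$per_sample_pct)))
  invisible(x)
}

#' Processing-induced sensitivity reduction
#'
#' Compares the LOD of a spiked (synthetic peptide) calibration with the LOD
#' of an incurred (fortified-before-baking) calibration for the same marker:
#' `reduction_pct = 100 * (1 - lod_spiked / lod_incurred)`. A negative value
#' (sensitivity gain) is permitted and flagged.
#'
#' @param lod_spiked,lod_incurred LODs in ug total protein / g matrix; > 0.
#' @param marker_code Optional marker label.
#' @return Object of class `processing_effect` with `reduction_pct` and a
#'   `sensitivity_gain` flag.
#' @examples
#' processing_effect(0.10, 1.6)$reduction_pct  # 93.75
#' @export
processing_effect <- function(lod_spiked, lod_incurred,
                              marker_code = NA_character_) {
  stopifnot(is.numeric(lod_spiked), is.numeric(lod_incurred))
  if (lod_spiked <= 0 || lod_incurred <= 0) {
    stop("LODs must be > 0", call. = FALSE)
  }
  red <- 100 * (1 - lod_spiked / lod_incurred)
  structure(list(marker_code = marker_code,
                 lod_spiked = lod_spiked, lod_incurred = lod_incurred,
                 reduction_pct = red, sensitivity_gain = red < 0),
            class = "processing_effect")
}

#' @export
print.processing_effect <- function(x, ...) {
  cat(sprintf("<processing_effect>%s LOD %.3g -> %.3g ug/g: %s%.1f%%%s\n",
              if (is.na(x$marker_code)) "" else paste0(" ", x$marker_code),
              x$lod_spiked, x$lod_incurred,
              if (x$sensitivity_gain) "gain " else "reduction ",
              abs(x$reduction_pct),
              if (x$sensitivity_gain) " (flagged)" else ""))
  invisible(x)
}
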