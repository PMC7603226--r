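#' One calibration level
#'
#' @param nominal_conc Nominal concentration of the level (units tracked by
#'   the caller: ug/g total protein after conversion, or peptide ug/mL /
#'   ingredient ug/g before conversion).
#' @param areas Numeric vector of replicate peak areas (>= 1).
#' @return Object of class `calibration_level`.
#' @export
calibration_level <- function(nominal_conc, areas) {
  stopifnot(is.numeric(nominal_conc), length(nominal_conc) == 1L,
            is.numeric(areas), length(areas) >= 1L)
  if (nominal_conc < 0) stop("nominal_conc must be >= 0", call. = FALSE)
  structure(list(nominal_conc = nominal_conc, areas = as.numeric(areas)),
            class = "calibration_level")
}

levels_to_frame <- function(levels) {
  if (is.data.frame(levels)) {
    if (!all(c("conc", "area") %in% names(levels))) {
      stop("calibration data frame needs columns 'conc' and 'area'",
           call. = FALSE)
    }
    return(levels[, c("conc", "area")])
  }
  if (is.list(levels) && all(vapply(levels, inherits, logical(1),
                                    "calibration_level"))) {
    return(do.call(rbind, lapply(levels, function(l) {
      data.frame(conc = l$nominal_conc, area = l$areas)
    })))
  }
  stop("levels must be a data frame (conc, area) or a list of calibration_level",
       call. = FALSE)
}

new_calibration_curve <- function(slope, intercept, se_intercept, r_squared,
                                  n_points, df_residual,
                                  se_slope = NA_real_,
                                  marker_code = NA_character_,
                                  transition = NA_character_,
                                  curve_kind = NA_character_,
                                  weighting = "none",
                                  lod = NA_real_, loq = NA_real_,
                                  ion_ratios = NULL, provenance = NULL) {
  structure(list(marker_code = marker_code, transition = transition,
                 slope = slope, intercept = intercept,
                 se_intercept = se_intercept, se_slope = se_slope,
                 r_squared = r_squared, n_points = n_points,
                 df_residual = df_residual, weighting = weighting,
                 curve_kind = curve_kind, lod = lod, loq = loq,
                 ion_ratios = ion_ratios, provenance = provenance),
            class = "calibration_curve")
}

#' Fit a matrix-matched calibration line
#'
#' Ordinary least squares of peak area on concentration. Each replicate
#' injection enters as its own observation by default, preserving residual
#' degrees of freedom for the intercept standard error that drives LOD/LOQ;
#' `average_replicates = TRUE` collapses replicates per level first (for
#' sensitivity analysis). Inverse-concentration weighting is available but
#' off by default.
#'
#' @param levels Data frame with columns `conc`, `area`, or a list of
#'   [calibration_level()] objects.
#' @param weighting `"none"` (default) or `"inverse_x"` (weights 1/conc;
#'   requires all conc > 0).
#' @param average_replicates Average replicate areas per level before
#'   fitting.
#' @return A `calibration_curve` without LOD/LOQ (see [lod_loq()] /
#'   [build_curve()]).
#' @export
fit_line <- function(levels, weighting = c("none", "inverse_x"),
                     average_replicates = FALSE) {
  weighting <- match.arg(weighting)
  df <- levels_to_frame(levels)
  if (anyNA(df$conc) || anyNA(df$area)) {
    stop("calibration data contain missing values", call. = FALSE)
  }
  n_distinct <- length(unique(df$conc))
  if (n_distinct == 1L) {
    stop("all calibration concentrations are identical; design is rank-deficient",
         call. = FALSE)
  }
  if (n_distinct < 3L) {
    stop("insufficient design: at least 3 distinct concentration levels required",
         call. = FALSE)
  }
  if (average_replicates) {
    df <- stats::aggregate(area ~ conc, data = df, FUN = mean)
  }
  if (nrow(df) <= 2L) {
    stop("insufficient design: more than 2 observations required", call. = FALSE)
  }
  w <- NULL
  if (weighting == "inverse_x") {
    if (any(df$conc <= 0)) {
      stop("inverse_x weighting requires all concentrations > 0", call. = FALSE)
    }
    w <- 1 / df$conc
  }
  fit <- stats::lm(area ~ conc, data = df, weights = w)
  # summary.lm warns on zero-residual (noise-free) fits; se_intercept = 0 is
  # a legitimate degenerate value here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  co <- sm$coefficients
  new_calibration_curve(
    slope = unname(co["conc", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    se_intercept = unname(co["(Intercept)", "Std. Error"]),
    se_slope = unname(co["conc", "Std. Error"]),
    r_squared = sm$r.squared,
    n_points = nrow(df),
    df_residual = fit$df.residual,
    weighting = weighting
  )
}

#' Limits of detection and quantification of a calibration line
#'
#' LOD and LOQ are defined as 3 times and 10 times the standard deviation of
#' the line intercept (its OLS standard error) divided by the slope; their
#' ratio is exactly 10/3 by construction. Units follow the concentration
#' axis of the fit.
#'
#' @param curve A fitted `calibration_curve` with positive slope.
#' @return Named numeric vector `c(lod =, loq =)`.
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("LOD/LOQ require a positive calibration slope", call. = FALSE)
  }
  c(lod = 3 * curve$se_intercept / curve$slope,
    loq = 10 * curve$se_intercept / curve$slope)
}

#' Build a complete calibration curve from peak-area records
#'
#' Extracts the quantifier-transition areas of one marker from a peak-area
#' table, converts the nominal values of the levels into total-protein units
#' (ug/g) - via the peptide conversion chain for spiked (synthetic-peptide)
#' curves, or via the ingredient protein fraction for incurred curves - fits
#' the line, attaches LOD/LOQ, and records the mean qualifier/quantifier ion
#' ratio per qualifier transition for later confirmation.
#'
#' @param records Peak-area data frame (see [read_peak_areas()] for the
#'   column contract); `nominal_value` must be populated.
#' @param marker_code Marker to calibrate.
#' @param registry An `allergen_registry`.
#' @param curve_kind `"spiked"` or `"incurred"`.
#' @param conversion For `"spiked"`, a `conversion_context` (default:
#'   [marker_context()] with the extraction + SPE chain); for `"incurred"`,
#'   an ingredient record or protein fraction (default: the marker's
#'   ingredient from the registry).
#' @param weighting Passed to [fit_line()].
#' @return A `calibration_curve` with LOD/LOQ in ug total protein / g matrix
#'   and conversion provenance.
#' @export
build_curve <- function(records, marker_code, registry,
                        curve_kind = c("spiked", "incurred"),
                        conversion = NULL,
                        weighting = c("none", "inverse_x")) {
  curve_kind <- match.arg(curve_kind)
  weighting <- match.arg(weighting)
  rec <- records[records$marker == marker_code, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no peak-area records for marker ", marker_code, call. = FALSE)
  }
  qt <- quantifier_transition(registry, marker_code)
  qt_id <- transition_id(qt$q1_mz, qt$q3_mz)
  quant <- rec[rec$transition == qt_id, , drop = FALSE]
  if (nrow(quant) == 0L) {
    stop("no quantifier-transition records (", qt_id, ") for marker ",
         marker_code, call. = FALSE)
  }
  if (anyNA(quant$nominal_value)) {
    stop("calibration records for ", marker_code,
         " carry missing nominal_value", call. = FALSE)
  }

  if (curve_kind == "spiked") {
    if (is.null(conversion)) conversion <- marker_context(registry, marker_code)
    if (!inherits(conversion, "conversion_context")) {
      stop("spiked curves need a conversion_context", call. = FALSE)
    }
    conc <- peptide_to_total_protein(quant$nominal_value, conversion)
    prov <- list(path = "peptide_ug_per_mL -> ug_tot_prot_per_g",
                 factor = conversion_factor(conversion),
                 chain = as.list(conversion$chain))
  } else {
    if (is.null(conversion)) conversion <- marker_ingredient(registry, marker_code)
    frac <- resolve_fraction(conversion)
    conc <- ingredient_to_protein(quant$nominal_value, frac)
    prov <- list(path = "ug_ingredient_per_g -> ug_tot_prot_per_g",
                 protein_fraction = frac)
  }

  curve <- fit_line(data.frame(conc = conc, area = quant$area),
                    weighting = weighting)
  ll <- lod_loq(curve)

  # expected ion ratio per qualifier transition: mean of (qualifier area /
  # quantifier area) over calibration observations, matched by sample and
  # replicate
  quals <- qualifier_transitions(registry, marker_code)
  ion_ratios <- NULL
  if (nrow(quals) > 0L) {
    ion_ratios <- numeric(0)
    key_q <- paste(quant$sample_id, quant$replicate)
    for (i in seq_len(nrow(quals))) {
      ql_id <- transition_id(quals$q1_mz[i], quals$q3_mz[i])
      ql <- rec[rec$transition == ql_id, , drop = FALSE]
      if (nrow(ql) == 0L) next
      key_l <- paste(ql$sample_id, ql$replicate)
      j <- match(key_q, key_l)
      ok <- !is.na(j) & quant$area > 0
      if (!any(ok)) next
      ion_ratios[ql_id] <- mean(ql$area[j[ok]] / quant$area[ok])
    }
    if (length(ion_ratios) == 0L) ion_ratios <- NULL
  }

  curve$marker_code <- marker_code
  curve$transition <- qt_id
  curve$curve_kind <- curve_kind
  curve$lod <- unname(ll["lod"])
  curve$loq <- unname(ll["loq"])
  curve$ion_ratios <- ion_ratios
  curve$provenance <- prov
  curve
}

#' Inverse prediction from a calibration curve
#'
#' @param curve A fitted `calibration_curve` with positive slope.
#' @param area Peak area(s).
#' @return Concentration(s) `(area - intercept) / slope` on the curve's
#'   concentration axis; may be negative (callers censor).
#' @export
inverse_predict <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(area))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("inverse prediction requires a positive slope", call. = FALSE)
  }
  (area - curve$intercept) / curve$slope
}

#' @export
print.calibration_curve <- function(x, digits = 4, ...) {
  cat("<calibration_curve>",
      if (!is.na(x$marker_code)) paste0(" ", x$marker_code) else "",
      if (!is.na(x$curve_kind)) paste0(" (", x$curve_kind, ")") else "",
      "\n", sep = "")
  cat(sprintf("  area = %.*g * conc + %.*g   (se_intercept %.*g, R^2 %.4f, n %d)\n",
              digits, x$slope, digits, x$intercept, digits, x$se_intercept,
              x$r_squared, x$n_points))
  if (!is.na(x$lod)) {
    cat(sprintf("  LOD %s, LOQ %s ug tot prot/g\n",
                signif(x$lod, 2), signif(x$loq, 2)))
  }
  invisible(x)
}
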