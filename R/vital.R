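#' VITAL action level 1 concentration
#'
#' Converts a reference dose (mg total protein per eating occasion) and a
#' reference amount (portion size, g) into the action level 1 concentration
#' threshold: `reference_dose / reference_amount * 1000` mg total protein
#' per kg of food.
#'
#' @param reference_dose Reference dose, mg total protein; > 0.
#' @param reference_amount Portion size, g; > 0.
#' @return Action level 1 concentration, mg/kg (numerically equal to ug/g).
#' @examples
#' action_level_concentration(0.2, 50)  # 4 mg/kg
#' @export
action_level_concentration <- function(reference_dose, reference_amount) {
  stopifnot(is.numeric(reference_dose), is.numeric(reference_amount))
  if (reference_dose <= 0 || reference_amount <= 0) {
    stop("reference dose and amount must be > 0", call. = FALSE)
  }
  reference_dose / reference_amount * 1000
}

#' A VITAL rule for one allergen
#'
#' @param allergen Allergen label.
#' @param reference_dose ED01-based reference dose, mg total protein
#'   (VITAL 3.0: 0.2 mg for both milk and egg).
#' @param reference_amount Portion size, g (50 g is reasonable for cookies).
#' @param action_level_3_conc Optional "contains" threshold, mg/kg; absent by
#'   default, in which case [vital_decide()] never emits level 3.
#' @return Object of class `vital_rule` with the derived
#'   `action_level_1_conc`.
#' @export
vital_rule <- function(allergen, reference_dose = 0.2, reference_amount = 50,
                       action_level_3_conc = NULL) {
  al1 <- action_level_concentration(reference_dose, reference_amount)
  if (!is.null(action_level_3_conc) && action_level_3_conc <= al1) {
    stop("action_level_3_conc must exceed the action level 1 concentration",
         call. = FALSE)
  }
  structure(list(allergen = allergen, reference_dose = reference_dose,
                 reference_amount = reference_amount,
                 action_level_1_conc = al1,
                 action_level_3_conc = action_level_3_conc),
            class = "vital_rule")
}

#' Default VITAL 3.0 rules (milk and egg)
#' @return Named list of [vital_rule()] objects.
#' @export
default_vital_rules <- function() {
  list(milk = vital_rule("milk", 0.2, 50),
       egg = vital_rule("egg", 0.2, 50))
}

#' VITAL compliance decision for one allergen result
#'
#' Combines a censored concentration call with a VITAL rule:
#'
#' * `quantified`: per-serving dose `conc * portion_g / 1000`; dose at or
#'   below the reference dose -> `level1_no_PAL` (the boundary is inclusive:
#'   at the grid threshold no precautionary labelling is required);
#'   otherwise `level2_may_contain` (or `level3_contains` when a configured
#'   level-3 threshold is met).
#' * `detected_below_loq`: the semi-quantitative concentration is used for
#'   the dose comparison and the rationale says so.
#' * `not_detected`: `level1_no_PAL` when the method LOD is at or below the
#'   action level 1 concentration (the method can certify compliance);
#'   otherwise `indeterminate`.
#' * `unconfirmed`: `indeterminate` (identity not confirmed).
#'
#' @param conc Measured concentration, mg/kg (= ug/g); may be NA when
#'   censored.
#' @param status One of `"quantified"`, `"detected_below_loq"`,
#'   `"not_detected"`, `"unconfirmed"`.
#' @param rule A [vital_rule()].
#' @param method_lod Method LOD, mg/kg; required for censored results.
#' @param portion_g Portion size used for the dose, g (defaults to the
#'   rule's reference amount).
#' @return Object of class `compliance_decision` with `dose_per_serving_mg`,
#'   `action_level` and a rationale string.
#' @export
vital_decide <- function(conc, status, rule, method_lod = NULL,
                         portion_g = rule$reference_amount) {
  stopifnot(inherits(rule, "vital_rule"))
  status <- match.arg(status, c("quantified", "detected_below_loq",
                                "not_detected", "unconfirmed"))
  dose <- NA_real_
  if (status %in% c("quantified", "detected_below_loq")) {
    if (is.na(conc)) stop("quantified/detected result requires a concentration",
                          call. = FALSE)
    dose <- conc * portion_g / 1000
    if (dose <= rule$reference_dose) {
      level <- "level1_no_PAL"
      rationale <- sprintf(
        "dose %.4g mg per %g g serving <= reference dose %.4g mg%s",
        dose, portion_g, rule$reference_dose,
        if (status == "detected_below_loq") " (semi-quantitative, below LOQ)" else "")
    } else if (!is.null(rule$action_level_3_conc) &&
               conc >= rule$action_level_3_conc) {
      level <- "level3_contains"
      rationale <- sprintf("conc %.4g mg/kg >= configured level-3 threshold %.4g mg/kg",
                           conc, rule$action_level_3_conc)
    } else {
      level <- "level2_may_contain"
      rationale <- sprintf(
        "dose %.4g mg per %g g serving exceeds reference dose %.4g mg%s",
        dose, portion_g, rule$reference_dose,
        if (status == "detected_below_loq") " (semi-quantitative, below LOQ)" else "")
    }
  } else if (status == "not_detected") {
    if (is.null(method_lod) || is.na(method_lod)) {
      stop("censored result requires the method LOD", call. = FALSE)
    }
    if (method_lod <= rule$action_level_1_conc) {
      level <- "level1_no_PAL"
      rationale <- sprintf(
        "not detected; method LOD %.4g mg/kg at or below action level 1 (%.4g mg/kg)",
        method_lod, rule$action_level_1_conc)
    } else {
      level <- "indeterminate"
      rationale <- sprintf(
        "not detected, but method LOD %.4g mg/kg exceeds action level 1 (%.4g mg/kg); sensitivity insufficient to certify",
        method_lod, rule$action_level_1_conc)
    }
  } else {
    level <- "indeterminate"
    rationale <- "quantifier signal present but qualifier ion ratio failed confirmation"
  }
  structure(list(allergen = rule$allergen, measured_conc = conc,
                 status = status, portion_g = portion_g,
                 dose_per_serving_mg = dose, action_level = level,
                 action_level_1_conc = rule$action_level_1_conc,
                 method_lod = if (is.null(method_lod)) NA_real_ else method_lod,
                 rationale = rationale),
            class = "compliance_decision")
}

#' @export
print.compliance_decision <- function(x, ...) {
  cat(sprintf("<compliance_decision> %s: %s\n  %s\n",
              x$allergen, x$action_level, x$rationale))
  invisible(x)
}

#' VITAL decisions for a screening report
#'
#' Applies [vital_decide()] to each per-allergen headline row of a
#' [screen_lots()] report.
#'
#' @param report A `screening_report`.
#' @param rules Named list of [vital_rule()] objects keyed by allergen.
#' @return Data frame with one row per lot x allergen, including dose,
#'   action level and rationale.
#' @export
comply_batch <- function(report, rules = default_vital_rules()) {
  stopifnot(inherits(report, "screening_report"))
  rows <- report$allergens
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    rule <- rules[[r$allergen]]
    if (is.null(rule)) stop("no VITAL rule for allergen ", r$allergen,
                            call. = FALSE)
    d <- vital_decide(r$conc, r$status, rule, method_lod = r$lod)
    data.frame(sample_id = r$sample_id, allergen = r$allergen,
               marker_code = r$marker_code, conc = r$conc, status = r$status,
               dose_per_serving_mg = d$dose_per_serving_mg,
               action_level = d$action_level, rationale = d$rationale,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
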