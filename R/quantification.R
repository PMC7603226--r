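#' Quantification / confirmation policy
#'
#' @param ion_ratio_tolerance Relative tolerance on the qualifier/quantifier
#'   area ratio versus the calibration-derived expectation (default 0.30,
#'   i.e. +/-30 percent).
#' @param confirm Enable qualifier-ion confirmation (default TRUE; skipped
#'   silently when no expected ratio is available).
#' @return Object of class `quant_policy`.
#' @export
quant_policy <- function(ion_ratio_tolerance = 0.30, confirm = TRUE) {
  stopifnot(is.numeric(ion_ratio_tolerance), ion_ratio_tolerance > 0,
            is.logical(confirm))
  structure(list(ion_ratio_tolerance = ion_ratio_tolerance, confirm = confirm),
            class = "quant_policy")
}

headline_markers <- c(milk = "FFV", egg = "ISQ")

#' Quantify one sample from its peak-area records
#'
#' For each marker present: duplicate injections are averaged per transition
#' (arithmetic mean), the quantifier area is inverse-predicted through the
#' marker's calibration curve, and the concentration is censored against the
#' curve's LOD/LOQ:
#'
#' * conc < LOD (or negative) -> `not_detected`
#' * LOD <= conc < LOQ        -> `detected_below_loq`
#' * conc >= LOQ              -> `quantified` (boundaries inclusive upward)
#'
#' When qualifier transitions are present and the curve carries expected ion
#' ratios, a quantified call whose observed qualifier/quantifier ratio falls
#' outside the policy tolerance is demoted to `unconfirmed`. Negative
#' inverse predictions are reported as `not_detected` with `conc = NA`.
#'
#' @param records Peak-area data frame for one sample.
#' @param curves Named list of `calibration_curve` objects keyed by marker
#'   code.
#' @param registry An `allergen_registry`.
#' @param policy A [quant_policy()].
#' @return Data frame of class `quant_result` with one row per marker:
#'   `sample_id`, `allergen`, `marker_code`, `conc` (ug total protein/g; NA
#'   when below LOD), `raw_conc` (uncensored), `status`, `ion_ratio`,
#'   `curve_kind`, `lod`, `loq`.
#' @export
quantify_sample <- function(records, curves, registry, policy = quant_policy()) {
  stopifnot(is.data.frame(records), inherits(policy, "quant_policy"))
  sid <- unique(records$sample_id)
  if (length(sid) != 1L) {
    stop("quantify_sample expects records for exactly one sample", call. = FALSE)
  }
  marker_codes <- intersect(names(registry$markers), unique(records$marker))
  out <- lapply(marker_codes, function(code) {
    curve <- curves[[code]]
    if (is.null(curve)) {
      stop("no calibration curve supplied for marker ", code, call. = FALSE)
    }
    rec <- records[records$marker == code, , drop = FALSE]
    qt_id <- with(quantifier_transition(registry, code), transition_id(q1_mz, q3_mz))
    qa <- rec$area[rec$transition == qt_id]
    if (length(qa) == 0L) return(NULL)
    quant_area <- mean(qa)
    raw_conc <- inverse_predict(curve, quant_area)

    status <- if (raw_conc < curve$lod) "not_detected"
              else if (raw_conc < curve$loq) "detected_below_loq"
              else "quantified"

    ion_ratio <- NA_real_
    if (!is.null(curve$ion_ratios) && quant_area > 0) {
      quals <- qualifier_transitions(registry, code)
      ratios <- c()
      confirmed <- TRUE
      for (i in seq_len(nrow(quals))) {
        ql_id <- transition_id(quals$q1_mz[i], quals$q3_mz[i])
        expected <- curve$ion_ratios[ql_id]
        la <- rec$area[rec$transition == ql_id]
        if (length(la) == 0L || is.na(expected)) next
        obs <- mean(la) / quant_area
        ratios <- c(ratios, obs)
        if (abs(obs - expected) > policy$ion_ratio_tolerance * expected) {
          confirmed <- FALSE
        }
      }
      if (length(ratios) > 0L) ion_ratio <- mean(ratios)
      if (policy$confirm && length(ratios) > 0L && !confirmed &&
          status == "quantified") {
        status <- "unconfirmed"
      }
    }
    # integrity flag: a zero quantifier while a qualifier implies quantifiable
    # signal cannot be confirmed (baseline noise on a qualifier does not count)
    if (policy$confirm && quant_area == 0 && !is.null(curve$ion_ratios)) {
      quals <- qualifier_transitions(registry, code)
      for (i in seq_len(nrow(quals))) {
        ql_id <- transition_id(quals$q1_mz[i], quals$q3_mz[i])
        expected <- curve$ion_ratios[ql_id]
        la <- rec$area[rec$transition == ql_id]
        if (length(la) == 0L || is.na(expected) || expected <= 0) next
        implied <- inverse_predict(curve, mean(la)) / expected
        if (implied >= curve$loq) status <- "unconfirmed"
      }
    }

    data.frame(sample_id = sid,
               allergen = marker_allergen(registry, code),
               marker_code = code,
               conc = if (status == "not_detected" || raw_conc < 0) NA_real_
                      else raw_conc,
               raw_conc = raw_conc,
               status = status,
               ion_ratio = ion_ratio,
               curve_kind = curve$curve_kind,
               lod = curve$lod, loq = curve$loq,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop("no quantifier-transition records found in sample ", sid, call. = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("quant_result", class(res))
  res
}

#' Per-allergen headline summary of marker results
#'
#' The headline concentration per allergen comes from the quantifier marker
#' of the most abundant protein (FFV for milk casein, ISQ for egg
#' ovalbumin); the whey and yolk markers remain in the table as specific
#' markers of partial-ingredient formulations.
#'
#' @param results A `quant_result` data frame (one sample).
#' @param headline Named map allergen -> marker code.
#' @return Data frame with one row per allergen present.
#' @export
summarize_allergens <- function(results, headline = headline_markers) {
  out <- lapply(unique(results$allergen), function(al) {
    rows <- results[results$allergen == al, , drop = FALSE]
    pick <- rows[rows$marker_code == headline[[al]], , drop = FALSE]
    if (nrow(pick) == 0L) pick <- rows[1L, , drop = FALSE]
    pick$headline <- TRUE
    pick
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen a batch of lots for allergen contamination
#'
#' Applies [quantify_sample()] to every sample (lot) in the batch and calls
#' a per-lot verdict: a lot is `contaminated` only when at least one marker
#' yields a confirmed `quantified` status; `detected_below_loq` and
#' `unconfirmed` results are reported but do not flag the lot, mirroring a
#' "no quantifiable peak areas" screening rule.
#'
#' @param batch Peak-area data frame for one or more samples.
#' @param curves Named list of calibration curves keyed by marker code.
#' @param registry An `allergen_registry`.
#' @param policy A [quant_policy()].
#' @return Object of class `screening_report`: list with `results` (all
#'   marker-level rows), `allergens` (per lot x allergen headline rows) and
#'   `lots` (per-lot verdict data frame with `contaminated` logical).
#' @export
screen_lots <- function(batch, curves, registry, policy = quant_policy()) {
  stopifnot(is.data.frame(batch))
  ids <- unique(batch$sample_id)
  if (length(ids) == 0L) stop("empty screening batch", call. = FALSE)
  results <- do.call(rbind, lapply(ids, function(id) {
    quantify_sample(batch[batch$sample_id == id, , drop = FALSE],
                    curves, registry, policy)
  }))
  allergens <- do.call(rbind, lapply(ids, function(id) {
    summarize_allergens(results[results$sample_id == id, , drop = FALSE])
  }))
  lots <- do.call(rbind, lapply(ids, function(id) {
    rows <- results[results$sample_id == id, , drop = FALSE]
    data.frame(sample_id = id,
               contaminated = any(rows$status == "quantified"),
               n_quantified = sum(rows$status == "quantified"),
               n_below_loq = sum(rows$status == "detected_below_loq"),
               n_unconfirmed = sum(rows$status == "unconfirmed"),
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- rownames(allergens) <- rownames(lots) <- NULL
  structure(list(results = results, allergens = allergens, lots = lots),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n <- nrow(x$lots)
  nc <- sum(x$lots$contaminated)
  cat("<screening_report> ", n, " lots: ", n - nc,
      " contamination-free at method sensitivity, ", nc, " flagged\n", sep = "")
  if (nc > 0) {
    cat("  flagged:", paste(x$lots$sample_id[x$lots$contaminated],
                            collapse = ", "), "\n")
  }
  invisible(x)
}
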