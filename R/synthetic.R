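#' Configuration of the synthetic peak-area generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a linear peak-area response per marker, replicate (injection)
#' noise, multiplicative day-to-day response drift, a matrix baseline (the
#' line intercept), a multiplicative processing-loss factor `lambda` on the
#' slope of incurred samples, and an extraction-recovery factor `rho` applied
#' to reference-material signal. It starts at integrated areas: no
#' chromatogram-level simulation.
#'
#' Defaults are fixed study conditions: duplicate injections, spiked levels
#' 0.0125/0.05/0.166/0.25 ug peptide/mL, incurred levels 10/30/100/200/300 ug
#' ingredient/g, 5 replicates x 3 days at 100 ug ingredient/g for precision,
#' `lambda` per marker derived from the spiked/incurred LOD ratios typical of
#' baked matrices (casein markers 0.0625, ovalbumin 0.075, yolk 0.625, whey
#' 0.857), `rho = 0.5`, proportional noise 3 percent and additive noise 3000
#' area units against a slope of 5e4 area per (ug/g).
#'
#' @param registry An `allergen_registry`.
#' @param slope,intercept True response parameters (area per ug/g; area);
#'   scalars or named per-marker vectors.
#' @param noise_model `"combined"` (default), `"additive_gaussian"` or
#'   `"proportional_gaussian"`.
#' @param sigma_add Additive noise SD, area units.
#' @param sigma_prop Proportional noise SD, fraction of the mean area.
#' @param day_effect_sd SD of the per-day log response factor.
#' @param processing_loss Named per-marker `lambda` in (0, 1]: slope
#'   multiplier for incurred samples.
#' @param extraction_recovery `rho` in (0, 1]: signal multiplier for
#'   reference-material samples.
#' @param ion_ratio True qualifier/quantifier signal ratio.
#' @param spiked_levels_ugml Spiked calibration levels, ug peptide/mL.
#' @param incurred_levels_ing Incurred calibration levels, ug ingredient/g.
#' @param n_injection_reps Injections per calibration point / sample.
#' @param chain Volumetric chain preset for spiked-level conversion.
#' @param seed Default RNG seed; every generator is a pure function of
#'   (config, seed).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(registry = default_registry(),
                             slope = 5e4, intercept = 1000,
                             noise_model = c("combined", "additive_gaussian",
                                             "proportional_gaussian"),
                             sigma_add = 3000, sigma_prop = 0.03,
                             day_effect_sd = 0.02,
                             processing_loss = c(FFV = 0.0625, YLG = 0.0625,
                                                 TPE = 0.857, VLV = 0.857,
                                                 ISQ = 0.075, GGL = 0.075,
                                                 NIP = 0.625, NIG = 0.625),
                             extraction_recovery = 0.5,
                             ion_ratio = 0.35,
                             spiked_levels_ugml = c(0.0125, 0.05, 0.166, 0.25),
                             incurred_levels_ing = c(10, 30, 100, 200, 300),
                             n_injection_reps = 2L,
                             chain = "extraction_spe",
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(sigma_add >= 0, sigma_prop >= 0, day_effect_sd >= 0,
            all(processing_loss > 0), all(processing_loss <= 1),
            extraction_recovery > 0, extraction_recovery <= 1,
            n_injection_reps >= 1L)
  structure(list(registry = registry, slope = slope, intercept = intercept,
                 noise_model = noise_model, sigma_add = sigma_add,
                 sigma_prop = sigma_prop, day_effect_sd = day_effect_sd,
                 processing_loss = processing_loss,
                 extraction_recovery = extraction_recovery,
                 ion_ratio = ion_ratio,
                 spiked_levels_ugml = spiked_levels_ugml,
                 incurred_levels_ing = incurred_levels_ing,
                 n_injection_reps = as.integer(n_injection_reps),
                 chain = chain, seed = as.integer(seed)),
            class = "synthetic_config")
}

param_for <- function(x, marker) {
  if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
  if (!is.null(names(x)) && marker %in% names(x)) return(as.numeric(x[[marker]]))
  if (length(x) == 1L) return(as.numeric(x))
  stop("no parameter value for marker ", marker, call. = FALSE)
}

perturb <- function(mu, cfg) {
  n <- length(mu)
  out <- switch(cfg$noise_model,
    additive_gaussian = mu + stats::rnorm(n, 0, cfg$sigma_add),
    proportional_gaussian = mu * (1 + stats::rnorm(n, 0, cfg$sigma_prop)),
    combined = mu * (1 + stats::rnorm(n, 0, cfg$sigma_prop)) +
      stats::rnorm(n, 0, cfg$sigma_add)
  )
  pmax(0, out)
}

record_rows <- function(sample_id, marker, q1, q3, areas, replicate, day,
                        sample_type, nominal_value, nominal_unit) {
  data.frame(sample_id = sample_id, marker = marker,
             transition = transition_id(q1, q3), area = areas,
             replicate = replicate, day = day, sample_type = sample_type,
             nominal_value = nominal_value, nominal_unit = nominal_unit,
             stringsAsFactors = FALSE)
}

# one calibration point / sample for one marker: quantifier + qualifiers,
# n injection replicates, truth signal = signal_scale * slope * conc_tp
marker_sample_rows <- function(cfg, marker, sample_id, conc_tp, signal_scale,
                               day, sample_type, nominal_value, nominal_unit,
                               n_inj = cfg$n_injection_reps) {
  reg <- cfg$registry
  slope <- param_for(cfg$slope, marker)
  intercept <- param_for(cfg$intercept, marker)
  signal <- signal_scale * slope * conc_tp
  reps <- seq_len(n_inj)
  qt <- quantifier_transition(reg, marker)
  rows <- record_rows(sample_id, marker, qt$q1_mz, qt$q3_mz,
                      perturb(rep(signal + intercept, length(reps)), cfg),
                      reps, day, sample_type, nominal_value, nominal_unit)
  quals <- qualifier_transitions(reg, marker)
  for (i in seq_len(nrow(quals))) {
    mu_q <- param_for(cfg$ion_ratio, marker) * signal + intercept
    rows <- rbind(rows, record_rows(sample_id, marker, quals$q1_mz[i],
                                    quals$q3_mz[i],
                                    perturb(rep(mu_q, length(reps)), cfg),
                                    reps, day, sample_type, nominal_value,
                                    nominal_unit))
  }
  rows
}

finish_records <- function(rows_list, truth) {
  out <- do.call(rbind, rows_list)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a synthetic calibration data set
#'
#' Spiked curves place levels on the peptide ug/mL axis (converted internally
#' to total-protein ug/g through the marker's conversion context); incurred
#' curves place levels on the ingredient ug/g axis (converted through the
#' ingredient protein fraction) and carry the processing-loss factor
#' `lambda` on the slope.
#'
#' @param cfg A [synthetic_config()].
#' @param curve_kind `"spiked"` or `"incurred"`.
#' @param markers Marker codes to simulate (default: all in the registry).
#' @param seed RNG seed (default: `cfg$seed`).
#' @return Peak-area data frame (standard column contract) with a
#'   `ground_truth` attribute.
#' @export
generate_calibration <- function(cfg, curve_kind = c("spiked", "incurred"),
                                 markers = names(cfg$registry$markers),
                                 seed = cfg$seed) {
  curve_kind <- match.arg(curve_kind)
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(as.integer(seed))
  reg <- cfg$registry
  truth <- list(curve_kind = curve_kind, seed = as.integer(seed), markers = list())
  rows <- list()
  for (m in markers) {
    if (curve_kind == "spiked") {
      ctx <- marker_context(reg, m, chain = cfg$chain)
      nominal <- cfg$spiked_levels_ugml
      conc_tp <- peptide_to_total_protein(nominal, ctx)
      unit <- "ug_peptide/mL"
      lam <- 1
    } else {
      frac <- resolve_fraction(marker_ingredient(reg, m))
      nominal <- cfg$incurred_levels_ing
      conc_tp <- ingredient_to_protein(nominal, frac)
      unit <- "ug_ingredient/g"
      lam <- param_for(cfg$processing_loss, m)
    }
    truth$markers[[m]] <- list(slope = param_for(cfg$slope, m),
                               intercept = param_for(cfg$intercept, m),
                               lambda = lam, conc_tp = conc_tp,
                               nominal = nominal, nominal_unit = unit)
    for (k in seq_along(nominal)) {
      sid <- sprintf("%s_cal_L%02d", curve_kind, k)
      rows[[length(rows) + 1L]] <- marker_sample_rows(
        cfg, m, sid, conc_tp[k], lam, day = 1L,
        sample_type = paste0(curve_kind, "_calibrant"),
        nominal_value = nominal[k], nominal_unit = unit)
    }
  }
  finish_records(rows, truth)
}

#' Generate a synthetic precision (repeatability) data set
#'
#' Independent fortified-QC replicates at a single contamination level
#' repeated over several days, with a multiplicative per-day response factor
#' drawn once per day.
#'
#' @param cfg A [synthetic_config()].
#' @param markers Marker codes to simulate.
#' @param level_ingredient Fortification level, ug ingredient/g (default
#'   100).
#' @param n_replicates,n_days Design (default 5 x 3).
#' @param seed RNG seed.
#' @return Peak-area data frame with `ground_truth` attribute.
#' @export
generate_precision_set <- function(cfg, markers = names(cfg$registry$markers),
                                   level_ingredient = 100,
                                   n_replicates = 5L, n_days = 3L,
                                   seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_replicates >= 2L, n_days >= 2L)
  set.seed(as.integer(seed))
  reg <- cfg$registry
  day_factor <- exp(stats::rnorm(n_days, 0, cfg$day_effect_sd))
  truth <- list(level_ingredient = level_ingredient, day_factor = day_factor,
                seed = as.integer(seed), markers = list())
  rows <- list()
  for (m in markers) {
    frac <- resolve_fraction(marker_ingredient(reg, m))
    conc_tp <- ingredient_to_protein(level_ingredient, frac)
    truth$markers[[m]] <- list(conc_tp = conc_tp,
                               slope = param_for(cfg$slope, m),
                               intercept = param_for(cfg$intercept, m))
    for (d in seq_len(n_days)) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("qc_day%d_rep%d", d, r)
        # each analytical replicate is one independent preparation injected
        # once; repeatability lives across replicates, not injections
        rows[[length(rows) + 1L]] <- marker_sample_rows(
          cfg, m, sid, conc_tp, day_factor[d], day = d,
          sample_type = "fortified_qc", nominal_value = level_ingredient,
          nominal_unit = "ug_ingredient/g", n_inj = 1L)
      }
    }
  }
  finish_records(rows, truth)
}

#' Generate a synthetic reference-material data set
#'
#' Independent incurred reference-material samples at validated total-protein
#' levels, with the extraction-recovery factor `rho` applied to the true
#' signal (so a perfect pipeline measures `rho * validated`).
#'
#' @param cfg A [synthetic_config()].
#' @param marker Marker to simulate (trueness is assessed on the milk casein
#'   marker by default).
#' @param levels Named validated concentrations, ug total protein/g
#'   (defaults to the LOW/HIGH milk RM levels 3.54 and 17.7).
#' @param n_samples Independent samples per level (default 3).
#' @param seed RNG seed.
#' @return Peak-area data frame with `ground_truth` attribute.
#' @export
generate_rm_set <- function(cfg, marker = "FFV",
                            levels = c(LOW = 3.54, HIGH = 17.7),
                            n_samples = 3L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_samples >= 1L)
  set.seed(as.integer(seed))
  rho <- cfg$extraction_recovery
  truth <- list(marker = marker, rho = rho, levels = levels,
                slope = param_for(cfg$slope, marker),
                intercept = param_for(cfg$intercept, marker),
                seed = as.integer(seed))
  rows <- list()
  for (lv in names(levels)) {
    for (s in seq_len(n_samples)) {
      sid <- sprintf("rm_%s_s%d", lv, s)
      rows[[length(rows) + 1L]] <- marker_sample_rows(
        cfg, marker, sid, levels[[lv]], rho, day = 1L,
        sample_type = "reference_material", nominal_value = levels[[lv]],
        nominal_unit = "ug_tot_prot/g")
    }
  }
  finish_records(rows, truth)
}

#' Generate a synthetic screening batch
#'
#' Blank lots emit baseline-only areas (noise around the intercept);
#' contaminated lots emit signal at the given total-protein concentration on
#' every marker of the batch.
#'
#' @param cfg A [synthetic_config()].
#' @param n_lots Number of lots (default 10).
#' @param contaminated Named numeric: lot id (e.g. `"lot_03"`) -> true
#'   contamination, ug total protein/g. Empty by default (all blank).
#' @param markers Marker codes to simulate.
#' @param seed RNG seed.
#' @return Peak-area data frame with `ground_truth` attribute.
#' @export
generate_screening_batch <- function(cfg, n_lots = 10L,
                                     contaminated = numeric(0),
                                     markers = names(cfg$registry$markers),
                                     seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_lots >= 1L)
  set.seed(as.integer(seed))
  ids <- sprintf("lot_%02d", seq_len(n_lots))
  if (length(contaminated) > 0L) {
    unknown <- setdiff(names(contaminated), ids)
    if (length(unknown) > 0L) {
      stop("contaminated lot id(s) not in batch: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  truth <- list(n_lots = n_lots, contaminated = as.list(contaminated),
                seed = as.integer(seed))
  rows <- list()
  for (id in ids) {
    conc <- if (id %in% names(contaminated)) contaminated[[id]] else 0
    for (m in markers) {
      rows[[length(rows) + 1L]] <- marker_sample_rows(
        cfg, m, id, conc, 1, day = 1L, sample_type = "unknown",
        nominal_value = NA_real_, nominal_unit = NA_character_)
    }
  }
  finish_records(rows, truth)
}
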