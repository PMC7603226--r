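# construct a fully specified curve (b0 = 100, b1 = 50, LOD 1, LOQ 10/3)
make_curve <- function(kind = "incurred", ion_ratios = NULL) {
  curve <- allerquant:::new_calibration_curve(
    slope = 50, intercept = 100, se_intercept = 50 / 3, r_squared = 0.999,
    n_points = 8, df_residual = 6, marker_code = "FFV",
    transition = "692.9>991.4", curve_kind = kind, ion_ratios = ion_ratios)
  ll <- lod_loq(curve)
  curve$lod <- unname(ll["lod"]); curve$loq <- unname(ll["loq"])
  curve
}

records_for <- function(reg, code, quant_area, qual_area = NULL,
                        sample_id = "s1") {
  q <- quantifier_id(reg, code)
  out <- data.frame(sample_id = sample_id, marker = code, transition = q,
                    area = quant_area, replicate = seq_along(quant_area),
                    day = 1, sample_type = "unknown",
                    nominal_value = NA_real_, nominal_unit = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(qual_area)) {
    tr <- reg$markers[[code]]$transitions
    ql <- tr[tr$role == "qualifier", ][1, ]
    out <- rbind(out, data.frame(
      sample_id = sample_id, marker = code,
      transition = sprintf("%.1f>%.1f", ql$q1_mz, ql$q3_mz),
      area = qual_area, replicate = seq_along(qual_area), day = 1,
      sample_type = "unknown", nominal_value = NA_real_,
      nominal_unit = NA_character_, stringsAsFactors = FALSE))
  }
  out
}

test_that("statuses partition the concentration axis at LOD and LOQ", {
  reg <- test_registry()
  curve <- make_curve()
  curves <- list(FFV = curve)
  conc_to_area <- function(conc) curve$intercept + curve$slope * conc
  cases <- list(
    list(conc = 0.5 * curve$lod, status = "not_detected"),
    list(conc = curve$lod, status = "detected_below_loq"),       # boundary up
    list(conc = 0.5 * (curve$lod + curve$loq), status = "detected_below_loq"),
    list(conc = curve$loq, status = "quantified"),               # boundary up
    list(conc = 2 * curve$loq, status = "quantified")
  )
  for (cs in cases) {
    rec <- records_for(reg, "FFV", rep(conc_to_area(cs$conc), 2))
    res <- quantify_sample(rec, curves, reg, quant_policy(confirm = FALSE))
    expect_equal(res$status, cs$status, info = paste("conc", cs$conc))
    if (cs$status == "quantified") expect_equal(res$conc, cs$conc)
  }
  # negative inverse prediction is truncated to not_detected with NA conc
  res <- quantify_sample(records_for(reg, "FFV", c(0, 0)), curves, reg,
                         quant_policy(confirm = FALSE))
  expect_equal(res$status, "not_detected")
  expect_true(is.na(res$conc))
  expect_lt(res$raw_conc, 0)
})

test_that("duplicate injections are averaged before inversion", {
  reg <- test_registry()
  curve <- make_curve()
  rec <- records_for(reg, "FFV", c(600, 800))  # mean 700 -> conc 12
  res <- quantify_sample(rec, list(FFV = curve), reg,
                         quant_policy(confirm = FALSE))
  expect_equal(res$conc, (700 - 100) / 50)
})

test_that("failed ion-ratio confirmation demotes a quantified call", {
  reg <- test_registry()
  curve <- make_curve(ion_ratios = c("692.9>920.3" = 0.4))
  curves <- list(FFV = curve)
  area <- curve$intercept + curve$slope * (2 * curve$loq)
  ok <- quantify_sample(records_for(reg, "FFV", rep(area, 2),
                                    qual_area = rep(0.4 * area, 2)),
                        curves, reg)
  expect_equal(ok$status, "quantified")
  expect_equal(ok$ion_ratio, 0.4)
  bad <- quantify_sample(records_for(reg, "FFV", rep(area, 2),
                                     qual_area = rep(0.1 * area, 2)),
                         curves, reg)
  expect_equal(bad$status, "unconfirmed")
  # confirmation can be disabled
  off <- quantify_sample(records_for(reg, "FFV", rep(area, 2),
                                     qual_area = rep(0.1 * area, 2)),
                         curves, reg, quant_policy(confirm = FALSE))
  expect_equal(off$status, "quantified")
  # zero quantifier with strong qualifier signal is unconfirmed
  zero <- quantify_sample(records_for(reg, "FFV", c(0, 0),
                                      qual_area = rep(0.4 * area * 10, 2)),
                          curves, reg)
  expect_equal(zero$status, "unconfirmed")
})

test_that("status is monotone non-decreasing in quantifier area", {
  reg <- test_registry()
  curves <- list(FFV = make_curve())
  order_of <- c(not_detected = 1, detected_below_loq = 2, unconfirmed = 2.5,
                quantified = 3)
  areas <- seq(0, 1500, by = 25)
  st <- vapply(areas, function(a) {
    quantify_sample(records_for(reg, "FFV", rep(a, 2)), curves, reg,
                    quant_policy(confirm = FALSE))$status
  }, character(1))
  expect_true(all(diff(order_of[st]) >= 0))
})

test_that("missing curve or quantifier record raises a configuration error", {
  reg <- test_registry()
  rec <- records_for(reg, "FFV", c(10, 10))
  expect_error(quantify_sample(rec, list(), reg), "no calibration curve")
  rec2 <- rec; rec2$sample_id <- c("a", "a")
  multi <- rbind(rec, rec2)
  multi$sample_id <- c("s1", "s2")
  expect_error(quantify_sample(multi, list(FFV = make_curve()), reg),
               "exactly one sample")
})

test_that("screening flags only confirmed quantifiable lots", {
  reg <- test_registry()
  cfg <- synthetic_config(registry = reg, seed = 21)
  cal <- generate_calibration(cfg, "incurred", seed = 21)
  curves <- calibrate_all(cal, reg, "incurred")
  blanks <- generate_screening_batch(cfg, n_lots = 10, seed = 22)
  rep_blank <- screen_lots(blanks, curves, reg)
  expect_equal(nrow(rep_blank$lots), 10)
  expect_false(any(rep_blank$lots$contaminated))
  # one lot spiked at 2x LOQ of the mildest curve
  hot <- 2 * max(vapply(curves, function(c) c$loq, numeric(1)))
  spiked <- generate_screening_batch(cfg, n_lots = 10,
                                     contaminated = c(lot_04 = hot), seed = 22)
  rep_hot <- screen_lots(spiked, curves, reg)
  expect_equal(rep_hot$lots$sample_id[rep_hot$lots$contaminated], "lot_04")
  expect_equal(sum(rep_hot$lots$contaminated), 1)
  expect_error(screen_lots(blanks[0, ], curves, reg), "empty")
})

test_that("screening reports are deterministic for identical inputs", {
  reg <- test_registry()
  cfg <- synthetic_config(registry = reg, seed = 5)
  cal <- generate_calibration(cfg, "incurred", seed = 5)
  curves <- calibrate_all(cal, reg, "incurred")
  batch <- generate_screening_batch(cfg, seed = 6)
  r1 <- screen_lots(batch, curves, reg)
  r2 <- screen_lots(batch, curves, reg)
  expect_identical(r1, r2)
})
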