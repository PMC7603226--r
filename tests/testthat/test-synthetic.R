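test_that("generators are pure functions of (config, seed)", {
  cfg <- synthetic_config(seed = 9)
  a <- generate_calibration(cfg, "spiked")
  b <- generate_calibration(cfg, "spiked")
  expect_identical(a, b)
  expect_false(identical(a, generate_calibration(cfg, "spiked", seed = 10)))
  # identical CSV bytes under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_peak_areas(generate_screening_batch(cfg), p1)
  write_peak_areas(generate_screening_batch(cfg), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # ground truth sidecar written alongside
  expect_true(file.exists(paste0(p1, ".truth.json")))
})

test_that("noise-free calibration data reproduce the true line exactly", {
  cfg <- quiet_cfg(seed = 2)
  for (kind in c("spiked", "incurred")) {
    recs <- generate_calibration(cfg, kind, markers = c("FFV", "NIP"))
    truth <- attr(recs, "ground_truth")$markers
    curves <- calibrate_all(recs, cfg$registry, kind)
    for (m in names(curves)) {
      lam <- if (kind == "incurred") truth[[m]]$lambda else 1
      expect_equal(curves[[m]]$slope, truth[[m]]$slope * lam, tolerance = 1e-9)
      expect_equal(curves[[m]]$intercept, truth[[m]]$intercept,
                   tolerance = 1e-6)
      expect_equal(curves[[m]]$r_squared, 1)
      expect_equal(curves[[m]]$lod, 0, tolerance = 1e-8)
    }
  }
})

test_that("generated designs reproduce the study level grids", {
  cfg <- synthetic_config(seed = 1)
  sp <- generate_calibration(cfg, "spiked", markers = "FFV")
  expect_setequal(unique(sp$nominal_value), c(0.0125, 0.05, 0.166, 0.25))
  expect_equal(unique(sp$nominal_unit), "ug_peptide/mL")
  expect_equal(max(table(sp$transition, sp$nominal_value)), 2)  # duplicates
  inc <- generate_calibration(cfg, "incurred", markers = "FFV")
  expect_setequal(unique(inc$nominal_value), c(10, 30, 100, 200, 300))
  prec <- generate_precision_set(cfg, markers = "FFV")
  q <- quant_areas(prec, cfg$registry, "FFV")
  expect_equal(nrow(q), 15)  # 5 replicates x 3 days
  expect_equal(sort(unique(q$day)), 1:3)
})

test_that("processing-loss twins recover the configured lambda", {
  # near-noiseless twins: reduction in LOD-based sensitivity equals
  # 100 * (1 - lambda); averaged over a few seeds via mean LODs
  lam <- 0.0625
  reg <- test_registry()
  # put the incurred axis on the same total-protein grid as the spiked curve
  # so that the intercept-SE design factor cancels and only lambda differs
  fac <- conversion_factor(marker_context(reg, "FFV"))
  frac <- marker_ingredient(reg, "FFV")$protein_fraction
  spiked_ugml <- c(0.0125, 0.05, 0.166, 0.25)
  matched_ing <- spiked_ugml * fac / frac
  lods <- sapply(1:40, function(s) {
    cfg <- synthetic_config(registry = reg, sigma_add = 20, sigma_prop = 0,
                            day_effect_sd = 0,
                            spiked_levels_ugml = spiked_ugml,
                            incurred_levels_ing = matched_ing,
                            processing_loss = c(FFV = lam), seed = s)
    sp <- generate_calibration(cfg, "spiked", markers = "FFV", seed = s)
    inc <- generate_calibration(cfg, "incurred", markers = "FFV", seed = s + 1000)
    c(spiked = build_curve(sp, "FFV", cfg$registry, "spiked")$lod,
      incurred = build_curve(inc, "FFV", cfg$registry, "incurred")$lod)
  })
  eff <- processing_effect(mean(lods["spiked", ]), mean(lods["incurred", ]))
  expect_equal(eff$reduction_pct, 100 * (1 - lam), tolerance = 0.05)
})

test_that("precision sets carry the configured noise level", {
  cvs <- sapply(1:40, function(s) {
    cfg <- synthetic_config(sigma_add = 0, sigma_prop = 0.05,
                            day_effect_sd = 0, seed = s)
    prec <- generate_precision_set(cfg, markers = "FFV")
    q <- quant_areas(prec, cfg$registry, "FFV")
    mean(precision_study(data.frame(day = q$day, area = q$area))$cv_intra_day)
  })
  expect_gt(mean(cvs), 3.5)
  expect_lt(mean(cvs), 6.5)
  # zero noise -> zero CV, degenerate ANOVA
  cfg0 <- quiet_cfg(seed = 1)
  q0 <- quant_areas(generate_precision_set(cfg0, markers = "FFV"),
                    cfg0$registry, "FFV")
  rep0 <- precision_study(data.frame(day = q0$day, area = q0$area))
  expect_true(rep0$degenerate)
  expect_equal(max(rep0$cv_intra_day), 0)
})

test_that("reference-material sets embody the extraction recovery", {
  # rho = 1: pipeline recovery is exactly 100% without noise
  cfg1 <- quiet_cfg(extraction_recovery = 1, seed = 4)
  curves <- calibrate_all(generate_calibration(cfg1, "spiked", markers = "FFV"),
                          cfg1$registry, "spiked")
  rm <- generate_rm_set(cfg1)
  measure <- function(rm, curve, level) {
    ids <- unique(rm$sample_id[grepl(level, rm$sample_id)])
    vapply(ids, function(s) {
      q <- quant_areas(rm[rm$sample_id == s, ], cfg1$registry, "FFV")
      inverse_predict(curve, mean(q$area))
    }, numeric(1))
  }
  expect_equal(recovery(measure(rm, curves$FFV, "LOW"), 3.54)$recovery_pct,
               100, tolerance = 1e-8)
  # rho = 0.5 with noise: recovery near 50%
  cfg5 <- synthetic_config(extraction_recovery = 0.5, seed = 4)
  curves5 <- calibrate_all(generate_calibration(cfg5, "spiked", markers = "FFV"),
                           cfg5$registry, "spiked")
  rm5 <- generate_rm_set(cfg5)
  rec <- recovery(measure(rm5, curves5$FFV, "HIGH"), 17.7)
  expect_equal(rec$recovery_pct, 50, tolerance = 0.1)
})

test_that("screening batches respect the contamination map", {
  cfg <- synthetic_config(seed = 12)
  batch <- generate_screening_batch(cfg, n_lots = 3,
                                    contaminated = c(lot_02 = 50))
  truth <- attr(batch, "ground_truth")
  expect_equal(truth$contaminated$lot_02, 50)
  q1 <- quant_areas(batch[batch$sample_id == "lot_01", ], cfg$registry, "FFV")
  q2 <- quant_areas(batch[batch$sample_id == "lot_02", ], cfg$registry, "FFV")
  expect_gt(mean(q2$area), 10 * mean(q1$area))
  expect_error(generate_screening_batch(cfg, n_lots = 2,
                                        contaminated = c(lot_09 = 1)),
               "not in batch")
})
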