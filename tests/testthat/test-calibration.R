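test_that("noise-free lines are recovered exactly", {
  conc <- rep(c(1, 2, 5, 10), each = 2)
  df <- data.frame(conc = conc, area = 5 * conc + 2)
  curve <- fit_line(df)
  expect_equal(curve$slope, 5)
  expect_equal(curve$intercept, 2)
  expect_equal(curve$se_intercept, 0, tolerance = 1e-8)
  expect_equal(curve$r_squared, 1)
  ll <- lod_loq(curve)
  expect_equal(unname(ll["lod"]), 0, tolerance = 1e-8)
})

test_that("OLS agrees with the normal-equations oracle on random designs", {
  set.seed(101)
  for (i in 1:100) {
    n_lvl <- sample(3:6, 1)
    conc <- rep(sort(runif(n_lvl, 0.1, 100)), each = sample(1:3, 1))
    area <- 1000 * conc + 500 + rnorm(length(conc), 0, 200)
    curve <- fit_line(data.frame(conc = conc, area = area))
    oracle <- ols_oracle(conc, area)
    expect_equal(curve$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(curve$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(curve$se_intercept, oracle$se_intercept, tolerance = 1e-10)
    expect_equal(curve$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_line(data.frame(conc = rep(5, 6), area = rnorm(6, 100))),
               "rank-deficient")
  expect_error(fit_line(data.frame(conc = c(1, 1, 2, 2), area = c(1, 2, 3, 4))),
               "insufficient design")
  expect_error(fit_line(list(calibration_level(1, 10))), "rank-deficient")
})

test_that("LOD/LOQ follow the 3x/10x intercept-deviation definition", {
  curve <- allerquant:::new_calibration_curve(
    slope = 3, intercept = 1, se_intercept = 0.3, r_squared = 0.999,
    n_points = 8, df_residual = 6)
  ll <- lod_loq(curve)
  expect_equal(unname(ll["lod"]), 0.3)
  expect_equal(unname(ll["loq"]), 1.0)
  # definitional ratio on arbitrary fitted curves
  set.seed(7)
  for (i in 1:20) {
    conc <- rep(c(1, 3, 8, 20), each = 2)
    area <- 50 * conc + 10 + rnorm(8, 0, 5)
    ll <- lod_loq(fit_line(data.frame(conc = conc, area = area)))
    expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3)
  }
  bad <- allerquant:::new_calibration_curve(-2, 1, 0.3, 0.9, 8, 6)
  expect_error(lod_loq(bad), "positive")
})

test_that("axis scaling moves slope and LOD/LOQ consistently", {
  set.seed(31)
  conc <- rep(c(1, 2, 5, 10), each = 2)
  area <- 40 * conc + 7 + rnorm(8, 0, 3)
  k <- 4.2
  c1 <- fit_line(data.frame(conc = conc, area = area))
  c2 <- fit_line(data.frame(conc = k * conc, area = area))
  expect_equal(c2$slope, c1$slope / k)
  expect_equal(lod_loq(c2), k * lod_loq(c1))
})

test_that("inverse prediction inverts the line", {
  curve <- allerquant:::new_calibration_curve(5, 2, 0.1, 1, 8, 6)
  expect_equal(inverse_predict(curve, 2), 0)
  for (x in c(0.1, 1, 7.5, 100)) {
    expect_equal(inverse_predict(curve, 2 + 5 * x), x)
  }
  expect_equal(inverse_predict(curve, c(7, 12)), c(1, 2))
  expect_lt(inverse_predict(curve, 0), 0)  # caller censors
})

test_that("build_curve converts the axis and records provenance", {
  reg <- test_registry()
  cfg <- quiet_cfg()
  inc <- generate_calibration(cfg, "incurred", markers = "FFV")
  curve <- build_curve(inc, "FFV", reg, curve_kind = "incurred")
  # noise-free: slope recovered on the total-protein axis with lambda applied
  truth <- attr(inc, "ground_truth")$markers$FFV
  expect_equal(curve$slope, truth$slope * truth$lambda, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$provenance$protein_fraction, 0.3539)
  expect_equal(range(truth$conc_tp), c(3.539, 106.17), tolerance = 1e-6)
  # egg incurred axis spans 4.8-144.2
  inc_e <- generate_calibration(cfg, "incurred", markers = "ISQ")
  expect_equal(range(attr(inc_e, "ground_truth")$markers$ISQ$conc_tp),
               c(4.805, 144.15), tolerance = 1e-6)
  # spiked curves go through the peptide conversion context
  sp <- generate_calibration(cfg, "spiked", markers = "FFV")
  sc <- build_curve(sp, "FFV", reg, curve_kind = "spiked")
  expect_equal(sc$provenance$path, "peptide_ug_per_mL -> ug_tot_prot_per_g")
  expect_equal(sc$slope, truth$slope, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1)
})

test_that("estimated LOD concentrates near its theoretical value with replication", {
  # additive noise sigma: se(b0) has a closed form; average estimate over
  # seeds should approach 3 * se_theoretical / slope
  slope <- 1000; b0 <- 200; sigma <- 50
  conc <- rep(c(1, 2, 5, 10), each = 6)
  X <- cbind(1, conc)
  se_theo <- sigma * sqrt(solve(t(X) %*% X)[1, 1])
  set.seed(99)
  lods <- replicate(200, {
    area <- slope * conc + b0 + rnorm(length(conc), 0, sigma)
    unname(lod_loq(fit_line(data.frame(conc = conc, area = area)))["lod"])
  })
  expect_equal(mean(lods), 3 * se_theo / slope, tolerance = 0.1)
})

test_that("R-squared is 1 without noise and degrades as noise grows", {
  conc <- rep(c(1, 2, 5, 10), each = 2)
  set.seed(13)
  r2_at <- function(sigma) {
    mean(replicate(50, {
      area <- 100 * conc + 10 + rnorm(8, 0, sigma)
      fit_line(data.frame(conc = conc, area = area))$r_squared
    }))
  }
  expect_gt(r2_at(5), r2_at(50))
  expect_gt(r2_at(50), r2_at(250))
})

test_that("replicate averaging and inverse-x weighting are available", {
  set.seed(3)
  conc <- rep(c(1, 2, 5, 10), each = 2)
  area <- 10 * conc + 3 + rnorm(8, 0, 1)
  c_avg <- fit_line(data.frame(conc = conc, area = area),
                    average_replicates = TRUE)
  expect_equal(c_avg$n_points, 4)
  c_w <- fit_line(data.frame(conc = conc, area = area), weighting = "inverse_x")
  expect_true(is.finite(c_w$slope))
  expect_error(fit_line(data.frame(conc = c(0, 1, 2, 3), area = 1:4),
                        weighting = "inverse_x"), "> 0")
})
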