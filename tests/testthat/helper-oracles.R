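# Independent oracles used across the suite.

# Brute-force OLS through the normal equations, with intercept SE from the
# residual variance. Kept independent of fit_line()'s lm() route.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(s2 * xtx_inv)))
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = unname(beta[1L]), slope = unname(beta[2L]),
       se_intercept = se[1L], se_slope = se[2L],
       r_squared = 1 - sum(resid^2) / ss_tot)
}

# Published average residue masses (independent transcription) for the
# registry mass cross-check.
ORACLE_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, L = 113.1594, I = 113.1594, N = 114.1038, D = 115.0886,
  Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132, C = 103.1388
)
ORACLE_WATER <- 18.0153

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_AVG_MASS[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# Small shared fixtures
test_registry <- function() load_registry()

quiet_cfg <- function(...) {
  # near-noiseless config for deterministic recovery checks
  synthetic_config(sigma_add = 0, sigma_prop = 0, day_effect_sd = 0, ...)
}

quantifier_id <- function(registry, code) {
  tr <- registry$markers[[code]]$transitions
  q <- tr[tr$role == "quantifier", ]
  sprintf("%.1f>%.1f", q$q1_mz, q$q3_mz)
}

quant_areas <- function(records, registry, code) {
  records[records$marker == code &
            records$transition == quantifier_id(registry, code), ]
}
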