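# Shared fixture builders. Everything is generated in code; no data files.

# Independent dimensional-analysis oracle for the chamber flux
# conversion: mole-fraction slope -> mol s^-1 via PV/RT -> mg h^-1 via
# molar mass -> per m^2. Written from first principles, separate from
# the package's internal conversion.
oracle_flux <- function(slope_units, gas, volume_l, area_m2, temp_k,
                        r_gas = 0.082) {
  unit_scale <- if (gas == "co2") 1e-6 else 1e-9   # ppm/ppb -> mole fraction
  molar_mass <- c(co2 = 44.01, ch4 = 16.04, n2o = 44.01)[[gas]]
  dx_dt <- slope_units * unit_scale                # mole fraction s^-1
  n_mol <- 1 * volume_l / (r_gas * temp_k)         # PV = nRT at 1 atm
  g_per_s <- dx_dt * n_mol * molar_mass
  g_per_s * 1000 * 3600 / area_m2                  # mg m^-2 h^-1
}

# Normal-equations OLS oracle (brute force, no lm).
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1L], slope = beta[2L],
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       se_slope = sqrt(sum(res^2) / (length(y) - 2) /
                         sum((x - mean(x))^2)))
}

# Series engineered to have an exact R^2: residuals are built orthogonal
# to the regression design, so R^2 = SSfit / (SSfit + SSres) exactly.
series_with_r2 <- function(r2, slope = 1, n = 50, gas = "co2",
                           temp_k = 298.15, chamber_id = "x") {
  t <- seq_len(n) - 1
  base <- 400 + slope * t
  e <- sin(seq(0, 6 * pi, length.out = n))
  X <- cbind(1, t)
  e <- e - X %*% solve(crossprod(X), crossprod(X, e))   # orthogonalize
  ss_fit <- sum((slope * (t - mean(t)))^2)
  e <- e * sqrt(ss_fit * (1 - r2) / r2 / sum(e^2))
  concentration_series(t, base + drop(e), gas, temp_k, chamber_id)
}

# Three-construct chain A -> B -> C with configurable paths/loadings.
chain_truth <- function(b1 = 0.5, b2 = 0.4, loading = 0.8, k = 3,
                        n = 2000, seed = 42) {
  B <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  B[2, 1] <- b1; B[3, 2] <- b2
  latent_truth(B, list(A = rep(loading, k), B = rep(loading, k),
                       C = rep(loading, k)), n_obs = n, seed = seed)
}

chain_spec <- function(k = 3) {
  pls_model_spec(
    constructs = list(A = paste0("A_", 1:k), B = paste0("B_", 1:k),
                      C = paste0("C_", 1:k)),
    paths = data.frame(from = c("A", "B"), to = c("B", "C")))
}

# Small noise-free campaign for end-to-end identities.
tiny_campaign_config <- function(noise_sd = 0, seed = 11) {
  campaign_config(n_sites = 1, trees_per_site = 2,
                  height_intervals = list(c(0, 40), c(40, 80)),
                  noise_sd = noise_sd, seed = seed)
}
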