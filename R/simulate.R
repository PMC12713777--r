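## Synthetic-data generation: chamber campaigns and latent-variable
## datasets with known ground truth, so every downstream stage can be
## validated without field data.

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses (and advances) the global RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Ambient baselines for the synthetic series (series units).
.AMBIENT <- c(co2 = 420, ch4 = 1900, n2o = 335)

#' Synthesize a chamber concentration series with known flux
#'
#' Inverts the ideal-gas flux conversion: given a true areal flux, the
#' noise-free concentration slope is chosen so that fitting the series
#' and running it through [compute_flux()] returns the flux exactly.
#' Gaussian noise of SD `noise_sd` (series units: ppm for CO2, ppb
#' otherwise) is then added independently per time point.
#'
#' @param true_flux Areal flux, mg m^-2 h^-1 (sign-faithful).
#' @param chamber A [chamber_spec()].
#' @param air_temp_k Chamber air temperature, kelvin.
#' @param gas Gas label.
#' @param noise_sd Concentration noise SD (>= 0), ppm or ppb.
#' @param duration_s Deployment length, seconds; default 300 (about a
#'   5-minute closure).
#' @param dt_s Sampling cadence, seconds; default 1 Hz.
#' @param baseline Starting concentration; default ambient for the gas.
#' @param chamber_id Identifier stamped on the series.
#' @param seed Optional integer seed (local to this call).
#' @return A [concentration_series()].
#' @export
make_concentration_series <- function(true_flux, chamber, air_temp_k, gas,
                                      noise_sd = 0, duration_s = 300,
                                      dt_s = 1, baseline = NULL,
                                      chamber_id = "chamber", seed = NULL) {
  stopifnot(inherits(chamber, "chamber_spec"))
  g <- .gas_row(gas)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(baseline)) baseline <- .AMBIENT[[g$gas]]
  slope <- true_flux / .flux_per_slope(g$gas, chamber$volume_l,
                                       chamber$area_m2, air_temp_k)
  t <- seq(0, duration_s, by = dt_s)
  y <- baseline + slope * t
  if (noise_sd > 0) y <- y + .with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  concentration_series(t, y, g$gas, air_temp_k, chamber_id)
}

#' Preset flux magnitudes by species and pathway
#'
#' Lognormal location/scale presets for synthetic campaigns. Locations
#' are anchored to reported species-mean stem and soil flux magnitudes
#' for mangroves (e.g. the Avicennia marina stem N2O mean of about 521
#' ug m^-2 h^-1); scales are set to a common dispersion. These are
#' presets for generating plausible campaigns, not estimates.
#'
#' @return Data frame with columns `species`, `surface`, `gas`,
#'   `meanlog`, `sdlog` (flux in mg m^-2 h^-1 on the log scale).
#' @export
flux_presets <- function() {
  # means in mg m-2 h-1; meanlog chosen so the lognormal mean matches
  mk <- function(species, surface, gas, mean_flux, sdlog = 1) {
    data.frame(species = species, surface = surface, gas = gas,
               meanlog = log(mean_flux) - sdlog^2 / 2, sdlog = sdlog,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("A. marina",   "stem", "co2", 170),
    mk("A. marina",   "stem", "ch4", 0.06156),
    mk("A. marina",   "stem", "n2o", 0.52104),
    mk("A. marina",   "soil", "ch4", 1.33),
    mk("A. marina",   "soil", "n2o", 0.026),
    mk("K. obovata",  "stem", "co2", 120),
    mk("K. obovata",  "stem", "ch4", 0.00093),
    mk("K. obovata",  "stem", "n2o", 0.00049),
    mk("K. obovata",  "soil", "ch4", 0.58),
    mk("K. obovata",  "soil", "n2o", 0.013),
    mk("L. racemosa", "stem", "ch4", 0.00014),
    mk("L. racemosa", "stem", "n2o", 0.00171),
    mk("L. racemosa", "soil", "ch4", 0.34),
    mk("R. stylosa",  "stem", "ch4", 0.00545),
    mk("R. stylosa",  "stem", "n2o", 0.00127),
    mk("R. stylosa",  "soil", "ch4", 0.0724)
  )
}

# Mean seasonal air temperatures (deg C) used as the default forcing;
# west-coast subtropical values.
.SEASON_TEMP_C <- c(winter = 17.5, spring = 23.0, summer = 28.9, autumn = 25.7)

#' Campaign configuration for the synthetic generator
#'
#' Defines a simulated chamber campaign: sites, trees, stem height
#' intervals, per-gas flux magnitudes with a height-decay profile,
#' seasonal temperature forcing on log-flux, and concentration noise.
#'
#' @param n_sites Number of sites.
#' @param species_per_site Species label(s), recycled across sites.
#' @param seasons Season labels, a non-empty subset of winter, spring,
#'   summer, autumn.
#' @param trees_per_site Trees sampled per site.
#' @param height_intervals List of `c(low_cm, high_cm)` pairs; must be
#'   ordered, non-overlapping and of positive width.
#' @param true_flux_params Data frame with columns `gas`, `meanlog`,
#'   `sdlog` (stem flux lognormal parameters, mg m^-2 h^-1 scale) and
#'   optionally `soil_meanlog`, `soil_sdlog`; defaults are modest
#'   mangrove-like magnitudes.
#' @param height_decay Per-interval multiplier on the (linear-scale) stem
#'   flux, length matching `height_intervals`; default a geometric decay
#'   0.5^(interval index - 1), emulating the concentration of stem CH4
#'   emissions near the stem base.
#' @param temp_effect Slope of log-flux on temperature (per deg C).
#' @param noise_sd Concentration noise SD (ppm/ppb).
#' @param replicates_per_season Chamber deployments per tree interval and
#'   season (within-season replication is not fixed by any field design;
#'   exposed as a free parameter). Default 1.
#' @param soil_plots_per_site Soil chambers per site per season.
#' @param season_temp_c Named vector of mean seasonal temperatures.
#' @param seed Integer seed; all campaign randomness flows from it.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(n_sites = 1, species_per_site = "A. marina",
                            seasons = c("winter", "spring", "summer", "autumn"),
                            trees_per_site = 5,
                            height_intervals = list(c(0, 40), c(40, 80),
                                                    c(80, 120), c(120, 200)),
                            true_flux_params = NULL,
                            height_decay = NULL,
                            temp_effect = 0.05,
                            noise_sd = 0.5,
                            replicates_per_season = 1,
                            soil_plots_per_site = 3,
                            season_temp_c = .SEASON_TEMP_C,
                            seed = 1L) {
  if (!length(seasons)) stop("seasons must be non-empty")
  bad <- setdiff(seasons, c("winter", "spring", "summer", "autumn"))
  if (length(bad)) stop("unknown seasons: ", paste(bad, collapse = ", "))
  lows <- vapply(height_intervals, `[`, 0, 1L)
  highs <- vapply(height_intervals, `[`, 0, 2L)
  if (any(highs <= lows)) stop("height intervals need positive width")
  if (length(lows) > 1L && any(lows[-1L] < highs[-length(highs)]))
    stop("height intervals must be ordered and non-overlapping")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(true_flux_params)) {
    true_flux_params <- data.frame(
      gas = c("co2", "ch4", "n2o"),
      meanlog = c(log(100), log(0.06), log(0.5)),
      sdlog = c(0.4, 0.8, 0.8),
      soil_meanlog = c(log(200), log(1.3), log(0.03)),
      soil_sdlog = c(0.4, 0.8, 0.8),
      stringsAsFactors = FALSE)
  }
  if (is.null(height_decay)) height_decay <- 0.5^(seq_along(lows) - 1)
  if (length(height_decay) != length(lows))
    stop("height_decay length must match height_intervals")
  structure(list(n_sites = n_sites,
                 species_per_site = rep_len(species_per_site, n_sites),
                 seasons = seasons, trees_per_site = trees_per_site,
                 height_low_cm = lows, height_high_cm = highs,
                 true_flux_params = true_flux_params,
                 height_decay = height_decay, temp_effect = temp_effect,
                 noise_sd = noise_sd,
                 replicates_per_season = replicates_per_season,
                 soil_plots_per_site = soil_plots_per_site,
                 season_temp_c = season_temp_c, seed = as.integer(seed)),
            class = "campaign_config")
}

#' Simulate a chamber campaign
#'
#' Draws a full campaign from a [campaign_config()]: tree geometries,
#' per-deployment true fluxes (lognormal magnitudes with height decay and
#' a temperature effect on log-flux), and the corresponding noisy chamber
#' concentration series. Deterministic given the config seed. The truth
#' table carries, for every deployment, both the deterministic log-flux
#' location (`mu_log`) and the realized true flux, plus the generating
#' parameters, so recovery tests are self-contained.
#'
#' @param config A [campaign_config()].
#' @param stem_chamber,soil_chamber Chamber specs; defaults are a 20 x 25
#'   cm semirigid stem chamber (1.5 L) and the 30 cm / 6.4 L soil cover
#'   on a 16 cm ring inserted 10 cm.
#' @return A list of class `campaign` with elements `series` (list of
#'   [concentration_series()]), `meta` (provenance rows aligned with
#'   `series`), `truth` (truth table incl. `true_flux` and `mu_log`),
#'   `geometry` (named list of [tree_geometry()]), `sites` (site table
#'   with density and area), and `config`.
#' @export
simulate_campaign <- function(config,
                              stem_chamber = chamber_area_volume(
                                "stem_semirigid", arc_cm = 20, height_cm = 25,
                                volume_l = 1.5),
                              soil_chamber = chamber_area_volume(
                                "soil_static", diameter_cm = 30,
                                cover_volume_l = 6.4)) {
  stopifnot(inherits(config, "campaign_config"))
  .with_seed(config$seed, {
    p <- config$true_flux_params
    temp_c <- config$season_temp_c[config$seasons]
    t_ref <- mean(temp_c)
    nivl <- length(config$height_low_cm)
    series <- list(); meta <- list(); truth <- list(); geoms <- list()
    sites <- data.frame(site = character(), species = character(),
                        density = numeric(), area_ha = numeric(),
                        stringsAsFactors = FALSE)
    k <- 0L
    for (si in seq_len(config$n_sites)) {
      site_id <- sprintf("S%02d", si)
      sites <- rbind(sites, data.frame(
        site = site_id, species = config$species_per_site[si],
        density = stats::runif(1, 6000, 24000),   # trees ha-1
        area_ha = stats::runif(1, 5, 45),
        burial_co2e = stats::runif(1, 5, 330),    # t CO2e yr-1
        stringsAsFactors = FALSE))
      for (ti in seq_len(config$trees_per_site)) {
        tree_id <- sprintf("%s-T%02d", site_id, ti)
        base_per <- stats::runif(1, 0.15, 0.45)           # m
        taper <- stats::runif(nivl, 0.85, 1)
        per <- base_per * cumprod(taper)
        geoms[[tree_id]] <- tree_geometry(
          tree_id, config$height_low_cm / 100, config$height_high_cm / 100,
          per)
        for (season in config$seasons) {
          t_k <- 273.15 + temp_c[[season]]
          for (rep_i in seq_len(config$replicates_per_season)) {
            for (gi in seq_len(nrow(p))) {
              gas <- p$gas[gi]
              for (x in seq_len(nivl)) {
                mu <- p$meanlog[gi] + log(config$height_decay[x]) +
                  config$temp_effect * (temp_c[[season]] - t_ref)
                f <- exp(mu + stats::rnorm(1, 0, p$sdlog[gi]))
                k <- k + 1L
                cid <- sprintf("%s-%s-%s-r%d-i%d", tree_id, gas, season,
                               rep_i, x)
                series[[k]] <- make_concentration_series(
                  f, stem_chamber, t_k, gas, config$noise_sd,
                  chamber_id = cid)
                ivl <- paste0(config$height_low_cm[x] / 100, "-",
                              config$height_high_cm[x] / 100)
                meta[[k]] <- data.frame(
                  chamber_id = cid, site = site_id, tree = tree_id,
                  height_interval = ivl, season = season, surface = "stem",
                  stringsAsFactors = FALSE)
                truth[[k]] <- data.frame(
                  chamber_id = cid, site = site_id, tree = tree_id,
                  height_interval = ivl, season = season, surface = "stem",
                  gas = gas, temp_c = temp_c[[season]], mu_log = mu,
                  true_flux = f, stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
      # soil deployments
      for (season in config$seasons) {
        t_k <- 273.15 + temp_c[[season]]
        for (pl in seq_len(config$soil_plots_per_site)) {
          for (gi in seq_len(nrow(p))) {
            gas <- p$gas[gi]
            mu <- p$soil_meanlog[gi] +
              config$temp_effect * (temp_c[[season]] - t_ref)
            f <- exp(mu + stats::rnorm(1, 0, p$soil_sdlog[gi]))
            k <- k + 1L
            cid <- sprintf("%s-soil%d-%s-%s", site_id, pl, gas, season)
            series[[k]] <- make_concentration_series(
              f, soil_chamber, t_k, gas, config$noise_sd, chamber_id = cid)
            meta[[k]] <- data.frame(
              chamber_id = cid, site = site_id, tree = NA_character_,
              height_interval = NA_character_, season = season,
              surface = "soil", stringsAsFactors = FALSE)
            truth[[k]] <- data.frame(
              chamber_id = cid, site = site_id, tree = NA_character_,
              height_interval = NA_character_, season = season,
              surface = "soil", gas = gas, temp_c = temp_c[[season]],
              mu_log = mu, true_flux = f, stringsAsFactors = FALSE)
          }
        }
      }
    }
    structure(list(series = series,
                   meta = do.call(rbind, meta),
                   truth = do.call(rbind, truth),
                   geometry = geoms, sites = sites,
                   stem_chamber = stem_chamber, soil_chamber = soil_chamber,
                   config = config),
              class = "campaign")
  })
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign> %d sites, %d deployments, seasons: %s (seed %d)\n",
              x$config$n_sites, length(x$series),
              paste(x$config$seasons, collapse = ", "), x$config$seed))
  invisible(x)
}

#' Latent-variable ground truth
#'
#' A recursive (acyclic) latent path model with reflective indicators,
#' for validating the PLS-SEM estimator. Latent scores have unit
#' variance; `path_matrix[j, k]` is the effect of construct k on
#' construct j and must be strictly lower triangular. Each construct j's
#' structural error variance is `1 - b_j' Sigma b_j`; the model is
#' rejected if that is negative (implied covariance not positive
#' semi-definite).
#'
#' @param path_matrix Square, strictly lower-triangular numeric matrix
#'   with construct names on dimnames.
#' @param loadings Named list (one element per construct) of indicator
#'   loading vectors, values in [-1, 1].
#' @param n_obs Number of observations to generate.
#' @param seed Integer seed.
#' @return An object of class `latent_truth` (includes the implied
#'   latent covariance `sigma_latent`).
#' @export
latent_truth <- function(path_matrix, loadings, n_obs, seed = 1L) {
  stopifnot(is.matrix(path_matrix), nrow(path_matrix) == ncol(path_matrix))
  m <- nrow(path_matrix)
  if (any(path_matrix[upper.tri(path_matrix, diag = TRUE)] != 0))
    stop("path_matrix must be strictly lower triangular (recursive model)")
  cn <- rownames(path_matrix)
  if (is.null(cn)) cn <- colnames(path_matrix)
  if (is.null(cn)) cn <- paste0("C", seq_len(m))
  dimnames(path_matrix) <- list(cn, cn)
  if (!identical(sort(names(loadings)), sort(cn)))
    stop("loadings must be a named list matching the constructs")
  if (any(unlist(loadings) < -1 | unlist(loadings) > 1))
    stop("loadings must lie in [-1, 1]")
  # implied unit-variance latent covariance, construct by construct
  sigma <- diag(m); dimnames(sigma) <- list(cn, cn)
  err_var <- numeric(m)
  for (j in seq_len(m)) {
    b <- path_matrix[j, seq_len(j - 1L), drop = TRUE]
    if (j > 1L && any(b != 0)) {
      s_pred <- sigma[seq_len(j - 1L), seq_len(j - 1L), drop = FALSE]
      v_sys <- drop(t(b) %*% s_pred %*% b)
      if (v_sys > 1 + 1e-12)
        stop("implied covariance not positive semi-definite: construct '",
             cn[j], "' has systematic variance ", signif(v_sys, 4), " > 1")
      err_var[j] <- max(0, 1 - v_sys)
      if (j > 1L)
        sigma[j, seq_len(j - 1L)] <- sigma[seq_len(j - 1L), j] <-
          drop(s_pred %*% b)
    } else {
      err_var[j] <- 1
    }
  }
  structure(list(path_matrix = path_matrix, loadings = loadings,
                 constructs = cn, error_var = err_var,
                 sigma_latent = sigma, n_obs = as.integer(n_obs),
                 seed = as.integer(seed)),
            class = "latent_truth")
}

#' Simulate indicator data from a latent truth
#'
#' Generates latent scores by the recursive path equations (structural
#' errors scaled so every latent score has unit variance), then
#' indicators as `loading * latent + noise` with the noise scaled so each
#' indicator has unit variance. Deterministic given the truth's seed.
#'
#' @param truth A [latent_truth()].
#' @return A data frame of indicators named `<construct>_<i>`, with the
#'   latent score matrix in `attr(, "latent")` and the truth in
#'   `attr(, "truth")`.
#' @export
simulate_latent_model <- function(truth) {
  stopifnot(inherits(truth, "latent_truth"))
  .with_seed(truth$seed, {
    m <- length(truth$constructs); n <- truth$n_obs
    eta <- matrix(0, n, m, dimnames = list(NULL, truth$constructs))
    for (j in seq_len(m)) {
      e <- stats::rnorm(n, 0, sqrt(truth$error_var[j]))
      pred <- if (j > 1L)
        eta[, seq_len(j - 1L), drop = FALSE] %*%
          truth$path_matrix[j, seq_len(j - 1L)]
      else 0
      eta[, j] <- drop(pred) + e
    }
    cols <- list()
    for (cname in truth$constructs) {
      lam <- truth$loadings[[cname]]
      for (i in seq_along(lam)) {
        x <- lam[i] * eta[, cname] +
          stats::rnorm(n, 0, sqrt(max(0, 1 - lam[i]^2)))
        cols[[paste0(cname, "_", i)]] <- x
      }
    }
    out <- as.data.frame(cols)
    attr(out, "latent") <- eta
    attr(out, "truth") <- truth
    out
  })
}
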