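## Delimited-table schemas and the end-to-end pipeline runner. All files
## are plain tab-separated text with a one-line header; comment lines
## starting with '#' carry provenance (package version, seed, config
## hash) and are skipped on read.

# 32-bit FNV-1a over the serialized object; cheap content hash for
# provenance headers, not cryptographic.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double to
    # stay clear of 32-bit integer overflow
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

.write_table <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in provenance) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a long-format concentration series table
#'
#' Expects one row per time point with columns `chamber_id`, `gas`,
#' `time_s`, `concentration`, `unit`, `temp_K`. Rows are grouped into
#' deployments by (`chamber_id`, `gas`) and sorted by time, so row order
#' in the file does not matter. The declared unit must match the gas
#' (ppm for CO2, ppb for CH4/N2O); mismatches and non-monotone times are
#' reported with the offending deployment.
#'
#' @param path Path to a tab- or comma-delimited file (delimiter
#'   auto-detected from the header line).
#' @return Named list of [concentration_series()], keyed by chamber id.
#' @export
read_series_table <- function(path) {
  header <- grep("^#", readLines(path, n = 20L), value = TRUE,
                 invert = TRUE)[1L]
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chamber_id", "gas", "time_s", "concentration", "unit", "temp_K")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("series table missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (key in unique(paste(df$chamber_id, df$gas, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    rows <- df[df$chamber_id == parts[1L] & df$gas == parts[2L], , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    g <- .gas_row(parts[2L])
    badu <- unique(rows$unit[rows$unit != g$unit])
    if (length(badu))
      stop("deployment '", parts[1L], "': unit '", badu[1L],
           "' invalid for ", g$gas, " (expected ", g$unit, ")")
    if (length(unique(rows$temp_K)) > 1L)
      stop("deployment '", parts[1L], "': temp_K must be constant")
    out[[parts[1L]]] <- concentration_series(
      rows$time_s, rows$concentration, g$gas, rows$temp_K[1L], parts[1L])
  }
  out
}

#' Write a list of concentration series to the long-format schema
#'
#' Inverse of [read_series_table()].
#'
#' @param series_list Named list of [concentration_series()].
#' @param path Output path.
#' @param provenance Optional comment header lines.
#' @return The path, invisibly.
#' @export
write_series_table <- function(series_list, path, provenance = character()) {
  rows <- lapply(series_list, function(s)
    data.frame(chamber_id = s$chamber_id, gas = s$gas, time_s = s$time_s,
               concentration = s$concentration, unit = s$unit,
               temp_K = s$temp_k, stringsAsFactors = FALSE))
  .write_table(do.call(rbind, rows), path, provenance)
}

#' Read a chamber registry table
#'
#' Columns: `chamber_id`, `kind`, `volume_l`, `area_m2`.
#'
#' @param path Path to a delimited registry file.
#' @return Named list of [chamber_spec()] keyed by chamber id.
#' @export
read_chamber_registry <- function(path) {
  df <- .read_table(path)
  need <- c("chamber_id", "kind", "volume_l", "area_m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("chamber registry missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    chamber_spec(df$kind[i], df$volume_l[i], df$area_m2[i]))
  stats::setNames(out, df$chamber_id)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Either give a
#' [campaign_config()] (`campaign`) to run on synthetic data, or paths
#' to a series table, a deployment metadata table (chamber_id-keyed
#' provenance) and a chamber registry.
#'
#' @param campaign A [campaign_config()], or `NULL` when reading files.
#' @param series_path,meta_path,registry_path Input files for the
#'   file-driven mode.
#' @param qc_threshold R^2 threshold for [qc_filter()].
#' @param hours_per_season Hours per season (default equal quarters).
#' @param gwp A [gwp_table()].
#' @param quantile_type Quantile rule for [global_upscale()].
#' @param global_density,global_area_km2 Globals for [global_upscale()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param seed Integer seed; the single source of randomness for the
#'   run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(campaign = NULL, series_path = NULL,
                            meta_path = NULL, registry_path = NULL,
                            qc_threshold = 0.7,
                            hours_per_season = 8760 / 4,
                            gwp = gwp_table(), quantile_type = 7,
                            global_density = 263.68,
                            global_area_km2 = 145608,
                            out_dir = NULL, seed = 1L) {
  if (is.null(campaign)) {
    for (p in c(series_path, registry_path))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    stopifnot(inherits(campaign, "campaign_config"))
  }
  structure(list(campaign = campaign, series_path = series_path,
                 meta_path = meta_path, registry_path = registry_path,
                 qc_threshold = qc_threshold,
                 hours_per_season = hours_per_season, gwp = gwp,
                 quantile_type = quantile_type,
                 global_density = global_density,
                 global_area_km2 = global_area_km2,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full flux pipeline
#'
#' Binds the stages end to end: obtain deployments (simulate a campaign
#' or read the configured tables), fit slopes and apply QC, compute
#' areal fluxes, upscale per site to annual stem/soil fluxes, assemble
#' the CO2e budget with burial offsets, and pool per-tree fluxes into a
#' global first-order estimate. Deterministic given the config seed.
#' When `out_dir` is set, each table is written as tab-separated text
#' with a provenance header (package version, seed, config hash).
#'
#' @param config A [pipeline_config()].
#' @return List with `fluxes` (full flux table), `rejects` (QC
#'   failures with reasons), `site_fluxes`, `budget` (site budget
#'   table), `global` (list of [global_upscale()] results per trace
#'   gas), `qc_log`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL; geoms <- NULL; sites <- NULL
  if (!is.null(config$campaign)) {
    camp <- config$campaign
    camp$seed <- config$seed     # single seed governs the run
    sim <- simulate_campaign(camp)
    series <- sim$series
    meta <- sim$meta
    chambers <- stats::setNames(
      lapply(sim$meta$surface,
             function(s) if (s == "stem") sim$stem_chamber else sim$soil_chamber),
      sim$meta$chamber_id)
    truth <- sim$truth; geoms <- sim$geometry; sites <- sim$sites
  } else {
    series <- read_series_table(config$series_path)
    chambers <- read_chamber_registry(config$registry_path)
    meta <- if (!is.null(config$meta_path)) .read_table(config$meta_path)
            else NULL
  }
  fluxes <- flux_table(series, chambers, meta, config$qc_threshold)
  rejects <- fluxes[!fluxes$qc_pass, , drop = FALSE]
  passing <- fluxes[fluxes$qc_pass, , drop = FALSE]
  qc_log <- sprintf("%d deployments, %d passed QC (threshold %.3g), %d rejected",
                    nrow(fluxes), nrow(passing), config$qc_threshold,
                    nrow(rejects))
  budget <- NULL; site_fluxes <- NULL; global <- NULL
  if (nrow(passing) == 0L) {
    warning("no deployments passed QC; budget is empty")
  } else if (!is.null(sites)) {
    site_fluxes <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      sf <- site_annual_fluxes(
        fluxes[fluxes$site == sites$site[i], , drop = FALSE],
        geoms, sites$density[i], config$hours_per_season)
      cbind(site = sites$site[i], sf)
    }))
    wide <- function(g, col) {
      v <- site_fluxes[[col]][site_fluxes$gas == g]
      v[match(sites$site, site_fluxes$site[site_fluxes$gas == g])]
    }
    budget_in <- data.frame(
      site = sites$site,
      f_taw_ch4 = wide("ch4", "f_taw"), f_saw_ch4 = wide("ch4", "f_saw"),
      f_taw_n2o = wide("n2o", "f_taw"), f_saw_n2o = wide("n2o", "f_saw"),
      area_ha = sites$area_ha, burial_co2e = sites$burial_co2e,
      stringsAsFactors = FALSE)
    budget <- site_budget(budget_in, config$gwp)
    # pooled per-tree fluxes for the global estimate
    global <- lapply(c(ch4 = "ch4", n2o = "n2o"), function(g) {
      stem <- passing[passing$gas == g & passing$surface == "stem", ,
                      drop = FALSE]
      pool <- unlist(lapply(unique(stem$tree), function(tr) {
        st <- stem[stem$tree == tr, , drop = FALSE]
        geo <- geoms[[tr]]
        vapply(unique(st$season), function(s) {
          ss <- st[st$season == s, , drop = FALSE]
          labels <- paste0(geo$height_low_m, "-", geo$height_high_m)
          fx <- vapply(labels, function(il) {
            v <- ss$flux[ss$height_interval == il]
            if (!length(v)) NA_real_ else mean(v)
          }, 0)
          if (anyNA(fx)) NA_real_ else per_tree_flux(fx, geo)
        }, 0)
      }))
      pool <- pool[is.finite(pool)]
      if (!length(pool)) return(NULL)
      global_upscale(pool, config$global_density, config$global_area_km2,
                     gas = g, gwp = config$gwp,
                     quantile_type = config$quantile_type)
    })
  }
  out <- list(fluxes = fluxes, rejects = rejects, site_fluxes = site_fluxes,
              budget = budget, global = global, qc_log = qc_log,
              truth = truth, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- c(paste0("stemflux ",
                     as.character(utils::packageVersion("stemflux"))),
              paste0("seed=", config$seed),
              paste0("config_hash=", .config_hash(config)),
              qc_log)
    .write_table(fluxes, file.path(config$out_dir, "fluxes.tsv"), prov)
    .write_table(rejects, file.path(config$out_dir, "rejects.tsv"), prov)
    if (!is.null(budget))
      .write_table(budget, file.path(config$out_dir, "site_budget.tsv"), prov)
    if (!is.null(global)) {
      gl <- do.call(rbind, lapply(Filter(Negate(is.null), global), function(g)
        data.frame(gas = g$gas, q1_mg_yr = g$mg_yr["q1"],
                   median_mg_yr = g$mg_yr["median"], q3_mg_yr = g$mg_yr["q3"],
                   median_gg_co2e_yr = g$gg_co2e_yr["median"],
                   density = g$density, area_km2 = g$area_km2,
                   row.names = NULL, stringsAsFactors = FALSE)))
      .write_table(gl, file.path(config$out_dir, "global_estimate.tsv"), prov)
    }
  }
  out
}
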