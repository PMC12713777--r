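## Chamber flux estimation: concentration time series -> QC'd areal flux.

# Gas registry. Concentration units are fixed per gas (CO2 in ppm, trace
# gases in ppb) and never inferred from the data.
.GASES <- data.frame(
  gas        = c("co2", "ch4", "n2o"),
  unit       = c("ppm", "ppb", "ppb"),
  molar_mass = c(44.01, 16.04, 44.01),   # g mol-1
  to_molefrac = c(1e-6, 1e-9, 1e-9),
  stringsAsFactors = FALSE
)

# Ideal gas constant in chamber-flux units (L atm K-1 mol-1), as printed
# in the flux equation this package implements.
R_GAS <- 0.082

.gas_row <- function(gas) {
  gas <- tolower(gas)
  i <- match(gas, .GASES$gas)
  if (is.na(i)) {
    stop("unknown gas '", gas, "'; accepted labels: ",
         paste(.GASES$gas, collapse = ", "), call. = FALSE)
  }
  .GASES[i, ]
}

#' Supported greenhouse gases
#'
#' Registry of the gases the package handles, with their fixed
#' concentration unit and molar mass.
#'
#' @return A data frame with columns `gas`, `unit` (ppm or ppb) and
#'   `molar_mass` (g mol^-1).
#' @export
gas_registry <- function() .GASES[, c("gas", "unit", "molar_mass")]

#' Chamber specification
#'
#' Describes a measurement chamber by its headspace volume and the surface
#' area it encloses, the two geometric quantities entering the flux
#' equation.
#'
#' @param kind One of `"stem_cylindrical"`, `"stem_semirigid"`,
#'   `"soil_static"`, `"floating"`.
#' @param volume_l Headspace volume in liters; must be positive.
#' @param area_m2 Enclosed surface area in m^2; must be positive.
#' @param description Optional free-text note.
#' @return An object of class `chamber_spec`.
#' @seealso [chamber_area_volume()] for building specs from raw dimensions.
#' @export
chamber_spec <- function(kind, volume_l, area_m2, description = "") {
  kinds <- c("stem_cylindrical", "stem_semirigid", "soil_static", "floating")
  kind <- match.arg(kind, kinds)
  stopifnot(is.numeric(volume_l), length(volume_l) == 1L,
            is.numeric(area_m2), length(area_m2) == 1L)
  if (!is.finite(volume_l) || volume_l <= 0) stop("chamber volume must be > 0")
  if (!is.finite(area_m2) || area_m2 <= 0) stop("chamber area must be > 0")
  structure(list(kind = kind, volume_l = volume_l, area_m2 = area_m2,
                 description = description),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> %s: V = %.4g L, A = %.6g m2\n",
              x$kind, x$volume_l, x$area_m2))
  invisible(x)
}

#' Build a chamber spec from physical dimensions
#'
#' Computes area and headspace volume for the chamber designs used in the
#' field: a semicircular soil cover placed on a partially inserted steel
#' ring, rectangular bark-patch stem chambers, and a floating chamber for
#' inundated plots.
#'
#' For the soil chamber the enclosed area is the ring's circle and the
#' headspace is the cover volume plus the ring cylinder standing above the
#' soil surface (ring height minus insertion depth). Stem chambers enclose
#' a bark patch of arc width x chamber height. The floating chamber uses
#' the cover volume over the water surface.
#'
#' @param kind Chamber kind (see [chamber_spec()]).
#' @param diameter_cm Ring/cover diameter in cm (soil, floating).
#' @param cover_volume_l Cover volume in liters (soil, floating).
#' @param ring_height_cm Soil ring height in cm; default 16.
#' @param insertion_cm Depth the ring is pressed into the soil, cm;
#'   default 10, leaving 6 cm of ring headspace.
#' @param arc_cm,height_cm Stem chamber bark-patch arc width and height, cm.
#' @param volume_l Stem chamber headspace volume in liters.
#' @param description Optional note.
#' @return A `chamber_spec`.
#' @examples
#' chamber_area_volume("soil_static", diameter_cm = 30, cover_volume_l = 6.4)
#' chamber_area_volume("stem_semirigid", arc_cm = 20, height_cm = 25,
#'                     volume_l = 1.5)
#' @export
chamber_area_volume <- function(kind,
                                diameter_cm = NULL, cover_volume_l = NULL,
                                ring_height_cm = 16, insertion_cm = 10,
                                arc_cm = NULL, height_cm = NULL,
                                volume_l = NULL, description = "") {
  kinds <- c("stem_cylindrical", "stem_semirigid", "soil_static", "floating")
  kind <- match.arg(kind, kinds)
  need <- function(x, nm) {
    if (is.null(x)) stop("missing required dimension '", nm, "' for ", kind)
    if (!is.numeric(x) || any(x <= 0)) stop("'", nm, "' must be positive")
    x
  }
  if (kind == "soil_static") {
    d <- need(diameter_cm, "diameter_cm") / 100   # m
    v0 <- need(cover_volume_l, "cover_volume_l")
    if (insertion_cm > ring_height_cm)
      stop("insertion depth exceeds ring height")
    above_m <- (ring_height_cm - insertion_cm) / 100
    area <- pi * (d / 2)^2
    vol <- v0 + pi * (d / 2)^2 * above_m * 1000   # m3 -> L
    chamber_spec(kind, vol, area, description)
  } else if (kind == "floating") {
    d <- need(diameter_cm, "diameter_cm") / 100
    v0 <- need(cover_volume_l, "cover_volume_l")
    chamber_spec(kind, v0, pi * (d / 2)^2, description)
  } else {
    a <- need(arc_cm, "arc_cm") / 100
    h <- need(height_cm, "height_cm") / 100
    v <- need(volume_l, "volume_l")
    chamber_spec(kind, v, a * h, description)
  }
}

#' Chamber concentration time series
#'
#' One chamber deployment's trace of headspace concentration against time
#' since closure, for a single gas.
#'
#' @param time_s Seconds since chamber closure; strictly increasing.
#' @param concentration Concentrations in the gas's unit (ppm for CO2,
#'   ppb for CH4 and N2O).
#' @param gas Gas label (`"co2"`, `"ch4"`, `"n2o"`).
#' @param temp_k Air temperature inside the chamber, kelvin.
#' @param chamber_id Deployment/chamber identifier.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(time_s, concentration, gas, temp_k,
                                 chamber_id = "chamber") {
  g <- .gas_row(gas)
  stopifnot(is.numeric(time_s), is.numeric(concentration))
  if (length(time_s) != length(concentration))
    stop("time and concentration lengths differ")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(temp_k) || temp_k <= 0) stop("temp_k must be > 0 kelvin")
  structure(list(time_s = as.numeric(time_s),
                 concentration = as.numeric(concentration),
                 gas = g$gas, unit = g$unit, temp_k = temp_k,
                 chamber_id = chamber_id),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %s [%s], %d points over %.0f s, T = %.2f K\n",
              x$gas, x$unit, length(x$time_s), diff(range(x$time_s)), x$temp_k))
  invisible(x)
}

#' Fit the concentration slope of a chamber deployment
#'
#' Ordinary least-squares regression of concentration on time. The slope
#' (ppm s^-1 or ppb s^-1) is the raw material of the flux equation; the
#' coefficient of determination drives quality control.
#'
#' A flat series (zero concentration variance) has an undefined R^2; it is
#' returned as `NA` with slope 0 and caught downstream by [qc_filter()].
#'
#' @param series A [concentration_series()].
#' @return An object of class `slope_fit` with fields `slope`, `intercept`,
#'   `r_squared` (`NA` when undefined), `n_points`, `gas`, `unit`.
#' @export
fit_slope <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  t <- series$time_s; y <- series$concentration
  n <- length(t)
  if (n < 3L) stop("need at least 3 points for a slope fit")
  if (diff(range(t)) == 0) stop("constant times: slope undefined")
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else {
    ss_res <- sum(fit$residuals^2)
    # clamp tiny negative round-off
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  if (ss_tot == 0) slope <- 0
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = n, gas = series$gas, unit = series$unit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.6g %s/s, R2 = %s, n = %d\n",
              x$slope, x$unit,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared),
              x$n_points))
  invisible(x)
}

#' Quality-control decision for a slope fit
#'
#' Deployments whose linear fit has R^2 below the threshold are removed
#' from all downstream aggregation. The rule is strict-less-than: a fit
#' with R^2 exactly at the threshold passes. An undefined R^2 (flat
#' series) fails with a distinct `"degenerate"` reason so it is never
#' silently treated as a zero flux.
#'
#' @param fit A [fit_slope()] result.
#' @param threshold R^2 threshold; default 0.7.
#' @return A list with `pass` (logical) and `reason` (`"ok"`,
#'   `"low_r_squared"` or `"degenerate"`).
#' @export
qc_filter <- function(fit, threshold = 0.7) {
  stopifnot(inherits(fit, "slope_fit"))
  if (is.na(fit$r_squared)) {
    list(pass = FALSE, reason = "degenerate")
  } else if (fit$r_squared < threshold) {
    list(pass = FALSE, reason = "low_r_squared")
  } else {
    list(pass = TRUE, reason = "ok")
  }
}

# mg m-2 h-1 per unit (ppm/s or ppb/s) of slope, for a given chamber,
# temperature and gas. Shared by the forward computation and the
# synthetic-data inverse so the round trip is exact.
.flux_per_slope <- function(gas, volume_l, area_m2, temp_k, r_gas = R_GAS) {
  g <- .gas_row(gas)
  mol_headspace <- volume_l / (r_gas * temp_k)       # P = 1 atm
  g$to_molefrac * mol_headspace * g$molar_mass * 1000 * 3600 / area_m2
}

#' Compute an areal flux from a fitted slope
#'
#' Converts the concentration slope S to a flux F (mg m^-2 h^-1) using the
#' ideal-gas headspace conversion at 1 atm:
#' \deqn{F = S_{molefrac} \times \frac{V}{R\,T} \times M \times
#'       \frac{3600 \times 1000}{A}}
#' where V is chamber volume (L), A enclosed area (m^2), T kelvin, M the
#' gas molar mass (g mol^-1) and R = 0.082 L atm K^-1 mol^-1. F is linear
#' in S and V and inversely proportional to T and A.
#'
#' @param fit A [fit_slope()] result.
#' @param chamber A [chamber_spec()].
#' @param series The originating [concentration_series()] (supplies the
#'   temperature and gas label).
#' @param qc_threshold R^2 threshold passed to [qc_filter()].
#' @param site,tree,height_interval,season,surface Provenance labels
#'   carried on the record.
#' @param r_gas Ideal gas constant, L atm K^-1 mol^-1.
#' @return An object of class `flux_record`: `flux` (mg m^-2 h^-1), `gas`,
#'   `qc_pass`, `qc_reason` and the provenance labels.
#' @export
compute_flux <- function(fit, chamber, series, qc_threshold = 0.7,
                         site = NA_character_, tree = NA_character_,
                         height_interval = NA_character_,
                         season = NA_character_, surface = NA_character_,
                         r_gas = R_GAS) {
  stopifnot(inherits(fit, "slope_fit"), inherits(chamber, "chamber_spec"),
            inherits(series, "concentration_series"))
  if (fit$gas != series$gas) stop("fit and series disagree on gas")
  qc <- qc_filter(fit, qc_threshold)
  f <- fit$slope * .flux_per_slope(series$gas, chamber$volume_l,
                                   chamber$area_m2, series$temp_k, r_gas)
  structure(list(flux = f, gas = series$gas, qc_pass = qc$pass,
                 qc_reason = qc$reason, r_squared = fit$r_squared,
                 site = site, tree = tree, height_interval = height_interval,
                 season = season, surface = surface,
                 chamber_id = series$chamber_id),
            class = "flux_record")
}

#' @export
print.flux_record <- function(x, ...) {
  cat(sprintf("<flux_record> %s %s: %.6g mg m-2 h-1 [QC %s: %s]\n",
              x$surface, x$gas, x$flux,
              if (x$qc_pass) "pass" else "FAIL", x$qc_reason))
  invisible(x)
}

#' @export
as.data.frame.flux_record <- function(x, ...) {
  data.frame(chamber_id = x$chamber_id, gas = x$gas, flux = x$flux,
             r_squared = x$r_squared, qc_pass = x$qc_pass,
             qc_reason = x$qc_reason, site = x$site, tree = x$tree,
             height_interval = x$height_interval, season = x$season,
             surface = x$surface, stringsAsFactors = FALSE)
}

#' Process a batch of deployments into a flux table
#'
#' Runs slope fit, QC and the flux conversion over a list of series and
#' returns one table of all records (passing and failing), suitable for
#' the upscaling stage, plus the rejects with reasons.
#'
#' @param series_list List of [concentration_series()].
#' @param chambers Either a single [chamber_spec()] used for all series or
#'   a named list keyed by `chamber_id`.
#' @param meta Optional data frame of provenance (one row per series, or
#'   keyed by `chamber_id`) with any of the columns `site`, `tree`,
#'   `height_interval`, `season`, `surface`.
#' @param qc_threshold R^2 threshold.
#' @return A data frame, one row per deployment, with the [compute_flux()]
#'   fields. Failing records have `qc_pass = FALSE` and must be excluded
#'   from aggregation (the upscaling functions take only passing rows).
#' @export
flux_table <- function(series_list, chambers, meta = NULL, qc_threshold = 0.7) {
  stopifnot(is.list(series_list))
  pick_chamber <- function(s) {
    if (inherits(chambers, "chamber_spec")) return(chambers)
    ch <- chambers[[s$chamber_id]]
    if (is.null(ch)) stop("no chamber registered for id '", s$chamber_id, "'")
    ch
  }
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    m <- list(site = NA, tree = NA, height_interval = NA,
              season = NA, surface = NA)
    if (!is.null(meta)) {
      mi <- if ("chamber_id" %in% names(meta))
        meta[match(s$chamber_id, meta$chamber_id), , drop = FALSE]
      else meta[i, , drop = FALSE]
      for (f in names(m)) if (f %in% names(mi)) m[[f]] <- mi[[f]]
    }
    rec <- compute_flux(fit_slope(s), pick_chamber(s), s, qc_threshold,
                        site = m$site, tree = m$tree,
                        height_interval = m$height_interval,
                        season = m$season, surface = m$surface)
    as.data.frame(rec)
  })
  do.call(rbind, rows)
}
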