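## Hierarchical upscaling: interval fluxes -> per-tree -> stem-area-weighted
## -> forest-area-weighted annual fluxes, plus vertical/seasonal breakdowns.

#' Tree stem geometry
#'
#' Per-interval stem perimeters and heights for the lateral-area weighting
#' of interval fluxes. Heights are in metres above ground; the interval
#' height H is `high - low`. The total stem area A_t up to the highest
#' sampled interval may be supplied independently (e.g. from an allometric
#' model); when omitted it is derived as the sum of the sampled lateral
#' areas P x H.
#'
#' @param tree_id Identifier.
#' @param height_low_m,height_high_m Interval bounds, metres; intervals
#'   must be ordered, non-overlapping and of positive width.
#' @param perimeter_m Stem perimeter at the chamber position, metres.
#' @param total_stem_area_m2 Optional A_t (m^2).
#' @return An object of class `tree_geometry`.
#' @export
tree_geometry <- function(tree_id, height_low_m, height_high_m, perimeter_m,
                          total_stem_area_m2 = NULL) {
  n <- length(height_low_m)
  stopifnot(length(height_high_m) == n, length(perimeter_m) == n, n >= 1L)
  if (any(height_high_m <= height_low_m))
    stop("intervals must have positive width")
  if (n > 1L) {
    o <- order(height_low_m)
    if (any(height_low_m[o][-1L] < height_high_m[o][-n]))
      stop("intervals must be non-overlapping")
    if (any(o != seq_len(n))) stop("intervals must be ordered by height")
  }
  if (any(perimeter_m <= 0)) stop("perimeters must be > 0")
  lateral <- perimeter_m * (height_high_m - height_low_m)
  a_t <- if (is.null(total_stem_area_m2)) sum(lateral) else total_stem_area_m2
  if (a_t <= 0) stop("total stem area must be > 0")
  structure(list(tree_id = tree_id,
                 height_low_m = as.numeric(height_low_m),
                 height_high_m = as.numeric(height_high_m),
                 perimeter_m = as.numeric(perimeter_m),
                 lateral_area_m2 = lateral,
                 total_stem_area_m2 = a_t),
            class = "tree_geometry")
}

#' @export
print.tree_geometry <- function(x, ...) {
  cat(sprintf("<tree_geometry> %s: %d intervals, A_t = %.4g m2\n",
              x$tree_id, length(x$perimeter_m), x$total_stem_area_m2))
  invisible(x)
}

#' Per-tree flux from interval fluxes
#'
#' Weights each height interval's areal flux F_x (mg m^-2 h^-1) by the
#' interval's lateral stem area P_x H_x and sums:
#' \deqn{F_t = \sum_x F_x P_x H_x}
#' giving a whole-tree emission rate in mg tree^-1 h^-1. Linear in each
#' F_x; negative interval fluxes (stem uptake) are retained.
#'
#' @param interval_fluxes Areal fluxes, one per geometry interval, in
#'   mg m^-2 h^-1.
#' @param geometry A [tree_geometry()].
#' @return F_t in mg tree^-1 h^-1.
#' @export
per_tree_flux <- function(interval_fluxes, geometry) {
  stopifnot(inherits(geometry, "tree_geometry"))
  if (length(interval_fluxes) != length(geometry$lateral_area_m2))
    stop("one flux per sampled interval required (",
         length(interval_fluxes), " fluxes vs ",
         length(geometry$lateral_area_m2), " intervals)")
  sum(interval_fluxes * geometry$lateral_area_m2)
}

#' Stem-surface-area-weighted flux
#'
#' Normalizes the per-tree flux by the total stem area:
#' \deqn{F_{ta} = F_t / A_t} in mg m^-2 stem h^-1. When A_t equals the
#' summed sampled lateral area, F_ta is the area-weighted mean of the
#' interval fluxes and lies within their range.
#'
#' @param f_t Per-tree flux, mg tree^-1 h^-1.
#' @param a_t Total stem area, m^2 (> 0).
#' @return F_ta in mg m^-2 stem h^-1.
#' @export
stem_area_weighted <- function(f_t, a_t) {
  if (!is.numeric(a_t) || any(a_t <= 0)) stop("total stem area must be > 0")
  f_t / a_t
}

#' Forest-area-weighted annual stem flux
#'
#' Annualizes seasonal per-tree fluxes over the stand:
#' \deqn{F_{taw} = \sum_s \bar F_{t,s} \times d \times 10^{-6} \times h_s}
#' where \eqn{\bar F_{t,s}} is the seasonal mean per-tree flux
#' (mg tree^-1 h^-1), d the tree density (trees ha^-1), 1e-6 converts mg
#' to kg and \eqn{h_s} the hours assigned to season s. With the default
#' equal-quarter calendar (2190 h per season, 4 seasons = 8760 h) a
#' constant flux f gives `f * d * 8.76e-3` kg ha^-1 yr^-1.
#'
#' Duplicate measurements of the same season (campaigns spanning more
#' than one year) must be averaged before this step; pass one mean per
#' season label.
#'
#' @param seasonal_ft Named numeric vector of per-season mean F_t
#'   (mg tree^-1 h^-1).
#' @param density Tree density, trees ha^-1.
#' @param hours_per_season Hours assigned to each season; a scalar
#'   (recycled) or a vector matching `seasonal_ft`. Default 8760/4.
#' @return F_taw in kg ha^-1 yr^-1.
#' @export
forest_area_weighted_stem <- function(seasonal_ft, density,
                                      hours_per_season = 8760 / 4) {
  if (length(seasonal_ft) == 0L) stop("empty seasonal flux table")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  h <- rep_len(hours_per_season, length(seasonal_ft))
  sum(seasonal_ft * density * 1e-6 * h)
}

#' Forest-area-weighted annual soil flux
#'
#' Annualizes seasonal mean areal soil fluxes over a hectare:
#' \deqn{F_{saw} = \sum_s \bar F_s \times 10^4 \times 10^{-6} \times h_s}
#' with \eqn{\bar F_s} in mg m^-2 h^-1, 1e4 m^2 per ha and 1e-6 kg per
#' mg. A constant 1 mg m^-2 h^-1 over the default calendar gives 87.6
#' kg ha^-1 yr^-1.
#'
#' @param seasonal_means Named numeric vector of per-season mean soil
#'   fluxes, mg m^-2 h^-1.
#' @param hours_per_season As in [forest_area_weighted_stem()].
#' @return F_saw in kg ha^-1 yr^-1.
#' @export
forest_area_weighted_soil <- function(seasonal_means,
                                      hours_per_season = 8760 / 4) {
  if (length(seasonal_means) == 0L) stop("empty seasonal flux table")
  h <- rep_len(hours_per_season, length(seasonal_means))
  sum(seasonal_means * 1e4 * 1e-6 * h)
}

#' Total ecosystem flux and stem contribution
#'
#' Sums the annual stem and soil pathways and reports the stem share.
#' With opposing signs the contribution can be negative or exceed 100%
#' (e.g. stem emission over a soil sink); a zero total leaves the
#' contribution undefined (`NA`).
#'
#' @param f_taw Forest-area-weighted stem flux, kg ha^-1 yr^-1.
#' @param f_saw Forest-area-weighted soil flux, kg ha^-1 yr^-1.
#' @return List with `total` (kg ha^-1 yr^-1) and `stem_contribution_pct`.
#' @export
ecosystem_flux <- function(f_taw, f_saw) {
  total <- f_taw + f_saw
  pct <- if (total == 0) NA_real_ else 100 * f_taw / total
  list(total = total, stem_contribution_pct = pct)
}

#' Vertical contribution of each height interval
#'
#' Share of the per-tree flux carried by each interval:
#' \deqn{c_x = 100 \, F_x P_x H_x / F_t.}
#' Contributions sum to exactly 100%; a negative contribution indicates
#' an interval acting as a sink while the tree is a net source (or vice
#' versa), so individual shares may fall outside [0, 100].
#'
#' @param interval_fluxes Areal fluxes per interval, mg m^-2 h^-1.
#' @param geometry A [tree_geometry()].
#' @return Numeric vector of percentages (sums to 100), or all-`NA` when
#'   F_t = 0 (undefined).
#' @export
vertical_contributions <- function(interval_fluxes, geometry) {
  f_t <- per_tree_flux(interval_fluxes, geometry)
  if (f_t == 0) return(rep(NA_real_, length(interval_fluxes)))
  100 * interval_fluxes * geometry$lateral_area_m2 / f_t
}

#' Seasonal summary of flux records
#'
#' Per-season mean, SD and n of a flux table, and each season's share of
#' the annual forest-area-weighted flux. With equal season hours the
#' share reduces to each season's mean over the sum of seasonal means;
#' shares sum to 100% whenever the annual flux is nonzero, and are
#' flagged `NA` when seasonal fluxes cancel exactly.
#'
#' @param flux A data frame with columns `season` and `flux` (QC-passing
#'   records only; mg tree^-1 h^-1 for stems, mg m^-2 h^-1 for soil).
#' @param hours_per_season Scalar or per-season hours, matched to the
#'   seasons present (in order of appearance).
#' @return A data frame with columns `season`, `mean`, `sd`, `n`,
#'   `share_pct`.
#' @export
seasonal_summary <- function(flux, hours_per_season = 8760 / 4) {
  stopifnot(is.data.frame(flux), all(c("season", "flux") %in% names(flux)))
  seasons <- unique(flux$season)
  h <- rep_len(hours_per_season, length(seasons))
  means <- vapply(seasons, function(s) mean(flux$flux[flux$season == s]), 0)
  sds <- vapply(seasons, function(s) stats::sd(flux$flux[flux$season == s]), 0)
  ns <- vapply(seasons, function(s) sum(flux$season == s), 0L)
  terms <- means * h
  tot <- sum(terms)
  share <- if (tot == 0) rep(NA_real_, length(seasons)) else 100 * terms / tot
  data.frame(season = seasons, mean = means, sd = sds, n = ns,
             share_pct = share, row.names = NULL, stringsAsFactors = FALSE)
}

#' Site-level annual fluxes from a flux table
#'
#' Convenience aggregator: takes a QC'd flux table (one row per
#' deployment) together with tree geometries and a site configuration,
#' and produces per-gas F_taw and F_saw for the site. Stem records are
#' averaged per (tree, interval, season), rolled up to per-tree seasonal
#' fluxes via [per_tree_flux()], averaged across trees within season,
#' then annualized; soil records are averaged per season and annualized.
#' Duplicate season labels (multi-year campaigns) are averaged by the
#' seasonal mean step.
#'
#' @param flux Data frame from [flux_table()]; only rows with
#'   `qc_pass == TRUE` are used.
#' @param geometries Named list of [tree_geometry()] keyed by tree id.
#' @param density Trees ha^-1.
#' @param hours_per_season Hours per season (default equal quarters).
#' @return Data frame with columns `gas`, `f_taw`, `f_saw`, `total`,
#'   `stem_contribution_pct` (kg ha^-1 yr^-1).
#' @export
site_annual_fluxes <- function(flux, geometries, density,
                               hours_per_season = 8760 / 4) {
  stopifnot(is.data.frame(flux))
  flux <- flux[flux$qc_pass, , drop = FALSE]
  gases <- unique(flux$gas)
  rows <- lapply(gases, function(g) {
    fg <- flux[flux$gas == g, , drop = FALSE]
    stem <- fg[fg$surface == "stem", , drop = FALSE]
    soil <- fg[fg$surface == "soil", , drop = FALSE]
    f_taw <- 0
    if (nrow(stem)) {
      seasons <- unique(stem$season)
      ft_s <- vapply(seasons, function(s) {
        ss <- stem[stem$season == s, , drop = FALSE]
        ft_tree <- vapply(unique(ss$tree), function(tr) {
          st <- ss[ss$tree == tr, , drop = FALSE]
          geo <- geometries[[tr]]
          if (is.null(geo)) stop("no geometry for tree '", tr, "'")
          ivl_labels <- paste0(geo$height_low_m, "-", geo$height_high_m)
          fx <- vapply(ivl_labels, function(il) {
            v <- st$flux[st$height_interval == il]
            if (!length(v)) NA_real_ else mean(v)
          }, 0)
          if (anyNA(fx)) return(NA_real_)  # tree lacks a sampled interval
          per_tree_flux(fx, geo)
        }, 0)
        mean(ft_tree, na.rm = TRUE)
      }, 0)
      keep <- is.finite(ft_s)
      if (any(keep))
        f_taw <- forest_area_weighted_stem(ft_s[keep], density,
                                           rep_len(hours_per_season,
                                                   length(ft_s))[keep])
    }
    f_saw <- 0
    if (nrow(soil)) {
      seasons <- unique(soil$season)
      ms <- vapply(seasons, function(s) mean(soil$flux[soil$season == s]), 0)
      f_saw <- forest_area_weighted_soil(ms, hours_per_season)
    }
    eco <- ecosystem_flux(f_taw, f_saw)
    data.frame(gas = g, f_taw = f_taw, f_saw = f_saw, total = eco$total,
               stem_contribution_pct = eco$stem_contribution_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
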