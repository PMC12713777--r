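## Measurement and structural assessment for PLS path models:
## reliability, convergent and discriminant validity, collinearity,
## bootstrap inference, out-of-sample RMSE and BIC model comparison.

# HTMT matrix from an indicator data frame. Heterotrait-monotrait ratio:
# mean absolute between-block correlation over the geometric mean of the
# mean absolute within-block correlations. NA for single-indicator blocks
# (no monotrait correlations).
.htmt_matrix <- function(data, spec) {
  R <- abs(stats::cor(as.matrix(data[, unlist(spec$constructs), drop = FALSE])))
  cn <- names(spec$constructs)
  m <- length(cn)
  out <- matrix(NA_real_, m, m, dimnames = list(cn, cn))
  mono <- vapply(cn, function(ci) {
    b <- spec$constructs[[ci]]
    if (length(b) < 2L) return(NA_real_)
    rb <- R[b, b, drop = FALSE]
    mean(rb[upper.tri(rb)])
  }, 0)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    hetero <- mean(R[spec$constructs[[cn[i]]], spec$constructs[[cn[j]]]])
    denom <- sqrt(mono[i] * mono[j])
    out[i, j] <- out[j, i] <- if (is.na(denom)) NA_real_ else hetero / denom
  }
  out
}

#' Assess the reflective measurement model
#'
#' Computes, per construct: indicator loadings and reliabilities
#' (loading^2) with the retain / consider / eliminate classification
#' (retain > 0.708, consider for removal in [0.400, 0.708], eliminate
#' < 0.400); internal consistency via Cronbach's alpha, composite
#' reliability rho_C and the Dijkstra-Henseler reliability rho_A;
#' convergent validity via the average variance extracted (AVE, mean
#' squared loading; criterion >= 0.50); and discriminant validity via
#' the heterotrait-monotrait ratio (HTMT) with percentile bootstrap
#' confidence intervals (criterion: CI upper bound < 0.90).
#'
#' Elimination is advisory: flagged indicators are surfaced, and re-fit
#' after removal is the caller's decision.
#'
#' @param fit A [pls_sem()] fit.
#' @param n_boot Bootstrap subsamples for the HTMT CIs; default 10000.
#' @param level CI coverage; default 0.90 (significance level 0.10).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `pls_measurement` with elements
#'   `indicators` (loading, reliability, status), `constructs` (alpha,
#'   rho_a, rho_c, ave and flags; single-indicator constructs have the
#'   reliability statistics `NA` and AVE = loading^2), `htmt` (matrix)
#'   and `htmt_ci` (per pair: estimate, lower, upper, pass).
#' @export
assess_measurement <- function(fit, n_boot = 10000L, level = 0.90,
                               seed = 1L) {
  stopifnot(inherits(fit, "pls_sem"))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  spec <- fit$spec
  cn <- names(spec$constructs)
  lo <- unlist(fit$loadings, use.names = FALSE)
  ind <- data.frame(
    construct = rep(cn, vapply(fit$loadings, length, 0L)),
    indicator = unlist(spec$constructs, use.names = FALSE),
    loading = lo, reliability = lo^2, stringsAsFactors = FALSE)
  ind$status <- ifelse(abs(ind$loading) < 0.400, "eliminate",
                       ifelse(abs(ind$loading) > 0.708, "retain", "consider"))
  X <- as.matrix(fit$data)
  cons <- do.call(rbind, lapply(cn, function(ci) {
    b <- spec$constructs[[ci]]
    lam <- fit$loadings[[ci]]
    k <- length(b)
    if (k == 1L) {
      return(data.frame(construct = ci, n_indicators = 1L,
                        cronbach_alpha = NA_real_, rho_a = NA_real_,
                        rho_c = NA_real_, ave = lam^2,
                        stringsAsFactors = FALSE))
    }
    Rb <- stats::cor(X[, b, drop = FALSE])
    rbar <- mean(Rb[upper.tri(Rb)])
    alpha <- k * rbar / (1 + (k - 1) * rbar)
    rho_c <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
    w <- fit$outer_weights[[ci]]
    # Dijkstra-Henseler rho_A
    num <- drop(t(w) %*% (Rb - diag(k)) %*% w)
    den <- drop(t(w) %*% (w %*% t(w) - diag(diag(w %*% t(w)))) %*% w)
    rho_a <- if (den <= 0) NA_real_ else drop(crossprod(w))^2 * num / den
    data.frame(construct = ci, n_indicators = k, cronbach_alpha = alpha,
               rho_a = rho_a, rho_c = rho_c, ave = mean(lam^2),
               stringsAsFactors = FALSE)
  }))
  cons$reliability_ok <- is.na(cons$cronbach_alpha) |
    (cons$cronbach_alpha >= 0.60 &
       (is.na(cons$rho_c) | cons$rho_c >= 0.60))
  cons$ave_ok <- cons$ave >= 0.50
  htmt <- .htmt_matrix(fit$data, spec)
  pairs <- which(upper.tri(htmt), arr.ind = TRUE)
  pairs <- pairs[!is.na(htmt[pairs]), , drop = FALSE]
  htmt_ci <- NULL
  if (nrow(pairs)) {
    n <- fit$n_obs
    boot <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        hb <- .htmt_matrix(fit$data[i, , drop = FALSE], spec)
        hb[pairs]
      }, numeric(nrow(pairs)))
    })
    boot <- matrix(boot, nrow = nrow(pairs))
    a <- (1 - level) / 2
    htmt_ci <- data.frame(
      construct_1 = rownames(htmt)[pairs[, 1L]],
      construct_2 = colnames(htmt)[pairs[, 2L]],
      htmt = htmt[pairs],
      lower = apply(boot, 1L, stats::quantile, probs = a),
      upper = apply(boot, 1L, stats::quantile, probs = 1 - a),
      stringsAsFactors = FALSE)
    htmt_ci$pass <- htmt_ci$upper < 0.90
  }
  structure(list(indicators = ind, constructs = cons, htmt = htmt,
                 htmt_ci = htmt_ci, n_boot = n_boot, level = level),
            class = "pls_measurement")
}

#' @export
print.pls_measurement <- function(x, digits = 3, ...) {
  cat("Measurement model assessment\n\nIndicators:\n")
  print(format(x$indicators, digits = digits), row.names = FALSE)
  cat("\nConstructs:\n")
  print(format(x$constructs, digits = digits), row.names = FALSE)
  if (!is.null(x$htmt_ci)) {
    cat(sprintf("\nHTMT (%d%% bootstrap CI, %d subsamples; criterion upper < 0.90):\n",
                round(100 * x$level), x$n_boot))
    print(format(x$htmt_ci, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Assess the structural model
#'
#' Collinearity diagnostics (VIF of each endogenous construct's
#' predictors, computed from the latent score correlation matrix; values
#' above 5 flag possible collinearity), percentile bootstrap confidence
#' intervals and two-sided significance for every path coefficient
#' (significant iff the CI excludes zero), and R^2 per endogenous
#' construct. Resamples in which the estimator fails (e.g. singular
#' blocks) are counted and reported, not silently dropped.
#'
#' @param fit A [pls_sem()] fit.
#' @param n_boot Bootstrap subsamples; default 10000.
#' @param level CI coverage; default 0.95 (significance level 0.05).
#' @param seed Integer seed.
#' @return An object of class `pls_structural` with `paths` (estimate,
#'   lower, upper, significant), `vif` (per endogenous construct per
#'   predictor, `flag` when > 5), `r_squared`, `n_failed` resamples.
#' @export
assess_structural <- function(fit, n_boot = 10000L, level = 0.95,
                              seed = 1L) {
  stopifnot(inherits(fit, "pls_sem"))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  spec <- fit$spec
  p <- fit$path_coefficients
  # VIF from score correlations; a numerically singular predictor set
  # (perfect collinearity) is reported as Inf rather than an error.
  vif <- do.call(rbind, lapply(unique(p$to), function(ci) {
    preds <- p$from[p$to == ci]
    if (length(preds) == 1L)
      return(data.frame(construct = ci, predictor = preds, vif = 1,
                        stringsAsFactors = FALSE))
    R <- stats::cor(fit$scores[, preds, drop = FALSE])
    v <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, length(preds)))
    data.frame(construct = ci, predictor = preds, vif = v,
               stringsAsFactors = FALSE)
  }))
  vif$flag <- vif$vif > 5
  n <- fit$n_obs
  idx <- .pls_index(fit$spec, colnames(fit$data))
  key <- paste(p$from, p$to)
  n_failed <- 0L
  boot <- .with_seed(seed, {
    out <- matrix(NA_real_, n_boot, nrow(p))
    Xall <- as.matrix(fit$data)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      est <- tryCatch({
        Xb <- Xall[i, , drop = FALSE]
        sc <- apply(Xb, 2, stats::sd)
        if (any(sc == 0)) stop("degenerate resample")
        pb <- .pls_paths_only(scale(Xb, colMeans(Xb), sc), idx,
                              fit$tol, 300L, fit$method)
        pb$estimate[match(key, paste(pb$from, pb$to))]
      }, error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else out[b, ] <- est
    }
    out
  })
  a <- (1 - level) / 2
  lower <- apply(boot, 2L, stats::quantile, probs = a, na.rm = TRUE)
  upper <- apply(boot, 2L, stats::quantile, probs = 1 - a, na.rm = TRUE)
  paths <- cbind(p, lower = lower, upper = upper,
                 significant = lower > 0 | upper < 0)
  structure(list(paths = paths, vif = vif, r_squared = fit$r_squared,
                 n_boot = n_boot, level = level, n_failed = n_failed),
            class = "pls_structural")
}

#' @export
print.pls_structural <- function(x, digits = 3, ...) {
  cat(sprintf("Structural model assessment (%d%% percentile bootstrap, %d subsamples",
              round(100 * x$level), x$n_boot))
  if (x$n_failed) cat(sprintf(", %d failed resamples", x$n_failed))
  cat(")\n\nPaths:\n")
  print(format(x$paths, digits = digits), row.names = FALSE)
  cat("\nVIF (flag when > 5):\n")
  print(format(x$vif, digits = digits), row.names = FALSE)
  cat("\nR-squared:\n")
  print(round(x$r_squared, digits))
  invisible(x)
}

#' Indirect effect along a construct chain
#'
#' Product of the path coefficients along a directed chain, with a
#' percentile bootstrap CI of the product. The product-CI construction
#' is one common convention; it is reported as such, not as the only
#' admissible test.
#'
#' @param fit A [pls_sem()] fit.
#' @param chain Character vector of constructs, e.g.
#'   `c("TEMP", "TCO2", "TCH4")`; consecutive pairs must be fitted paths.
#' @param n_boot,level,seed Bootstrap settings (defaults 10000, 0.95).
#' @return List with `estimate`, `lower`, `upper`, `significant`.
#' @export
indirect_effect <- function(fit, chain, n_boot = 10000L, level = 0.95,
                            seed = 1L) {
  stopifnot(inherits(fit, "pls_sem"), length(chain) >= 3L)
  p <- fit$path_coefficients
  key <- paste(p$from, p$to)
  links <- paste(chain[-length(chain)], chain[-1L])
  if (anyNA(match(links, key)))
    stop("chain contains a pair that is not a fitted path")
  est <- prod(p$estimate[match(links, key)])
  idx <- .pls_index(fit$spec, colnames(fit$data))
  n <- fit$n_obs
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch({
        Xb <- as.matrix(fit$data)[i, , drop = FALSE]
        pb <- .pls_paths_only(scale(Xb), idx, fit$tol, 300L, fit$method)
        prod(pb$estimate[match(links, paste(pb$from, pb$to))])
      }, error = function(e) NA_real_)
    }, 0)
  })
  a <- (1 - level) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = ci[1L], upper = ci[2L],
       significant = ci[1L] > 0 | ci[2L] < 0)
}

#' Out-of-sample RMSE: PLS structural chain vs a linear benchmark
#'
#' K-fold cross-validation comparing, for each target indicator, the
#' PLS prediction through the structural chain ([predict.pls_sem()])
#' with a plain linear regression of the indicator on all exogenous
#' indicators, using the same folds.
#'
#' @param fit A [pls_sem()] fit (its training data are re-split).
#' @param k_folds Number of folds (>= 2).
#' @param targets Constructs whose indicators to evaluate; default all
#'   endogenous constructs.
#' @param seed Integer seed controlling the fold assignment.
#' @return Data frame with columns `indicator`, `rmse_pls`, `rmse_lm`;
#'   folds in which an indicator had zero variance are flagged via the
#'   `degenerate_folds` attribute.
#' @export
predictive_rmse <- function(fit, k_folds = 10L, targets = NULL, seed = 1L) {
  stopifnot(inherits(fit, "pls_sem"))
  if (k_folds < 2L) stop("k_folds must be >= 2")
  spec <- fit$spec
  endo <- unique(spec$paths$to)
  if (is.null(targets)) targets <- endo
  if (length(setdiff(targets, endo)))
    stop("targets must be endogenous constructs")
  t_ind <- unlist(spec$constructs[targets], use.names = FALSE)
  exo <- setdiff(names(spec$constructs), endo)
  e_ind <- unlist(spec$constructs[exo], use.names = FALSE)
  dat <- fit$data
  n <- nrow(dat)
  folds <- .with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  sq_pls <- sq_lm <- stats::setNames(rep(0, length(t_ind)), t_ind)
  degenerate <- character(0)
  for (kf in seq_len(k_folds)) {
    tr <- dat[folds != kf, , drop = FALSE]
    te <- dat[folds == kf, , drop = FALSE]
    if (any(vapply(tr[, t_ind, drop = FALSE], stats::sd, 0) == 0)) {
      degenerate <- c(degenerate, sprintf("fold %d", kf))
      next
    }
    f_tr <- pls_sem(tr, spec, tol = fit$tol, inner_scheme = fit$inner_scheme)
    pp <- predict(f_tr, te)
    for (v in t_ind) {
      sq_pls[v] <- sq_pls[v] + sum((te[[v]] - pp[[v]])^2)
      lmf <- stats::lm(stats::reformulate(e_ind, response = v), data = tr)
      sq_lm[v] <- sq_lm[v] + sum((te[[v]] - stats::predict(lmf, te))^2)
    }
  }
  out <- data.frame(indicator = t_ind,
                    rmse_pls = sqrt(sq_pls / n),
                    rmse_lm = sqrt(sq_lm / n),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate_folds") <- degenerate
  out
}

#' Rank candidate structural models by BIC
#'
#' For each candidate specification, fits the PLS model and computes the
#' Bayesian information criterion of the target construct's structural
#' regression, `n log(SSE/n) + k log(n)` with k the number of predictors
#' plus intercept. Lowest BIC ranks first; ties break toward fewer
#' parameters.
#'
#' @param data Indicator data frame.
#' @param specs Named list of [pls_model_spec()] candidates (>= 2).
#' @param target Endogenous construct the candidates are compared on;
#'   must be endogenous in every candidate.
#' @param ... Passed to [pls_sem()].
#' @return Data frame ranked by BIC with columns `model`, `bic`, `k`,
#'   `r_squared`.
#' @export
model_select_bic <- function(data, specs, target, ...) {
  if (length(specs) < 2L) stop("need at least 2 candidate specs")
  if (is.null(names(specs))) names(specs) <- paste0("model_", seq_along(specs))
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    if (!target %in% spec$paths$to)
      stop("'", target, "' is not endogenous in candidate ", nm)
    f <- pls_sem(data, spec, ...)
    preds <- spec$paths$from[spec$paths$to == target]
    r2 <- unname(f$r_squared[target])
    # unit-variance scores: SSE of the structural regression is
    # (n-1)(1 - R^2), valid for both the composite and consistent fits
    n <- f$n_obs; k <- length(preds) + 1L
    sse <- (n - 1) * (1 - r2)
    data.frame(model = nm, bic = n * log(sse / n) + k * log(n), k = k,
               r_squared = r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$bic, out$k), , drop = FALSE]
}
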