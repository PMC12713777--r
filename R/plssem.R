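## Partial least squares structural equation modelling: Lohmoller/Wold
## iterative estimator (reflective outer mode, path inner scheme) with
## print/summary/coef/predict methods. Assessment workflow in
## plssem-assess.R.

#' Specify a PLS path model
#'
#' Declares the latent constructs, their reflective indicator blocks, and
#' the directed structural paths. The structural graph must be acyclic
#' and every indicator belongs to exactly one construct.
#'
#' @param constructs Named list; each element is a character vector of
#'   indicator column names measuring that construct reflectively.
#' @param paths Two-column data frame (or matrix) of directed edges with
#'   columns `from`, `to` naming constructs.
#' @return An object of class `pls_model_spec` with the constructs in
#'   topological order.
#' @examples
#' pls_model_spec(
#'   constructs = list(TEMP = c("t_0", "t_5", "t_10"),
#'                     REDOX = c("orp_0", "orp_5", "orp_10"),
#'                     SCH4 = "soil_ch4"),
#'   paths = data.frame(from = c("TEMP", "REDOX"),
#'                      to   = c("REDOX", "SCH4")))
#' @export
pls_model_spec <- function(constructs, paths) {
  stopifnot(is.list(constructs), !is.null(names(constructs)))
  cn <- names(constructs)
  if (anyDuplicated(cn)) stop("duplicate construct names")
  if (any(!vapply(constructs, length, 0L))) stop("every construct needs >= 1 indicator")
  ind <- unlist(constructs, use.names = FALSE)
  if (anyDuplicated(ind))
    stop("indicator assigned to more than one construct: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(paths)))
    stop("paths needs columns 'from' and 'to'")
  paths <- paths[, c("from", "to")]
  bad <- setdiff(unique(c(paths$from, paths$to)), cn)
  if (length(bad)) stop("unknown constructs in paths: ", paste(bad, collapse = ", "))
  if (any(paths$from == paths$to)) stop("self-loops not allowed")
  if (anyDuplicated(paste(paths$from, paths$to))) stop("duplicate paths")
  # topological order (Kahn); failure means a cycle
  order <- character(0); remaining <- cn; edges <- paths
  while (length(remaining)) {
    free <- remaining[!(remaining %in% edges$to)]
    if (!length(free)) stop("structural paths must form a DAG (cycle detected)")
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
    edges <- edges[!(edges$from %in% free), , drop = FALSE]
  }
  isolated <- setdiff(cn, unique(c(paths$from, paths$to)))
  if (length(isolated))
    stop("construct(s) not connected to any path: ",
         paste(isolated, collapse = ", "))
  structure(list(constructs = constructs[order], paths = paths,
                 order = order),
            class = "pls_model_spec")
}

#' @export
print.pls_model_spec <- function(x, ...) {
  cat("<pls_model_spec>", length(x$constructs), "constructs,",
      nrow(x$paths), "paths\n")
  for (cn in names(x$constructs))
    cat(sprintf("  %s <- [%s]\n", cn, paste(x$constructs[[cn]], collapse = ", ")))
  cat("  paths:", paste(paste(x$paths$from, x$paths$to, sep = " -> "),
                        collapse = ", "), "\n")
  invisible(x)
}

# Column indices per block, predecessor/successor construct indices.
.pls_index <- function(spec, colnames_x) {
  cn <- names(spec$constructs)
  blocks <- lapply(spec$constructs, function(v) {
    i <- match(v, colnames_x)
    if (anyNA(i)) stop("indicator(s) missing from data: ",
                       paste(v[is.na(i)], collapse = ", "))
    i
  })
  pred <- lapply(cn, function(ci) match(spec$paths$from[spec$paths$to == ci], cn))
  succ <- lapply(cn, function(ci) match(spec$paths$to[spec$paths$from == ci], cn))
  list(cn = cn, blocks = blocks, pred = pred, succ = succ)
}

# Core iterative fit on a standardized matrix. Returns weights, scores,
# loadings, paths, r2. Kept lean: called thousands of times under the
# bootstrap.
.pls_core <- function(X, idx, tol = 1e-7, max_iter = 300L) {
  n <- nrow(X); m <- length(idx$cn)
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance score; singular block")
    (v - mean(v)) / s
  }
  w <- lapply(idx$blocks, function(b) {
    v <- rep(1, length(b))
    y <- X[, b, drop = FALSE] %*% v
    v / stats::sd(y)
  })
  scores <- matrix(0, n, m)
  for (j in seq_len(m))
    scores[, j] <- std(X[, idx$blocks[[j]], drop = FALSE] %*% w[[j]])
  delta <- Inf; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # inner proxies, path scheme
    Z <- matrix(0, n, m)
    for (j in seq_len(m)) {
      z <- numeric(n)
      pj <- idx$pred[[j]]
      if (length(pj)) {
        # regression weights of score_j on predecessor scores
        b <- tryCatch(
          solve(crossprod(scores[, pj, drop = FALSE]),
                crossprod(scores[, pj, drop = FALSE], scores[, j])),
          error = function(e) stop("singular predictor matrix for construct '",
                                   idx$cn[j], "'", call. = FALSE))
        z <- z + drop(scores[, pj, drop = FALSE] %*% b)
      }
      sj <- idx$succ[[j]]
      if (length(sj)) {
        r <- drop(stats::cor(scores[, j], scores[, sj, drop = FALSE]))
        z <- z + drop(scores[, sj, drop = FALSE] %*% r)
      }
      Z[, j] <- std(z)
    }
    # outer update, mode A (correlation weights)
    delta <- 0
    for (j in seq_len(m)) {
      b <- idx$blocks[[j]]
      wj <- drop(crossprod(X[, b, drop = FALSE], Z[, j])) / (n - 1)
      y <- X[, b, drop = FALSE] %*% wj
      sdy <- stats::sd(y)
      if (sdy == 0) stop("zero-variance score; degenerate block '",
                         idx$cn[j], "'", call. = FALSE)
      wj <- wj / sdy
      # sign anchor: construct correlates non-negatively with first indicator
      if (drop(stats::cor(X[, b[1L]], y)) < 0) wj <- -wj
      delta <- max(delta, max(abs(wj - w[[j]])))
      w[[j]] <- wj
      scores[, j] <- std(X[, b, drop = FALSE] %*% wj)
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("PLS did not converge in %d iterations (last max weight change %.3g)",
                 max_iter, delta), call. = FALSE)
  colnames(scores) <- idx$cn
  loadings <- lapply(seq_len(m), function(j)
    drop(stats::cor(X[, idx$blocks[[j]], drop = FALSE], scores[, j])))
  names(loadings) <- idx$cn
  # structural coefficients
  paths_est <- numeric(0); path_from <- character(0); path_to <- character(0)
  r2 <- stats::setNames(rep(NA_real_, m), idx$cn)
  for (j in seq_len(m)) {
    pj <- idx$pred[[j]]
    if (!length(pj)) next
    Xp <- scores[, pj, drop = FALSE]
    b <- tryCatch(solve(crossprod(Xp), crossprod(Xp, scores[, j])),
                  error = function(e) stop("singular predictor matrix for construct '",
                                           idx$cn[j], "'", call. = FALSE))
    yhat <- Xp %*% b
    r2[j] <- drop(stats::var(yhat)) / drop(stats::var(scores[, j]))
    paths_est <- c(paths_est, drop(b))
    path_from <- c(path_from, idx$cn[pj])
    path_to <- c(path_to, rep(idx$cn[j], length(pj)))
  }
  list(weights = w, scores = scores, loadings = loadings,
       paths = data.frame(from = path_from, to = path_to,
                          estimate = paths_est, stringsAsFactors = FALSE),
       r_squared = r2, n_iterations = iter, last_delta = delta)
}

# Dijkstra-Henseler consistent correction: per-block correction factor
# c-hat rescales weights into consistent loadings, rho_A = (w'w)^2 c^2
# is the composite reliability, and construct correlations are
# disattenuated by sqrt(rho_A_i rho_A_j) before the structural
# regressions. Single-indicator blocks have rho_A = 1 (no correction).
.pls_disattenuate <- function(core, Xs, idx) {
  m <- length(idx$cn)
  rho_a <- stats::setNames(rep(1, m), idx$cn)
  load_c <- core$loadings
  for (j in seq_len(m)) {
    b <- idx$blocks[[j]]; k <- length(b)
    if (k == 1L) { load_c[[j]] <- sign(core$loadings[[j]]); next }
    w <- core$weights[[j]]
    S <- stats::cor(Xs[, b, drop = FALSE])
    num <- drop(t(w) %*% (S - diag(k)) %*% w)
    den <- drop(t(w) %*% (tcrossprod(w) - diag(w^2)) %*% w)
    c2 <- num / den
    if (!is.finite(c2) || c2 <= 0) next  # degenerate block: no correction
    load_c[[j]] <- sqrt(c2) * w
    rho_a[j] <- drop(crossprod(w))^2 * c2
  }
  Rc <- stats::cor(core$scores) / sqrt(tcrossprod(rho_a))
  diag(Rc) <- 1
  paths_est <- numeric(0); path_from <- character(0); path_to <- character(0)
  r2 <- stats::setNames(rep(NA_real_, m), idx$cn)
  for (j in seq_len(m)) {
    pj <- idx$pred[[j]]
    if (!length(pj)) next
    b <- tryCatch(solve(Rc[pj, pj, drop = FALSE], Rc[pj, j]),
                  error = function(e) stop("singular disattenuated predictor matrix for construct '",
                                           idx$cn[j], "'", call. = FALSE))
    r2[j] <- sum(b * Rc[pj, j])
    paths_est <- c(paths_est, drop(b))
    path_from <- c(path_from, idx$cn[pj])
    path_to <- c(path_to, rep(idx$cn[j], length(pj)))
  }
  list(weights = core$weights, scores = core$scores, loadings = load_c,
       rho_a = rho_a,
       paths = data.frame(from = path_from, to = path_to,
                          estimate = paths_est, stringsAsFactors = FALSE),
       r_squared = r2, n_iterations = core$n_iterations,
       last_delta = core$last_delta)
}

# One fit returning just the path table; bootstrap hot path.
.pls_paths_only <- function(Xs, idx, tol, max_iter, method) {
  core <- .pls_core(Xs, idx, tol, max_iter)
  if (method == "plsc") .pls_disattenuate(core, Xs, idx)$paths else core$paths
}

#' Fit a PLS path model
#'
#' Estimates a reflective PLS structural equation model by the iterative
#' outer/inner algorithm: indicators are standardized; construct scores
#' are standardized weighted sums of their block; inner proxies use the
#' path weighting scheme (regression weights toward predecessors,
#' correlations toward successors); outer weights are updated in mode A
#' (indicator-proxy correlations) until the largest weight change falls
#' below `tol`. Path coefficients are then ordinary least squares of each
#' endogenous construct's score on its predecessors' scores. Scores are
#' sign-anchored so each construct correlates non-negatively with its
#' first indicator.
#'
#' @param data Data frame or matrix containing all indicator columns; no
#'   missing values (rows with `NA` are an error, not dropped).
#' @param spec A [pls_model_spec()].
#' @param tol Convergence tolerance on the maximum outer-weight change.
#' @param max_iter Iteration cap; non-convergence is an error reporting
#'   the last weight change.
#' @param inner_scheme Inner weighting scheme; `"path"` (default),
#'   `"centroid"` or `"factorial"` are accepted, the latter two mapping
#'   sums of sign / correlation weights over all adjacent constructs.
#' @param method `"pls"` (default) reports the classical composite-score
#'   regressions, which are attenuated toward zero when indicators carry
#'   measurement error; `"plsc"` applies the Dijkstra-Henseler
#'   consistent correction (construct correlations disattenuated by
#'   rho_A) so path coefficients estimate the latent-variable effects.
#'   Both reduce to the same estimates for error-free (single-indicator,
#'   loading 1) blocks.
#' @return An object of class `pls_sem` with components `outer_weights`,
#'   `loadings`, `scores` (unit variance), `path_coefficients`
#'   (`from`, `to`, `estimate`), `r_squared` (per endogenous construct),
#'   `converged`, `n_iterations`, plus the centering/scaling needed by
#'   [predict.pls_sem()].
#' @export
pls_sem <- function(data, spec, tol = 1e-7, max_iter = 300L,
                    inner_scheme = c("path", "centroid", "factorial"),
                    method = c("pls", "plsc")) {
  inner_scheme <- match.arg(inner_scheme)
  method <- match.arg(method)
  stopifnot(inherits(spec, "pls_model_spec"))
  ind <- unlist(spec$constructs, use.names = FALSE)
  X <- as.matrix(as.data.frame(data)[, ind, drop = FALSE])
  if (!is.numeric(X)) stop("indicators must be numeric")
  if (anyNA(X)) stop("missing values in indicators; impute or drop upstream")
  if (nrow(X) <= length(spec$constructs))
    stop("need more observations than constructs")
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  if (any(scales == 0)) stop("zero-variance indicator(s): ",
                             paste(ind[scales == 0], collapse = ", "))
  Xs <- scale(X, centers, scales)
  idx <- .pls_index(spec, colnames(Xs))
  core <- if (inner_scheme == "path") .pls_core(Xs, idx, tol, max_iter)
          else .pls_core_scheme(Xs, idx, tol, max_iter, inner_scheme)
  if (method == "plsc") core <- .pls_disattenuate(core, Xs, idx)
  structure(list(spec = spec,
                 outer_weights = stats::setNames(core$weights, idx$cn),
                 loadings = core$loadings,
                 scores = core$scores,
                 path_coefficients = core$paths,
                 r_squared = core$r_squared[!is.na(core$r_squared)],
                 converged = TRUE,
                 n_iterations = core$n_iterations,
                 rho_a = core$rho_a,
                 tol = tol, inner_scheme = inner_scheme, method = method,
                 centers = centers, scales = scales,
                 data = as.data.frame(data)[, ind, drop = FALSE],
                 n_obs = nrow(X)),
            class = "pls_sem")
}

# centroid / factorial inner schemes share the iteration skeleton; kept
# separate from the hot path.
.pls_core_scheme <- function(X, idx, tol, max_iter, scheme) {
  n <- nrow(X); m <- length(idx$cn)
  adj <- lapply(seq_len(m), function(j) union(idx$pred[[j]], idx$succ[[j]]))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  w <- lapply(idx$blocks, function(b) {
    v <- rep(1, length(b)); v / stats::sd(X[, b, drop = FALSE] %*% v)
  })
  scores <- matrix(0, n, m)
  for (j in seq_len(m))
    scores[, j] <- std(X[, idx$blocks[[j]], drop = FALSE] %*% w[[j]])
  delta <- Inf; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Z <- matrix(0, n, m)
    for (j in seq_len(m)) {
      a <- adj[[j]]
      r <- drop(stats::cor(scores[, j], scores[, a, drop = FALSE]))
      e <- if (scheme == "centroid") sign(r) else r
      Z[, j] <- std(drop(scores[, a, drop = FALSE] %*% e))
    }
    delta <- 0
    for (j in seq_len(m)) {
      b <- idx$blocks[[j]]
      wj <- drop(crossprod(X[, b, drop = FALSE], Z[, j])) / (n - 1)
      wj <- wj / stats::sd(X[, b, drop = FALSE] %*% wj)
      if (drop(stats::cor(X[, b[1L]], X[, b, drop = FALSE] %*% wj)) < 0)
        wj <- -wj
      delta <- max(delta, max(abs(wj - w[[j]])))
      w[[j]] <- wj
      scores[, j] <- std(X[, b, drop = FALSE] %*% wj)
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("PLS did not converge in %d iterations (last max weight change %.3g)",
                 max_iter, delta), call. = FALSE)
  colnames(scores) <- idx$cn
  loadings <- lapply(seq_len(m), function(j)
    drop(stats::cor(X[, idx$blocks[[j]], drop = FALSE], scores[, j])))
  names(loadings) <- idx$cn
  paths_est <- numeric(0); path_from <- character(0); path_to <- character(0)
  r2 <- stats::setNames(rep(NA_real_, m), idx$cn)
  for (j in seq_len(m)) {
    pj <- idx$pred[[j]]
    if (!length(pj)) next
    Xp <- scores[, pj, drop = FALSE]
    b <- solve(crossprod(Xp), crossprod(Xp, scores[, j]))
    r2[j] <- drop(stats::var(Xp %*% b))
    paths_est <- c(paths_est, drop(b))
    path_from <- c(path_from, idx$cn[pj])
    path_to <- c(path_to, rep(idx$cn[j], length(pj)))
  }
  list(weights = w, scores = scores, loadings = loadings,
       paths = data.frame(from = path_from, to = path_to,
                          estimate = paths_est, stringsAsFactors = FALSE),
       r_squared = r2, n_iterations = iter, last_delta = delta)
}

#' @export
print.pls_sem <- function(x, digits = 3, ...) {
  cat(sprintf("PLS path model (%s): %d constructs, %d paths, n = %d (%s scheme, %d iterations)\n",
              if (identical(x$method, "plsc")) "consistent" else "composite",
              length(x$spec$constructs), nrow(x$path_coefficients), x$n_obs,
              x$inner_scheme, x$n_iterations))
  cat("\nPath coefficients:\n")
  p <- x$path_coefficients
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s -> %s: %+.*f\n", p$from[i], p$to[i], digits, p$estimate[i]))
  if (length(x$r_squared)) {
    cat("\nR-squared:\n")
    for (nm in names(x$r_squared))
      cat(sprintf("  %s: %.*f\n", nm, digits, x$r_squared[[nm]]))
  }
  invisible(x)
}

#' @export
coef.pls_sem <- function(object, ...) {
  stats::setNames(object$path_coefficients$estimate,
                  paste(object$path_coefficients$from,
                        object$path_coefficients$to, sep = "->"))
}

#' @export
summary.pls_sem <- function(object, ...) {
  lo <- data.frame(
    construct = rep(names(object$loadings),
                    vapply(object$loadings, length, 0L)),
    indicator = unlist(object$spec$constructs, use.names = FALSE),
    loading = unlist(object$loadings, use.names = FALSE),
    stringsAsFactors = FALSE)
  lo$reliability <- lo$loading^2
  structure(list(fit = object, loadings = lo,
                 paths = object$path_coefficients,
                 r_squared = object$r_squared),
            class = "summary.pls_sem")
}

#' @export
print.summary.pls_sem <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nLoadings (indicator reliability = loading^2):\n")
  print(format(x$loadings, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Predict indicators through the structural chain
#'
#' For new observations, exogenous construct scores are formed from the
#' (training-standardized) indicators and the fitted outer weights;
#' endogenous scores are then propagated in topological order through the
#' path coefficients, and each endogenous indicator is predicted as
#' `loading x predicted score`, returned on the original scale.
#'
#' @param object A [pls_sem()] fit.
#' @param newdata Data frame with at least the exogenous indicators;
#'   defaults to the training data.
#' @param ... Unused.
#' @return Data frame of predicted values for every endogenous
#'   construct's indicators.
#' @export
predict.pls_sem <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  spec <- object$spec
  cn <- spec$order
  endo <- unique(spec$paths$to)
  exo <- setdiff(cn, endo)
  scores <- matrix(NA_real_, nrow(newdata), length(cn),
                   dimnames = list(NULL, cn))
  for (cname in exo) {
    ind <- spec$constructs[[cname]]
    if (!all(ind %in% names(newdata)))
      stop("newdata lacks indicators for exogenous construct ", cname)
    Xb <- scale(as.matrix(newdata[, ind, drop = FALSE]),
                object$centers[ind], object$scales[ind])
    scores[, cname] <- Xb %*% object$outer_weights[[cname]]
  }
  p <- object$path_coefficients
  for (cname in cn) {
    if (!cname %in% endo) next
    pp <- p[p$to == cname, , drop = FALSE]
    scores[, cname] <- as.matrix(scores[, pp$from, drop = FALSE]) %*% pp$estimate
  }
  out <- list()
  for (cname in endo) {
    ind <- spec$constructs[[cname]]
    lam <- object$loadings[[cname]]
    for (i in seq_along(ind)) {
      out[[ind[i]]] <- scores[, cname] * lam[i] * object$scales[ind[i]] +
        object$centers[ind[i]]
    }
  }
  as.data.frame(out)
}

#' @export
residuals.pls_sem <- function(object, ...) {
  pred <- predict(object)
  obs <- object$data[, names(pred), drop = FALSE]
  obs - pred
}

#' Sketch the structural model
#'
#' Draws constructs on a circle with arrows labelled by path
#' coefficients; a quick visual check of the fitted inner model.
#'
#' @param x A [pls_sem()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pls_sem <- function(x, ...) {
  cn <- names(x$spec$constructs)
  m <- length(cn)
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", pch = NA, asp = 1, ...)
  p <- x$path_coefficients
  for (i in seq_len(nrow(p))) {
    a <- match(p$from[i], cn); b <- match(p$to[i], cn)
    dx <- px[b] - px[a]; dy <- py[b] - py[a]
    len <- sqrt(dx^2 + dy^2); sh <- 0.18 / len
    graphics::arrows(px[a] + dx * sh, py[a] + dy * sh,
                     px[b] - dx * sh, py[b] - dy * sh, length = 0.1)
    graphics::text(px[a] + dx / 2, py[a] + dy / 2,
                   sprintf("%.2f", p$estimate[i]), cex = 0.8, pos = 3)
  }
  graphics::text(px, py, cn, font = 2)
  invisible(x)
}
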