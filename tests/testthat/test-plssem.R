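test_that("model spec validation enforces the DAG and indicator contracts", {
  expect_error(pls_model_spec(list(A = "a", B = "b"),
                              data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
  expect_error(pls_model_spec(list(A = c("a", "x"), B = c("b", "x")),
                              data.frame(from = "A", to = "B")),
               "more than one construct")
  expect_error(pls_model_spec(list(A = "a", B = "b", C = "c"),
                              data.frame(from = "A", to = "B")),
               "not connected")
  expect_error(pls_model_spec(list(A = "a", B = "b"),
                              data.frame(from = "A", to = "Z")),
               "unknown constructs")
})

test_that("single-indicator path equals the Pearson correlation, both methods", {
  set.seed(21)
  d <- data.frame(x = rnorm(400))
  d$y <- 0.6 * d$x + rnorm(400)
  sp <- pls_model_spec(list(X = "x", Y = "y"),
                       data.frame(from = "X", to = "Y"))
  for (m in c("pls", "plsc")) {
    f <- pls_sem(d, sp, method = m)
    expect_equal(unname(coef(f)), cor(d$x, d$y), tolerance = 1e-10)
  }
})

test_that("single-indicator models reduce to OLS path analysis on standardized data", {
  set.seed(31)
  d <- data.frame(a = rnorm(300), b = rnorm(300))
  d$c <- 0.4 * d$a - 0.3 * d$b + rnorm(300)
  sp <- pls_model_spec(list(A = "a", B = "b", C = "c"),
                       data.frame(from = c("A", "B"), to = c("C", "C")))
  f <- pls_sem(d, sp)
  z <- as.data.frame(scale(d))
  ols <- coef(lm(c ~ a + b - 1, data = z))
  expect_equal(unname(coef(f)[c("A->C", "B->C")]), unname(ols),
               tolerance = 1e-8)
})

test_that("identical indicators in a block get equal weights and unit loadings", {
  set.seed(41)
  d <- data.frame(A_1 = rnorm(200))
  d$A_2 <- d$A_1; d$A_3 <- d$A_1
  d$B_1 <- 0.5 * d$A_1 + rnorm(200)
  sp <- pls_model_spec(list(A = c("A_1", "A_2", "A_3"), B = "B_1"),
                       data.frame(from = "A", to = "B"))
  f <- pls_sem(d, sp)
  expect_equal(unname(f$outer_weights$A), rep(f$outer_weights$A[[1]], 3))
  expect_equal(unname(f$loadings$A), rep(1, 3))
  m <- assess_measurement(f, n_boot = 5, seed = 1)
  a <- m$constructs[m$constructs$construct == "A", ]
  expect_equal(a$cronbach_alpha, 1)
  expect_equal(a$rho_c, 1)
  expect_equal(a$ave, 1)
})

test_that("path estimates are invariant to affine rescaling of indicators", {
  tr <- chain_truth(n = 500, seed = 13)
  d <- simulate_latent_model(tr)
  sp <- chain_spec()
  f1 <- pls_sem(d, sp)
  d2 <- d
  d2$A_1 <- 100 + 42 * d2$A_1
  d2$C_3 <- -3 * d2$C_3   # sign flip on a non-anchor indicator
  f2 <- pls_sem(d2, sp)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(apply(f1$scores, 2, sd), c(A = 1, B = 1, C = 1),
               tolerance = 1e-12)
})

test_that("consistent estimation recovers the generating chain", {
  tr <- chain_truth(b1 = 0.5, b2 = 0.4, loading = 0.8, n = 2000, seed = 42)
  f <- pls_sem(simulate_latent_model(tr), chain_spec(), method = "plsc")
  expect_lt(abs(coef(f)[["A->B"]] - 0.5), 0.05)
  expect_lt(abs(coef(f)[["B->C"]] - 0.4), 0.05)
  # composite estimates are attenuated by about rho_A
  fc <- pls_sem(simulate_latent_model(tr), chain_spec(), method = "pls")
  expect_lt(coef(fc)[["A->B"]], coef(f)[["A->B"]])
})

test_that("input contracts are enforced and non-convergence is reported", {
  tr <- chain_truth(n = 50, seed = 2)
  d <- simulate_latent_model(tr)
  sp <- chain_spec()
  d_na <- d; d_na[3, 2] <- NA
  expect_error(pls_sem(d_na, sp), "missing values")
  expect_error(pls_sem(d[1:3, ], sp), "more observations")
  expect_error(pls_sem(d, sp, max_iter = 0L), "did not converge")
  d_const <- d; d_const$A_1 <- 1
  expect_error(pls_sem(d_const, sp), "zero-variance")
})

test_that("measurement assessment classifies loadings and validates constructs", {
  B <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  B[2, 1] <- 0.5
  tr <- latent_truth(B, list(X = c(0.2, 0.5, 0.95), Y = 1),
                     n_obs = 4000, seed = 8)
  d <- simulate_latent_model(tr)
  sp <- pls_model_spec(list(X = paste0("X_", 1:3), Y = "Y_1"),
                       data.frame(from = "X", to = "Y"))
  m <- assess_measurement(pls_sem(d, sp, method = "plsc"),
                          n_boot = 50, seed = 1)
  ind <- m$indicators[m$indicators$construct == "X", ]
  expect_equal(ind$status, c("eliminate", "consider", "retain"))
  # rule consistency on every indicator
  want <- ifelse(abs(m$indicators$loading) < 0.400, "eliminate",
                 ifelse(abs(m$indicators$loading) > 0.708, "retain",
                        "consider"))
  expect_equal(m$indicators$status, want)
  expect_equal(m$indicators$reliability, m$indicators$loading^2)
  # single-indicator construct: reliability NA, AVE = loading^2
  y <- m$constructs[m$constructs$construct == "Y", ]
  expect_true(is.na(y$cronbach_alpha))
  expect_equal(y$ave, 1)
  expect_error(assess_measurement(pls_sem(d, sp), n_boot = 0), "n_boot")
})

test_that("HTMT of independent constructs stays below the 0.90 criterion", {
  B <- matrix(0, 2, 2, dimnames = list(c("P", "Q"), c("P", "Q")))
  tr <- latent_truth(B, list(P = rep(0.8, 3), Q = rep(0.8, 3)),
                     n_obs = 1000, seed = 4)
  d <- simulate_latent_model(tr)
  sp <- pls_model_spec(list(P = paste0("P_", 1:3), Q = paste0("Q_", 1:3)),
                       data.frame(from = "P", to = "Q"))
  m <- assess_measurement(pls_sem(d, sp), n_boot = 300, level = 0.90,
                          seed = 2)
  expect_lt(m$htmt_ci$upper, 0.90)
  expect_true(m$htmt_ci$pass)

  # direct correlation-ratio oracle
  R <- abs(cor(d))
  hetero <- mean(R[paste0("P_", 1:3), paste0("Q_", 1:3)])
  mono_p <- mean(R[paste0("P_", 1:3), paste0("P_", 1:3)][upper.tri(diag(3))])
  mono_q <- mean(R[paste0("Q_", 1:3), paste0("Q_", 1:3)][upper.tri(diag(3))])
  expect_equal(m$htmt_ci$htmt, hetero / sqrt(mono_p * mono_q),
               tolerance = 1e-12)
})

test_that("structural assessment flags collinearity and bootstrap significance", {
  set.seed(51)
  n <- 300
  d <- data.frame(a = rnorm(n))
  d$a2 <- d$a                       # exactly duplicated predictor construct
  d$b <- rnorm(n)
  d$y <- 0.5 * d$a + 0.3 * d$b + rnorm(n)
  sp_dup <- pls_model_spec(list(A = "a", A2 = "a2", Y = "y"),
                           data.frame(from = c("A", "A2"), to = c("Y", "Y")))
  # perfect collinearity is an estimator error, not a silent fit
  expect_error(pls_sem(d, sp_dup), "singular predictor")
  # a near-duplicate fits but is flagged by the VIF criterion
  d$a2 <- d$a + rnorm(n, 0, 0.02)
  s_dup <- assess_structural(pls_sem(d, sp_dup), n_boot = 20, seed = 1)
  expect_true(all(s_dup$vif$vif > 5))
  expect_true(all(s_dup$vif$flag))

  sp <- pls_model_spec(list(A = "a", B = "b", Y = "y"),
                       data.frame(from = c("A", "B"), to = c("Y", "Y")))
  f <- pls_sem(d, sp)
  s <- assess_structural(f, n_boot = 400, seed = 3)
  # near-orthogonal single-indicator predictors: VIF close to 1
  expect_true(all(abs(s$vif$vif - 1) < 0.1))
  expect_true(all(s$paths$significant))
  # CIs contain the point estimate
  expect_true(all(s$paths$lower <= s$paths$estimate &
                    s$paths$estimate <= s$paths$upper))
})

test_that("bootstrap CI width shrinks with sample size", {
  w <- sapply(c(200, 800), function(n) {
    tr <- chain_truth(n = n, seed = 17)
    f <- pls_sem(simulate_latent_model(tr), chain_spec())
    s <- assess_structural(f, n_boot = 300, seed = 5)
    mean(s$paths$upper - s$paths$lower)
  })
  expect_lt(w[2], w[1])
  # roughly 1/sqrt(n): fourfold n halves the width, within generous slack
  expect_lt(w[2] / w[1], 0.75)
})

test_that("indirect effects multiply path coefficients with a bootstrap CI", {
  tr <- chain_truth(n = 800, seed = 23)
  f <- pls_sem(simulate_latent_model(tr), chain_spec(), method = "plsc")
  ie <- indirect_effect(f, c("A", "B", "C"), n_boot = 200, seed = 7)
  p <- coef(f)
  expect_equal(ie$estimate, p[["A->B"]] * p[["B->C"]], tolerance = 1e-12)
  expect_true(ie$lower <= ie$estimate && ie$estimate <= ie$upper)
  expect_true(ie$significant)
  expect_error(indirect_effect(f, c("A", "C", "B")), "not a fitted path")
})

test_that("out-of-sample RMSE comparison behaves at the no-signal limit and is seeded", {
  set.seed(61)
  n <- 300
  d <- data.frame(matrix(rnorm(n * 4), n, 4,
                         dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  sp <- pls_model_spec(list(A = c("a1", "a2"), B = c("b1", "b2")),
                       data.frame(from = "A", to = "B"))
  f <- pls_sem(d, sp)
  r <- predictive_rmse(f, k_folds = 5, seed = 9)
  # pure-noise targets: both RMSEs near the target SD
  for (v in c("b1", "b2")) {
    expect_lt(abs(r$rmse_pls[r$indicator == v] - sd(d[[v]])), 0.1 * sd(d[[v]]))
    expect_lt(abs(r$rmse_lm[r$indicator == v] - sd(d[[v]])), 0.1 * sd(d[[v]]))
  }
  expect_identical(r, predictive_rmse(f, k_folds = 5, seed = 9))
  expect_error(predictive_rmse(f, k_folds = 1), "k_folds")
})

test_that("PLS beats the saturated linear benchmark when indicators are many and n small", {
  # 8 noisy exogenous indicators, one structural dimension: the LM
  # benchmark must estimate 8 coefficients where the chain needs 1
  B <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  B[2, 1] <- 0.8; B[3, 2] <- 0.8
  tr <- latent_truth(B, list(A = rep(0.6, 8), B = 1, C = 1),
                     n_obs = 120, seed = 33)
  d <- simulate_latent_model(tr)
  sp <- pls_model_spec(list(A = paste0("A_", 1:8), B = "B_1", C = "C_1"),
                       data.frame(from = c("A", "B"), to = c("B", "C")))
  f <- pls_sem(d, sp)
  r <- predictive_rmse(f, k_folds = 5, seed = 3)
  expect_lt(r$rmse_pls[r$indicator == "C_1"],
            r$rmse_lm[r$indicator == "C_1"])
})

test_that("BIC model ranking penalizes a pure-noise predictor and is stable", {
  tr <- chain_truth(b1 = 0.5, b2 = 0.4, n = 2000, seed = 19)
  d <- simulate_latent_model(tr)
  set.seed(20)
  d$noise_1 <- rnorm(2000)
  true_spec <- chain_spec()
  bloat_spec <- pls_model_spec(
    constructs = c(list(D = "noise_1"),
                   true_spec$constructs[c("A", "B", "C")]),
    paths = rbind(true_spec$paths, data.frame(from = "D", to = "C")))
  r <- model_select_bic(d, list(true = true_spec, bloated = bloat_spec),
                        target = "C")
  expect_equal(r$model[1], "true")
  expect_lt(r$bic[1], r$bic[2])
  # identical candidates give identical BIC
  r2 <- model_select_bic(d, list(m1 = true_spec, m2 = true_spec),
                         target = "C")
  expect_equal(r2$bic[1], r2$bic[2])
  expect_error(model_select_bic(d, list(true_spec), target = "C"),
               "at least 2")
})
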