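test_that("degenerate closed forms: single observation and inverse-variance weighting", {
  # single observation, all components fixed at 0
  f1 <- suppressWarnings(
    reml_fit(0.7, matrix(0.09), matrix(1), list(obs = factor(1)),
             sigma2_fixed = 0))
  expect_equal(f1$beta$estimate, 0.7)
  expect_equal(f1$beta$se, 0.3)

  # k independent effects, sigma2 = 0: inverse-variance weighted mean
  set.seed(2)
  v <- runif(12, 0.05, 0.6)
  y <- rnorm(12, 0.3, sqrt(v))
  f <- reml_fit(y, diag(v), matrix(1, 12), list(obs = factor(1:12)),
                sigma2_fixed = 0)
  expect_equal(f$beta$estimate, sum(y / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(f$beta$se, sqrt(1 / sum(1 / v)), tolerance = 1e-12)
})

test_that("REML matches brute-force restricted-likelihood maximization (1 component)", {
  set.seed(31)
  for (case in 1:20) {
    n <- 20
    v <- runif(n, 0.05, 0.4)
    tau2 <- runif(1, 0.05, 0.8)
    y <- rnorm(n, 0.2, sqrt(v + tau2))
    V <- diag(v)
    X <- matrix(1, n)
    fit <- suppressWarnings(
      reml_fit(y, V, X, list(obs = factor(1:n))))
    # golden-section-style refinement of a dense grid oracle
    grid <- seq(1e-6, 5, length.out = 2001)
    ll <- oracle_reml_1d(y, V, X, diag(n), grid)
    s2_grid <- grid[which.max(ll)]
    expect_lt(abs(fit$sigma2[["obs"]] - s2_grid), 2.5e-3)  # grid step
    expect_gte(fit$loglik_restricted, max(ll) - 1e-6)
  }
})

test_that("the multilevel fit agrees with metafor::rma.mv as an independent oracle", {
  skip_if_not_installed("metafor")
  sim <- simulate_dataset(simulation_config(n_sources = 8L), seed = 3)
  rec <- impute_sd(sim$comparisons, "poisson")
  es <- build_effect_size_set(rec)
  tab <- es$table
  dat <- data.frame(obs = seq_len(nrow(tab)), src = tab$source_id,
                    stdy = paste(tab$source_id, tab$study_id))

  # two-component structure: exact agreement expected
  fit <- reml_fit(tab$value, es$vcov, matrix(1, nrow(tab)),
                  list(observation = dat$obs, source = dat$src))
  mf <- suppressWarnings(metafor::rma.mv(
    tab$value, V = es$vcov, random = list(~1 | obs, ~1 | src), data = dat,
    sparse = TRUE))
  expect_equal(fit$beta$estimate, as.numeric(mf$beta), tolerance = 1e-5)
  expect_equal(fit$beta$se, mf$se, tolerance = 1e-5)
  expect_equal(unname(fit$sigma2), mf$sigma2, tolerance = 1e-4)
  # metafor's restricted ll differs by the constant 0.5 log|X'X|
  const <- 0.5 * log(nrow(tab))
  expect_equal(fit$loglik_restricted - (-const),
               as.numeric(stats::logLik(mf)), tolerance = 1e-6)

  # three-component nested structure with shared-control covariance: the
  # multi-start optimum must be at least as good as metafor's, and the GLS
  # fixed-effect step must agree exactly when both sit at the same sigma2
  fit3 <- reml_fit(tab$value, es$vcov, matrix(1, nrow(tab)),
                   list(observation = dat$obs, source = dat$src,
                        study = dat$stdy))
  mf3 <- suppressWarnings(metafor::rma.mv(
    tab$value, V = es$vcov, random = list(~1 | obs, ~1 | src, ~1 | stdy),
    data = dat, sparse = TRUE))
  expect_gte(fit3$loglik_restricted + const,
             as.numeric(stats::logLik(mf3)) - 1e-4)
  mf3_fixed <- suppressWarnings(metafor::rma.mv(
    tab$value, V = es$vcov, random = list(~1 | obs, ~1 | src, ~1 | stdy),
    data = dat, sparse = TRUE, sigma2 = unname(fit3$sigma2)))
  expect_equal(fit3$beta$estimate, as.numeric(mf3_fixed$beta),
               tolerance = 1e-8)
  expect_equal(fit3$beta$se, mf3_fixed$se, tolerance = 1e-8)
  expect_equal(fit3$loglik_restricted + const,
               as.numeric(stats::logLik(mf3_fixed)), tolerance = 1e-6)
})

test_that("fits are permutation-equivariant", {
  sim <- simulate_dataset(simulation_config(n_sources = 6L), seed = 9)
  rec <- impute_sd(sim$comparisons, "poisson")
  es <- build_effect_size_set(rec)
  tab <- es$table
  X <- build_design(tab, moderator_spec("distance"), "mammal")
  g <- random_effects_groups(tab)
  fit <- suppressWarnings(reml_fit(tab$value, es$vcov, X, g))
  set.seed(4)
  perm <- sample(nrow(tab))
  gp <- lapply(g, function(f) f[perm])
  fitp <- suppressWarnings(
    reml_fit(tab$value[perm], es$vcov[perm, perm], X[perm, ], gp))
  expect_equal(fitp$beta$estimate, fit$beta$estimate, tolerance = 1e-5)
  expect_equal(fitp$sigma2, fit$sigma2, tolerance = 1e-4)
  expect_equal(fitp$loglik_restricted, fit$loglik_restricted,
               tolerance = 1e-6)
  expect_equal(fitp$aicc, fit$aicc, tolerance = 1e-5)
  expect_equal(fitp$qe$statistic, fit$qe$statistic, tolerance = 1e-8)
})

test_that("input validation catches rank deficiency, asymmetry and dimension errors", {
  y <- c(0.1, 0.2, 0.3)
  V <- diag(0.1, 3)
  X_bad <- cbind(1, c(2, 2, 2))  # collinear
  expect_error(reml_fit(y, V, X_bad, list(obs = factor(1:3))),
               "rank deficient")
  V_asym <- V; V_asym[1, 2] <- 0.05
  expect_error(reml_fit(y, V_asym, matrix(1, 3), list(obs = factor(1:3))),
               "symmetric")
  expect_error(reml_fit(y, diag(0.1, 2), matrix(1, 3),
                        list(obs = factor(1:3))), "dimension")
  expect_error(reml_fit(y, V, matrix(1, 3), list(obs = factor(1:2))),
               "grouping")
  expect_warning(
    reml_fit(y, diag(c(0.1, 0.1, 0)), matrix(1, 3),
             list(obs = factor(1:3)), sigma2_fixed = 0.1),
    "flooring")
})

test_that("Q_E matches hand arithmetic and is chi-square calibrated", {
  # perfect fit
  y <- c(1, 2, 3)
  X <- cbind(1, y)
  expect_equal(q_e(y, diag(0.2, 3), X)$statistic, 0, tolerance = 1e-10)
  # y = (1, -1), V = I, intercept-only
  qe <- q_e(c(1, -1), diag(2), matrix(1, 2))
  expect_equal(qe$statistic, 2)
  expect_equal(qe$df, 1)
  expect_equal(qe$p, pchisq(2, 1, lower.tail = FALSE))
})

test_that("Q_M reduces to the squared Wald z for one coefficient", {
  sim <- simulate_dataset(simulation_config(n_sources = 6L), seed = 11)
  es <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
  fit <- suppressWarnings(
    fit_meta_regression(es, moderator_spec("distance"), "mammal"))
  qm <- q_m(fit, "distance")
  z <- fit$beta$estimate[2] / fit$beta$se[2]
  expect_equal(qm$statistic, z^2, tolerance = 1e-10)
  expect_equal(qm$df, 1)
  expect_equal(qm$p, fit$beta$pval[2], tolerance = 1e-12)
  # df equals the number of tested coefficients; intercept excluded
  expect_error(q_m(fit, "intercept"), "intercept")
  expect_error(q_m(fit, character(0)), "empty")
})

test_that("term-level Q_M drops interactions before testing main effects", {
  sim <- simulate_dataset(
    simulation_config(spec = moderator_spec(c("distance", "habitat",
                                              "distance:habitat")),
                      true_beta = c(intercept = 0.2, distance = -0.2,
                                    habitat_open = 0.3,
                                    `distance:habitat_open` = -0.1),
                      n_sources = 8L),
    seed = 13)
  es <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
  fit <- suppressWarnings(fit_meta_regression(
    es, moderator_spec(c("distance", "habitat", "distance:habitat")),
    "mammal"))
  res <- qm_term(fit, "habitat")
  expect_equal(res$refit_without, "distance:habitat")
  expect_equal(res$df, 1)
  # the interaction itself is tested in the full model
  res2 <- qm_term(fit, "distance:habitat")
  direct <- q_m(fit, "distance:habitat_open")
  expect_equal(res2$statistic, direct$statistic)
})

test_that("AICc follows the full-likelihood small-sample formula", {
  sim <- simulate_dataset(simulation_config(n_sources = 5L), seed = 21)
  es <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
  fit <- suppressWarnings(fit_meta_regression(es, moderator_spec(), "mammal"))
  k <- fit$n_params
  n <- fit$n_obs
  expect_equal(k, 1 + 5)  # intercept + five variance components
  expect_equal(aicc(fit),
               -2 * fit$loglik_full + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_equal(fit$aicc, aicc(fit))
  # AICc - AIC identity
  aic <- -2 * fit$loglik_full + 2 * k
  expect_equal(aicc(fit) - aic, 2 * k * (k + 1) / (n - k - 1))
})

test_that("R2 reduces to its forced values in degenerate configurations", {
  sim <- simulate_dataset(simulation_config(n_sources = 6L), seed = 23)
  es <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
  # intercept-only: no fixed-effect variance
  fit0 <- suppressWarnings(fit_meta_regression(es, moderator_spec(),
                                               "mammal"))
  expect_equal(fit0$r2_marginal, 0)
  expect_gte(fit0$r2_conditional, 0)
  expect_lte(fit0$r2_conditional, 1)

  # all sigma2 = 0 and var(Xb) = s2 forces R2m = R2c = 0.5
  n <- 40
  V <- diag(0.2, n)
  s2 <- iezmeta:::.typical_sampling_variance(V)
  x <- rep(c(0, 1), n / 2)
  fit <- suppressWarnings(
    reml_fit(rnorm(n), V, cbind(1, x), list(obs = factor(1:n)),
             sigma2_fixed = 0))
  # rescale the fitted values to have variance exactly s2
  f <- as.numeric(cbind(1, x) %*% fit$beta$estimate)
  fit$beta$estimate <- fit$beta$estimate * sqrt(s2 / var(f))
  r2 <- r2_nakagawa(fit)
  expect_equal(unname(r2["r2_marginal"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(r2["r2_conditional"]), 0.5, tolerance = 1e-10)
})

test_that("variance proportions are the components' share of total heterogeneity", {
  n <- 30
  V <- diag(0.3, n)
  s2 <- iezmeta:::.typical_sampling_variance(V)
  fit <- suppressWarnings(
    reml_fit(rnorm(n, 0, sqrt(0.3 + s2)), V, matrix(1, n),
             list(obs = factor(1:n), src = factor(rep(1:5, 6))),
             sigma2_fixed = c(s2, 0)))
  vp <- variance_proportions(fit)
  expect_equal(unname(vp["obs"]), 50)
  expect_equal(unname(vp["src"]), 0)
  expect_equal(sum(vp), 100)
  # independent recomputation from the sigma2 vector
  manual <- c(fit$sigma2, s2) / (sum(fit$sigma2) + s2) * 100
  expect_equal(unname(vp), unname(manual))
})

test_that("profile likelihood flags identifiable and degenerate components", {
  sim <- simulate_dataset(
    simulation_config(n_sources = 10L,
                      true_sigma2 = c(observation = 0.3, clade = 0,
                                      species = 0, source = 0.4,
                                      study = 0)),
    seed = 5)
  es <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
  tab <- es$table
  g2 <- list(observation = factor(seq_len(nrow(tab))),
             source = factor(tab$source_id))
  fit <- suppressWarnings(reml_fit(tab$value, es$vcov, matrix(1, nrow(tab)),
                                   g2))
  pr <- profile_component(fit, "observation")
  expect_true(pr$identifiable)
  imax <- which.max(pr$loglik)
  expect_equal(pr$grid[imax], fit$sigma2[["observation"]],
               tolerance = max(diff(pr$grid)))

  # duplicated grouping factor: a ridge in the likelihood
  gdup <- list(source = factor(tab$source_id),
               source_again = factor(tab$source_id))
  fdup <- suppressWarnings(reml_fit(tab$value, es$vcov,
                                    matrix(1, nrow(tab)), gdup))
  prd <- profile_component(fdup, "source",
                           grid = seq(1e-4, sum(fdup$sigma2) * 0.98,
                                      length.out = 15))
  expect_false(prd$identifiable)
})

test_that("Egger regression returns a zero intercept for exact fits", {
  n <- 20
  V <- diag(runif(n, 0.05, 0.3))
  X <- matrix(1, n)
  beta <- 0.4
  y <- rep(beta, n)
  fit <- suppressWarnings(reml_fit(y, V, X, list(obs = factor(1:n)),
                                   sigma2_fixed = 0))
  eg <- egger_test(fit)
  expect_equal(eg$intercept, 0, tolerance = 1e-8)
  f2 <- suppressWarnings(reml_fit(c(0.1, 0.2), diag(0.1, 2), matrix(1, 2),
                                  list(obs = factor(1:2)),
                                  sigma2_fixed = 0))
  expect_error(egger_test(f2), "at least 3")
})
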