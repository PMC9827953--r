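test_that("truncated means pass positives through and replace zeros by 1/(2nD)", {
  expect_equal(truncated_mean(3.2, 5, 1), 3.2)
  expect_equal(truncated_mean(0, 10, 1), 0.05)
  expect_equal(truncated_mean(0, 4, 25), 0.005)
  expect_error(truncated_mean(1, 0, 1), "n")
  expect_error(truncated_mean(1, 5, 0), "D")
  expect_error(truncated_mean(-1, 5, 1), "mean")
})

test_that("delta-corrected LRR and its variance match hand arithmetic", {
  expect_equal(lrr_delta(5, 1, 10, 5, 1, 10), 0)
  expect_equal(lrr_delta(2, 1, 5, 4, 2, 5), log(0.5) + 0.5 * (1/20 - 4/80))
  expect_equal(lrr_delta(2, 1, 5, 4, 2, 5), -0.693147, tolerance = 1e-6)
  expect_equal(var_lrr_delta(4, 2, 5, 4, 2, 5), 0.1025)
  expect_equal(var_lrr_delta(3, 0, 5, 7, 0, 9), 0)
  expect_error(lrr_delta(0, 1, 5, 4, 2, 5), "truncated_mean")
})

test_that("LRR is antisymmetric and the variance symmetric under arm swap", {
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    sa <- runif(1, 0.1, 3); sb <- runif(1, 0.1, 3)
    na <- sample(2:20, 1); nb <- sample(2:20, 1)
    expect_equal(lrr_delta(a, sa, na, b, sb, nb),
                 -lrr_delta(b, sb, nb, a, sa, na))
    v <- var_lrr_delta(a, sa, na, b, sb, nb)
    expect_equal(v, var_lrr_delta(b, sb, nb, a, sa, na))
    expect_gt(v, sa^2 / (na * a^2) + sb^2 / (nb * b^2) - 1e-15)
    expect_gt(v, 0)
  }
})

test_that("effect-size formulas agree with literal transcriptions on random inputs", {
  set.seed(99)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    m <- ifelse(runif(1) < 0.25, 0, runif(1, 0.01, 50))
    n1 <- sample(1:30, 1); D <- runif(1, 0.5, 40)
    tm <- truncated_mean(m, n1, D)
    expect_identical(tm, oracle_truncated_mean(m, n1, D))

    At <- runif(1, 0.01, 20); Ac <- runif(1, 0.01, 20)
    St <- runif(1, 0, 5); Sc <- runif(1, 0, 5)
    nt <- sample(1:25, 1); nc <- sample(1:25, 1)
    expect_equal(lrr_delta(At, St, nt, Ac, Sc, nc),
                 oracle_lrr_delta(At, St, nt, Ac, Sc, nc),
                 tolerance = 1e-12)
    expect_equal(var_lrr_delta(At, St, nt, Ac, Sc, nc),
                 oracle_var_lrr_delta(At, St, nt, Ac, Sc, nc),
                 tolerance = 1e-12)
    if (St > 0)
      expect_identical(geary_pass(At, St, nt), oracle_geary(At, St, nt))
  }
})

test_that("poisson imputation fills missing and zero SDs with sqrt of the truncated mean", {
  x <- make_comparisons()
  x$sd_ctrl[5] <- 0  # reported zero SD is treated as missing
  out <- impute_sd(x, "poisson")
  expect_equal(out$sd_treat[3], sqrt(1 / (2 * 10 * 1)))  # zero mean arm
  expect_equal(out$sd_ctrl[4], sqrt(1.5))
  expect_equal(out$sd_ctrl[5], sqrt(3))
  expect_true(out$sd_imputed_treat[3] && out$sd_imputed_ctrl[4])
  expect_false(out$sd_imputed_treat[1])
  expect_equal(out$sd_treat[1], 1)  # reported SDs untouched
})

test_that("bracken imputation scales by the pooled SD-to-mean ratio of complete cases", {
  x <- make_comparisons()[1:2, ]
  x$study_id <- c("S01_st1", "S01_st9")
  x$species_id <- c("sp1", "sp9")
  # complete arms: (2,1), (4,2), (3.5,1.5), (4,2); one missing arm At=10
  x$mean_treat[2] <- 10
  x$sd_treat[2] <- NA
  out <- impute_sd(x, "bracken1992")
  ratio <- (1 + 2 + 2) / (2 + 4 + 4)
  expect_equal(out$sd_treat[2], 10 * ratio)

  x$sd_treat <- NA; x$sd_ctrl <- NA
  expect_error(impute_sd(x, "bracken1992"), "complete cases")
})

test_that("hot-deck imputation is seed-reproducible and degenerates to copying a single donor", {
  x <- make_comparisons()
  x$sd_treat[2:5] <- NA
  x$sd_ctrl <- NA  # single complete arm: treat of c1 (SD = 1)
  out <- impute_sd(x, "hotdeck_nn", seed = 7, n_imputations = 5)
  expect_length(out, 5)
  for (m in out) {
    expect_true(all(m$sd_treat == 1) && all(m$sd_ctrl == 1))
  }
  a <- impute_sd(make_comparisons(), "hotdeck_nn", seed = 3,
                 n_imputations = 4)
  b <- impute_sd(make_comparisons(), "hotdeck_nn", seed = 3,
                 n_imputations = 4)
  expect_identical(a, b)
  # donors are actual observed SDs from the k nearest complete arms
  full <- impute_sd(make_comparisons(), "hotdeck_nn", seed = 1,
                    n_imputations = 10, k = 2)
  donor_pool <- c(1, 1.5, 0.8, 2, 2, 2, 1, 1.2)  # all complete arms
  for (m in full) {
    expect_true(all(m$sd_treat %in% donor_pool))
    expect_true(all(m$sd_ctrl %in% donor_pool))
  }
})

test_that("the assembled vcov has shared-control covariances and is PSD", {
  x <- make_comparisons()
  rec <- impute_sd(x, "poisson")
  es <- build_effect_size_set(rec)
  V <- es$vcov
  expect_true(isSymmetric(V))
  expect_equal(diag(V), es$table$variance, ignore_attr = TRUE)
  # c1 and c2 share the control (A=4, SD=2, n=5) -> cov = 4/(5*16) = 0.05
  expect_equal(V["c1", "c2"], 0.05)
  # records from different studies/species are independent
  expect_equal(V["c1", "c3"], 0)
  expect_equal(V["c4", "c5"], 0)
  expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)

  # PSD across random assemblies with many shared controls
  for (s in 1:5) {
    sim <- simulate_dataset(simulation_config(n_sources = 4L), seed = s)
    esr <- build_effect_size_set(impute_sd(sim$comparisons, "poisson"))
    expect_gt(min(eigen(esr$vcov, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
    expect_true(all(is.finite(esr$table$value)))
    expect_true(all(esr$table$variance > 0))
  }
})

test_that("geary screening is scale-invariant and only removes records", {
  expect_true(geary_pass(10, 1, 4))
  expect_false(geary_pass(0.05, 0.2236, 10))
  for (k in c(0.1, 1, 7, 100)) {
    expect_identical(geary_pass(10 * k, 1 * k, 4), geary_pass(10, 1, 4))
    expect_identical(geary_pass(0.05 * k, 0.2236 * k, 10),
                     geary_pass(0.05, 0.2236, 10))
  }
  expect_error(geary_pass(1, 0, 5), "sd")

  sim <- simulate_dataset(taxon_preset("amphibian", scale = 0.5), seed = 2)
  rec <- impute_sd(sim$comparisons, "poisson")
  kept <- geary_subset(rec)
  expect_lte(nrow(kept), nrow(rec))
  frac <- nrow(kept) / nrow(rec)
  expect_gt(frac, 0)  # mixture retains a nontrivial subset
  expect_lt(frac, 1)
})

test_that("percentage change transform is exact and strictly increasing", {
  expect_equal(percentage_change(0), 0)
  expect_equal(round(percentage_change(-0.74)), -52)
  expect_equal(round(percentage_change(0.18)), 20)
  xs <- seq(-2, 2, length.out = 101)
  expect_true(all(diff(percentage_change(xs)) > 0))
  for (v in c(0.2, 1, 3.7)) {
    expect_equal(percentage_change(log(v)), (v - 1) * 100)
  }
})
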