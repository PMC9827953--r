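#' Configuration for the hierarchical abundance-comparison simulator
#'
#' Defines the study conditions the generator emulates: a nested
#' source -> study -> species hierarchy with clade taxonomy, distances in
#' `[0, 4500]` m with one shared far control per study-species, a known
#' fixed-effect surface on the standard moderator coding, five Gaussian
#' variance components, lognormal control abundances, within-site sampling
#' noise on a coefficient-of-variation scale, a target fraction of zero
#' means and a fraction of withheld SDs.
#'
#' @param taxon_group taxon name; sets the moderator coding.
#' @param spec `moderator_spec` of the true fixed-effect surface.
#' @param true_beta named coefficients on the design coding of `spec`.
#' @param true_sigma2 named five-vector of variance components
#'   (observation, clade, species, source, study).
#' @param n_sources number of data sources.
#' @param studies_per_source integer range `c(min, max)`.
#' @param species_per_study integer range `c(min, max)`.
#' @param n_clades number of orders/families in the species pool.
#' @param distances_per_study integer range for the number of disturbed
#'   distances per study-species (the shared control sits beyond them).
#' @param control_mean_scale `c(meanlog, sdlog)` of the lognormal control
#'   abundance.
#' @param within_site_n integer range for per-site replicate counts.
#' @param cv_shape,cv_mean gamma-distributed coefficient of variation of
#'   site abundance (shape and mean); `cv_mean = NULL` calibrates the mean
#'   CV so the expected fraction of zero observed means matches
#'   `zero_rate_target`.
#' @param zero_rate_target expected fraction of zero observed means.
#' @param sd_missing_rate fraction of arms with SD withheld.
#' @param bm_log10_range `log10` body-mass range (g) sampled uniformly.
#' @param diet_zero_prob,diet_beta diet sampler: probability of a strictly
#'   non-carnivorous species, else a scaled Beta; `NULL` diet for taxa
#'   without the trait.
#' @param open_prob probability a study is in open habitat.
#' @param noise logical; `FALSE` switches off within-site sampling noise
#'   (observed means equal true means and SDs are 0), for exactness tests.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(taxon_group = "mammal",
                              spec = moderator_spec(c("distance",
                                                      "distance2")),
                              true_beta = c(intercept = 0.2,
                                            distance = -0.3,
                                            distance2 = 0.08),
                              true_sigma2 = c(observation = 0.15,
                                              clade = 0.05, species = 0.15,
                                              source = 0.1, study = 0.05),
                              n_sources = 15L,
                              studies_per_source = c(1L, 3L),
                              species_per_study = c(1L, 4L),
                              n_clades = 8L,
                              distances_per_study = c(2L, 5L),
                              control_mean_scale = c(1.5, 1.0),
                              within_site_n = c(3L, 12L),
                              cv_shape = 4, cv_mean = NULL,
                              zero_rate_target = 0.2,
                              sd_missing_rate = 0.4,
                              bm_log10_range = c(0.6, 5.6),
                              diet_zero_prob = 0.65, diet_beta = c(1, 3),
                              open_prob = 0.31,
                              noise = TRUE) {
  taxon_group <- match.arg(taxon_group, .taxon_groups)
  stopifnot(length(true_sigma2) == 5L, all(true_sigma2 >= 0),
            n_sources >= 1L, distances_per_study[1] >= 1L,
            zero_rate_target >= 0, zero_rate_target < 1,
            sd_missing_rate >= 0, sd_missing_rate <= 1)
  expected <- unlist(.term_column_map(spec, taxon_group), use.names = FALSE)
  if (!identical(names(true_beta), expected))
    stop("true_beta names must be: ", paste(expected, collapse = ", "))
  names(true_sigma2) <- c("observation", "clade", "species", "source",
                          "study")
  cfg <- list(taxon_group = taxon_group, spec = spec, true_beta = true_beta,
              true_sigma2 = true_sigma2, n_sources = n_sources,
              studies_per_source = studies_per_source,
              species_per_study = species_per_study, n_clades = n_clades,
              distances_per_study = distances_per_study,
              control_mean_scale = control_mean_scale,
              within_site_n = within_site_n, cv_shape = cv_shape,
              cv_mean = cv_mean, zero_rate_target = zero_rate_target,
              sd_missing_rate = sd_missing_rate,
              bm_log10_range = bm_log10_range,
              diet_zero_prob = diet_zero_prob, diet_beta = diet_beta,
              open_prob = open_prob, noise = noise)
  if (is.null(cfg$cv_mean)) cfg$cv_mean <- .calibrate_cv(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

# Solve for the mean CV such that the expected zero fraction over the
# replicate-count and CV distributions matches the target:
# P(zero) = Phi(-sqrt(n) / CV) for an observed mean that is a Normal
# draw around the true mean with SD = CV * mean / sqrt(n), censored at 0.
.calibrate_cv <- function(cfg) {
  if (cfg$zero_rate_target <= 0 || !cfg$noise) return(0.75)
  ns <- seq(cfg$within_site_n[1], cfg$within_site_n[2])
  qs <- stats::qgamma(seq(0.01, 0.99, by = 0.02), shape = cfg$cv_shape,
                      rate = cfg$cv_shape)  # unit-mean gamma quantiles
  zero_rate <- function(cv_mean) {
    cvs <- qs * cv_mean
    mean(outer(sqrt(ns), cvs, function(sn, cv)
      stats::pnorm(-sn / cv))) - cfg$zero_rate_target
  }
  stats::uniroot(zero_rate, c(0.05, 50), tol = 1e-6)$root
}

#' Simulate a hierarchical infrastructure-abundance dataset with known truth
#'
#' Draws the source/study/species hierarchy, distances and traits from the
#' configuration; computes each record's true log response ratio as
#' `design-row x true_beta` plus the five Gaussian random effects; draws
#' lognormal control means and sets the treatment's true mean to
#' `control x exp(true LRR)`; then observes each arm as a Normal draw
#' around its true mean with SD `CV x mean / sqrt(n)`, censored at zero
#' (which induces zero means), with sample SDs drawn from the scaled
#' chi-square law and withheld at the configured rate. Fully reproducible
#' from the seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return object of class `simulated_dataset`: list with `comparisons`
#'   (the standard record schema), and `truth` (`true_beta`, `true_sigma2`,
#'   per-record `true_lrr`, and the per-record random-effect draws).
#' @export
simulate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  cfg <- config
  clades <- paste0("clade", seq_len(cfg$n_clades))
  rows <- list()
  species_clade <- new.env()
  species_bm <- new.env()
  species_diet <- new.env()
  has_diet <- cfg$taxon_group %in% c("mammal", "bird")
  rint <- function(rng) sample(seq(rng[1], rng[2]), 1L)

  for (so in seq_len(cfg$n_sources)) {
    source_id <- sprintf("S%02d", so)
    for (st in seq_len(rint(cfg$studies_per_source))) {
      study_id <- sprintf("%s_st%d", source_id, st)
      habitat <- if (stats::runif(1) < cfg$open_prob) "open" else "closed"
      infra <- sample(.infra_levels_for(cfg$taxon_group), 1L)
      n_species <- rint(cfg$species_per_study)
      # species pool is global so a species can recur across studies
      sp_ids <- paste0("sp", sample.int(cfg$n_sources * 4L, n_species))
      for (sp in sp_ids) {
        if (is.null(species_clade[[sp]])) {
          species_clade[[sp]] <- sample(clades, 1L)
          species_bm[[sp]] <- 10^stats::runif(1, cfg$bm_log10_range[1],
                                              cfg$bm_log10_range[2])
          species_diet[[sp]] <- if (!has_diet) NA_real_
            else if (stats::runif(1) < cfg$diet_zero_prob) 0
            else 100 * stats::rbeta(1, cfg$diet_beta[1], cfg$diet_beta[2])
        }
        n_dist <- rint(cfg$distances_per_study)
        dists <- sort(round(10^stats::runif(n_dist, 0, log10(4500))))
        for (d in dists) {
          rows[[length(rows) + 1L]] <- data.frame(
            source_id = source_id, study_id = study_id, species_id = sp,
            taxon_group = cfg$taxon_group, clade = species_clade[[sp]],
            distance_m = d, infra_type = infra, habitat = habitat,
            body_mass_g = species_bm[[sp]], diet_pct = species_diet[[sp]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  x <- do.call(rbind, rows)
  n <- nrow(x)
  x$comparison_id <- sprintf("c%04d", seq_len(n))

  # five random-effect draws on the grouping structure
  groups <- random_effects_groups(x)
  u <- numeric(n)
  re_draws <- list()
  for (k in seq_along(groups)) {
    f <- groups[[k]]
    draws <- stats::rnorm(nlevels(f), 0, sqrt(cfg$true_sigma2[k]))
    re_draws[[names(groups)[k]]] <- draws
    u <- u + draws[as.integer(f)]
  }
  X <- build_design(x, cfg$spec, cfg$taxon_group)
  true_lrr <- as.numeric(X %*% cfg$true_beta) + u

  # one control observation per study x species, shared across distances
  grp <- interaction(x$study_id, x$species_id, drop = TRUE)
  g <- nlevels(grp)
  gi <- as.integer(grp)
  ctrl_true_g <- stats::rlnorm(g, cfg$control_mean_scale[1],
                               cfg$control_mean_scale[2])
  n_ctrl_g <- vapply(seq_len(g), function(i) rint(cfg$within_site_n),
                     numeric(1))
  ctrl_true <- ctrl_true_g[gi]
  treat_true <- ctrl_true * exp(true_lrr)
  x$n_treat <- vapply(seq_len(n), function(i) rint(cfg$within_site_n),
                      numeric(1))
  x$n_ctrl <- n_ctrl_g[gi]
  x$scale_D <- 1

  if (cfg$noise) {
    cv_t <- stats::rgamma(n, shape = cfg$cv_shape,
                          rate = cfg$cv_shape) * cfg$cv_mean
    cv_c_g <- stats::rgamma(g, shape = cfg$cv_shape,
                            rate = cfg$cv_shape) * cfg$cv_mean
    sd_t_true <- cv_t * treat_true
    sd_c_true_g <- cv_c_g * ctrl_true_g
    mean_ctrl_g <- pmax(stats::rnorm(g, ctrl_true_g,
                                     sd_c_true_g / sqrt(n_ctrl_g)), 0)
    sd_ctrl_g <- sd_c_true_g *
      sqrt(stats::rchisq(g, n_ctrl_g - 1) / pmax(n_ctrl_g - 1, 1))
    sd_ctrl_g[stats::runif(g) < cfg$sd_missing_rate] <- NA_real_
    x$mean_treat <- pmax(stats::rnorm(n, treat_true,
                                      sd_t_true / sqrt(x$n_treat)), 0)
    x$mean_ctrl <- mean_ctrl_g[gi]
    x$sd_treat <- sd_t_true *
      sqrt(stats::rchisq(n, x$n_treat - 1) / pmax(x$n_treat - 1, 1))
    x$sd_ctrl <- sd_ctrl_g[gi]
    x$sd_treat[stats::runif(n) < cfg$sd_missing_rate] <- NA_real_
  } else {
    x$mean_treat <- treat_true
    x$mean_ctrl <- ctrl_true
    x$sd_treat <- 0
    x$sd_ctrl <- 0
  }
  x$quality_a <- as.numeric(stats::runif(n) > 0.05)
  x$quality_b <- as.numeric(stats::runif(n) > 0.6)
  x <- x[, .comparison_columns]
  structure(list(
    comparisons = x,
    truth = list(true_beta = cfg$true_beta, true_sigma2 = cfg$true_sigma2,
                 true_lrr = true_lrr, random_effects = re_draws,
                 spec = cfg$spec, taxon_group = cfg$taxon_group)
  ), class = "simulated_dataset")
}

#' Taxon-scale presets mirroring a global infrastructure database
#'
#' Configurations whose record counts approximate the published database
#' (mammals 863, birds 2471, reptiles 362, amphibians 216 comparisons),
#' with the bundled reference coefficients as the true fixed-effect
#' surface. `scale` shrinks every stratum proportionally for quick runs.
#'
#' @param taxon_group taxon name.
#' @param scale multiplier on the number of sources (default 1 = full
#'   scale).
#' @return a [simulation_config()].
#' @export
taxon_preset <- function(taxon_group, scale = 1) {
  taxon_group <- match.arg(taxon_group, .taxon_groups)
  ref <- reference_models()[[taxon_group]]
  beta <- stats::setNames(ref$beta$estimate, ref$beta$term)
  base <- switch(taxon_group,
    mammal = list(n_sources = 45L, zero = 0.20, sd_miss = 0.22,
                  n_clades = 17L, bm = c(0.56, 6.59)),
    bird = list(n_sources = 120L, zero = 0.19, sd_miss = 0.63,
                n_clades = 22L, bm = c(0.63, 4.04)),
    reptile = list(n_sources = 19L, zero = 0.20, sd_miss = 0.26,
                   n_clades = 22L, bm = c(-0.15, 4.54)),
    amphibian = list(n_sources = 11L, zero = 0.26, sd_miss = 0.54,
                     n_clades = 16L, bm = c(-2.85, 2.49))
  )
  simulation_config(
    taxon_group = taxon_group, spec = ref$spec, true_beta = beta,
    true_sigma2 = c(observation = 0.4, clade = 0.1, species = 0.8,
                    source = 0.25, study = 0.1),
    n_sources = max(2L, as.integer(round(base$n_sources * scale))),
    n_clades = base$n_clades, zero_rate_target = base$zero,
    sd_missing_rate = base$sd_miss, bm_log10_range = base$bm,
    open_prob = if (taxon_group == "amphibian") 0 else 0.31
  )
}

#' Parameter-recovery experiment over the full pipeline
#'
#' Repeatedly simulates a dataset, imputes SDs, builds effect sizes with
#' the shared-control covariance, and refits the true moderator structure
#' by REML; reports per-coefficient bias, RMSE and 95% CI coverage, and
#' per-component variance bias.
#'
#' @param config a [simulation_config()].
#' @param n_reps number of replicates.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param impute_method SD imputation method (deterministic methods only).
#' @param control optimizer settings (fewer starts speed up large runs).
#' @return list with `estimates` (tidy per-rep data.frame of coefficient
#'   estimates, CIs and truth), `sigma2` (per-rep component estimates),
#'   and `summary` (bias, rmse, coverage per coefficient).
#' @export
recovery_experiment <- function(config, n_reps = 50L, seed = 1L,
                                impute_method = "poisson",
                                control = reml_control(n_starts = 2L)) {
  est_rows <- list()
  sig_rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_dataset(config, seed = seed + r)
    rec <- impute_sd(sim$comparisons, method = impute_method)
    es <- build_effect_size_set(rec)
    fit <- tryCatch(suppressWarnings(
      fit_meta_regression(es, config$spec, config$taxon_group,
                          control = control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    est_rows[[length(est_rows) + 1L]] <- data.frame(
      rep = r, term = fit$beta$term, estimate = fit$beta$estimate,
      ci_lb = fit$beta$ci_lb, ci_ub = fit$beta$ci_ub,
      truth = unname(config$true_beta), converged = fit$converged
    )
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      rep = r, component = names(fit$sigma2), estimate = unname(fit$sigma2),
      truth = unname(config$true_sigma2)
    )
  }
  estimates <- do.call(rbind, est_rows)
  sigma2 <- do.call(rbind, sig_rows)
  summ <- do.call(rbind, lapply(split(estimates, estimates$term),
    function(d) data.frame(
      term = d$term[1],
      bias = mean(d$estimate - d$truth),
      rmse = sqrt(mean((d$estimate - d$truth)^2)),
      coverage = mean(d$ci_lb <= d$truth & d$truth <= d$ci_ub)
    )))
  rownames(summ) <- NULL
  list(estimates = estimates, sigma2 = sigma2, summary = summ)
}
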