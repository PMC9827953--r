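#' Run the full meta-analytic workflow and write a report bundle
#'
#' End-to-end driver over the package's stages in the standard order:
#' SD imputation -> effect sizes with shared-control covariance -> pooled
#' (intercept-only) multilevel model -> moderator meta-regressions with
#' AICc selection -> infrastructure-effect-zone table -> robustness
#' appendix (Geary subset refit, alternative imputations, quality subsets,
#' Egger test). Every table is serialized under `out_dir` and a plain-text
#' log records seeds and record counts at each filter.
#'
#' @param records comparison data.frame (e.g. from [read_comparisons()] or
#'   [simulate_dataset()]).
#' @param taxon_group taxon of the records.
#' @param out_dir output directory (created if needed).
#' @param candidates candidate moderator specs for selection; default: the
#'   linear/quadratic distance ladder plus the taxon's reference spec.
#' @param impute_method default SD imputation method.
#' @param seed master seed for stochastic stages.
#' @param robustness character vector of toggles among
#'   `c("geary", "imputation", "quality", "egger")`.
#' @param bm_values,diet_levels grids forwarded to [iez_table()].
#' @param control optimizer settings.
#' @return invisibly, a list with the fitted objects and file paths.
#' @export
run_pipeline <- function(records, taxon_group, out_dir,
                         candidates = NULL,
                         impute_method = "poisson", seed = 1L,
                         robustness = c("geary", "egger"),
                         bm_values = NULL, diet_levels = NULL,
                         control = reml_control(n_starts = 2L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("run_pipeline: taxon=%s seed=%d records=%d", taxon_group, seed,
       nrow(records))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  rec <- stage("impute", impute_sd(records, method = impute_method,
                                   seed = seed))
  es <- stage("effect_sizes", build_effect_size_set(rec))
  logf("effect sizes: %d (zero means treat/ctrl: %d/%d; imputed SDs: %d)",
       nrow(es$table), sum(es$table$used_truncation_treat),
       sum(es$table$used_truncation_ctrl),
       sum(es$table$sd_imputed_treat | es$table$sd_imputed_ctrl))
  write_effect_size_set(es, file.path(out_dir, "effect_sizes.csv"),
                        file.path(out_dir, "effect_sizes_vcov.csv"))

  pooled <- stage("pooled", suppressWarnings(
    fit_meta_regression(es, moderator_spec(), taxon_group,
                        control = control)))
  logf("pooled LRR = %.4f [%.4f, %.4f]", pooled$beta$estimate[1],
       pooled$beta$ci_lb[1], pooled$beta$ci_ub[1])

  if (is.null(candidates)) {
    ladder <- list(moderator_spec(), moderator_spec("distance"),
                   moderator_spec(c("distance", "distance2")))
    ref <- reference_specs()[[taxon_group]]
    candidates <- c(ladder, list(ref))
  }
  sel <- stage("selection", suppressWarnings(
    select_model(es, candidates, taxon_group, control = control)))
  utils::write.csv(sel$table, file.path(out_dir, "selection.csv"),
                   row.names = FALSE)
  best <- sel$best_fit
  logf("selected spec: %s (AICc=%.2f)", format(sel$best_spec), best$aicc)
  utils::write.csv(best$beta, file.path(out_dir, "best_model.csv"),
                   row.names = FALSE)
  summary_json <- list(
    taxon_group = taxon_group, spec = format(sel$best_spec),
    coefficients = best$beta, sigma2 = as.list(best$sigma2),
    qe = best$qe, aicc = best$aicc, r2_marginal = best$r2_marginal,
    r2_conditional = best$r2_conditional,
    pooled = list(estimate = pooled$beta$estimate[1],
                  ci_lb = pooled$beta$ci_lb[1],
                  ci_ub = pooled$beta$ci_ub[1])
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (is.null(bm_values) && any(grepl("bm", sel$best_spec$terms))) {
    q <- stats::quantile(log10(es$table$body_mass_g), c(0.1, 0.5, 0.9))
    bm_values <- stats::setNames(10^q, c("small", "medium", "large"))
  }
  iez <- stage("iez", iez_table(
    best, bm_values = bm_values,
    diet_levels = diet_levels %||% c(non_carnivore = 0, carnivore = 80)))
  utils::write.csv(iez, file.path(out_dir, "iez_table.csv"),
                   row.names = FALSE)

  rob <- list()
  if ("geary" %in% robustness) {
    gs <- stage("geary", geary_subset(rec))
    logf("geary subset: %d of %d records retained", nrow(gs), nrow(rec))
    if (nrow(gs) >= 10L) {
      es_g <- build_effect_size_set(gs)
      rob$geary <- suppressWarnings(
        fit_meta_regression(es_g, moderator_spec(), taxon_group,
                            control = control))
      logf("geary pooled LRR = %.4f", rob$geary$beta$estimate[1])
    }
  }
  if ("imputation" %in% robustness) {
    for (m in c("bracken1992")) {
      rec_m <- impute_sd(records, method = m)
      es_m <- build_effect_size_set(rec_m)
      rob[[m]] <- suppressWarnings(
        fit_meta_regression(es_m, moderator_spec(), taxon_group,
                            control = control))
      logf("%s pooled LRR = %.4f", m, rob[[m]]$beta$estimate[1])
    }
  }
  if ("quality" %in% robustness) {
    for (flags in list(c(TRUE, FALSE), c(FALSE, TRUE))) {
      qs <- quality_subset(rec, flags[1], flags[2])
      nm <- paste0("quality_", if (flags[1]) "a" else "b")
      logf("%s subset: %d records", nm, nrow(qs))
      if (nrow(qs) >= 10L) {
        rob[[nm]] <- suppressWarnings(
          fit_meta_regression(build_effect_size_set(qs), moderator_spec(),
                              taxon_group, control = control))
      }
    }
  }
  if ("egger" %in% robustness) {
    rob$egger <- egger_test(pooled)
    logf("egger intercept = %.4f (p = %.3g)", rob$egger$intercept,
         rob$egger$p)
  }
  rob_tab <- data.frame(
    check = names(rob),
    value = vapply(rob, function(r) {
      if (inherits(r, "meta_fit")) r$beta$estimate[1] else r$intercept
    }, numeric(1)),
    p = vapply(rob, function(r) {
      if (inherits(r, "meta_fit")) r$beta$pval[1] else r$p
    }, numeric(1))
  )
  utils::write.csv(rob_tab, file.path(out_dir, "robustness.csv"),
                   row.names = FALSE)
  logf("done")

  invisible(list(effect_sizes = es, pooled = pooled, selection = sel,
                 best = best, iez = iez, robustness = rob,
                 out_dir = out_dir))
}
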