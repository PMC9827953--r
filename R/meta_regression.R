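#' Fit a moderator meta-regression on an effect-size set
#'
#' Convenience wrapper tying the modules together: builds the design matrix
#' from a [moderator_spec()], the five-component grouping structure from
#' the record hierarchy, and fits by [reml_fit()] using the set's full
#' sampling variance-covariance matrix.
#'
#' @param es_set an `effect_size_set` (see [build_effect_size_set()]).
#' @param spec a `moderator_spec`; default intercept-only (the pooled
#'   model).
#' @param taxon_group taxon the model is for.
#' @param groups optional named list of grouping factors overriding the
#'   default five-component structure.
#' @param control optimizer settings, see [reml_control()].
#' @return a `meta_fit` carrying `spec`, `taxon_group` and the term-column
#'   map needed for term-level omnibus tests ([qm_term()]) and prediction.
#' @export
fit_meta_regression <- function(es_set, spec = moderator_spec(),
                                taxon_group, groups = NULL,
                                control = reml_control()) {
  stopifnot(inherits(es_set, "effect_size_set"))
  tab <- es_set$table
  X <- build_design(tab, spec, taxon_group)
  if (is.null(groups)) groups <- random_effects_groups(tab)
  fit <- reml_fit(tab$value, es_set$vcov, X, groups, control = control)
  fit$spec <- spec
  fit$taxon_group <- taxon_group
  fit$term_cols <- .term_column_map(spec, taxon_group)
  fit$es_set <- es_set
  fit
}

# term name -> design column names, for a given spec/taxon
.term_column_map <- function(spec, taxon_group) {
  lab <- function(tm) {
    nm <- switch(tm,
      intercept = "intercept", distance = "distance",
      distance2 = "distance2", diet = "diet", bm = "bm",
      habitat = "habitat_open",
      infratype = paste0("infra_", .infra_levels_for(taxon_group)[-1]),
      {
        parts <- .main_of(tm)
        first <- switch(parts[1], distance = "distance",
                        distance2 = "distance2")
        paste0(first, ":", lab(parts[2]))
      })
    nm
  }
  stats::setNames(lapply(spec$terms, lab), spec$terms)
}

#' Term-level omnibus test with interaction dropping
#'
#' Tests a moderator term with a Wald chi-square ([q_m()]). When the term
#' is a main effect and the model contains interactions involving it, the
#' model is refit without those interactions and the main effect is tested
#' in the reduced model; interaction terms are tested directly in the full
#' model (jointly with their higher-order distance companions, e.g.
#' `distance:bm` together with `distance2:bm`).
#'
#' @param fit a `meta_fit` from [fit_meta_regression()].
#' @param term term name from the model's spec.
#' @return list with `statistic`, `df`, `p` and `tested_coefs`.
#' @export
qm_term <- function(fit, term) {
  if (is.null(fit$spec)) stop("fit does not carry a moderator spec")
  if (!(term %in% fit$spec$terms)) stop("term not in model: ", term)
  if (term == "intercept") stop("Q_M excludes the intercept")
  parts <- .main_of(term)
  if (length(parts) == 1L && !(term %in% c("distance", "distance2"))) {
    inter <- grep(paste0(":", term, "$"), fit$spec$terms, value = TRUE)
    if (length(inter) > 0L) {
      reduced <- moderator_spec(setdiff(fit$spec$terms, inter))
      rfit <- fit_meta_regression(fit$es_set, reduced, fit$taxon_group,
                                  control = fit$control)
      res <- q_m(rfit, unlist(rfit$term_cols[term]))
      res$tested_coefs <- unlist(rfit$term_cols[term])
      res$refit_without <- inter
      return(res)
    }
  }
  # distance main effects: test linear and quadratic jointly; interactions:
  # test together with the matching distance2 interaction when present
  tested <- term
  if (term == "distance" && "distance2" %in% fit$spec$terms)
    tested <- c("distance", "distance2")
  if (length(parts) == 2L && parts[1] == "distance") {
    companion <- paste0("distance2:", parts[2])
    if (companion %in% fit$spec$terms) tested <- c(tested, companion)
  }
  coefs <- unlist(fit$term_cols[tested])
  res <- q_m(fit, coefs)
  res$tested_coefs <- coefs
  res
}

#' Pool per-imputation fits from multiple imputation
#'
#' For hot-deck imputation the model is refit on each completed data set;
#' results are summarized as the median and the 2.5/97.5 percentiles of
#' the per-imputation coefficient estimates.
#'
#' @param fits list of `meta_fit` objects (one per completed data set).
#' @return data.frame with `term`, `median`, `ci_lb`, `ci_ub` across
#'   imputations.
#' @export
pool_imputations <- function(fits) {
  est <- sapply(fits, function(f) f$beta$estimate)
  if (is.null(dim(est))) est <- matrix(est, nrow = 1)
  data.frame(
    term = fits[[1]]$beta$term,
    median = apply(est, 1, stats::median),
    ci_lb = apply(est, 1, stats::quantile, 0.025),
    ci_ub = apply(est, 1, stats::quantile, 0.975),
    row.names = NULL
  )
}

#' Select the most parsimonious moderator structure by AICc
#'
#' Fits every candidate spec by REML with the same random-effects
#' structure and data, ranks them by AICc computed from the full
#' likelihood, and selects the minimum; ties (within 1e-6) are broken
#' toward fewer parameters. Candidates that fail to converge are excluded
#' with a warning.
#'
#' @param es_set an `effect_size_set`.
#' @param candidates list of `moderator_spec` objects (see
#'   [enumerate_candidate_specs()]).
#' @param taxon_group taxon name.
#' @param groups optional grouping override.
#' @param control optimizer settings.
#' @return object of class `selection_result`: list with `table`
#'   (spec label, k, aicc, delta_aicc, loglik_full, converged; sorted by
#'   AICc), `best_spec` and `best_fit`.
#' @export
select_model <- function(es_set, candidates, taxon_group, groups = NULL,
                         control = reml_control()) {
  if (length(candidates) == 0L) stop("no candidate specifications")
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    f <- tryCatch(suppressWarnings(
      fit_meta_regression(es_set, candidates[[i]], taxon_group,
                          groups = groups, control = control)),
      error = function(e) NULL)
    conv <- !is.null(f) && isTRUE(f$converged) && is.finite(f$aicc)
    if (!is.null(f) && !conv)
      warning("candidate '", format(candidates[[i]]),
              "' excluded (non-convergence)")
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      spec = format(candidates[[i]]),
      k = if (is.null(f)) NA_integer_ else f$n_params,
      aicc = if (conv) f$aicc else NA_real_,
      loglik_full = if (is.null(f)) NA_real_ else f$loglik_full,
      converged = conv
    )
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$aicc))) stop("all candidate models failed")
  ord <- order(tab$aicc, tab$k)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  candidates <- candidates[ord]
  # tie-break toward fewer parameters within 1e-6
  ok <- which(!is.na(tab$aicc))
  best_i <- ok[1]
  ties <- ok[tab$aicc[ok] <= tab$aicc[best_i] + 1e-6]
  best_i <- ties[which.min(tab$k[ties])]
  tab$delta_aicc <- tab$aicc - tab$aicc[ok[1]]
  rownames(tab) <- NULL
  structure(list(table = tab, best_spec = candidates[[best_i]],
                 best_fit = fits[[best_i]]), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("AICc model selection over", nrow(x$table), "candidates\n")
  print(utils::head(x$table, 10), row.names = FALSE)
  cat("best:", format(x$best_spec), "\n")
  invisible(x)
}
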