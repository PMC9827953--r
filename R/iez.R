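#' Construct a meta-analytic model from externally supplied coefficients
#'
#' Builds a minimal model object usable by [predict_lrr()], [find_iez()]
#' and [iez_table()] from a coefficient vector, e.g. estimates printed in a
#' published synthesis. When only per-coefficient confidence intervals are
#' available the coefficient covariance is taken diagonal, which is an
#' approximation affecting prediction intervals (not point predictions).
#'
#' @param estimates named numeric vector; names must match the design
#'   column labels produced by [build_design()] for `spec`.
#' @param spec a `moderator_spec`.
#' @param taxon_group taxon name.
#' @param vb coefficient covariance matrix, or `NULL`.
#' @param se per-coefficient standard errors used to form a diagonal `vb`
#'   when `vb` is `NULL`.
#' @return object of class `meta_model`.
#' @export
meta_model <- function(estimates, spec, taxon_group, vb = NULL, se = NULL) {
  taxon_group <- match.arg(taxon_group, .taxon_groups)
  expected <- unlist(.term_column_map(spec, taxon_group), use.names = FALSE)
  if (!identical(names(estimates), expected))
    stop("coefficient names must be: ", paste(expected, collapse = ", "))
  p <- length(estimates)
  if (is.null(vb)) {
    vb <- diag(if (is.null(se)) rep(0, p) else se^2, nrow = p)
    dimnames(vb) <- list(names(estimates), names(estimates))
  }
  structure(list(
    beta = data.frame(term = names(estimates),
                      estimate = unname(estimates), row.names = NULL),
    vb = vb, spec = spec, taxon_group = taxon_group,
    term_cols = .term_column_map(spec, taxon_group)
  ), class = "meta_model")
}

.model_coefs <- function(model) {
  stats::setNames(model$beta$estimate, model$beta$term)
}

.design_row <- function(model, distance_m, diet_pct, body_mass_g, habitat,
                        infra_type) {
  rec <- data.frame(distance_m = distance_m,
                    diet_pct = diet_pct %||% NA_real_,
                    body_mass_g = body_mass_g %||% NA_real_,
                    habitat = habitat, infra_type = infra_type,
                    stringsAsFactors = FALSE)
  build_design(rec, model$spec, model$taxon_group)
}

#' Predict the log response ratio at given moderator values
#'
#' Evaluates the fitted fixed-effects surface at a distance and set of
#' moderators: `lrr = x' beta` with standard error from the coefficient
#' covariance and a Wald 95% interval.
#'
#' @param model a `meta_fit` (from [fit_meta_regression()]) or a
#'   [meta_model()].
#' @param distance_m distance to infrastructure in metres (vectorised).
#' @param diet_pct,body_mass_g,habitat,infra_type moderator values; only
#'   those used by the model's spec are required.
#' @return data.frame with `distance_m`, `lrr`, `se`, `ci_lb`, `ci_ub`.
#' @export
predict_lrr <- function(model, distance_m, diet_pct = NA_real_,
                        body_mass_g = NA_real_, habitat = "closed",
                        infra_type = "non_traffic") {
  if (!(habitat %in% .habitats)) stop("unknown habitat level: ", habitat)
  if (!(infra_type %in% .infra_levels_for(model$taxon_group)))
    stop("unknown infrastructure level for this taxon: ", infra_type)
  X <- .design_row(model, distance_m, diet_pct, body_mass_g, habitat,
                   infra_type)
  b <- .model_coefs(model)
  lrr <- as.numeric(X %*% b)
  se <- sqrt(pmax(rowSums((X %*% model$vb) * X), 0))
  data.frame(distance_m = distance_m, lrr = lrr, se = se,
             ci_lb = lrr - 1.96 * se, ci_ub = lrr + 1.96 * se)
}

# Exact quadratic coefficients of the prediction in x = log10(distance):
# the fixed-effect surface is at most quadratic in x for any spec.
.lrr_poly <- function(model, diet_pct, body_mass_g, habitat, infra_type) {
  f <- function(d) predict_lrr(model, d, diet_pct, body_mass_g, habitat,
                               infra_type)$lrr
  f0 <- f(1); f1 <- f(10); f2 <- f(100)
  c2 <- (f2 - 2 * f1 + f0) / 2
  c1 <- f1 - f0 - c2
  c(a = f0, b = c1, c = c2)
}

.poly_roots_in <- function(coefs, x_max) {
  a <- coefs[["a"]]; b <- coefs[["b"]]; cc <- coefs[["c"]]
  roots <- if (abs(cc) > 1e-12) {
    disc <- b^2 - 4 * cc * a
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * cc)
  } else if (abs(b) > 1e-12) {
    -a / b
  } else numeric(0)
  sort(roots[roots > 1e-12 & roots <= x_max])
}

# first sign change of envelope g(x) relative to its value at x = 0,
# scanned on a dense grid; returns 0 when already opposite-signed at the
# origin, Inf when it never crosses within x_max
.first_envelope_cross <- function(g, ref_sign, x_max, n_grid = 2000L) {
  if (sign(g(0)) != ref_sign) return(0)
  xs <- seq(0, x_max, length.out = n_grid)
  v <- g(xs)
  idx <- which(sign(v[-1]) != sign(v[-length(v)]))[1]
  if (is.na(idx)) return(Inf)
  root <- stats::uniroot(g, c(xs[idx], xs[idx + 1L]),
                         tol = 1e-10)$root
  10^root
}

#' Infrastructure-effect zone from a fitted model
#'
#' The IEZ is the smallest distance (at least 1 m) at which the modelled
#' log response ratio crosses zero. Because the fixed-effect surface is at
#' most quadratic in `log10` distance, the crossing is found from the
#' closed-form roots. The estimate is undefined when the prediction never
#' crosses zero within `d_max` (e.g. a response that does not recover with
#' distance). Confidence bounds are the first crossings of the pointwise
#' 95% CI envelope; a bound is 0 when the envelope already brackets zero
#' at 1 m and `Inf` (unbounded) when the envelope never crosses.
#'
#' @param model a `meta_fit` or `meta_model`.
#' @param diet_pct,body_mass_g,habitat,infra_type moderator values (no
#'   distance: the IEZ is solved over distance).
#' @param d_max search horizon in metres (default 1e5, far beyond observed
#'   distances).
#' @return object of class `iez_estimate`: list with `iez_m`, `ci_low_m`,
#'   `ci_high_m`, `sign_near` (`"+"` or `"-"`: effect direction at 1 m)
#'   and `defined`.
#' @export
find_iez <- function(model, diet_pct = NA_real_, body_mass_g = NA_real_,
                     habitat = "closed", infra_type = "non_traffic",
                     d_max = 1e5) {
  if (d_max < 1) stop("d_max must be >= 1 m")
  x_max <- log10(d_max)
  coefs <- .lrr_poly(model, diet_pct, body_mass_g, habitat, infra_type)
  f <- function(x) coefs[["a"]] + coefs[["b"]] * x + coefs[["c"]] * x^2
  at1 <- coefs[["a"]]
  if (abs(at1) < 1e-12) {
    slope <- coefs[["b"]]
    sign_near <- if (slope >= 0) "+" else "-"
    return(structure(list(iez_m = 1, ci_low_m = 0, ci_high_m = NA_real_,
                          sign_near = sign_near, defined = TRUE),
                     class = "iez_estimate"))
  }
  sign_near <- if (at1 > 0) "+" else "-"
  roots <- .poly_roots_in(coefs, x_max)
  # keep only genuine sign changes (tangency does not end the effect zone)
  roots <- roots[vapply(roots, function(r) {
    eps <- min(0.05, (x_max - r) / 2, r / 2)
    sign(f(r - eps)) != sign(f(r + eps))
  }, logical(1))]
  if (length(roots) == 0L) {
    return(structure(list(iez_m = NA_real_, ci_low_m = NA_real_,
                          ci_high_m = NA_real_, sign_near = sign_near,
                          defined = FALSE), class = "iez_estimate"))
  }
  iez_m <- 10^roots[1]
  ref <- sign(at1)
  se_fun <- function(x) {
    predict_lrr(model, 10^x, diet_pct, body_mass_g, habitat, infra_type)$se
  }
  lo <- function(x) f(x) - 1.96 * se_fun(x)
  hi <- function(x) f(x) + 1.96 * se_fun(x)
  cross_lo <- .first_envelope_cross(lo, ref, x_max)
  cross_hi <- .first_envelope_cross(hi, ref, x_max)
  bounds <- sort(c(cross_lo, cross_hi))
  structure(list(iez_m = iez_m, ci_low_m = bounds[1], ci_high_m = bounds[2],
                 sign_near = sign_near, defined = TRUE),
            class = "iez_estimate")
}

#' @export
print.iez_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("IEZ: undefined (no zero crossing); effect at 1 m is",
        x$sign_near, "\n")
  } else {
    hi <- if (is.infinite(x$ci_high_m)) "-" else sprintf("%.0f", x$ci_high_m)
    cat(sprintf("IEZ: %.0f m (95%% CI %.0f, %s)%s\n", x$iez_m, x$ci_low_m,
                hi, if (x$sign_near == "+") " [positive effect near]" else ""))
  }
  invisible(x)
}

#' Tabulate infrastructure-effect zones over a trait grid
#'
#' Evaluates [find_iez()] over combinations of body-mass percentiles,
#' diet levels (carnivorous = 80%, non-carnivorous = 0%) and habitats.
#' Trait dimensions not used by the model are collapsed. Bird models are
#' evaluated at paved roads; other taxa at the non-traffic reference.
#'
#' @param model a `meta_fit` or `meta_model`.
#' @param bm_values named numeric vector of body masses in grams (e.g.
#'   `c(small = 100, medium = 3000, large = 30000)`), or `NULL` when the
#'   model has no body-mass term.
#' @param diet_levels numeric vector of diet percentages (default
#'   `c(non_carnivore = 0, carnivore = 80)`), or `NULL`.
#' @param habitats habitat levels to tabulate.
#' @param d_max search horizon in metres.
#' @return data.frame with one row per grid cell: `taxon_group`,
#'   `diet_class`, `bm_label`, `body_mass_g`, `habitat`, `iez_m`,
#'   `ci_low_m`, `ci_high_m`, `sign_near`, `defined`.
#' @export
iez_table <- function(model, bm_values = NULL,
                      diet_levels = c(non_carnivore = 0, carnivore = 80),
                      habitats = c("open", "closed"), d_max = 1e5) {
  has_bm <- any(grepl("^bm$|:bm$", model$spec$terms))
  has_diet <- any(grepl("^diet$|:diet$", model$spec$terms))
  if (!has_bm) bm_values <- c(`-` = NA_real_)
  if (!has_diet) diet_levels <- c(`-` = NA_real_)
  if (is.null(names(bm_values)))
    names(bm_values) <- paste0("bm", seq_along(bm_values))
  if (is.null(names(diet_levels)))
    names(diet_levels) <- paste0("diet", seq_along(diet_levels))
  infra <- if (identical(model$taxon_group, "bird")) "paved_road"
           else "non_traffic"
  grid <- expand.grid(bm = names(bm_values), diet = names(diet_levels),
                      habitat = habitats, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    est <- find_iez(model, diet_pct = diet_levels[[g$diet]],
                    body_mass_g = bm_values[[g$bm]], habitat = g$habitat,
                    infra_type = infra, d_max = d_max)
    data.frame(taxon_group = model$taxon_group, diet_class = g$diet,
               bm_label = g$bm, body_mass_g = bm_values[[g$bm]],
               habitat = g$habitat, iez_m = est$iez_m,
               ci_low_m = est$ci_low_m, ci_high_m = est$ci_high_m,
               sign_near = est$sign_near, defined = est$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference meta-regression models for the four vertebrate taxa
#'
#' Coefficient estimates (with 95% CIs) from a published global synthesis
#' of linear-infrastructure effects on vertebrate abundance, bundled as a
#' plain-text table. These serve as worked examples and as default "truth"
#' for the synthetic-data presets. Coefficient covariances are not
#' published, so each model carries a diagonal covariance derived from the
#' printed intervals (adequate for point predictions and IEZs; interval
#' envelopes are approximate).
#'
#' @return named list of [meta_model()] objects (`mammal`, `bird`,
#'   `reptile`, `amphibian`).
#' @export
reference_models <- function() {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "iezmeta")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- reference_specs()
  out <- lapply(names(specs), function(tx) {
    sub <- tab[tab$taxon_group == tx, ]
    est <- stats::setNames(sub$estimate, sub$coef)
    se <- (sub$ci_ub - sub$ci_lb) / (2 * stats::qnorm(0.975))
    meta_model(est, specs[[tx]], tx, se = se)
  })
  stats::setNames(out, names(specs))
}

#' Moderator specifications of the reference models
#'
#' @return named list of `moderator_spec` objects matching
#'   [reference_models()].
#' @export
reference_specs <- function() {
  list(
    mammal = moderator_spec(c("distance", "distance2", "diet", "bm",
                              "habitat", "distance:diet", "distance:bm",
                              "distance2:bm", "distance:habitat")),
    bird = moderator_spec(c("distance", "diet", "habitat", "infratype",
                            "distance:diet", "distance:habitat")),
    reptile = moderator_spec(c("distance", "distance2", "habitat",
                               "distance:habitat")),
    amphibian = moderator_spec(c("distance", "distance2"))
  )
}
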