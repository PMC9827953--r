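#' Optimizer settings for the REML engine
#'
#' @param n_starts number of multi-starts (near-zero, method-of-moments,
#'   large); defaults to 3. Variance components in these models are often
#'   near the zero boundary, where a single start can stall.
#' @param lower,upper box bounds for the components on the log scale.
#' @param factr relative convergence tolerance passed to `optim`'s
#'   L-BFGS-B (`factr * .Machine$double.eps`); the default corresponds to
#'   about 1e-8 relative.
#' @param maxit maximum iterations per start.
#' @return list of control settings.
#' @export
reml_control <- function(n_starts = 3L, lower = log(1e-10),
                         upper = log(1e4), factr = 1e7, maxit = 200L) {
  list(n_starts = n_starts, lower = lower, upper = upper, factr = factr,
       maxit = maxit)
}

# Dense group indicator products Z_k Z_k' for each grouping factor.
.group_gram <- function(f) {
  f <- as.integer(factor(f))
  outer(f, f, "==") * 1
}

# Marginal covariance M = V + sum_k sigma2_k G_k.
.marginal_cov <- function(V, G, sigma2) {
  M <- V
  for (k in seq_along(G)) {
    if (sigma2[k] > 0) M <- M + sigma2[k] * G[[k]]
  }
  M
}

# Restricted log-likelihood and sufficient pieces at a given sigma2.
.reml_pieces <- function(y, V, X, G, sigma2) {
  n <- length(y)
  p <- ncol(X)
  M <- .marginal_cov(V, G, sigma2)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdetM <- 2 * sum(log(diag(R)))
  A <- backsolve(R, cbind(X, y), transpose = TRUE)  # R^-T [X y]
  AX <- A[, seq_len(p), drop = FALSE]
  Ay <- A[, p + 1L]
  XtMiX <- crossprod(AX)
  XtMiy <- crossprod(AX, Ay)[, 1]
  cR <- tryCatch(chol(XtMiX), error = function(e) NULL)
  if (is.null(cR)) return(NULL)
  logdetXtMiX <- 2 * sum(log(diag(cR)))
  beta <- backsolve(cR, backsolve(cR, XtMiy, transpose = TRUE))
  quad <- sum(Ay^2) - sum(XtMiy * beta)  # (y-Xb)' M^-1 (y-Xb)
  ll <- -0.5 * ((n - p) * log(2 * pi) + logdetM + logdetXtMiX + quad)
  list(ll = ll, M = M, R = R, beta = beta, XtMiX = XtMiX, cR = cR,
       logdetM = logdetM, quad = quad)
}

# Gradient of the restricted log-likelihood wrt sigma2 (natural scale).
.reml_grad <- function(y, V, X, G, sigma2, groups) {
  pieces <- .reml_pieces(y, V, X, G, sigma2)
  if (is.null(pieces)) return(rep(NA_real_, length(G)))
  Minv <- chol2inv(pieces$R)
  MiX <- Minv %*% X
  Cinv <- chol2inv(pieces$cR)  # (X'M^-1X)^-1
  Py <- Minv %*% y - MiX %*% (Cinv %*% crossprod(MiX, y))
  P <- Minv - MiX %*% Cinv %*% t(MiX)
  vapply(seq_along(G), function(k) {
    f <- groups[[k]]
    agg <- rowsum(P, f)                  # g x n
    tr <- sum(diag(rowsum(t(agg), f)))   # tr(P G_k)
    s <- rowsum(Py, f)
    -0.5 * (tr - sum(s^2))
  }, numeric(1))
}

#' Fit a multilevel random-effects meta-analytic model by REML
#'
#' Fits the marginal model `y ~ N(X beta, M)` with
#' `M = V + sum_k sigma2_k Z_k Z_k'`, where `V` is the known sampling
#' variance-covariance matrix of the effect sizes and the `Z_k` are
#' grouping indicators (typically observation, clade, species-in-clade,
#' source, study-in-source; see [random_effects_groups()]). Variance
#' components are estimated by maximizing the restricted log-likelihood
#' with a bounded quasi-Newton optimizer on log-parameterized components
#' (analytic gradients, multiple starts). Fixed effects are the
#' generalized least squares solution at the REML estimates, with Wald
#' (normal) confidence intervals.
#'
#' @param y numeric vector of effect sizes.
#' @param V sampling variance-covariance matrix (PSD; diagonal entries
#'   below 1e-8 are floored with a warning).
#' @param X fixed-effects design matrix, full column rank (a single
#'   intercept column for the pooled model).
#' @param groups named list of grouping factors, one per variance
#'   component, each of length `n`.
#' @param sigma2_fixed optional numeric vector (length = number of
#'   components) holding components fixed at given values; `NA` entries
#'   are estimated. Used by likelihood profiling.
#' @param control see [reml_control()].
#' @return object of class `meta_fit` with elements `beta` (coefficient
#'   table: estimate, SE, z, p, 95% CI), `vb` (coefficient covariance),
#'   `sigma2` (named variance components), `loglik_restricted`,
#'   `loglik_full`, `aicc`, `qe` (residual-heterogeneity test),
#'   `r2_marginal`, `r2_conditional`, `converged`, `n_obs`, `k_fixed`,
#'   `k_var`, plus the inputs needed for downstream tests and profiling.
#' @export
reml_fit <- function(y, V, X, groups, sigma2_fixed = NULL,
                     control = reml_control()) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("b", seq_len(ncol(X)) - 1L)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between y, V and X")
  if (qr(X)$rank < p) stop("design matrix X is rank deficient")
  if (max(abs(V - t(V))) > 1e-10) stop("V must be symmetric")
  if (any(diag(V) < 1e-8)) {
    warning("flooring ", sum(diag(V) < 1e-8),
            " near-zero sampling variance(s) at 1e-8")
    diag(V) <- pmax(diag(V), 1e-8)
  }
  if (is.null(chol_ok <- tryCatch(chol(V + 1e-8 * diag(n)),
                                  error = function(e) NULL)))
    stop("V is not positive semidefinite")
  if (!all(vapply(groups, length, integer(1)) == n))
    stop("each grouping factor must cover all observations")
  K <- length(groups)
  groups <- lapply(groups, function(f) factor(f))
  G <- lapply(groups, .group_gram)
  if (is.null(sigma2_fixed)) sigma2_fixed <- rep(NA_real_, K)
  free <- which(is.na(sigma2_fixed))
  fixed_vals <- sigma2_fixed

  expand <- function(theta_free) {
    s <- fixed_vals
    s[free] <- exp(theta_free)
    s
  }

  obj <- function(theta_free) {
    pieces <- .reml_pieces(y, V, X, G, expand(theta_free))
    if (is.null(pieces)) return(1e10)
    -pieces$ll
  }
  gr <- function(theta_free) {
    s <- expand(theta_free)
    g <- .reml_grad(y, V, X, G, s, groups)
    if (any(is.na(g))) return(rep(0, length(free)))
    -(g[free] * s[free])  # chain rule to log scale
  }

  if (length(free) == 0L) {
    sigma2 <- fixed_vals
    opt <- list(convergence = 0L)
  } else {
    # multi-start values: near zero, method-of-moments heuristic, large
    qe0 <- tryCatch(q_e(y, V, X), error = function(e) NULL)
    mom <- if (!is.null(qe0) && qe0$statistic > qe0$df) {
      max((qe0$statistic - qe0$df) / sum(1 / diag(V)), 1e-4)
    } else 1e-3
    starts <- list(
      rep(1e-4, length(free)),
      rep(mom / max(length(free), 1), length(free)),
      rep(max(stats::var(y), 0.1), length(free))
    )[seq_len(max(1L, min(control$n_starts, 3L)))]
    best <- NULL
    for (s0 in starts) {
      o <- tryCatch(
        stats::optim(log(s0), obj, gr, method = "L-BFGS-B",
                     lower = control$lower, upper = control$upper,
                     control = list(factr = control$factr,
                                    maxit = control$maxit)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-10) best <- o
    }
    if (is.null(best)) stop("REML optimization failed from all starts")
    opt <- best
    sigma2 <- expand(opt$par)
  }
  names(sigma2) <- names(groups) %||% paste0("sigma2_", seq_len(K))

  pieces <- .reml_pieces(y, V, X, G, sigma2)
  if (is.null(pieces)) stop("marginal covariance not PD at the solution")
  beta <- pieces$beta
  vb <- chol2inv(pieces$cR)
  se <- sqrt(diag(vb))
  zval <- beta / se
  pval <- 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
  ci_lb <- beta + stats::qnorm(0.025) * se
  ci_ub <- beta + stats::qnorm(0.975) * se
  coef_tab <- data.frame(
    term = colnames(X), estimate = beta, se = se, zval = zval, pval = pval,
    ci_lb = ci_lb, ci_ub = ci_ub, row.names = NULL
  )
  dimnames(vb) <- list(colnames(X), colnames(X))

  # full (unrestricted) log-likelihood at the REML estimates
  loglik_full <- -0.5 * (n * log(2 * pi) + pieces$logdetM + pieces$quad)
  k_var <- length(free)
  k <- p + k_var
  aicc_val <- if (n - k - 1 > 0) {
    -2 * loglik_full + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else NA_real_

  qe <- tryCatch(q_e(y, V, X), error = function(e) NULL)

  fit <- structure(list(
    beta = coef_tab, vb = vb, sigma2 = sigma2,
    loglik_restricted = pieces$ll, loglik_full = loglik_full,
    aicc = aicc_val, qe = qe, converged = opt$convergence == 0L,
    n_obs = n, k_fixed = p, k_var = k_var, n_params = k,
    sigma2_fixed = fixed_vals,
    y = y, V = V, X = X, groups = groups, control = control
  ), class = "meta_fit")
  r2 <- r2_nakagawa(fit)
  fit$r2_marginal <- r2[["r2_marginal"]]
  fit$r2_conditional <- r2[["r2_conditional"]]
  if (!fit$converged)
    warning("REML optimizer did not report convergence")
  fit
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Multilevel meta-analytic model (REML): %d effect sizes, %d fixed, %d variance component(s)\n",
    x$n_obs, x$k_fixed, x$k_var))
  print(cbind(
    round(x$beta[, c("estimate", "se", "zval", "pval", "ci_lb", "ci_ub")],
          digits),
    term = x$beta$term), row.names = FALSE)
  cat("sigma2:", paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2),
                       collapse = ", "), "\n")
  if (!is.null(x$qe))
    cat(sprintf("Q_E = %.2f (df = %d, p = %.3g); ", x$qe$statistic,
                x$qe$df, x$qe$p))
  cat(sprintf("AICc = %.2f; R2m = %.3f, R2c = %.3f\n", x$aicc,
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Coefficients of a fitted meta-analytic model
#' @param object a `meta_fit`.
#' @param ... unused.
#' @return named numeric vector of fixed-effect estimates.
#' @export
coef.meta_fit <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' Residual heterogeneity test (Cochran's Q, weighted least squares form)
#'
#' `Q_E = (y - X b)' V^-1 (y - X b)` with `b` the V-weighted
#' (fixed-effects) GLS solution; under homogeneity `Q_E` is chi-square
#' with `n - p` degrees of freedom.
#'
#' @param y effect sizes.
#' @param V sampling variance-covariance matrix.
#' @param X design matrix (intercept-only for the pooled test).
#' @return list with `statistic`, `df`, `p`.
#' @export
q_e <- function(y, V, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e)
    stop("V must be positive definite for Q_E"))
  A <- backsolve(R, cbind(X, y), transpose = TRUE)
  AX <- A[, seq_len(ncol(X)), drop = FALSE]
  Ay <- A[, ncol(X) + 1L]
  b <- solve(crossprod(AX), crossprod(AX, Ay))
  resid <- Ay - AX %*% b
  stat <- sum(resid^2)
  df <- n - ncol(X)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Omnibus Wald test of moderators (Q_M)
#'
#' Wald chi-square test `b_s' [cov(b_s)]^-1 b_s` on a subset of the fixed
#' effects. By default all non-intercept coefficients are tested. When a
#' main effect's interactions are present in the model, test the main
#' effect on a refit without those interactions (see
#' [qm_term()] for the term-level interface that performs the refit).
#'
#' @param fit a `meta_fit`.
#' @param coefs coefficient names or column indices to test (excluding the
#'   intercept). `NULL` tests every non-intercept coefficient.
#' @return list with `statistic`, `df`, `p`.
#' @export
q_m <- function(fit, coefs = NULL) {
  nm <- fit$beta$term
  if (is.null(coefs)) coefs <- setdiff(nm, "intercept")
  idx <- if (is.numeric(coefs)) coefs else match(coefs, nm)
  if (anyNA(idx)) stop("unknown coefficient(s): ",
                       paste(coefs[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) stop("empty coefficient subset")
  if (any(nm[idx] == "intercept")) stop("Q_M excludes the intercept")
  b <- fit$beta$estimate[idx]
  Vb <- fit$vb[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(Vb, b))
  df <- length(idx)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' AICc from the full likelihood
#'
#' `AICc = -2 logLik_full + 2k + 2k(k+1)/(n-k-1)` where `k` counts fixed
#' effects plus free variance components and the full (unrestricted)
#' likelihood is evaluated at the REML estimates.
#'
#' @param fit a `meta_fit`.
#' @return the AICc value.
#' @export
aicc <- function(fit) {
  k <- fit$n_params
  n <- fit$n_obs
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * fit$loglik_full + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Higgins-Thompson "typical" sampling variance.
.typical_sampling_variance <- function(V) {
  w <- 1 / diag(V)
  n <- length(w)
  if (n == 1L) return(V[1, 1])
  (n - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Marginal and conditional R-squared for meta-analytic mixed models
#'
#' The proportion of total variance explained by the moderators alone
#' (marginal) and by moderators plus random effects (conditional), using a
#' typical sampling variance `s2` in place of a residual variance:
#' `R2m = var(Xb) / (var(Xb) + sum(sigma2) + s2)` and
#' `R2c = (var(Xb) + sum(sigma2)) / (var(Xb) + sum(sigma2) + s2)`, with
#' `s2 = (n-1) sum(w) / ((sum w)^2 - sum(w^2))`, `w = 1/V_ii`.
#'
#' @param fit a `meta_fit`.
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  f <- as.numeric(fit$X %*% fit$beta$estimate)
  sigma_f2 <- if (length(f) > 1) stats::var(f) else 0
  s2 <- .typical_sampling_variance(fit$V)
  denom <- sigma_f2 + sum(fit$sigma2) + s2
  if (denom <= 0) stop("degenerate variance total in R2 computation")
  c(r2_marginal = sigma_f2 / denom,
    r2_conditional = (sigma_f2 + sum(fit$sigma2)) / denom)
}

#' Percentage of total heterogeneity attributed to each variance component
#'
#' Each component is reported as `sigma2_k / (sum(sigma2) + s2) * 100`,
#' with `s2` the typical sampling variance; the `sampling` entry makes the
#' proportions sum to 100.
#'
#' @param fit a `meta_fit`.
#' @return named numeric vector of percentages (components plus
#'   `sampling`).
#' @export
variance_proportions <- function(fit) {
  s2 <- .typical_sampling_variance(fit$V)
  total <- sum(fit$sigma2) + s2
  out <- c(fit$sigma2, sampling = s2) / total * 100
  out
}

#' Profile likelihood of a variance component
#'
#' Fixes one variance component at each grid value, re-optimizes the
#' remaining parameters, and reports the profiled restricted
#' log-likelihood. The component is judged identifiable when the profile
#' has a unique interior maximum and drops by at least 1.92 units (the
#' chi-square(1)/2 critical value) within the grid on each side where the
#' grid allows.
#'
#' @param fit a `meta_fit`.
#' @param component index or name of the component to profile.
#' @param grid numeric vector of sigma2 values; defaults to a log-spaced
#'   grid around the estimate.
#' @return list with `grid`, `loglik`, `identifiable` and `verdict`
#'   (character diagnosis).
#' @export
profile_component <- function(fit, component, grid = NULL) {
  K <- length(fit$sigma2)
  k <- if (is.character(component)) match(component, names(fit$sigma2))
       else component
  if (is.na(k) || k < 1 || k > K) stop("unknown component")
  if (is.null(grid)) {
    centre <- max(fit$sigma2[k], 1e-3)
    grid <- exp(seq(log(centre) - 4, log(centre) + 4, length.out = 25))
  }
  if (any(grid < 0)) stop("grid values must be >= 0")
  ll <- vapply(grid, function(s2k) {
    fixed <- rep(NA_real_, K)
    fixed[k] <- s2k
    f <- tryCatch(suppressWarnings(
      reml_fit(fit$y, fit$V, fit$X, fit$groups, sigma2_fixed = fixed,
               control = reml_control(n_starts = 1L))),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$loglik_restricted
  }, numeric(1))
  ok <- is.finite(ll)
  verdict <- "identifiable"
  identifiable <- TRUE
  llv <- ll[ok]
  if (sum(ok) < 3L) {
    identifiable <- FALSE
    verdict <- "profile could not be evaluated"
  } else {
    imax <- which.max(llv)
    rng <- max(llv) - min(llv)
    if (rng < 1e-4) {
      identifiable <- FALSE
      verdict <- "flat profile"
    } else {
      # unique interior maximum: no secondary local maximum within 0.1 units
      d <- diff(llv)
      sign_changes <- sum(diff(sign(d[d != 0])) != 0)
      if (sign_changes > 1L) {
        identifiable <- FALSE
        verdict <- "multimodal profile"
      }
      drop_left <- if (imax > 1L) llv[imax] - min(llv[seq_len(imax)]) else Inf
      drop_right <- if (imax < length(llv))
        llv[imax] - min(llv[imax:length(llv)]) else Inf
      if (is.finite(drop_left) && drop_left < 1.92 &&
          is.finite(drop_right) && drop_right < 1.92) {
        identifiable <- FALSE
        verdict <- "profile does not drop 1.92 units on either side"
      }
    }
  }
  list(grid = grid, loglik = ll, identifiable = identifiable,
       verdict = verdict)
}

#' Egger-type test for funnel-plot asymmetry
#'
#' Classic Egger regression on the meta-analytic residuals: the
#' standardized residuals `(y - X b) / sqrt(V_ii)` are regressed on
#' precision `1 / sqrt(V_ii)` by ordinary least squares (equivalently, the
#' residuals are modelled as a function of precision with
#' inverse-variance weights), and the intercept, its standard error and
#' the two-sided t-test p-value are reported. Standardizing makes the
#' regression errors homoscedastic, so the t-test holds its nominal size.
#' An intercept indistinguishable from zero (`p >= 0.05`) is read as no
#' evidence of publication bias.
#'
#' @param fit a `meta_fit`.
#' @return list with `intercept`, `se`, `p`.
#' @export
egger_test <- function(fit) {
  if (fit$n_obs < 3L) stop("Egger test needs at least 3 observations")
  se_i <- sqrt(diag(fit$V))
  r <- (fit$y - as.numeric(fit$X %*% fit$beta$estimate)) / se_i
  precision <- 1 / se_i
  m <- stats::lm(r ~ precision)
  sm <- summary(m)$coefficients
  list(intercept = sm[1, 1], se = sm[1, 2], p = sm[1, 4])
}
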