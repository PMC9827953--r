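#' Truncated sample mean for zero abundances
#'
#' A response ratio is undefined when a species was not detected at the
#' disturbed or the control site. Zero means are therefore replaced by the
#' positive truncation value `1 / (2 n D)`, where `n` is the sample size of
#' the mean and `D` the reporting-scale constant (e.g. the number of trap
#' nights when abundance is individuals per trap night). Positive means
#' pass through unchanged.
#'
#' @param mean sample mean abundance, `>= 0` (vectorised).
#' @param n sample size, integer `>= 1`.
#' @param D reporting-scale constant, `> 0`.
#' @return truncated mean, always `> 0`.
#' @export
truncated_mean <- function(mean, n, D) {
  if (any(is.na(mean)) || any(mean < 0)) stop("mean must be >= 0")
  if (any(is.na(n)) || any(n < 1) || any(n != round(n)))
    stop("n must be an integer >= 1")
  if (any(is.na(D)) || any(D <= 0)) stop("D must be > 0")
  ifelse(mean > 0, mean, 1 / (2 * n * D))
}

#' Delta-corrected log response ratio
#'
#' The effect size is the natural log of the ratio of (truncated) mean
#' abundance at the disturbed site to the control site, with a second-order
#' small-sample bias correction:
#' \deqn{LRR^{\Delta} = \log(\tilde{A}_d / \tilde{A}_c) +
#'   \frac{1}{2}\left[\frac{SD_d^2}{n_d \tilde{A}_d^2} -
#'   \frac{SD_c^2}{n_c \tilde{A}_c^2}\right].}
#' Negative values mean lower abundance near infrastructure.
#'
#' @param mean_treat,sd_treat,n_treat truncated mean (`> 0`), SD (`>= 0`)
#'   and sample size at the disturbed site (vectorised).
#' @param mean_ctrl,sd_ctrl,n_ctrl same for the control site.
#' @return the corrected log response ratio.
#' @export
lrr_delta <- function(mean_treat, sd_treat, n_treat,
                      mean_ctrl, sd_ctrl, n_ctrl) {
  if (any(mean_treat <= 0) || any(mean_ctrl <= 0))
    stop("means must be > 0; apply truncated_mean() to zero means first")
  if (any(is.na(sd_treat)) || any(is.na(sd_ctrl)))
    stop("SDs must be present; impute missing SDs first")
  log(mean_treat / mean_ctrl) +
    0.5 * (sd_treat^2 / (n_treat * mean_treat^2) -
           sd_ctrl^2 / (n_ctrl * mean_ctrl^2))
}

#' Sampling variance of the delta-corrected log response ratio
#'
#' Second-order delta-method variance:
#' \deqn{VAR(LRR^{\Delta}) = \frac{SD_d^2}{n_d \tilde{A}_d^2} +
#'   \frac{SD_c^2}{n_c \tilde{A}_c^2} +
#'   \frac{1}{2}\left[\frac{SD_d^4}{n_d^2 \tilde{A}_d^4} +
#'   \frac{SD_c^4}{n_c^2 \tilde{A}_c^4}\right].}
#'
#' @inheritParams lrr_delta
#' @return sampling variance (non-negative; zero only when both SDs are 0).
#' @export
var_lrr_delta <- function(mean_treat, sd_treat, n_treat,
                          mean_ctrl, sd_ctrl, n_ctrl) {
  if (any(mean_treat <= 0) || any(mean_ctrl <= 0))
    stop("means must be > 0; apply truncated_mean() to zero means first")
  if (any(is.na(sd_treat)) || any(is.na(sd_ctrl)))
    stop("SDs must be present; impute missing SDs first")
  vt <- sd_treat^2 / (n_treat * mean_treat^2)
  vc <- sd_ctrl^2 / (n_ctrl * mean_ctrl^2)
  vt + vc + 0.5 * (vt^2 + vc^2)
}

#' Impute missing standard deviations
#'
#' Abundance SDs are frequently unreported. Three imputation methods are
#' provided, applied to every missing or zero SD (a reported zero SD is
#' treated as missing) on both the treatment and control side:
#' \describe{
#'   \item{poisson}{assume the counts are Poisson so the variance equals
#'     the (truncated) mean: `SD = sqrt(A~)`. Deterministic; the default.}
#'   \item{bracken1992}{scale each incomplete case's truncated mean by the
#'     pooled SD-to-mean ratio of the complete cases:
#'     `SD_i = A~_i * sum(SD)/sum(A~)`.}
#'   \item{hotdeck_nn}{for each missing SD, draw uniformly from the `k`
#'     complete cases nearest in truncated mean (ties broken by record
#'     order), independently in each of `n_imputations` completed data
#'     sets. Donor pools are restricted to the same taxon group.}
#' }
#'
#' @param records comparison data.frame (the standard schema).
#' @param method one of `"poisson"`, `"bracken1992"`, `"hotdeck_nn"`.
#' @param seed integer seed for `hotdeck_nn` draws.
#' @param n_imputations number of completed data sets for `hotdeck_nn`
#'   (default 100).
#' @param k donor-pool size for `hotdeck_nn` (default 5).
#' @return For deterministic methods, one data.frame with columns
#'   `sd_imputed_treat`/`sd_imputed_ctrl` flagging filled values. For
#'   `hotdeck_nn`, a list of `n_imputations` such data.frames.
#' @export
impute_sd <- function(records, method = c("poisson", "bracken1992",
                                          "hotdeck_nn"),
                      seed = 1L, n_imputations = 100L, k = 5L) {
  method <- match.arg(method)
  x <- records
  x$.tm_treat <- truncated_mean(x$mean_treat, x$n_treat, x$scale_D)
  x$.tm_ctrl  <- truncated_mean(x$mean_ctrl, x$n_ctrl, x$scale_D)
  miss_t <- is.na(x$sd_treat) | x$sd_treat == 0
  miss_c <- is.na(x$sd_ctrl) | x$sd_ctrl == 0
  x$sd_imputed_treat <- miss_t
  x$sd_imputed_ctrl <- miss_c

  finish <- function(x) {
    x$.tm_treat <- NULL
    x$.tm_ctrl <- NULL
    x
  }

  if (method == "poisson") {
    x$sd_treat[miss_t] <- sqrt(x$.tm_treat[miss_t])
    x$sd_ctrl[miss_c] <- sqrt(x$.tm_ctrl[miss_c])
    return(finish(x))
  }

  # donor pool: arms with a reported, nonzero SD
  donor_means <- c(x$.tm_treat[!miss_t], x$.tm_ctrl[!miss_c])
  donor_sds <- c(x$sd_treat[!miss_t], x$sd_ctrl[!miss_c])
  donor_taxon <- c(x$taxon_group[!miss_t], x$taxon_group[!miss_c])
  if (length(donor_sds) == 0L)
    stop("no complete cases available for donor-based imputation")

  if (method == "bracken1992") {
    ratio <- sum(donor_sds) / sum(donor_means)
    x$sd_treat[miss_t] <- x$.tm_treat[miss_t] * ratio
    x$sd_ctrl[miss_c] <- x$.tm_ctrl[miss_c] * ratio
    return(finish(x))
  }

  # hotdeck_nn; the control arm is one observation shared by all
  # comparisons of the same study x species, so its SD is drawn once per
  # control group, not once per row
  draw_pool <- function(tm, taxon) {
    pool <- which(donor_taxon == taxon)
    if (length(pool) == 0L) pool <- seq_along(donor_sds)
    d <- abs(donor_means[pool] - tm)
    pool[order(d, seq_along(d))][seq_len(min(k, length(pool)))]
  }
  ctrl_grp <- interaction(x$study_id, x$species_id, x$mean_ctrl, x$n_ctrl,
                          drop = TRUE)
  miss_c_grp <- tapply(miss_c, ctrl_grp, any)
  grp_first <- match(levels(ctrl_grp), as.character(ctrl_grp))
  set.seed(as.integer(seed))
  out <- vector("list", n_imputations)
  nn_t <- lapply(which(miss_t), function(i)
    draw_pool(x$.tm_treat[i], x$taxon_group[i]))
  nn_c <- lapply(which(miss_c_grp), function(gi) {
    i <- grp_first[gi]
    draw_pool(x$.tm_ctrl[i], x$taxon_group[i])
  })
  for (m in seq_len(n_imputations)) {
    xi <- x
    if (length(nn_t) > 0L)
      xi$sd_treat[miss_t] <- vapply(nn_t, function(nn)
        donor_sds[nn[sample.int(length(nn), 1L)]], numeric(1))
    if (length(nn_c) > 0L) {
      draw_g <- vapply(nn_c, function(nn)
        donor_sds[nn[sample.int(length(nn), 1L)]], numeric(1))
      fill <- draw_g[match(as.integer(ctrl_grp), which(miss_c_grp))]
      xi$sd_ctrl[miss_c] <- fill[miss_c]
    }
    out[[m]] <- finish(xi)
  }
  out
}

#' Assemble effect sizes with the shared-control covariance matrix
#'
#' Computes the delta-corrected log response ratio and its sampling
#' variance for every record and builds the full sampling
#' variance-covariance matrix. Comparisons at different distances within
#' the same study and species divide by the same control mean, which
#' induces a sampling covariance equal to the control's first-order
#' variance contribution `SD_c^2 / (n_c A~_c^2)`; all other off-diagonal
#' entries are zero.
#'
#' @param records comparison data.frame with SDs complete (post
#'   imputation, see [impute_sd()]).
#' @return object of class `effect_size_set`: a list with `table` (one row
#'   per effect size: `comparison_id`, `value`, `variance`, truncation and
#'   imputation flags, and all moderators) and `vcov` (the dense sampling
#'   variance-covariance matrix in table order).
#' @export
build_effect_size_set <- function(records) {
  if (any(is.na(records$sd_treat)) || any(is.na(records$sd_ctrl)))
    stop("SDs must be complete; run impute_sd() first")
  tm_t <- truncated_mean(records$mean_treat, records$n_treat, records$scale_D)
  tm_c <- truncated_mean(records$mean_ctrl, records$n_ctrl, records$scale_D)
  value <- lrr_delta(tm_t, records$sd_treat, records$n_treat,
                     tm_c, records$sd_ctrl, records$n_ctrl)
  variance <- var_lrr_delta(tm_t, records$sd_treat, records$n_treat,
                            tm_c, records$sd_ctrl, records$n_ctrl)
  n <- nrow(records)
  tab <- data.frame(
    comparison_id = records$comparison_id,
    value = value,
    variance = variance,
    used_truncation_treat = records$mean_treat == 0,
    used_truncation_ctrl = records$mean_ctrl == 0,
    sd_imputed_treat = records$sd_imputed_treat %||% rep(FALSE, n),
    sd_imputed_ctrl = records$sd_imputed_ctrl %||% rep(FALSE, n),
    source_id = records$source_id,
    study_id = records$study_id,
    species_id = records$species_id,
    taxon_group = records$taxon_group,
    clade = records$clade,
    distance_m = records$distance_m,
    infra_type = records$infra_type,
    habitat = records$habitat,
    body_mass_g = records$body_mass_g,
    diet_pct = records$diet_pct,
    stringsAsFactors = FALSE
  )
  V <- diag(variance, nrow = n)
  ctrl_var <- records$sd_ctrl^2 / (records$n_ctrl * tm_c^2)
  # sharing is identified by equality of the control observation within
  # study x species (distinct controls in one study stay independent)
  grp <- interaction(records$study_id, records$species_id,
                     records$mean_ctrl, records$sd_ctrl, records$n_ctrl,
                     drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        # shared control: same control observation within study x species
        V[i, j] <- V[j, i] <- ctrl_var[i]
      }
    }
  }
  dimnames(V) <- list(tab$comparison_id, tab$comparison_id)
  out <- structure(list(table = tab, vcov = V), class = "effect_size_set")
  stopifnot(isTRUE(all.equal(diag(V), variance, check.names = FALSE)))
  out
}

#' @export
print.effect_size_set <- function(x, ...) {
  cat(sprintf("Effect-size set: %d effect sizes, %d shared-control pairs\n",
              nrow(x$table), sum(x$vcov[upper.tri(x$vcov)] != 0)))
  invisible(x)
}

#' Geary's normality screen for ratio effect sizes
#'
#' Log response ratios are unreliable when a site mean is close to zero
#' relative to its sampling noise. A comparison arm passes the screen when
#' \deqn{\frac{\tilde{A}}{SD}\,\frac{4 n^{3/2}}{1 + 4n} \ge 3.}
#'
#' @param mean truncated mean, `> 0` (vectorised).
#' @param sd standard deviation, `> 0`.
#' @param n sample size, `>= 1`.
#' @return logical: `TRUE` when the arm passes.
#' @export
geary_pass <- function(mean, sd, n) {
  if (any(is.na(sd)) || any(sd <= 0)) stop("sd must be > 0")
  (mean / sd) * (4 * n^1.5) / (1 + 4 * n) >= 3
}

#' Filter an effect-size input table by Geary's rule
#'
#' Keeps the records whose treatment and control arms both pass
#' [geary_pass()], evaluated on truncated means.
#'
#' @param records comparison data.frame with SDs complete.
#' @return filtered data.frame.
#' @export
geary_subset <- function(records) {
  tm_t <- truncated_mean(records$mean_treat, records$n_treat, records$scale_D)
  tm_c <- truncated_mean(records$mean_ctrl, records$n_ctrl, records$scale_D)
  ok <- geary_pass(tm_t, records$sd_treat, records$n_treat) &
    geary_pass(tm_c, records$sd_ctrl, records$n_ctrl)
  records[ok, , drop = FALSE]
}

#' Percentage abundance change implied by a log response ratio
#'
#' `(exp(lrr) - 1) * 100`: the percent difference in abundance at the
#' disturbed site relative to the control.
#'
#' @param lrr log response ratio (vectorised).
#' @return percentage change.
#' @export
percentage_change <- function(lrr) {
  (exp(lrr) - 1) * 100
}

#' Serialize an effect-size set to CSV files
#'
#' Writes the effect-size table and the dense variance-covariance matrix as
#' two index-aligned CSV files.
#'
#' @param es_set an `effect_size_set`.
#' @param table_path,vcov_path output paths.
#' @return invisibly, the two paths.
#' @export
write_effect_size_set <- function(es_set, table_path, vcov_path) {
  utils::write.csv(es_set$table, table_path, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(es_set$vcov), vcov_path, row.names = FALSE)
  invisible(c(table_path, vcov_path))
}
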