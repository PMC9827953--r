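# Shared fixtures and independent oracles used across the suite.

# A small valid comparison table covering both habitats, shared controls
# (two distances of sp1 in study S01_st1 share mean_ctrl/sd_ctrl/n_ctrl)
# and a missing SD.
make_comparisons <- function() {
  data.frame(
    comparison_id = paste0("c", 1:5),
    source_id = c("S01", "S01", "S01", "S02", "S02"),
    study_id = c("S01_st1", "S01_st1", "S01_st2", "S02_st1", "S02_st1"),
    species_id = c("sp1", "sp1", "sp2", "sp3", "sp4"),
    taxon_group = "mammal",
    clade = c("carnivora", "carnivora", "rodentia", "rodentia", "rodentia"),
    distance_m = c(10, 100, 0, 50, 250),
    infra_type = c("paved_road", "paved_road", "unpaved_road",
                   "non_traffic", "non_traffic"),
    habitat = c("closed", "closed", "open", "open", "open"),
    mean_treat = c(2, 3.5, 0, 1.2, 4),
    sd_treat = c(1, 1.5, NA, 0.8, 2),
    n_treat = c(5, 5, 10, 4, 6),
    mean_ctrl = c(4, 4, 2, 1.5, 3),
    sd_ctrl = c(2, 2, 1, NA, 1.2),
    n_ctrl = c(5, 5, 8, 4, 6),
    scale_D = c(1, 1, 1, 25, 1),
    body_mass_g = c(5000, 5000, 30, 30, 120),
    diet_pct = c(80, 80, 0, 0, 10),
    quality_a = c(1, 1, 1, 0, 1),
    quality_b = c(1, 0, 1, 1, 0),
    stringsAsFactors = FALSE
  )
}

# Literal transcriptions of the effect-size formulas, kept deliberately
# separate from the package implementation (scalar, no shared code).
oracle_truncated_mean <- function(mean, n, D) {
  if (mean > 0) mean else 1 / (2 * n * D)
}
oracle_lrr_delta <- function(At, SDt, nt, Ac, SDc, nc) {
  log(At / Ac) + (1 / 2) * (SDt^2 / (nt * At^2) - SDc^2 / (nc * Ac^2))
}
oracle_var_lrr_delta <- function(At, SDt, nt, Ac, SDc, nc) {
  SDt^2 / (nt * At^2) + SDc^2 / (nc * Ac^2) +
    (1 / 2) * (SDt^4 / (nt^2 * At^4) + SDc^4 / (nc^2 * Ac^4))
}
oracle_geary <- function(A, SD, n) {
  (A / SD) * (4 * n^(3 / 2)) / (1 + 4 * n) >= 3
}

# Brute-force restricted log-likelihood for a single variance component
# (intercept-only): direct dense evaluation on a grid, no shared code with
# the engine's chol-based pieces.
oracle_reml_1d <- function(y, V, X, Gmat, grid) {
  n <- length(y)
  p <- ncol(X)
  vapply(grid, function(s2) {
    M <- V + s2 * Gmat
    Mi <- solve(M)
    XtMiX <- t(X) %*% Mi %*% X
    b <- solve(XtMiX, t(X) %*% Mi %*% y)
    r <- y - X %*% b
    -0.5 * ((n - p) * log(2 * pi) +
              as.numeric(determinant(M)$modulus) +
              as.numeric(determinant(XtMiX)$modulus) +
              as.numeric(t(r) %*% Mi %*% r))
  }, numeric(1))
}

# Simple homogeneous-null simulator: k independent effect sizes with known
# sampling variances and no heterogeneity, plus one pure-noise moderator.
simulate_null_effects <- function(n, seed) {
  set.seed(seed)
  v <- runif(n, 0.05, 0.5)
  list(y = rnorm(n, 0, sqrt(v)), V = diag(v), x = rnorm(n))
}
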