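test_that("prediction at the reference point returns the intercept", {
  m <- reference_models()
  for (tx in names(m)) {
    p <- predict_lrr(m[[tx]], 1,
                     diet_pct = if (tx %in% c("mammal", "bird")) 0 else NA,
                     body_mass_g = 1, habitat = "closed",
                     infra_type = "non_traffic")
    expect_equal(p$lrr, m[[tx]]$beta$estimate[1], tolerance = 1e-12)
  }
  expect_error(predict_lrr(m$reptile, 1, habitat = "wetland"), "habitat")
  expect_error(predict_lrr(m$mammal, 1, diet_pct = 0, body_mass_g = 10,
                           infra_type = "power_line"), "infrastructure")
})

test_that("near-infrastructure percentages reproduce the published worked examples", {
  m <- reference_models()
  pct <- function(model, ...) {
    round(percentage_change(predict_lrr(model, 1, ...)$lrr))
  }
  expect_equal(pct(m$amphibian), -52)
  expect_equal(pct(m$reptile, habitat = "closed"), 20)
  expect_equal(pct(m$reptile, habitat = "open"), -39)
  expect_equal(pct(m$bird, diet_pct = 0, habitat = "closed",
                   infra_type = "paved_road"), -33)
  expect_equal(pct(m$bird, diet_pct = 0, habitat = "open",
                   infra_type = "paved_road"), -58)
})

test_that("closed-form IEZ agrees with a dense brute-force sign scan", {
  m <- reference_models()
  cases <- list(
    list(model = m$mammal, diet = 80, bm = 100, hab = "closed"),
    list(model = m$mammal, diet = 80, bm = 30000, hab = "open"),
    list(model = m$mammal, diet = 0, bm = 10, hab = "closed"),
    list(model = m$mammal, diet = 0, bm = 400000, hab = "open"),
    list(model = m$reptile, diet = NA, bm = NA, hab = "closed"),
    list(model = m$amphibian, diet = NA, bm = NA, hab = "closed")
  )
  for (cs in cases) {
    est <- find_iez(cs$model, diet_pct = cs$diet, body_mass_g = cs$bm,
                    habitat = cs$hab)
    # brute force: 10,000 log-spaced distances
    xs <- seq(0, 5, length.out = 10000)
    lrr <- predict_lrr(cs$model, 10^xs, diet_pct = cs$diet,
                       body_mass_g = cs$bm, habitat = cs$hab)$lrr
    flip <- which(sign(lrr[-1]) != sign(lrr[-length(lrr)]))[1]
    if (is.na(flip)) {
      expect_false(est$defined)
    } else {
      step <- 10^xs[flip + 1] - 10^xs[flip]
      expect_true(est$defined)
      expect_lte(abs(est$iez_m - 10^xs[flip]), step + 1e-9)
    }
  }
})

test_that("IEZ distances match the published mammal and reptile zones", {
  m <- reference_models()
  expect_equal(round(find_iez(m$mammal, 80, 100, "closed")$iez_m), 107)
  expect_equal(round(find_iez(m$mammal, 80, 30000, "open")$iez_m), 21)
  expect_equal(round(find_iez(m$mammal, 0, 10, "closed")$iez_m), 2)
  # large non-carnivores in open habitat: ~603 m (within rounding of the
  # two-decimal coefficients)
  expect_equal(find_iez(m$mammal, 0, 400000, "open")$iez_m, 603,
               tolerance = 0.01)
  expect_equal(round(find_iez(m$reptile, habitat = "closed")$iez_m), 3)
  # effect direction at 1 m
  expect_equal(find_iez(m$mammal, 80, 100, "closed")$sign_near, "+")
  expect_equal(find_iez(m$mammal, 0, 400000, "open")$sign_near, "-")
  expect_equal(find_iez(m$reptile, habitat = "closed")$sign_near, "+")
})

test_that("responses that never recover yield an undefined IEZ", {
  # linear, negative intercept, negative slope: moves away from zero
  m <- meta_model(c(intercept = -0.4, distance = -0.04),
                  moderator_spec("distance"), "bird",
                  se = c(0.1, 0.02))
  est <- find_iez(m)
  expect_false(est$defined)
  expect_equal(est$sign_near, "-")
  expect_true(is.na(est$iez_m))
  # the published non-carnivorous-bird case in closed habitat behaves the
  # same way (intercept 0.05 - 0.45, slope -0.04)
  rb <- reference_models()$bird
  est2 <- find_iez(rb, diet_pct = 0, habitat = "closed",
                   infra_type = "paved_road")
  expect_false(est2$defined)
})

test_that("monotone curves cross at most once and quadratics return the smaller root", {
  # quadratic with two admissible roots: 0.18 - 0.44x + 0.15x^2
  m <- reference_models()$reptile
  coefs <- iezmeta:::.lrr_poly(m, NA, NA, "closed", "non_traffic")
  roots <- iezmeta:::.poly_roots_in(coefs, 5)
  expect_length(roots, 2)
  est <- find_iez(m, habitat = "closed")
  expect_equal(est$iez_m, 10^roots[1], tolerance = 1e-8)

  # strictly monotone linear curve: exactly one crossing
  m2 <- meta_model(c(intercept = -0.5, distance = 0.25),
                   moderator_spec("distance"), "amphibian",
                   se = c(0.05, 0.02))
  est2 <- find_iez(m2)
  expect_true(est2$defined)
  expect_equal(log10(est2$iez_m), 2, tolerance = 1e-9)
  expect_lte(est2$ci_low_m, est2$iez_m)
  expect_gte(est2$ci_high_m, est2$iez_m)
})

test_that("CI envelope bounds bracket the IEZ and can be one-sided", {
  # wide uncertainty on the intercept: upper envelope never crosses
  m <- meta_model(c(intercept = 0.6, distance = -0.3),
                  moderator_spec("distance"), "amphibian",
                  se = c(2, 0.01))
  est <- find_iez(m)
  expect_true(est$defined)
  expect_equal(est$ci_low_m, 0)        # lower envelope negative at 1 m
  expect_true(is.infinite(est$ci_high_m))  # upper envelope never crosses
})

test_that("the IEZ grid collapses unused trait dimensions", {
  m <- reference_models()
  grid_m <- iez_table(m$mammal,
                      bm_values = c(small = 100, large = 30000))
  expect_equal(nrow(grid_m), 2 * 2 * 2)  # bm x diet x habitat
  grid_a <- iez_table(m$amphibian)
  expect_equal(nrow(grid_a), 2)  # one row per habitat only
  expect_true(all(grid_a$diet_class == "-"))
  # the two-decimal amphibian quadratic has no real root (its exact
  # crossing near 27 m is only recoverable from full-precision
  # coefficients), so the zone is undefined here for both habitat rows
  expect_true(all(!grid_a$defined))
  expect_true(all(grid_a$sign_near == "-"))

  # bird cells are evaluated at paved roads
  grid_b <- iez_table(m$bird)
  expect_equal(nrow(grid_b), 4)  # diet x habitat
  carn_open <- grid_b[grid_b$diet_class == "carnivore" &
                        grid_b$habitat == "open", ]
  expect_true(carn_open$defined)
})
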