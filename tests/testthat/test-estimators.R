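test_that("Wald ratio and its delta-method SE are exact", {
  v <- list(beta_x = 0.5, se_x = 0.01, beta_y = 0.05, se_y = 0.01)
  e <- wald_ratio(v)
  expect_equal(e$theta, 0.1)
  expect_equal(e$se, 0.02)
  expect_equal(wald_ratio(list(beta_x = 0.5, se_y = 0.01,
                               beta_y = 0))$theta, 0)
  # joint sign flip leaves the ratio unchanged
  e2 <- wald_ratio(list(beta_x = -0.5, se_y = 0.01, beta_y = -0.05))
  expect_equal(e2$theta, e$theta)
  expect_error(wald_ratio(list(beta_x = 0, se_y = 1, beta_y = 1)),
               "beta_x = 0")
})

test_that("IVW reproduces exact proportionality and the worked example", {
  h <- make_h(beta_x = c(0.2, 0.5, 0.3), beta_y = c(0.02, 0.05, 0.03))
  e <- mr_ivw(h)
  expect_equal(e$theta, 0.1)
  expect_equal(e$extra$q, 0, tolerance = 1e-20)
  # frozen from the origin-constrained WLS oracle
  h2 <- harmonized_set(data.frame(
    variant_id = c("a", "b", "c"), beta_x = c(0.2, 0.5, 0.3),
    se_x = 0.01, beta_y = c(0.04, 0.11, 0.05),
    se_y = c(0.01, 0.02, 0.015)))
  expect_equal(mr_ivw(h2)$theta, 0.1994152046, tolerance = 1e-8)
  # permutation invariance
  perm <- harmonized_set(h2$variants[c(3, 1, 2), ])
  expect_equal(mr_ivw(perm)$theta, mr_ivw(h2)$theta)
  expect_error(mr_ivw(make_h(0.1, 0.01)), "at least 2")
})

test_that("IVW equals the brute-force weighted-regression oracle to 1e-12", {
  for (seed in 1:1000) {
    set.seed(seed)
    J <- sample(2:20, 1)
    bx <- rnorm(J, 0, 0.2); by <- rnorm(J, 0.1 * bx, 0.02)
    sey <- runif(J, 0.005, 0.05)
    h <- make_h(bx, by, se_y = sey)
    w <- 1 / sey^2
    oracle <- sum(bx * by * w) / sum(bx^2 * w)
    est <- mr_ivw(h)
    expect_equal(est$theta, oracle, tolerance = 1e-12)
    # fixed-effect SE against the closed form
    expect_equal(mr_ivw(h, "fixed")$se, 1 / sqrt(sum(bx^2 * w)),
                 tolerance = 1e-12)
  }
})

test_that("multiplicative floor never shrinks the SE below fixed-effect", {
  set.seed(5)
  for (r in 1:20) {
    J <- sample(3:15, 1)
    h <- make_h(rnorm(J, 0, 0.2), rnorm(J, 0, 0.05), se_y = 0.01)
    expect_gte(mr_ivw(h)$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("Egger recovers an exact linear relation with intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, 0.05 + 0.2 * bx)
  e <- mr_egger(h)
  expect_equal(e$theta, 0.2, tolerance = 1e-10)
  expect_equal(e$extra$intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$extra$q, 0, tolerance = 1e-16)
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.01, 0.02))),
               "at least 3")
})

test_that("Egger is invariant to per-variant sign flips (orientation)", {
  set.seed(9)
  bx <- runif(6, 0.05, 0.3); by <- 0.02 + 0.15 * bx + rnorm(6, 0, 0.005)
  h1 <- make_h(bx, by)
  flip <- c(1, -1, 1, -1, -1, 1)
  h2 <- make_h(flip * bx, flip * by)
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e1$theta, e2$theta)
  expect_equal(e1$extra$intercept, e2$extra$intercept)
  expect_equal(e1$se, e2$se)
})

test_that("Egger intercept is centered at zero under balanced pleiotropy", {
  cfgb <- sim_config(sigma_gamma = 0.1,
                     pleiotropy = pleiotropy_regime("balanced",
                                                    sigma_alpha = 0.005))
  ints <- vapply(1:500, function(r)
    mr_egger(simulate_harmonized(50, 0.1, cfgb,
                                 seed = 3500 + r))$extra$intercept,
    numeric(1))
  expect_lt(abs(mean(ints)), 0.001)
})

test_that("weighted median interpolates the 50% weighted quantile", {
  h <- make_h(rep(0.1, 3), 0.1 * c(0.1, 0.2, 0.3))
  e <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(e$theta, 0.2)
  # >50% of weight valid: estimate tracks the valid ratios
  bx <- rep(0.1, 10)
  by <- 0.1 * c(rep(0.1, 7), rep(1, 3))
  sey <- c(rep(0.005, 7), rep(0.05, 3))   # outliers carry low weight
  h2 <- make_h(bx, by, se_y = sey)
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$theta, 0.1,
               tolerance = 1e-6)
  expect_error(mr_weighted_median(make_h(c(.1, .2), c(.01, .02))),
               "at least 3")
})

test_that("weighted-median bootstrap SE is deterministic given the seed", {
  set.seed(33)
  h <- make_h(runif(8, 0.05, 0.3), rnorm(8, 0, 0.02))
  a <- mr_weighted_median(h, n_boot = 200, seed = 17)
  b <- mr_weighted_median(h, n_boot = 200, seed = 17)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(h, n_boot = 200, seed = 18)
  expect_false(identical(a$se, c$se))
})

test_that("maximum likelihood peaks at truth and matches IVW as se_x -> 0", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, 0.1 * bx, se_x = 1e-4, se_y = 1e-4)
  expect_equal(mr_max_likelihood(h)$theta, 0.1, tolerance = 1e-6)
  set.seed(12)
  J <- 20
  bx <- rnorm(J, 0, 0.2); by <- rnorm(J, 0.15 * bx, 0.01)
  h2 <- make_h(bx, by, se_x = 1e-8, se_y = 0.01)
  expect_equal(mr_max_likelihood(h2)$theta, mr_ivw(h2, "fixed")$theta,
               tolerance = 1e-6)
})

test_that("maximum likelihood recovers theta = 0.2 with strong instruments", {
  cfg <- sim_config(sigma_gamma = 0.1)
  est <- vapply(1:200, function(r)
    mr_max_likelihood(simulate_harmonized(50, 0.2, cfg,
                                          seed = 5000 + r))$theta,
    numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.02)
})

test_that("all estimators are scale-equivariant in the exposure", {
  set.seed(44)
  J <- 12
  bx <- rnorm(J, 0.1, 0.05); by <- rnorm(J, 0.1 * bx, 0.01)
  h1 <- make_h(bx, by, se_x = 0.01, se_y = 0.01)
  c_scale <- 3.7
  h2 <- make_h(c_scale * bx, by, se_x = c_scale * 0.01, se_y = 0.01)
  expect_equal(mr_ivw(h2)$theta, mr_ivw(h1)$theta / c_scale)
  expect_equal(mr_egger(h2)$theta, mr_egger(h1)$theta / c_scale)
  expect_equal(mr_max_likelihood(h2)$theta,
               mr_max_likelihood(h1)$theta / c_scale,
               tolerance = 1e-6)
  expect_equal(mr_weighted_median(h2, 100, seed = 2)$theta,
               mr_weighted_median(h1, 100, seed = 2)$theta / c_scale,
               tolerance = 1e-10)
})

test_that("odds-ratio conversion matches the closed form", {
  e0 <- effect_to_or(0, 0.1)
  expect_equal(e0$or_value, 1)
  expect_equal(e0$pval, 1)
  expect_equal(e0$ci_low * e0$ci_high, 1, tolerance = 1e-12)
  # frozen from exp(theta -+ z se); consistent with an OR printed as
  # 1.09 (1.04-1.14)
  e <- effect_to_or(0.08618, 0.02342)
  expect_equal(round(e$or_value, 2), 1.09)
  expect_equal(round(e$ci_low, 2), 1.04)
  expect_equal(round(e$ci_high, 2), 1.14)
  # wider interval at higher confidence, same OR
  e99 <- effect_to_or(0.08618, 0.02342, level = 0.99)
  expect_equal(e99$or_value, e$or_value)
  expect_lt(e99$ci_low, e$ci_low)
  expect_gt(e99$ci_high, e$ci_high)
})

test_that("mr_all_methods falls back and skips with notes at small J", {
  h1 <- make_h(0.2, 0.02)
  out <- mr_all_methods(h1, seed = 1)
  expect_equal(out$ivw$method, "wald")
  expect_match(attr(out, "notes"), "Wald ratio", all = FALSE)
  h2 <- make_h(c(0.2, 0.3), c(0.02, 0.03))
  out2 <- mr_all_methods(h2, seed = 1)
  expect_null(out2$egger)
  expect_true(any(grepl("inapplicable", attr(out2, "notes"))))
  expect_s3_class(out2$ivw, "mr_estimate")
})
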