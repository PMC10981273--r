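test_that("Wald ratio arithmetic and contracts", {
  h <- make_h(bx = 0.1, by = 0.2, sy = 0.1)
  e <- wald_ratio(h)
  expect_equal(e$beta, 2.0)
  expect_equal(e$se, 1.0)
  h0 <- make_h(bx = 0.1, by = 0, sy = 0.1)
  e0 <- wald_ratio(h0)
  expect_equal(e0$beta, 0)
  expect_equal(e0$pval, 1)
  expect_error(wald_ratio(make_h(bx = 0, by = 0.2, sy = 0.1)), "zero exposure beta")
  expect_error(wald_ratio(consistent_h()), "exactly one SNP")
})

test_that("IVW equals the weighted-least-squares oracle; Q = 0 on consistent ratios", {
  h <- consistent_h()
  e <- ivw(h, "fixed")
  expect_equal(e$beta, 2.0, tolerance = 1e-12)
  expect_equal(e$extras$q, 0, tolerance = 1e-12)
  expect_error(ivw(make_h(bx = 0.1, by = 0.2, sy = 0.1)), "at least 2")

  set.seed(42)
  bx <- rnorm(25, 0, 0.1); by <- 0.4 * bx + rnorm(25, 0, 0.02); sy <- runif(25, .01, .05)
  h2 <- make_h(bx, by, sy)
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  e2 <- ivw(h2, "fixed")
  expect_equal(e2$beta, unname(coef(fit)), tolerance = 1e-12)
  # fixed-effects se is the exact-weights se: lm's estimate divided by sigma
  expect_equal(e2$se, unname(summary(fit)$coefficients[1, 2] / summary(fit)$sigma),
               tolerance = 1e-10)
  er <- ivw(h2, "random")
  expect_gte(er$se, e2$se)

  # invariance to ordering and to joint sign flips
  perm <- sample(25)
  expect_equal(ivw(make_h(bx[perm], by[perm], sy[perm]), "fixed")$beta, e2$beta,
               tolerance = 1e-12)
  flip <- sample(c(-1, 1), 25, replace = TRUE)
  expect_equal(ivw(make_h(flip * bx, flip * by, sy), "fixed")$beta, e2$beta,
               tolerance = 1e-12)
})

test_that("maximum likelihood: noiseless limit, IVW limit, simulation agreement", {
  h <- make_h(bx = c(0.1, 0.2, 0.3), by = c(0.2, 0.4, 0.6), sy = 0.05)
  expect_equal(max_likelihood(h)$beta, 2.0, tolerance = 1e-6)

  set.seed(7)
  bx <- rnorm(30, 0, 0.1); by <- 0.3 * bx + rnorm(30, 0, 0.02)
  h2 <- make_h(bx, by, sy = rep(0.02, 30), sx = rep(1e-8, 30))
  ml <- max_likelihood(h2); iv <- ivw(h2, "fixed")
  expect_equal(ml$beta, iv$beta, tolerance = 1e-5)
  expect_equal(ml$se, iv$se, tolerance = 1e-4)

  st <- quick_study(12, m = 50)
  h3 <- harmonize(st$exposure, st$outcome, snp_ids = instrument_ids(st))
  ml3 <- max_likelihood(h3); iv3 <- ivw(h3, "fixed")
  expect_lt(abs(ml3$beta - iv3$beta), 2 * iv3$se)
})

test_that("Egger regression: exact fit, constant-pleiotropy construction, IVW reduction", {
  bx <- c(0.1, 0.2, 0.3)
  h <- make_h(bx, by = 0.5 * bx + 0.1, sy = 0.1)
  e <- egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extras$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$extras$sigma, 0, tolerance = 1e-8)

  # constant pleiotropy +c on every outcome beta: intercept = c, slope unbiased
  set.seed(3)
  bx2 <- abs(rnorm(40, 0, 0.1)); by2 <- 0.4 * bx2 + 0.02
  e2 <- egger(make_h(bx2, by2, sy = rep(0.03, 40)))
  expect_equal(e2$extras$egger_intercept, 0.02, tolerance = 1e-10)
  expect_equal(e2$beta, 0.4, tolerance = 1e-10)

  # when the fitted intercept is exactly 0, slope equals IVW
  bx3 <- c(0.1, 0.2, 0.4); by3 <- 0.7 * bx3
  e3 <- egger(make_h(bx3, by3, sy = 0.05))
  expect_equal(e3$extras$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(e3$beta, ivw(make_h(bx3, by3, sy = 0.05), "fixed")$beta,
               tolerance = 1e-10)
  expect_error(egger(make_h(bx = c(.1, .2), by = c(.1, .2), sy = .1)), "at least 3")
})

test_that("weighted median follows the stated interpolation rule", {
  # equal weights, ratios {1,2,9}: standardized cumulative weights hit 1/2
  # exactly at the middle ratio
  h <- make_h(bx = c(1, 1, 1), by = c(1, 2, 9), sy = c(1, 1, 1))
  expect_equal(weighted_median(h, boot_reps = 100, seed = 1)$beta, 2.0)

  # weights {0.5, 0.25, 0.25}: p = (0.25, 0.625, 0.875); interpolating to
  # 0.5 between ratios 1 and 2 gives 1 + (0.25/0.375) = 5/3
  sy <- c(sqrt(1 / 0.5), sqrt(1 / 0.25), sqrt(1 / 0.25))
  h2 <- make_h(bx = c(1, 1, 1), by = c(1, 2, 9), sy = sy)
  expect_equal(weighted_median(h2, boot_reps = 100, seed = 1)$beta, 5 / 3,
               tolerance = 1e-12)

  # bootstrap standard errors reproduce under a fixed seed
  st <- quick_study(9, m = 20)
  h3 <- harmonize(st$exposure, st$outcome, snp_ids = instrument_ids(st))
  a <- weighted_median(h3, boot_reps = 200, seed = 5)
  b <- weighted_median(h3, boot_reps = 200, seed = 5)
  expect_identical(a$se, b$se)
})

test_that("weighted median tolerates up to (but not beyond) 50% contamination", {
  set.seed(13)
  make_contaminated <- function(n_bad) {
    n <- 100
    bx <- rep(1, n)
    by <- c(rep(2, n - n_bad) + rnorm(n - n_bad, 0, 0.01), rep(5, n_bad))
    make_h(bx, by, sy = rep(0.5, n))
  }
  ok <- weighted_median(make_contaminated(49), boot_reps = 100, seed = 1)$beta
  bad <- weighted_median(make_contaminated(60), boot_reps = 100, seed = 1)$beta
  expect_lt(abs(ok - 2), 0.05)
  expect_gt(abs(bad - 2), 1)
})

test_that("weighted mode finds the dominant ratio cluster and is bandwidth-stable", {
  h <- make_h(bx = rep(1, 3), by = c(3, 3, 3), sy = rep(0.5, 3))
  e <- weighted_mode(h, boot_reps = 100, seed = 1)
  expect_equal(e$beta, 3)
  expect_equal(e$se, 0)

  set.seed(4)
  by <- c(2 + rnorm(7, 0, 0.01), 5, 8, -1)
  h2 <- make_h(bx = rep(1, 10), by = by, sy = rep(0.5, 10))
  e2 <- weighted_mode(h2, boot_reps = 100, seed = 1)
  expect_lt(abs(e2$beta - 2), 0.1)
  e3 <- weighted_mode(h2, bandwidth_factor = 2, boot_reps = 100, seed = 1)
  expect_lt(abs(e3$beta - 2), 0.1)
})

test_that("all estimators agree on noiseless proportional data", {
  bx <- c(0.08, 0.12, 0.2, 0.31, 0.4)
  h <- make_h(bx, by = 1.7 * bx, sy = rep(0.05, 5), sx = rep(1e-10, 5))
  expect_equal(ivw(h, "fixed")$beta, 1.7, tolerance = 1e-6)
  expect_equal(ivw(h, "random")$beta, 1.7, tolerance = 1e-6)
  expect_equal(max_likelihood(h)$beta, 1.7, tolerance = 1e-6)
  expect_equal(egger(h)$beta, 1.7, tolerance = 1e-6)
  expect_equal(weighted_median(h, boot_reps = 100, seed = 1)$beta, 1.7, tolerance = 1e-6)
  expect_equal(weighted_mode(h, boot_reps = 100, seed = 1)$beta, 1.7, tolerance = 1e-6)
  h1 <- make_h(bx = 0.2, by = 1.7 * 0.2, sy = 0.05)
  expect_equal(wald_ratio(h1)$beta, 1.7, tolerance = 1e-12)
  # OR scale is the exact exponential of the beta scale
  e <- ivw(h, "fixed")
  expect_equal(e$or, exp(e$beta), tolerance = 1e-12)
  expect_equal(c(e$or_ci_low, e$or_ci_high), exp(c(e$ci_low, e$ci_high)),
               tolerance = 1e-12)
})
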