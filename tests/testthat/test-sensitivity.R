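test_that("Cochran's Q is zero on consistent ratios and additive over consistent subsets", {
  q <- cochran_q(consistent_h())
  expect_equal(q$q_stat, 0, tolerance = 1e-12)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 2L)

  # two disjoint internally consistent sets with equal theta: union Q equals
  # the sum of within-set Qs (0) plus a non-negative between-set term (0 here)
  h1 <- make_h(bx = c(0.1, 0.2), by = c(0.2, 0.4), sy = c(0.1, 0.1))
  h2 <- make_h(bx = c(0.3, 0.4), by = c(0.6, 0.8), sy = c(0.2, 0.2),
               snp = c("rs003", "rs004"))
  hu <- make_h(bx = c(0.1, 0.2, 0.3, 0.4), by = c(0.2, 0.4, 0.6, 0.8),
               sy = c(0.1, 0.1, 0.2, 0.2))
  expect_equal(cochran_q(hu)$q_stat,
               cochran_q(h1)$q_stat + cochran_q(h2)$q_stat, tolerance = 1e-12)
  # different thetas: between-set term strictly positive
  hv <- make_h(bx = c(0.1, 0.2, 0.3, 0.4), by = c(0.2, 0.4, 0.9, 1.2),
               sy = c(0.1, 0.1, 0.2, 0.2))
  expect_gt(cochran_q(hv)$q_stat, 0)
  # zero-exposure-beta SNPs are excluded with a warning
  hz <- make_h(bx = c(0, 0.1, 0.2), by = c(0.5, 0.2, 0.4), sy = 0.1)
  expect_warning(qz <- cochran_q(hz), "zero exposure beta")
  expect_equal(qz$df, 1L)
})

test_that("Egger intercept test recovers constructed pleiotropy", {
  bx <- c(0.1, 0.2, 0.3)
  t1 <- egger_intercept_test(make_h(bx, by = 0.5 * bx + 0.1, sy = 0.1))
  expect_equal(t1$intercept, 0.1, tolerance = 1e-10)
  set.seed(5)
  bx2 <- abs(rnorm(50, 0, 0.1))
  by2 <- 0.3 * bx2 + 0.04 + rnorm(50, 0, 0.01)
  t2 <- egger_intercept_test(make_h(bx2, by2, sy = rep(0.01, 50)))
  expect_lt(abs(t2$intercept - 0.04), 0.01)
  expect_lt(t2$pval, 0.05)
})

test_that("MR-PRESSO is deterministic, flags the injected outlier first, and restores the global test", {
  st <- quick_study(17, m = 20)
  st <- inject_outliers(st, 1, 10 * median(st$outcome$se))
  h <- harmonize(st$exposure, st$outcome, snp_ids = instrument_ids(st))
  a <- mr_presso(h, n_sim = 300, seed = 8)
  b <- mr_presso(h, n_sim = 300, seed = 8)
  expect_identical(a, b)

  target <- st$truth$outlier_ids
  expect_identical(names(which.min(a$raw_outlier_p)), target)
  expect_lte(a$global_p, 0.05)
  expect_identical(a$removed[1], target)
  expect_gt(a$final_global_p, 0.05)
  expect_false(a$unresolved_pleiotropy)
  # removal trail is monotone non-decreasing in global p on this fixture
  expect_true(all(diff(c(a$global_p, a$removal_trail$global_p)) >= 0))
  # probabilities respect the +1 correction bounds
  expect_gte(a$global_p, 1 / 301)
  expect_true(all(a$raw_outlier_p >= 1 / 301 & a$raw_outlier_p <= 1))
  # input untouched
  expect_identical(h$beta_outcome,
                   harmonize(st$exposure, st$outcome,
                             snp_ids = instrument_ids(st))$beta_outcome)
  expect_error(mr_presso(h, n_sim = 50, seed = 1), "n_sim")
  expect_error(mr_presso(consistent_h(), n_sim = 300, seed = 1), "at least 4")
})

test_that("two opposite-signed outliers shift IVW and trip the global test", {
  st <- quick_study(23, m = 20)
  mag <- 10 * median(st$outcome$se)
  st2 <- inject_outliers(st, 2, c(mag, -mag))
  h0 <- harmonize(st$exposure, st$outcome, snp_ids = instrument_ids(st))
  h2 <- harmonize(st2$exposure, st2$outcome, snp_ids = instrument_ids(st2))
  pr <- mr_presso(h2, n_sim = 300, seed = 2)
  expect_lte(pr$global_p, 0.05)
  expect_true(all(st2$truth$outlier_ids %in% pr$removed))
  expect_gt(abs(ivw(h2, "fixed")$beta - ivw(h0, "fixed")$beta), 0)
})

test_that("leave-one-out isolates influential SNPs", {
  loo <- leave_one_out(consistent_h())
  expect_equal(nrow(loo$loo), 3)
  expect_equal(loo$loo$beta, rep(loo$all_snp_beta, 3), tolerance = 1e-12)

  # single outlier: excluding it moves the estimate the most, toward truth
  set.seed(2)
  bx <- rep(1, 10); by <- 2 * bx + rnorm(10, 0, 0.01)
  by[10] <- by[10] + 3
  h <- make_h(bx, by, sy = rep(0.5, 10))
  loo2 <- leave_one_out(h)
  shift <- abs(loo2$loo$beta - loo2$all_snp_beta)
  expect_equal(which.max(shift), 10L)
  expect_lt(abs(loo2$loo$beta[10] - 2), abs(loo2$all_snp_beta - 2))
})

test_that("Steiger direction compares total variance explained", {
  st <- quick_study(29, m = 30)
  h <- harmonize(st$exposure, st$outcome, snp_ids = instrument_ids(st))
  s <- steiger_direction(h)
  expect_true(s$direction_ok)
  expect_lt(s$pval, 0.05)

  # instruments chosen on the outcome in a reverse-causal panel: direction fails
  strev <- quick_study(30, m = 1, sigma_b = 0.03, n_reverse_snps = 40)
  cand <- intersect(suppressWarnings(filter_by_pvalue(strev$outcome, 1e-5)),
                    instrument_ids(strev, "reverse"))
  expect_gte(length(cand), 2)
  hr <- harmonize(strev$exposure, strev$outcome, snp_ids = cand)
  expect_false(steiger_direction(hr)$direction_ok)

  # zero outcome variance explained: direction holds trivially
  h0 <- make_h(bx = c(0.1, 0.2), by = c(0, 0), sy = 0.1)
  expect_true(steiger_direction(h0)$direction_ok)
})
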