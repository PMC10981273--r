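test_that("p-value filtering is strict and sorted", {
  ds <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.3, 0.2, 0.02), se = 0.05,
                      pval = c(1e-6, 2e-5, 0.3))
  expect_identical(filter_by_pvalue(ds, 1e-5), "rs1")
  ds2 <- make_sumstats(c("rs1", "rs2"), beta = 0.1, se = 0.05, pval = c(1e-5, 1e-5))
  expect_warning(out <- filter_by_pvalue(ds2, 1e-5), "no SNP")
  expect_length(out, 0)
  ds3 <- make_sumstats(c("rsB", "rsA"), beta = 0.1, se = 0.05, pval = c(1e-6, 1e-7))
  expect_identical(filter_by_pvalue(ds3, 1e-5), c("rsA", "rsB"))
})

test_that("outcome-associated SNPs are excluded with a strict cut", {
  outc <- make_sumstats(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.05,
                        pval = c(0.01, 0.5, 0.05), trait_name = "out")
  kept <- exclude_outcome_associated(c("rs1", "rs2", "rs3"), outc, 0.05)
  expect_identical(as.character(kept), c("rs2", "rs3"))  # 0.05 itself is kept
  expect_identical(attr(kept, "removed"), "rs1")
  expect_warning(exclude_outcome_associated(c("rs1", "rs9"), outc, 0.05), "absent")
})

test_that("greedy clumping respects window, r2 and p-value priority", {
  ds <- make_sumstats(c("rs1", "rs2"), beta = 0.1, se = 0.05, pval = c(1e-8, 1e-6),
                      chrom = "1", pos = c(1e6, 1e6 + 100e3))
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
              dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  ld <- ld_matrix(r)
  kept <- clump(c("rs1", "rs2"), ds, ld, r2_max = 0.01, window_kb = 500)
  expect_identical(as.character(kept), "rs1")
  expect_identical(attr(kept, "removed")$index_snp, "rs1")

  # 600 kb apart with a 500 kb window: both kept despite high r2
  ds2 <- make_sumstats(c("rs1", "rs2"), beta = 0.1, se = 0.05, pval = c(1e-8, 1e-6),
                       pos = c(1e6, 1e6 + 600e3))
  expect_identical(as.character(clump(c("rs1", "rs2"), ds2, ld, 0.01, 500)),
                   c("rs1", "rs2"))

  # mutually independent SNPs: all kept, in p-value order, input-order invariant
  ds3 <- make_sumstats(c("rsC", "rsA", "rsB"), beta = 0.1, se = 0.05,
                       pval = c(1e-6, 1e-8, 1e-7), pos = c(1e6, 2e6, 3e6))
  ld3 <- ld_matrix(diag(3), snp_ids = c("rsC", "rsA", "rsB"))
  expect_identical(as.character(clump(c("rsC", "rsA", "rsB"), ds3, ld3, 0.01, 500)),
                   c("rsA", "rsB", "rsC"))
  expect_identical(as.character(clump(c("rsB", "rsC", "rsA"), ds3, ld3, 0.01, 500)),
                   c("rsA", "rsB", "rsC"))
  expect_error(clump(c("rsA", "rsZ"), ds3, ld3, 0.01, 500), "rsZ")
})

test_that("the F statistic follows the printed formula", {
  # 16 SNPs each explaining 0.125% of variance: R2 = 0.02, n = 8299
  beta <- sqrt(0.00125 / (2 * 0.5 * 0.5))
  ds <- make_sumstats(sprintf("rs%02d", 1:16), beta = beta, se = 0.01,
                      eaf = 0.5, n = 8299)
  f <- compute_f_statistic(ds$snp, ds)
  expect_equal(f$r2_total, 0.02, tolerance = 1e-12)
  expect_equal(f$f, (0.02 * (8299 - 16 - 1)) / (16 * 0.98), tolerance = 1e-12)
  expect_equal(f$f, 10.5637755102041, tolerance = 1e-10)

  # R2 = 0.5, n = 103, k = 1 -> F = 101
  ds2 <- make_sumstats("rs1", beta = 1, se = 0.1, eaf = 0.5, n = 103)
  expect_equal(compute_f_statistic("rs1", ds2)$f, 101, tolerance = 1e-12)

  # zero effect: F = 0; monotone in R2
  ds3 <- make_sumstats("rs1", beta = 0, se = 0.1, eaf = 0.5, pval = 1, n = 103)
  expect_equal(compute_f_statistic("rs1", ds3)$f, 0)
  f_lo <- compute_f_statistic("rs1", make_sumstats("rs1", beta = 0.5, se = 0.1, eaf = 0.5, n = 103))$f
  f_hi <- compute_f_statistic("rs1", make_sumstats("rs1", beta = 0.8, se = 0.1, eaf = 0.5, n = 103))$f
  expect_gt(f_hi, f_lo)
})

test_that("Steiger filtering removes SNPs explaining more outcome variance", {
  h <- make_h(bx = c(0.1, 0.01), by = c(0.03, 0.1), sy = 0.02)
  kept <- steiger_filter(h)
  expect_identical(as.character(kept), "rs001")
  expect_identical(attr(kept, "removed"), "rs002")
  # significance gate: tiny samples fall back to point comparison
  h$n_exposure <- 3; h$n_outcome <- 3
  expect_warning(steiger_filter(h, significance_gate = 0.05), "n <= 3")
})

test_that("selection fates partition the SNP panel and match the pipeline output", {
  st <- quick_study(31, m = 40, n_null_snps = 20)
  cfg <- selection_config(presso_nsim = 200)
  sel <- select_instruments(st$exposure, st$outcome, config = cfg, seed = 4)
  expect_setequal(sel$fates$snp, st$exposure$snp)
  expect_identical(anyDuplicated(sel$fates$snp), 0L)
  expect_setequal(sel$fates$snp[sel$fates$fate == "kept"], sel$kept)
  # order-faithful: applying rules 1-2 by hand reproduces the upstream fates
  cand <- suppressWarnings(filter_by_pvalue(st$exposure, cfg$p_exposure_threshold))
  expect_setequal(sel$fates$snp[sel$fates$fate == "fail_pthresh"],
                  setdiff(st$exposure$snp, cand))
  cand2 <- exclude_outcome_associated(cand, st$outcome, cfg$p_outcome_exclude)
  expect_setequal(sel$fates$snp[sel$fates$fate == "fail_outcome_assoc"],
                  attr(cand2, "removed"))
})
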