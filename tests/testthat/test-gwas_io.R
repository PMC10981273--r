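test_that("summary stats round-trip through the TSV dialect", {
  ds <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.25, 1e-3),
                      se = c(0.01, 0.02, 0.3), eaf = c(0.12, 0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  back <- read_summary_stats(path, trait_name = "trait")
  expect_equal(nrow(back), 3)
  expect_identical(back$snp, ds$snp)
  expect_identical(back$effect_allele, ds$effect_allele)
  for (col in c("beta", "se", "pval", "eaf", "pos", "n"))
    expect_equal(back[[col]], ds[[col]], tolerance = 1e-12)
})

test_that("rows lacking beta or se are dropped and counted; bad headers and values error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0.01\t0.5",
               "rs2\tA\tG\t0.2\t\t0.5",
               "rs3\tC\tT\t-0.1\t0.02\t0.9"), path)
  ds <- read_summary_stats(path)
  expect_equal(nrow(ds), 2)
  expect_equal(attr(ds, "n_dropped"), 1)

  writeLines(c("SNP\tEA\tOA\tSE\tP", "rs1\tA\tG\t0.01\t0.5"), path)
  expect_error(read_summary_stats(path), "required column 'beta'")

  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP", "rs1\tA\tG\toops\t0.01\t0.5"), path)
  expect_error(read_summary_stats(path), "non-numeric beta.*line 2")
})

test_that("harmonization flips swapped alleles, preserves magnitudes, is idempotent", {
  expo <- make_sumstats("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "G", eaf = 0.3)
  outc <- make_sumstats("rs1", beta = -0.2, se = 0.05, ea = "G", oa = "A", eaf = 0.7,
                        trait_name = "out")
  h <- harmonize(expo, outc)
  expect_equal(h$beta_outcome, 0.2)
  expect_equal(h$eaf_outcome, 0.3)

  # magnitude preservation + idempotence on a random panel with mixed orders
  set.seed(11)
  k <- 20
  flip <- rep(c(FALSE, TRUE), length.out = k)
  snp <- sprintf("rs%02d", 1:k)
  expo <- make_sumstats(snp, beta = rnorm(k), se = 0.05, eaf = runif(k, .1, .4))
  outc <- make_sumstats(snp, beta = rnorm(k), se = 0.05,
                        ea = ifelse(flip, "G", "A"), oa = ifelse(flip, "A", "G"),
                        eaf = runif(k), trait_name = "out")
  h1 <- harmonize(expo, outc)
  oi <- match(h1$snp_ids, outc$snp)
  expect_equal(abs(h1$beta_outcome), abs(outc$beta[oi]))
  # rebuild the aligned outcome dataset and harmonize again: fixed point
  outc2 <- make_sumstats(h1$snp_ids, beta = h1$beta_outcome, se = 0.05,
                         eaf = h1$eaf_outcome, trait_name = "out")
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_identical(h2$snp_ids, h1$snp_ids)
})

test_that("palindromic SNPs follow the policy and ambiguity band", {
  expo <- make_sumstats("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "T", eaf = 0.10)
  outc <- make_sumstats("rs1", beta = 0.2, se = 0.05, ea = "A", oa = "T", eaf = 0.12,
                        trait_name = "out")
  expect_error(harmonize(expo, outc, palindromic_policy = "drop"),
               "empty instrument set")
  h <- harmonize(expo, outc, palindromic_policy = "keep_if_eaf_informative")
  expect_equal(h$beta_outcome, 0.2)  # retained unflipped
  # inside the ambiguity band: dropped even under the keep policy
  expo2 <- make_sumstats("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "T", eaf = 0.50)
  outc2 <- make_sumstats("rs1", beta = 0.2, se = 0.05, ea = "A", oa = "T", eaf = 0.49,
                         trait_name = "out")
  expect_error(harmonize(expo2, outc2, palindromic_policy = "keep_if_eaf_informative"),
               "empty instrument set")
})

test_that("irreconcilable alleles are excluded with a reason; empty overlap errors", {
  expo <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02)
  outc <- make_sumstats(c("rs1", "rs2"), beta = c(0.3, 0.4), se = 0.05,
                        ea = c("A", "C"), oa = c("G", "T"), trait_name = "out")
  h <- harmonize(expo, outc)
  expect_identical(h$snp_ids, "rs1")
  expect_identical(h$excluded$reason, "allele_mismatch")
  outc2 <- make_sumstats("rs9", beta = 0.3, se = 0.05, trait_name = "out")
  expect_error(harmonize(expo, outc2), "empty instrument set")
})

test_that("LD matrices validate symmetry, range and squareness", {
  r <- diag(2); rownames(r) <- colnames(r) <- c("rs1", "rs2")
  expect_s3_class(ld_matrix(r), "ld_matrix")
  path <- withr::local_tempfile(fileext = ".tsv")
  m3 <- matrix(0.9, 3, 3); diag(m3) <- 1
  rownames(m3) <- colnames(m3) <- c("rs1", "rs2", "rs3")
  write_ld_matrix(ld_matrix(m3), path)
  back <- read_ld_matrix(path)
  expect_equal(back$r, ld_matrix(m3)$r, tolerance = 1e-12)

  bad <- r; bad[1, 2] <- 0.5; bad[2, 1] <- 0.4
  expect_error(ld_matrix(bad), "asymmetry")
  expect_error(ld_matrix(matrix(0.5, 2, 3)), "square")
  toob <- matrix(c(1, 1.1, 1.1, 1), 2); rownames(toob) <- colnames(toob) <- c("a", "b")
  expect_error(ld_matrix(toob), "exceeds 1")
})
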