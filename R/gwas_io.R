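#' Construct a GWAS summary-statistics dataset
#'
#' A `summary_dataset` holds one trait's per-SNP associations: alleles,
#' effect-allele frequency, effect size (`beta`, a log odds ratio for binary
#' traits), standard error, p-value and sample size. It is the unit every
#' other module consumes.
#'
#' @param data data.frame with columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. `chrom`/`pos`/`eaf`/`n`
#'   may be `NA`; the rest are required. Positions are 1-based.
#' @param trait_name character scalar.
#' @param trait_category one of `"microbiota"`, `"metabolite"`, `"blood_cell"`,
#'   `"immune_cell"`, `"cytokine"`, `"obesity"`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A `summary_dataset` (data.frame subclass with trait attributes).
#' @export
summary_dataset <- function(data, trait_name = "trait",
                            trait_category = c("microbiota", "metabolite",
                                               "blood_cell", "immune_cell",
                                               "cytokine", "obesity"),
                            trait_type = c("continuous", "binary")) {
  trait_category <- match.arg(trait_category)
  trait_type <- match.arg(trait_type)
  needed <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stopf("summary_dataset: missing column(s): %s", paste(miss, collapse = ", "))
  for (opt in c("chrom", "pos", "eaf", "n")) if (!opt %in% names(data)) data[[opt]] <- NA
  data <- data[, c("snp", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")]
  data$snp <- as.character(data$snp)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  if (anyDuplicated(data$snp)) stopf("summary_dataset: duplicated snp ids")
  bad_allele <- !(data$effect_allele %in% c("A", "C", "G", "T")) |
    !(data$other_allele %in% c("A", "C", "G", "T")) |
    data$effect_allele == data$other_allele
  if (any(bad_allele)) stopf("summary_dataset: invalid allele pair for %s",
                             paste(utils::head(data$snp[bad_allele], 3), collapse = ", "))
  if (any(data$se <= 0, na.rm = TRUE)) stopf("summary_dataset: se must be > 0")
  if (any(data$pval <= 0 | data$pval > 1, na.rm = TRUE)) stopf("summary_dataset: pval must lie in (0, 1]")
  if (any(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1))) stopf("summary_dataset: eaf must lie in [0, 1]")
  rownames(data) <- NULL
  structure(data,
            trait_name = trait_name, trait_category = trait_category,
            trait_type = trait_type,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s, %s): %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_category"),
              attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Default column-name mapping for summary-statistics files
#'
#' Maps internal field names to the documented default header set
#' (SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N).
#' @return Named character vector (internal name -> file header).
#' @export
default_column_map <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pval = "P", n = "N")
}

#' Read tab-delimited GWAS summary statistics
#'
#' Rows with missing `beta` or `se` are dropped; the drop count is stored in
#' attribute `n_dropped`. A required column that cannot be resolved through
#' `column_map` is a configuration error; a non-numeric `beta`/`se` value is
#' a parse error reported with its line number.
#'
#' @param path file path to a tab-delimited table with a header row.
#' @param column_map named character vector mapping internal field names to
#'   file headers (see [default_column_map()]).
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               trait_name = basename(path),
                               trait_category = "microbiota",
                               trait_type = "continuous") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  cols <- list()
  for (field in names(default_column_map())) {
    header <- if (field %in% names(column_map)) column_map[[field]] else default_column_map()[[field]]
    if (header %in% names(raw)) {
      cols[[field]] <- raw[[header]]
    } else if (field %in% required) {
      stopf("read_summary_stats: required column '%s' (mapped to header '%s') not found in %s",
            field, header, path)
    } else {
      cols[[field]] <- rep(NA_character_, nrow(raw))
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  for (field in c("pos", "eaf", "beta", "se", "pval", "n")) {
    txt <- df[[field]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & txt != "NA" & is.na(num))
    if (length(bad) && field %in% c("beta", "se")) {
      stopf("read_summary_stats: non-numeric %s value '%s' at line %d of %s",
            field, txt[bad[1]], bad[1] + 1L, path)
    }
    df[[field]] <- num
  }
  drop <- is.na(df$beta) | is.na(df$se)
  out <- summary_dataset(df[!drop, , drop = FALSE], trait_name = trait_name,
                         trait_category = trait_category, trait_type = trait_type)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write a summary dataset in the same tab-delimited dialect it is read in
#' @param x a [summary_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_dataset"))
  df <- as.data.frame(x)
  names(df) <- unname(default_column_map()[names(df)])
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

align_to_exposure <- function(e_ea, e_oa, rec) {
  # Returns list(action = "keep"|"flip"|"mismatch")
  if (rec$effect_allele == e_ea && rec$other_allele == e_oa) return("keep")
  if (rec$effect_allele == e_oa && rec$other_allele == e_ea) return("flip")
  "mismatch"
}

eaf_informative <- function(eaf1, eaf2, band = c(0.42, 0.58)) {
  if (is.na(eaf1) || is.na(eaf2)) return(FALSE)
  same_side <- (eaf1 - 0.5) * (eaf2 - 0.5) > 0
  outside <- (eaf1 < band[1] | eaf1 > band[2]) && (eaf2 < band[1] | eaf2 > band[2])
  isTRUE(same_side && outside)
}

#' Harmonize exposure and outcome datasets onto a shared effect allele
#'
#' For each SNP the outcome (and any covariate-exposure) record is aligned to
#' the exposure's effect allele: when the outcome lists the alleles in the
#' opposite order its beta is sign-flipped and its frequency complemented.
#' Palindromic (A/T, C/G) SNPs are strand-ambiguous and handled per policy:
#' `"drop"` removes them; `"keep_if_eaf_informative"` keeps a palindromic SNP
#' only when both allele frequencies fall on the same side of 0.5 and outside
#' the ambiguity band [0.42, 0.58]. Allele pairs that neither match nor flip
#' are excluded with a reason code. Harmonization only ever changes the sign
#' of a beta, never its magnitude, and is idempotent.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param snp_ids SNPs to harmonize (default: intersection, exposure order).
#' @param palindromic_policy `"drop"` or `"keep_if_eaf_informative"`.
#' @param covariates optional named list of additional exposure
#'   [summary_dataset()]s (for multivariable MR); SNPs missing in any
#'   covariate are excluded with reason `missing_in_covariate`.
#' @return A `harmonized_set`: list with `snp_ids`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf`, `eaf_outcome`,
#'   optional `beta_covariates`/`se_covariates` matrices, `palindromic_dropped`,
#'   `excluded` (data.frame of snp/reason), and `n_exposure`/`n_outcome`
#'   median sample sizes.
#' @export
harmonize <- function(exposure, outcome, snp_ids = NULL,
                      palindromic_policy = c("drop", "keep_if_eaf_informative"),
                      covariates = NULL) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(inherits(exposure, "summary_dataset"), inherits(outcome, "summary_dataset"))
  if (is.null(snp_ids)) snp_ids <- intersect(exposure$snp, outcome$snp)
  snp_ids <- snp_ids[snp_ids %in% exposure$snp & snp_ids %in% outcome$snp]
  if (!length(snp_ids)) stopf("harmonize: empty instrument set (no shared SNPs)")
  ei <- match(snp_ids, exposure$snp)
  oi <- match(snp_ids, outcome$snp)
  cov_idx <- NULL
  if (!is.null(covariates)) {
    cov_idx <- lapply(covariates, function(d) match(snp_ids, d$snp))
  }

  keep <- logical(length(snp_ids))
  flip_out <- logical(length(snp_ids))
  flip_cov <- if (is.null(covariates)) NULL else
    matrix(FALSE, length(snp_ids), length(covariates))
  pal_dropped <- character(0)
  excluded <- data.frame(snp = character(0), reason = character(0))

  for (i in seq_along(snp_ids)) {
    e <- exposure[ei[i], ]
    o <- outcome[oi[i], ]
    act <- align_to_exposure(e$effect_allele, e$other_allele, o)
    if (act == "mismatch") {
      excluded <- rbind(excluded, data.frame(snp = snp_ids[i], reason = "allele_mismatch"))
      next
    }
    o_eaf_aligned <- if (act == "flip") 1 - o$eaf else o$eaf
    if (is_palindromic(e$effect_allele, e$other_allele)) {
      ok <- palindromic_policy == "keep_if_eaf_informative" &&
        eaf_informative(e$eaf, o_eaf_aligned)
      if (!ok) {
        pal_dropped <- c(pal_dropped, snp_ids[i])
        next
      }
    }
    # align any covariate exposures the same way
    cov_ok <- TRUE
    if (!is.null(covariates)) {
      for (ci in seq_along(covariates)) {
        j <- cov_idx[[ci]][i]
        if (is.na(j)) { cov_ok <- FALSE; break }
        cact <- align_to_exposure(e$effect_allele, e$other_allele, covariates[[ci]][j, ])
        if (cact == "mismatch") { cov_ok <- FALSE; break }
        flip_cov[i, ci] <- cact == "flip"
      }
    }
    if (!cov_ok) {
      excluded <- rbind(excluded, data.frame(snp = snp_ids[i], reason = "missing_in_covariate"))
      next
    }
    keep[i] <- TRUE
    flip_out[i] <- act == "flip"
  }

  if (!any(keep)) stopf("harmonize: empty instrument set after allele alignment")
  idx <- which(keep)
  sgn <- ifelse(flip_out[idx], -1, 1)
  h <- list(
    snp_ids = snp_ids[idx],
    beta_exposure = exposure$beta[ei[idx]],
    se_exposure = exposure$se[ei[idx]],
    beta_outcome = sgn * outcome$beta[oi[idx]],
    se_outcome = outcome$se[oi[idx]],
    eaf = exposure$eaf[ei[idx]],
    eaf_outcome = ifelse(flip_out[idx], 1 - outcome$eaf[oi[idx]], outcome$eaf[oi[idx]]),
    pval_exposure = exposure$pval[ei[idx]],
    pval_outcome = outcome$pval[oi[idx]],
    palindromic_dropped = pal_dropped,
    excluded = excluded,
    n_exposure = stats::median(exposure$n, na.rm = TRUE),
    n_outcome = stats::median(outcome$n, na.rm = TRUE),
    exposure_name = attr(exposure, "trait_name"),
    outcome_name = attr(outcome, "trait_name"),
    exposure_category = attr(exposure, "trait_category"),
    outcome_type = attr(outcome, "trait_type")
  )
  if (!is.null(covariates)) {
    nm <- names(covariates) %||% paste0("covariate", seq_along(covariates))
    bc <- sapply(seq_along(covariates), function(ci) {
      j <- cov_idx[[ci]][idx]
      ifelse(flip_cov[idx, ci], -1, 1) * covariates[[ci]]$beta[j]
    })
    sc <- sapply(seq_along(covariates), function(ci) covariates[[ci]]$se[cov_idx[[ci]][idx]])
    h$beta_covariates <- matrix(bc, ncol = length(covariates), dimnames = list(NULL, nm))
    h$se_covariates <- matrix(sc, ncol = length(covariates), dimnames = list(NULL, nm))
    h$covariate_names <- nm
  }
  structure(h, class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d SNPs (%d palindromic dropped, %d excluded)\n",
              x$exposure_name %||% "exposure", x$outcome_name %||% "outcome",
              length(x$snp_ids), length(x$palindromic_dropped), nrow(x$excluded)))
  invisible(x)
}

# Restrict a harmonized set to a subset / reordering of its SNPs.
subset_harmonized <- function(h, idx) {
  if (is.character(idx)) idx <- match(idx, h$snp_ids)
  for (f in c("snp_ids", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome", "eaf", "eaf_outcome", "pval_exposure", "pval_outcome")) {
    if (!is.null(h[[f]])) h[[f]] <- h[[f]][idx]
  }
  for (f in c("beta_covariates", "se_covariates")) {
    if (!is.null(h[[f]])) h[[f]] <- h[[f]][idx, , drop = FALSE]
  }
  h
}

#' Construct a validated LD matrix
#'
#' @param r square numeric matrix of pairwise LD correlations, symmetric to
#'   1e-8, unit diagonal, entries in [-1, 1].
#' @param snp_ids row/column SNP ids.
#' @param pos,chrom optional 1-based positions and chromosome labels.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r), pos = NULL, chrom = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stopf("ld_matrix: matrix is not square (%d x %d)", nrow(r), ncol(r))
  if (is.null(snp_ids) || length(snp_ids) != nrow(r)) stopf("ld_matrix: snp ids do not label the matrix")
  if (max(abs(r - t(r))) > 1e-8) stopf("ld_matrix: asymmetry exceeds 1e-8")
  if (any(abs(r) > 1 + 1e-9)) stopf("ld_matrix: |r| exceeds 1")
  if (max(abs(diag(r) - 1)) > 1e-8) stopf("ld_matrix: diagonal must be 1")
  r <- (r + t(r)) / 2
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r = r, pos = pos, chrom = chrom),
            class = "ld_matrix")
}

#' Read an LD matrix from a TSV with SNP-id header row and column
#' @param path file path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(raw), snp_ids = rownames(raw))
}

#' Write an LD matrix in the dialect [read_ld_matrix()] reads
#' @param x an [ld_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  stopifnot(inherits(x, "ld_matrix"))
  df <- data.frame(SNP = x$snp_ids, x$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
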