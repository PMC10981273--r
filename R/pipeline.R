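# End-to-end orchestration: pair-level MR with the full sensitivity battery,
# forward/reverse runs over many pairs, two-step mediation, and report
# rendering.

#' Analyse one exposure-outcome pair end to end
#'
#' Runs instrument selection ([select_instruments()]), the estimator battery
#' ([mr_all_methods()]; one SNP dispatches to the Wald ratio, two or more to
#' the full set with IVW as the primary method), and the sensitivity
#' diagnostics (Cochran's Q, Egger intercept, MR-PRESSO from the selection
#' step, leave-one-out, Steiger direction). The pair qualifies for
#' downstream mediation only when the primary IVW p is below 0.05 with no
#' heterogeneity (Q p >= 0.05) and no pleiotropy (Egger intercept p >= 0.05
#' and MR-PRESSO global p > 0.05).
#'
#' @param exposure,outcome [summary_dataset()]s.
#' @param ld optional [ld_matrix()].
#' @param config a [selection_config()].
#' @param seed integer seed for stochastic stages.
#' @param boot_reps bootstrap replicates for median/mode standard errors.
#' @return A `pair_result` list: `exposure`, `outcome`, `untestable`,
#'   `kept`, `fates`, `f_stat`, `estimates`, `primary` (method name),
#'   `primary_p`, `heterogeneity`, `egger_intercept`, `presso`,
#'   `leave_one_out`, `steiger`, `advance` (mediation gate), `h`.
#' @export
mr_analyze <- function(exposure, outcome, ld = NULL, config = selection_config(),
                       seed = 1, boot_reps = 1000) {
  sel <- select_instruments(exposure, outcome, ld = ld, config = config, seed = seed)
  base <- list(exposure = attr(exposure, "trait_name"),
               outcome = attr(outcome, "trait_name"),
               exposure_category = attr(exposure, "trait_category"),
               fates = sel$fates, kept = sel$kept, f_stat = sel$f_stat,
               presso = sel$presso)
  if (!length(sel$kept)) {
    return(structure(c(base, list(untestable = TRUE, advance = FALSE,
                                  estimates = list(), primary_p = NA_real_)),
                     class = "pair_result"))
  }
  h <- sel$h
  k <- length(h$snp_ids)
  est <- mr_all_methods(h, "auto", boot_reps = boot_reps, seed = seed)
  primary <- if (k == 1) "wald_ratio" else "ivw"
  primary_p <- est[[primary]]$pval
  het <- if (k >= 2) cochran_q(h) else NULL
  eit <- if (k >= 3) egger_intercept_test(h) else NULL
  loo <- if (k >= 3) leave_one_out(h) else NULL
  steiger <- if (!anyNA(h$eaf)) steiger_direction(h) else NULL
  presso_p <- if (!is.null(sel$presso)) sel$presso$final_global_p else NA_real_
  advance <- isTRUE(primary_p < 0.05) &&
    (is.null(het) || het$pval >= 0.05) &&
    (is.null(eit) || eit$pval >= 0.05) &&
    (is.na(presso_p) || presso_p > 0.05)
  structure(c(base, list(
    untestable = FALSE, h = h, estimates = est,
    primary = primary, primary_p = primary_p,
    heterogeneity = het, egger_intercept = eit,
    leave_one_out = loo, steiger = steiger, advance = advance
  )), class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("<pair_result> %s -> %s: %s\n", x$exposure, x$outcome,
              if (isTRUE(x$untestable)) "untestable (no instruments)" else
                sprintf("%d instruments, primary p = %.3g, advance = %s",
                        length(x$kept), x$primary_p, x$advance)))
  invisible(x)
}

#' Run forward MR over exposure-outcome pairs with FDR tiering
#'
#' Every exposure is tested against every outcome via [mr_analyze()]; the
#' primary (IVW or Wald-ratio) p-values are then BH-adjusted within strata
#' (exposure trait-category crossed with outcome trait by default, or a
#' single pooled stratum) and tiered significant / suggestive / null.
#' Pairs with no surviving instruments are reported untestable and the run
#' continues.
#'
#' @param exposures a [summary_dataset()] or list of them.
#' @param outcomes a [summary_dataset()] or list of them.
#' @param ld optional [ld_matrix()] shared by all pairs.
#' @param config a [selection_config()].
#' @param seed integer seed.
#' @param boot_reps bootstrap replicates for median/mode.
#' @param fdr_strata `"category-outcome"` (default) or `"pooled"`.
#' @return A `study_result`: list of `pairs`, `tiers` data.frame, `config`.
#' @export
run_forward <- function(exposures, outcomes, ld = NULL,
                        config = selection_config(), seed = 1,
                        boot_reps = 1000,
                        fdr_strata = c("category-outcome", "pooled")) {
  fdr_strata <- match.arg(fdr_strata)
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  if (inherits(outcomes, "summary_dataset")) outcomes <- list(outcomes)
  pairs <- list()
  i <- 0L
  for (outc in outcomes) for (expo in exposures) {
    i <- i + 1L
    pairs[[i]] <- mr_analyze(expo, outc, ld = ld, config = config,
                             seed = split_seed(seed, i), boot_reps = boot_reps)
  }
  testable <- !vapply(pairs, function(p) isTRUE(p$untestable), TRUE)
  tiers <- NULL
  if (any(testable)) {
    idx <- which(testable)
    pv <- vapply(pairs[idx], `[[`, numeric(1), "primary_p")
    strat <- if (fdr_strata == "pooled") "all" else
      vapply(pairs[idx], function(p) paste(p$exposure_category, p$outcome, sep = ":"), "")
    tiers <- cbind(data.frame(exposure = vapply(pairs[idx], `[[`, "", "exposure"),
                              outcome = vapply(pairs[idx], `[[`, "", "outcome")),
                   assign_tiers(pv, strat))
    for (j in seq_along(idx)) pairs[[idx[j]]]$tier <- tiers$tier[j]
  }
  structure(list(pairs = pairs, tiers = tiers, config = config, seed = seed),
            class = "study_result")
}

#' Run reverse MR (roles swapped)
#'
#' Identical machinery to [run_forward()] with exposures and outcomes
#' exchanged: the former outcomes supply the instruments. Large-GWAS
#' exposures typically warrant the genome-wide 5e-8 instrument threshold;
#' pass a [selection_config()] accordingly.
#'
#' @inheritParams run_forward
#' @return A `study_result` (see [run_forward()]).
#' @export
run_reverse <- function(exposures, outcomes, ld = NULL,
                        config = selection_config(), seed = 1,
                        boot_reps = 1000, fdr_strata = "category-outcome") {
  run_forward(exposures = outcomes, outcomes = exposures, ld = ld,
              config = config, seed = seed, boot_reps = boot_reps,
              fdr_strata = fdr_strata)
}

#' Two-step MR mediation for an exposure-mediator-outcome triple
#'
#' Step A estimates exposure -> mediator by univariable MR on the
#' exposure's instruments. Step B estimates the mediator's effect on the
#' outcome conditional on the exposure by multivariable IVW over the union
#' of the exposure's and the mediator's selected instruments (re-harmonized
#' jointly; SNPs missing in any trait are dropped and counted). The
#' decomposition and evidence tier come from [mediation_summary()]. The
#' triple is only evaluated when the total-effect pair passes the
#' no-heterogeneity / no-pleiotropy gate (`forward_pair$advance`); a
#' mediator with no instruments of its own is skipped with a reason.
#'
#' @param exposure,mediator,outcome [summary_dataset()]s, or pass a
#'   `simulated_study` as `exposure` to unpack all three.
#' @param ld optional [ld_matrix()].
#' @param config a [selection_config()].
#' @param seed integer seed.
#' @param boot_reps bootstrap replicates.
#' @param forward_pair optional precomputed [mr_analyze()] result for the
#'   exposure-outcome pair (avoids recomputation in pipeline runs).
#' @return A `mediation_result` (see [mediation_summary()]) with the
#'   step A/B fits attached, or a list with `skipped = TRUE` and a `reason`
#'   when the triple does not qualify.
#' @export
run_mediation <- function(exposure, mediator = NULL, outcome = NULL, ld = NULL,
                          config = selection_config(), seed = 1,
                          boot_reps = 1000, forward_pair = NULL) {
  if (inherits(exposure, "simulated_study")) {
    study <- exposure
    mediator <- study$mediator; outcome <- study$outcome
    ld <- ld %||% study$ld
    exposure <- study$exposure
  }
  if (is.null(forward_pair))
    forward_pair <- mr_analyze(exposure, outcome, ld = ld, config = config,
                               seed = split_seed(seed, 1L), boot_reps = boot_reps)
  if (isTRUE(forward_pair$untestable) || !isTRUE(forward_pair$advance))
    return(list(skipped = TRUE, reason = "exposure-outcome pair fails the screening gate"))
  total <- forward_pair$estimates[[forward_pair$primary]]

  step_a_pair <- mr_analyze(exposure, mediator, ld = ld, config = config,
                            seed = split_seed(seed, 2L), boot_reps = boot_reps)
  if (isTRUE(step_a_pair$untestable))
    return(list(skipped = TRUE, reason = "no instruments for exposure -> mediator"))
  step_a <- step_a_pair$estimates[[step_a_pair$primary]]

  med_iv <- suppressWarnings(filter_by_pvalue(mediator, config$p_exposure_threshold))
  if (!length(med_iv))
    return(list(skipped = TRUE, reason = "mediator has no instruments"))
  if (!is.null(ld) && length(med_iv) > 1) {
    med_iv <- as.character(clump(med_iv[med_iv %in% ld$snp_ids], mediator, ld,
                                 config$clump_r2, config$clump_window_kb))
  }
  union_iv <- union(forward_pair$kept, med_iv)
  hm <- tryCatch(
    harmonize(exposure, outcome, snp_ids = union_iv,
              covariates = list(mediator = mediator)),
    error = function(e) NULL)
  if (is.null(hm) || length(hm$snp_ids) < 3)
    return(list(skipped = TRUE, reason = "too few jointly harmonized SNPs for MVMR"))
  mvmr <- mvmr_ivw(hm)
  res <- mediation_summary(total, step_a, mvmr, mediator_name = "mediator",
                           exposure = attr(exposure, "trait_name"),
                           mediator = attr(mediator, "trait_name"),
                           outcome = attr(outcome, "trait_name"))
  res$step_a_pair <- step_a_pair
  res$mvmr <- mvmr
  res$forward_pair <- forward_pair
  res$n_snp_mvmr <- mvmr$n_snp
  res
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

#' Render report tables for a study result
#'
#' Writes `mr_table.tsv` (method-level estimates with OR scale, p, FDR tier),
#' `sensitivity_table.tsv` (Q, Egger intercept, MR-PRESSO, Steiger per
#' pair), and — when mediation results are supplied — `mediation_table.tsv`
#' in the mediation-table column order (Exposure, Mediator, Outcome, Total
#' effect, Direct effect, Mediation effect (95% CI), P-value, Mediation
#' Proportion (95% CI), Evidence). Row order is deterministic (exposure,
#' outcome, method), and OR columns are `exp(beta)` exactly.
#'
#' @param result a `study_result` from [run_forward()] / [run_reverse()].
#' @param dir output directory.
#' @param mediation optional list of `mediation_result`s.
#' @param fmt `"tsv"` or `"markdown"`.
#' @return Character vector of file paths written, invisibly.
#' @export
render_report <- function(result, dir, mediation = NULL, fmt = c("tsv", "markdown")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sep <- if (fmt == "tsv") "\t" else " | "
  ext <- if (fmt == "tsv") ".tsv" else ".md"

  mr_rows <- list(); sens_rows <- list()
  for (p in result$pairs) {
    if (isTRUE(p$untestable)) {
      sens_rows[[length(sens_rows) + 1]] <- data.frame(
        exposure = p$exposure, outcome = p$outcome, n_snp = 0L,
        q = NA, q_p = NA, egger_intercept = NA, egger_intercept_p = NA,
        presso_global_p = NA, steiger_ok = NA, note = "untestable")
      next
    }
    for (m in names(p$estimates)) {
      e <- p$estimates[[m]]
      mr_rows[[length(mr_rows) + 1]] <- data.frame(
        exposure = p$exposure, outcome = p$outcome, method = e$method,
        n_snp = e$n_snp, beta = e$beta, se = e$se,
        ci_low = e$ci_low, ci_high = e$ci_high,
        or = e$or, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
        pval = e$pval, tier = if (m == p$primary) p$tier %||% NA else NA)
    }
    sens_rows[[length(sens_rows) + 1]] <- data.frame(
      exposure = p$exposure, outcome = p$outcome, n_snp = length(p$kept),
      q = p$heterogeneity$q_stat %||% NA, q_p = p$heterogeneity$pval %||% NA,
      egger_intercept = p$egger_intercept$intercept %||% NA,
      egger_intercept_p = p$egger_intercept$pval %||% NA,
      presso_global_p = if (!is.null(p$presso)) p$presso$final_global_p else NA,
      steiger_ok = p$steiger$direction_ok %||% NA, note = "")
  }
  write_tbl <- function(rows, name) {
    path <- file.path(dir, paste0(name, ext))
    df <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(df)) {
      ord_cols <- intersect(c("exposure", "outcome", "method"), names(df))
      df <- df[do.call(order, unname(as.list(df[ord_cols]))), ]
      utils::write.table(format(df, digits = 12, trim = TRUE), path, sep = sep,
                         quote = FALSE, row.names = FALSE)
    } else {
      writeLines(paste(c("exposure", "outcome"), collapse = sep), path)
    }
    path
  }
  paths <- c(write_tbl(mr_rows, "mr_table"), write_tbl(sens_rows, "sensitivity_table"))

  if (!is.null(mediation)) {
    med_rows <- lapply(mediation, function(m) {
      if (isTRUE(m$skipped)) return(NULL)
      data.frame(
        Exposure = m$exposure, Mediator = m$mediator, Outcome = m$outcome,
        `Total effect` = fmt_num(m$total_effect),
        `Direct effect` = fmt_num(m$direct_effect),
        `Mediation effect (95% CI)` = sprintf("%s (%s, %s)", fmt_num(m$mediation_effect),
                                              fmt_num(m$ci_low), fmt_num(m$ci_high)),
        `P-value` = fmt_num(m$mediation_p),
        `Mediation Proportion (95% CI)` = if (is.null(m$proportion_ci))
          sprintf("%.2f%%", m$proportion) else
            sprintf("%.2f%% (%.2f%%, %.2f%%)", m$proportion,
                    m$proportion_ci[1], m$proportion_ci[2]),
        Evidence = m$evidence, check.names = FALSE)
    })
    med_rows <- Filter(Negate(is.null), med_rows)
    path <- file.path(dir, paste0("mediation_table", ext))
    if (length(med_rows)) {
      df <- do.call(rbind, med_rows)
      df <- df[order(df$Exposure, df$Outcome, df$Mediator), ]
      utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    } else {
      writeLines(paste(c("Exposure", "Mediator", "Outcome"), collapse = sep), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

run_config_keys <- c("p_exposure_threshold", "p_outcome_exclude", "clump_r2",
                     "clump_window_kb", "f_min", "presso_alpha", "presso_nsim",
                     "steiger_enabled", "seed", "boot_reps", "fdr_strata",
                     "palindromic_policy")

#' Read a flat key-value run configuration
#'
#' The file holds `key = value` lines (`#` comments allowed); unknown keys
#' are errors (silent misconfiguration being the main reproducibility
#' hazard). A seed is mandatory. The configuration round-trips losslessly
#' through [write_run_config()].
#'
#' @param path file path.
#' @return List with a [selection_config()] under `$selection` plus `seed`,
#'   `boot_reps`, `fdr_strata`, `palindromic_policy`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stopf("read_run_config: malformed line: '%s'", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  unknown <- setdiff(keys, run_config_keys)
  if (length(unknown)) stopf("read_run_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stopf("read_run_config: duplicated key(s)")
  get <- function(key, default, cast = as.numeric) {
    if (key %in% keys) cast(vals[keys == key]) else default
  }
  if (!"seed" %in% keys) stopf("read_run_config: 'seed' is mandatory")
  list(
    selection = selection_config(
      p_exposure_threshold = get("p_exposure_threshold", 1e-5),
      p_outcome_exclude = get("p_outcome_exclude", 0.05),
      clump_r2 = get("clump_r2", 0.001),
      clump_window_kb = get("clump_window_kb", 10000),
      f_min = get("f_min", 10),
      presso_alpha = get("presso_alpha", 0.05),
      presso_nsim = get("presso_nsim", 1000),
      steiger_enabled = get("steiger_enabled", TRUE, cast = as.logical)),
    seed = get("seed", NULL, cast = as.integer),
    boot_reps = get("boot_reps", 1000, cast = as.integer),
    fdr_strata = get("fdr_strata", "category-outcome", cast = identity),
    palindromic_policy = get("palindromic_policy", "drop", cast = identity)
  )
}

#' Write a run configuration in the dialect [read_run_config()] reads
#' @param cfg list as returned by [read_run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  s <- cfg$selection
  lines <- c(
    sprintf("p_exposure_threshold = %.17g", s$p_exposure_threshold),
    sprintf("p_outcome_exclude = %.17g", s$p_outcome_exclude),
    sprintf("clump_r2 = %.17g", s$clump_r2),
    sprintf("clump_window_kb = %.17g", s$clump_window_kb),
    sprintf("f_min = %.17g", s$f_min),
    sprintf("presso_alpha = %.17g", s$presso_alpha),
    sprintf("presso_nsim = %d", as.integer(s$presso_nsim)),
    sprintf("steiger_enabled = %s", s$steiger_enabled),
    sprintf("seed = %d", as.integer(cfg$seed)),
    sprintf("boot_reps = %d", as.integer(cfg$boot_reps %||% 1000)),
    sprintf("fdr_strata = %s", cfg$fdr_strata %||% "category-outcome"),
    sprintf("palindromic_policy = %s", cfg$palindromic_policy %||% "drop"))
  writeLines(lines, path)
  invisible(path)
}
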