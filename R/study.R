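#' Run one simulation replicate through the analysis methods
#'
#' Simulates a single cohort under a scenario, summarises it, and returns
#' the interaction-term p-value for each requested method. The twin model
#' and the PBI test always operate on per-individual mean outcomes and test
#' G x E; the linear mixed model uses all repeated measures and tests G x E
#' for average-channel scenarios and G x E x T (Wald on the three-way
#' product, full hierarchy below it) for change-channel scenarios. For
#' simulation fits the LMM uses the visit-index segmented-time rule so the
#' fitted fixed-effect model matches the generating one. Non-convergence of
#' a method yields `NA` for its p-value; the replicate is retained.
#'
#' @param scenario A [ge_scenario()].
#' @param methods Subset of `c("twin", "lmm", "pbi")`.
#' @param seed Integer seed for the replicate.
#' @param n_mz,n_dz Cohort size in pairs.
#' @param genetic_coding Coding for the regression methods.
#' @param B_perm PBI permutation count for this replicate.
#' @param min_visits Passed to [mean_over_time()].
#' @return Named numeric vector of p-values (`NA` where a method failed).
#' @examples
#' run_replicate(scenario_preset("null_average"), seed = 1, n_mz = 20,
#'               n_dz = 20, B_perm = 99)
#' @export
run_replicate <- function(scenario, methods = c("twin", "lmm", "pbi"),
                          seed = NULL, n_mz = 168, n_dz = 226,
                          genetic_coding = "additive", B_perm = 1000,
                          min_visits = 2) {
  methods <- match.arg(methods, c("twin", "lmm", "pbi"), several.ok = TRUE)
  rec <- simulate_cohort_data(scenario, n_mz = n_mz, n_dz = n_dz, seed = seed)
  out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  sm <- NULL
  if (any(c("twin", "pbi") %in% methods))
    sm <- suppressMessages(mean_over_time(rec, min_visits = min_visits))
  if ("twin" %in% methods) {
    out["twin"] <- tryCatch({
      fit <- suppressWarnings(fit_twin_model(sm, genetic_coding))
      test_effect(fit, "G:E")$p.value
    }, error = function(err) NA_real_)
  }
  if ("lmm" %in% methods) {
    target <- scenario$test_target
    out["lmm"] <- tryCatch({
      fit <- fit_lmm(rec, test_target = target, genetic_coding = genetic_coding,
                     time_spec = "visit")
      test_effect(fit, if (target == "GTE") "G:E:T" else "G:E")$p.value
    }, error = function(err) NA_real_)
  }
  if ("pbi" %in% methods) {
    out["pbi"] <- tryCatch(
      pbi_test(sm$mean_bmi, sm$genotype, sm$exposure, sm$family_id,
               B = B_perm)$p.value,
      error = function(err) NA_real_)
  }
  out
}

#' Monte-Carlo type-I-error / power estimation over a scenario grid
#'
#' Runs [run_replicate()] `R` times per scenario and tabulates the rejection
#' proportion at level `alpha` per method, with its binomial Monte-Carlo
#' standard error `sqrt(p(1-p)/R)`. Replicate seeds are
#' `base_seed + (scenario index - 1) * 100000 + replicate index - 1`, so the
#' full table is reproducible from `(scenarios, R, base_seed)` alone and is
#' independent of any scheduling or worker count.
#'
#' @param scenarios A single `ge_scenario` or a (preferably named) list of
#'   them.
#' @param R Replicates per scenario.
#' @param alpha Significance level.
#' @param base_seed Base seed.
#' @inheritParams run_replicate
#' @return A data frame of class `power_table`: one row per scenario x
#'   method with `rejection_proportion`, `mc_se`, `n_used` (non-missing
#'   p-values) and `n_missing`.
#' @examples
#' estimate_power(scenario_preset("null_average"), R = 5, base_seed = 1,
#'                methods = "twin", n_mz = 20, n_dz = 20)
#' @export
estimate_power <- function(scenarios, R = 500, alpha = 0.05, base_seed = 1,
                           methods = c("twin", "lmm", "pbi"), n_mz = 168,
                           n_dz = 226, genetic_coding = "additive",
                           B_perm = 1000) {
  stopifnot(R >= 1)
  if (inherits(scenarios, "ge_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$family, "")
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    pm <- vapply(seq_len(R), function(r)
      run_replicate(sc, methods = methods,
                    seed = base_seed + (si - 1) * 100000 + r - 1,
                    n_mz = n_mz, n_dz = n_dz,
                    genetic_coding = genetic_coding, B_perm = B_perm),
      numeric(length(methods)))
    pm <- matrix(pm, nrow = length(methods),
                 dimnames = list(methods, NULL))
    for (m in methods) {
      ok <- !is.na(pm[m, ])
      ph <- if (any(ok)) mean(pm[m, ok] < alpha) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        scenario = names(scenarios)[si], method = m, coding = genetic_coding,
        alpha = alpha, n_replicates = R,
        rejection_proportion = ph,
        mc_se = if (any(ok)) sqrt(ph * (1 - ph) / sum(ok)) else NA_real_,
        n_used = sum(ok), n_missing = sum(!ok),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_table", "data.frame")
  out
}

#' @export
print.power_table <- function(x, digits = 3, ...) {
  cat("Monte-Carlo rejection proportions (alpha =", x$alpha[1], ")\n")
  df <- as.data.frame(x)
  df$rejection_proportion <- round(df$rejection_proportion, digits)
  df$mc_se <- signif(df$mc_se, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Gene-environment interaction scan across variants and exposures
#'
#' Applies the three methods to every QC-passed variant x exposure pair:
#' the twin model and the LMM test the G x E product term (continuous or
#' categorical exposure as supplied); the PBI test runs on the per-individual
#' mean outcome with continuous exposures quartile-categorised first.
#' Variants monomorphic in the analysis sample are skipped with a report
#' entry. Significance is flagged at the raw level and at the
#' Bonferroni-adjusted level `alpha / n_tests` within each exposure.
#'
#' @param summaries Per-individual summaries ([mean_over_time()]).
#' @param records Long-format records for the LMM.
#' @param genotypes Matrix individuals x variants (rownames = individual
#'   ids) of 0/1/2 counts.
#' @param exposures Data frame of exposure variables (rownames or column
#'   `individual_id` aligning with the summaries); numeric columns are
#'   treated as continuous, factors/characters as categorical.
#' @param alpha Nominal level (default 0.05).
#' @param n_tests Bonferroni family size within one exposure (default 9).
#' @param methods Methods to run.
#' @param B_perm PBI permutation count.
#' @param genetic_coding Genotype coding for the regression methods.
#' @return A data frame: `variant`, `exposure`, `method`, `p`,
#'   `significant_raw`, `significant_bonferroni`, `note`.
#' @export
gxe_scan <- function(summaries, records, genotypes, exposures, alpha = 0.05,
                     n_tests = 9, methods = c("twin", "lmm", "pbi"),
                     B_perm = 10000, genetic_coding = "additive") {
  genotypes <- as.matrix(genotypes)
  thr <- bonferroni_threshold(alpha, n_tests)
  if (!is.null(exposures$individual_id)) {
    rownames(exposures) <- exposures$individual_id
    exposures$individual_id <- NULL
  }
  ids <- summaries$individual_id
  rows <- list()
  add_row <- function(v, ex, m, p, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      variant = v, exposure = ex, method = m, p = p,
      significant_raw = !is.na(p) & p < alpha,
      significant_bonferroni = !is.na(p) & p < thr,
      note = note, stringsAsFactors = FALSE)
  }
  for (v in colnames(genotypes)) {
    gv <- genotypes[ids, v]
    if (length(unique(gv[!is.na(gv)])) < 2) {
      for (ex in colnames(exposures)) for (m in methods)
        add_row(v, ex, m, NA_real_, "monomorphic in analysis subset")
      next
    }
    for (ex in colnames(exposures)) {
      evals <- exposures[ids, ex]
      sm <- summaries
      sm$genotype <- gv
      sm$exposure <- evals
      keep <- !is.na(sm$genotype) & !is.na(sm$exposure)
      sm <- sm[keep, , drop = FALSE]
      if ("twin" %in% methods) {
        p <- tryCatch({
          fit <- suppressWarnings(fit_twin_model(sm, genetic_coding))
          test_effect(fit, "G:E")$p.value
        }, error = function(err) NA_real_)
        add_row(v, ex, "twin", p)
      }
      if ("lmm" %in% methods) {
        rec <- records
        rec$genotype <- gv[match(rec$individual_id, ids)]
        rec$exposure <- evals[match(rec$individual_id, ids)]
        rec <- rec[!is.na(rec$genotype) & !is.na(rec$exposure), , drop = FALSE]
        p <- tryCatch({
          fit <- fit_lmm(rec, test_target = "GE",
                         genetic_coding = genetic_coding)
          test_effect(fit, "G:E")$p.value
        }, error = function(err) NA_real_)
        add_row(v, ex, "lmm", p)
      }
      if ("pbi" %in% methods) {
        ecat <- if (is.numeric(sm$exposure) &&
                    length(unique(sm$exposure)) > 4)
          quartile_categorize(sm$exposure) else sm$exposure
        p <- tryCatch(
          pbi_test(sm$mean_bmi, sm$genotype, ecat, sm$family_id,
                   B = B_perm)$p.value,
          error = function(err) NA_real_)
        add_row(v, ex, "pbi", p)
      }
    }
  }
  do.call(rbind, rows)
}
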