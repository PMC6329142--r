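#' Summarise repeated measures by per-individual means
#'
#' Collapses long-format records to one row per individual with the
#' unweighted arithmetic mean of BMI and of age over the attended visits,
#' the route by which the twin model and the PBI test consume longitudinal
#' data. Individuals with fewer than `min_visits` observations are dropped
#' with a message (the default, 2 of 6 visits, mirrors excluding individuals
#' missing more than 4 of 6 measurements).
#'
#' @param records A `long_records` data frame.
#' @param min_visits Minimum number of non-missing visits to retain an
#'   individual (>= 1).
#' @return A data frame with one row per retained individual: columns
#'   `individual_id`, `family_id`, `zygosity`, `sex`, `genotype`, `exposure`,
#'   `mean_bmi`, `mean_age`, `n_visits`; attribute `"dropped"` lists excluded
#'   individual ids.
#' @examples
#' rec <- simulate_cohort_data(scenario_preset("null_average"), 5, 5, seed = 1)
#' head(mean_over_time(rec))
#' @export
mean_over_time <- function(records, min_visits = 2) {
  stopifnot(min_visits >= 1)
  rec <- records[!is.na(records$bmi), , drop = FALSE]
  ids <- unique(records$individual_id)
  f <- factor(rec$individual_id, levels = ids)
  n_visits <- as.integer(table(f))
  out <- data.frame(
    individual_id = ids,
    family_id = rec$family_id[match(ids, rec$individual_id)],
    zygosity = rec$zygosity[match(ids, rec$individual_id)],
    sex = rec$sex[match(ids, rec$individual_id)],
    genotype = rec$genotype[match(ids, rec$individual_id)],
    exposure = rec$exposure[match(ids, rec$individual_id)],
    mean_bmi = as.vector(tapply(rec$bmi, f, mean)),
    mean_age = as.vector(tapply(rec$age_months, f, mean)),
    n_visits = n_visits,
    stringsAsFactors = FALSE
  )
  drop <- out$n_visits < min_visits
  if (any(out$n_visits == 0))
    warning(sum(out$n_visits == 0), " individual(s) with zero visits dropped")
  if (any(drop))
    message("dropping ", sum(drop), " individual(s) with fewer than ",
            min_visits, " visits")
  dropped <- out$individual_id[drop]
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Co-dominant genotype coding
#'
#' Expands a minor-allele count into two indicator covariates, heterozygote
#' and minor-allele homozygote, with the common-allele homozygote as the
#' reference category. Missing genotypes propagate.
#'
#' @param g Integer vector with values in \{0, 1, 2\} or `NA`.
#' @return A two-column matrix `het`, `hom_minor`.
#' @examples
#' codominant_coding(c(0, 1, 2, NA))
#' @export
codominant_coding <- function(g) {
  ok <- is.na(g) | g %in% 0:2
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  cbind(het = ifelse(is.na(g), NA_real_, as.numeric(g == 1)),
        hom_minor = ifelse(is.na(g), NA_real_, as.numeric(g == 2)))
}

#' Quartile categorisation of a continuous exposure
#'
#' Assigns 4-level ordinal labels by the sample quartiles Q1-Q3, as needed to
#' turn a continuous exposure into a partitioning variable. Values exactly on
#' a boundary go to the lower category; missing values propagate.
#'
#' @param x Numeric vector with at least 4 distinct finite values.
#' @return Integer vector of categories 1-4 (`NA` preserved), with the
#'   quartile breaks as attribute `"breaks"`.
#' @examples
#' quartile_categorize(1:8)
#' @export
quartile_categorize <- function(x) {
  fin <- x[is.finite(x)]
  if (length(unique(fin)) < 4)
    stop("need at least 4 distinct finite values; use fewer levels instead")
  br <- stats::quantile(fin, c(0.25, 0.5, 0.75), names = FALSE)
  out <- as.integer(cut(x, c(-Inf, br, Inf), labels = FALSE, right = TRUE))
  attr(out, "breaks") <- br
  out
}

#' Proportion of follow-up time with positive exposure status
#'
#' Summarises a per-visit binary status (e.g. daycare attendance, or meeting
#' a sleep guideline) as the fraction of usable follow-up time spent in the
#' positive state, under a carry-forward rule: the status reported at a visit
#' is assumed to hold until the next visit. Intervals whose start status or
#' either bounding age is missing are excluded from numerator and
#' denominator alike.
#'
#' @param status Per-visit 0/1 indicator (last visit's status is never used).
#' @param ages Per-visit ages in months (same length as `status`).
#' @return Proportion in `[0, 1]`, or `NA` with a warning when no interval
#'   is usable.
#' @examples
#' followup_proportion(c(1, 0, NA), c(6, 20, 32))  # 14 / 26
#' @export
followup_proportion <- function(status, ages) {
  stopifnot(length(status) == length(ages))
  if (length(ages) < 2) stop("need at least 2 visits with known ages")
  k <- length(ages)
  len <- ages[-1] - ages[-k]
  use <- !is.na(status[-k]) & !is.na(ages[-1]) & !is.na(ages[-k])
  if (any(len[use] <= 0)) stop("ages must be increasing")
  if (!any(use)) {
    warning("no usable follow-up interval; returning NA")
    return(NA_real_)
  }
  sum(len[use] * (status[-k][use] == 1)) / sum(len[use])
}

#' Variant quality control
#'
#' Filters a genotype matrix on minor allele frequency, missingness, and
#' Hardy-Weinberg equilibrium. The HWE 1-df chi-square goodness-of-fit test
#' compares genotype counts with Hardy-Weinberg expectations among one
#' individual per family (lowest individual id), so that duplicated MZ
#' genotypes and sib sharing do not inflate the test.
#'
#' @param genotypes Matrix (individuals x variants) of 0/1/2 counts with
#'   `NA` for missing; rownames are individual ids.
#' @param family_id Family identifier per row (used to pick one independent
#'   individual per family for HWE).
#' @param maf_min Minimum minor allele frequency (exclusive; default 0.05).
#' @param miss_max Maximum missing proportion (exclusive; default 0.10).
#' @param hwe_alpha HWE p-value threshold (exclusive; default 0.01).
#' @return A list with `kept` (character vector of retained variant names)
#'   and `report` (data frame: `variant`, `maf`, `missingness`, `hwe_p`,
#'   `kept`). When every variant fails, `kept` is empty but the report is
#'   complete.
#' @export
variant_qc <- function(genotypes, family_id, maf_min = 0.05, miss_max = 0.10,
                       hwe_alpha = 0.01) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("v", seq_len(ncol(genotypes)))
  stopifnot(length(family_id) == nrow(genotypes))
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  # one individual per family, chosen deterministically (lowest id)
  founder <- ids %in% unlist(tapply(ids, family_id, function(v) sort(v)[1]))

  per_variant <- function(g) {
    missingness <- mean(is.na(g))
    gn <- g[!is.na(g)]
    p <- if (length(gn)) sum(gn) / (2 * length(gn)) else NA_real_
    maf <- min(p, 1 - p)
    gf <- g[founder]; gf <- gf[!is.na(gf)]
    hwe_p <- NA_real_
    if (length(gf) > 0) {
      q <- sum(gf) / (2 * length(gf))
      if (q == 0 || q == 1) hwe_p <- 1 else {
        obs <- c(sum(gf == 0), sum(gf == 1), sum(gf == 2))
        exp <- length(gf) * c((1 - q)^2, 2 * q * (1 - q), q^2)
        stat <- sum((obs - exp)^2 / exp)
        hwe_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      }
    }
    c(maf = maf, missingness = missingness, hwe_p = hwe_p)
  }
  stats_m <- t(apply(genotypes, 2, per_variant))
  keep <- !is.na(stats_m[, "maf"]) & stats_m[, "maf"] >= maf_min &
    stats_m[, "missingness"] <= miss_max &
    (!is.na(stats_m[, "hwe_p"]) & stats_m[, "hwe_p"] >= hwe_alpha)
  report <- data.frame(variant = colnames(genotypes),
                       maf = stats_m[, "maf"],
                       missingness = stats_m[, "missingness"],
                       hwe_p = stats_m[, "hwe_p"],
                       kept = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(kept = report$variant[keep], report = report)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Nominal level.
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' round(bonferroni_threshold(0.05, 9), 3)  # 0.006
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1, alpha >= 0, alpha <= 1)
  alpha / n_tests
}
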