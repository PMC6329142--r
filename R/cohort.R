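#' Default visit schedule of the emulated twin cohort
#'
#' Mean ages (months) at the six assessment points of the birth cohort the
#' simulator emulates: birth plus five follow-ups spanning roughly 6 to 62
#' months. The first visit is birth (age 0, no variability).
#'
#' @return A list with numeric vectors `means` and `sds`, both of length 6.
#' @export
visit_schedule <- function() {
  list(means = c(0, 6.28, 19.49, 31.77, 49.85, 62.25),
       sds   = c(0, 0.74, 0.75, 0.96, 1.82, 3.23))
}

#' Generate a twin cohort skeleton
#'
#' Builds the family structure every simulation walks: `n_mz + n_dz` twin
#' pairs with zygosity, sex, and per-individual visit ages. Visit ages beyond
#' birth are drawn per family from Normal(mean_k, sd_k), truncated so ages
#' strictly increase, and shared by co-twins. Monozygotic (MZ) pairs are
#' always same-sex; the opposite-sex (FM) probability applies to dizygotic
#' (DZ) pairs only, with MZ sex drawn from the FF/MM proportions renormalised.
#'
#' @param n_mz,n_dz Number of MZ and DZ twin pairs.
#' @param visit_age_means,visit_age_sds Numeric vectors (length = number of
#'   visits) of visit-age means and SDs in months; the first entry must be 0
#'   (birth). Means must be strictly increasing.
#' @param sex_pair_probs Named probabilities for pair sex composition
#'   `c(FF=, MM=, FM=)`.
#' @param dropout Per-visit probability that an individual misses a follow-up
#'   visit (missing completely at random; birth is never missed). Default 0.
#' @param seed Optional integer seed.
#'
#' @return An object of class `twin_cohort`: a list with `members` (data frame
#'   with `family_id`, `individual_id`, `zygosity`, `sex` where sex is 0 =
#'   female, 1 = male) and `ages` (matrix individuals x visits of ages in
#'   months, `NA` for missed visits, rownames = individual ids).
#' @examples
#' ch <- generate_cohort(5, 5, seed = 1)
#' nrow(ch$members)  # 20 individuals
#' @export
generate_cohort <- function(n_mz = 168, n_dz = 226,
                            visit_age_means = visit_schedule()$means,
                            visit_age_sds = visit_schedule()$sds,
                            sex_pair_probs = c(FF = 0.42, MM = 0.35, FM = 0.23),
                            dropout = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_mz >= 0, n_dz >= 0, all(visit_age_sds >= 0),
            length(visit_age_means) == length(visit_age_sds),
            dropout >= 0, dropout < 1)
  if (visit_age_means[1] != 0)
    stop("first visit is birth and must have mean age 0")
  if (is.unsorted(visit_age_means, strictly = TRUE))
    stop("visit age means must be strictly increasing")
  K <- length(visit_age_means)
  n_fam <- n_mz + n_dz
  zyg_pair <- rep(c("MZ", "DZ"), c(n_mz, n_dz))

  p <- sex_pair_probs[c("FF", "MM", "FM")]
  if (anyNA(p) || any(p < 0)) stop("sex_pair_probs must name FF, MM and FM")
  pair_sex <- character(n_fam)
  if (n_mz > 0) {
    pmz <- p[c("FF", "MM")] / sum(p[c("FF", "MM")])
    pair_sex[zyg_pair == "MZ"] <- sample(c("FF", "MM"), n_mz, TRUE, pmz)
  }
  if (n_dz > 0)
    pair_sex[zyg_pair == "DZ"] <- sample(c("FF", "MM", "FM"), n_dz, TRUE,
                                         p / sum(p))

  members <- data.frame(
    family_id = rep(seq_len(n_fam), each = 2),
    individual_id = if (n_fam)
      paste0("fam", formatC(rep(seq_len(n_fam), each = 2), width = 4, flag = "0"),
             "_", rep(1:2, n_fam)) else character(0),
    zygosity = rep(zyg_pair, each = 2),
    sex = if (n_fam) as.integer(unlist(lapply(pair_sex, function(s)
      switch(s, FF = c(0L, 0L), MM = c(1L, 1L), FM = c(0L, 1L))))) else integer(0),
    stringsAsFactors = FALSE
  )

  # family-level visit ages, sequentially truncated to be increasing
  fam_ages <- matrix(0, n_fam, K)
  if (n_fam > 0 && K > 1) {
    for (k in 2:K) {
      draw <- stats::rnorm(n_fam, visit_age_means[k], visit_age_sds[k])
      prev <- fam_ages[, k - 1]
      tries <- 0
      while (any(bad <- draw <= prev) && tries < 1000) {
        draw[bad] <- stats::rnorm(sum(bad), visit_age_means[k], visit_age_sds[k])
        tries <- tries + 1
      }
      draw[draw <= prev] <- prev[draw <= prev] + 0.01
      fam_ages[, k] <- draw
    }
  }
  ages <- fam_ages[members$family_id, , drop = FALSE]
  if (dropout > 0 && n_fam > 0 && K > 1) {
    miss <- matrix(stats::runif(2 * n_fam * (K - 1)) < dropout, 2 * n_fam, K - 1)
    ages[, -1][miss] <- NA_real_
  }
  rownames(ages) <- members$individual_id
  structure(list(members = members, ages = ages), class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  zy <- table(x$members$zygosity[seq(1, nrow(x$members), by = 2)])
  cat("Twin cohort:", nrow(x$members), "individuals in",
      nrow(x$members) / 2, "pairs (",
      paste(names(zy), as.integer(zy), collapse = ", "), ")\n")
  cat("Visits:", ncol(x$ages), "| missing visit entries:",
      sum(is.na(x$ages)), "\n")
  invisible(x)
}

#' Simulate biallelic SNP genotypes with Mendelian transmission
#'
#' For each family two parental genotypes are generated as the sum of two
#' independent Bernoulli(maf) allele draws (random mating), and each child
#' allele is transmitted uniformly from the corresponding parent. MZ co-twins
#' share a single transmission (identical genotypes); DZ co-twins inherit
#' independently, giving the sib expectation of half-sharing.
#'
#' @param cohort A `twin_cohort`.
#' @param maf Minor allele frequency in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer vector of minor-allele counts (0/1/2) named by individual
#'   id, with attribute `"parents"`: a data frame of the generating parental
#'   alleles per family (retained so Mendelian consistency can be audited).
#' @export
simulate_genotypes <- function(cohort, maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(cohort, "twin_cohort"), maf >= 0, maf <= 1)
  n_fam <- nrow(cohort$members) / 2
  if (n_fam == 0) {
    g <- integer(0)
    attr(g, "parents") <- data.frame(family_id = integer(0))
    return(g)
  }
  # parental alleles: columns pat1 pat2 mat1 mat2
  al <- matrix(stats::rbinom(4 * n_fam, 1, maf), n_fam, 4)
  zyg <- cohort$members$zygosity[seq(1, 2 * n_fam, by = 2)]
  pick1_p <- sample(1:2, n_fam, TRUE); pick1_m <- sample(1:2, n_fam, TRUE)
  pick2_p <- sample(1:2, n_fam, TRUE); pick2_m <- sample(1:2, n_fam, TRUE)
  mz <- zyg == "MZ"
  pick2_p[mz] <- pick1_p[mz]; pick2_m[mz] <- pick1_m[mz]
  idx <- seq_len(n_fam)
  g1 <- al[cbind(idx, pick1_p)] + al[cbind(idx, 2 + pick1_m)]
  g2 <- al[cbind(idx, pick2_p)] + al[cbind(idx, 2 + pick2_m)]
  g <- as.integer(rbind(g1, g2))
  names(g) <- cohort$members$individual_id
  attr(g, "parents") <- data.frame(family_id = idx, pat1 = al[, 1],
                                   pat2 = al[, 2], mat1 = al[, 3],
                                   mat2 = al[, 4])
  g
}

#' Simulate a binary environmental exposure
#'
#' Independent Bernoulli(exposure_freq) draws per individual; exposures are
#' independent even within twin pairs.
#'
#' @param cohort A `twin_cohort`.
#' @param exposure_freq Exposure frequency in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector named by individual id.
#' @export
simulate_environment <- function(cohort, exposure_freq = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(cohort, "twin_cohort"),
            exposure_freq >= 0, exposure_freq <= 1)
  e <- stats::rbinom(nrow(cohort$members), 1, exposure_freq)
  names(e) <- cohort$members$individual_id
  e
}
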