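#' Simulate longitudinal BMI trajectories
#'
#' Generates repeated BMI observations for every individual and attended
#' visit under the linear mixed generating model
#' \deqn{Y_{ijk} = (\beta_0 + C_{0ij}) + \beta_S S_{ij} +
#'   (\beta_T + C_{Tij}) T_{ijk} + \beta_{T'} T'_{ijk} + \beta_G G_{ij} +
#'   \beta_{GT} G_{ij} T_{ijk} + \beta_E E_{ij} + \theta_{ijk} + \epsilon_{ijk}}
#' where the segmented time term is visit-index based, \eqn{T'_{ijk} = 0} for
#' visits \eqn{k \le 2} and \eqn{T_{ijk} - 6} afterwards (fast infant growth
#' then plateau), and the interaction effect is
#' \eqn{\theta = \beta_{GE} M[G, E]} (average channel),
#' \eqn{\beta_{GTE} M[G, E] T} (change channel) or 0.
#' Per twin pair the random intercepts \eqn{(C_{0i1}, C_{0i2})} are zero-mean
#' bivariate normal with variance \eqn{\sigma^2_A + \sigma^2_C} and covariance
#' \eqn{\sigma^2_A + \sigma^2_C} (MZ) or \eqn{\sigma^2_A/2 + \sigma^2_C} (DZ);
#' the random slopes are analogous with \eqn{\tau^2}, independent of the
#' intercepts. Residuals are iid Normal(0, `sigma2_e`).
#'
#' @param cohort A [generate_cohort()] object.
#' @param genotypes,environments Vectors from [simulate_genotypes()] and
#'   [simulate_environment()] aligned on the same cohort.
#' @param scenario A [ge_scenario()].
#' @param seed Optional integer seed.
#' @return A long-format data frame of class `long_records` with columns
#'   `family_id`, `individual_id`, `zygosity`, `sex`, `visit`, `age_months`,
#'   `bmi`, `genotype`, `exposure` (one row per attended visit).
#' @export
simulate_trajectories <- function(cohort, genotypes, environments, scenario,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(cohort, "twin_cohort"), inherits(scenario, "ge_scenario"))
  mem <- cohort$members
  n <- nrow(mem)
  if (length(genotypes) != n || length(environments) != n)
    stop("genotypes and environments must align with the cohort")
  if (!is.null(names(genotypes)) &&
      !identical(names(genotypes), mem$individual_id))
    stop("genotype names do not match the cohort")
  K <- ncol(cohort$ages)
  sc <- scenario
  n_fam <- n / 2

  ranef_pair <- function(va, vc, zyg) {
    v <- va + vc
    if (v == 0) return(matrix(0, length(zyg), 2))
    cv <- ifelse(zyg == "MZ", va + vc, va / 2 + vc)
    if (any(v - cv^2 / v < -1e-12))
      stop("random-effect covariance matrix is not positive semi-definite")
    c1 <- stats::rnorm(length(zyg), 0, sqrt(v))
    c2 <- (cv / v) * c1 +
      stats::rnorm(length(zyg), 0, sqrt(pmax(v - cv^2 / v, 0)))
    cbind(c1, c2)
  }
  zyg_fam <- mem$zygosity[seq(1, n, by = 2)]
  C0 <- ranef_pair(sc$sigma2_a, sc$sigma2_c, zyg_fam)
  CT <- ranef_pair(sc$tau2_a, sc$tau2_c, zyg_fam)
  c0 <- as.vector(t(C0))   # per individual, pair order
  ct <- as.vector(t(CT))

  g <- as.integer(genotypes); e <- as.integer(environments)
  theta_cell <- sc$interaction[cbind(g + 1L, e + 1L)]

  # expand individuals x visits, drop missed visits
  Tmat <- cohort$ages
  keep <- !is.na(Tmat)
  idx <- rep(seq_len(n), times = K)[as.vector(keep)]
  visit <- rep(seq_len(K), each = n)[as.vector(keep)]
  ord <- order(idx, visit)
  idx <- idx[ord]; visit <- visit[ord]
  Tv <- Tmat[cbind(idx, visit)]
  Tp <- ifelse(visit <= 2, 0, Tv - 6)

  theta <- switch(sc$effect_channel,
    none    = 0,
    average = sc$beta_ge * theta_cell[idx],
    change  = sc$beta_gte * theta_cell[idx] * Tv)

  y <- (sc$beta_0 + c0[idx]) + sc$beta_s * mem$sex[idx] +
    (sc$beta_t + ct[idx]) * Tv + sc$beta_tp * Tp +
    sc$beta_g * g[idx] + sc$beta_gt * g[idx] * Tv +
    sc$beta_e * e[idx] + theta +
    stats::rnorm(length(idx), 0, sqrt(sc$sigma2_e))

  out <- data.frame(family_id = mem$family_id[idx],
                    individual_id = mem$individual_id[idx],
                    zygosity = mem$zygosity[idx],
                    sex = mem$sex[idx],
                    visit = visit, age_months = Tv, bmi = y,
                    genotype = g[idx], exposure = e[idx],
                    stringsAsFactors = FALSE)
  class(out) <- c("long_records", "data.frame")
  out
}

#' One-call cohort simulation under a scenario
#'
#' Convenience wrapper chaining [generate_cohort()], [simulate_genotypes()],
#' [simulate_environment()] and [simulate_trajectories()] under a single
#' seed.
#'
#' @inheritParams generate_cohort
#' @inheritParams simulate_trajectories
#' @param ... Passed to [generate_cohort()].
#' @return A `long_records` data frame with the generating `twin_cohort`
#'   attached as attribute `"cohort"`.
#' @examples
#' rec <- simulate_cohort_data(scenario_preset("null_average"), n_mz = 10,
#'                             n_dz = 10, seed = 1)
#' head(rec)
#' @export
simulate_cohort_data <- function(scenario, n_mz = 168, n_dz = 226,
                                 seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(n_mz = n_mz, n_dz = n_dz, ...)
  g <- simulate_genotypes(cohort, maf = scenario$maf)
  e <- simulate_environment(cohort, exposure_freq = scenario$exposure_freq)
  rec <- simulate_trajectories(cohort, g, e, scenario)
  attr(rec, "cohort") <- cohort
  rec
}

#' Read and write long-format repeated-measure records
#'
#' Plain-CSV persistence of the long record schema (`family_id`,
#' `individual_id`, `zygosity`, `sex`, `visit`, `age_months`, `bmi`,
#' `genotype`, `exposure`).
#'
#' @param records A `long_records` data frame.
#' @param path File path.
#' @return `read_long_records` returns a `long_records` data frame;
#'   `write_long_records` returns `path` invisibly.
#' @export
write_long_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_long_records
#' @export
read_long_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "zygosity", "sex", "visit",
            "age_months", "bmi", "genotype", "exposure")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  class(out) <- c("long_records", "data.frame")
  out
}
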