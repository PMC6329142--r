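noise_free_scenario <- function(...) {
  args <- list(beta_s = 0, beta_t = 0, beta_tp = 0, sigma2_a = 0,
               sigma2_c = 0, tau2_a = 0, tau2_c = 0, sigma2_e = 0)
  args[names(list(...))] <- list(...)
  do.call(ge_scenario, args)
}

test_that("trajectory generator collapses deterministically", {
  ch <- generate_cohort(3, 3, seed = 61)
  g <- simulate_genotypes(ch, 0.3, seed = 62)
  e <- simulate_environment(ch, 0.3, seed = 63)
  rec <- simulate_trajectories(ch, g, e, noise_free_scenario(), seed = 64)
  expect_true(all(rec$bmi == 11))
  expect_equal(nrow(rec), 12 * 6)
})

test_that("segmented time term follows the visit-index rule", {
  ch <- generate_cohort(5, 5, seed = 71)
  g <- rep(0L, 20); e <- rep(0L, 20)
  names(g) <- names(e) <- ch$members$individual_id
  sc <- noise_free_scenario(beta_t = 0.8, beta_tp = -0.8)
  rec <- simulate_trajectories(ch, g, e, sc)
  # visits 1-2: only beta_t * T; visits 3+: extra beta_tp * (T - 6)
  early <- rec$visit <= 2
  expect_equal(rec$bmi[early], 11 + 0.8 * rec$age_months[early])
  expect_equal(rec$bmi[!early],
               11 + 0.8 * rec$age_months[!early] -
                 0.8 * (rec$age_months[!early] - 6))
})

test_that("random intercepts carry the ACE twin covariance structure", {
  # isolate C0: no time effects, no residual, no slope variation
  sc <- noise_free_scenario(sigma2_a = 3, sigma2_c = 1.5)
  ch <- generate_cohort(800, 800, seed = 81)
  g <- simulate_genotypes(ch, 0.3); e <- simulate_environment(ch, 0.3)
  rec <- simulate_trajectories(ch, g, e, sc, seed = 82)
  b <- rec$bmi[rec$visit == 1]
  z <- rec$zygosity[rec$visit == 1]
  b1 <- b[seq(1, length(b), 2)]; b2 <- b[seq(2, length(b), 2)]
  mz <- z[seq(1, length(z), 2)] == "MZ"
  expect_equal(cor(b1[mz], b2[mz]), 1)
  r_dz <- cor(b1[!mz], b2[!mz])
  se_r <- (1 - (2 / 3)^2) / sqrt(800)      # Fisher-style large-sample SE
  expect_lt(abs(r_dz - 2 / 3), 3 * se_r)
})

test_that("marginal birth variance matches the generating components", {
  sc <- scenario_preset("null_average", beta_g = 0)
  ch <- generate_cohort(500, 500, seed = 91)
  g <- simulate_genotypes(ch, 0.3); e <- simulate_environment(ch, 0.3)
  rec <- simulate_trajectories(ch, g, e, sc, seed = 92)
  # one twin per pair at birth: independent draws, Var = sA2 + sC2 + sE2 = 6
  b <- rec$bmi[rec$visit == 1]
  b1 <- b[seq(1, length(b), 2)]
  v <- var(b1)
  se_v <- 6 * sqrt(2 / (length(b1) - 1))
  expect_lt(abs(v - 6), 3 * se_v)
  expect_lt(abs(mean(b1) - (11 + 0.5 * mean(rec$sex[rec$visit == 1][seq(1, length(b), 2)]))),
            0.5)
})

test_that("simulation is seed-deterministic and null-invariant to labels", {
  sc <- scenario_preset("null_average", beta_g = 0)
  r1 <- simulate_cohort_data(sc, 20, 20, seed = 101)
  r2 <- simulate_cohort_data(sc, 20, 20, seed = 101)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # under the null with no main effects, Y does not depend on (G, E) labels
  ch <- generate_cohort(10, 10, seed = 102)
  gA <- simulate_genotypes(ch, 0.3, seed = 103)
  gB <- rev(gA); names(gB) <- names(gA)
  e <- simulate_environment(ch, 0.3, seed = 104)
  set.seed(105); tA <- simulate_trajectories(ch, gA, e, sc)
  set.seed(105); tB <- simulate_trajectories(ch, gB, e, sc)
  expect_identical(tA$bmi, tB$bmi)
})

test_that("per-visit means track the closed-form generating means", {
  sc <- ge_scenario(beta_s = 0, beta_g = 0, beta_e = 0)  # time effects only
  set.seed(111)
  mus <- replicate(200, {
    rec <- simulate_cohort_data(sc, 10, 10)
    tapply(rec$bmi, rec$visit, mean)
  })
  mn <- rowMeans(mus)
  sch <- visit_schedule()$means
  expected <- 11 + 0.8 * sch - 0.8 * pmax(sch - 6, 0) * (seq_along(sch) > 2)
  mc_se <- apply(mus, 1, sd) / sqrt(200)
  expect_true(all(abs(mn - expected) < 3.5 * mc_se + 0.05))
})

test_that("interaction channels shift level or slope per the matrix", {
  ch <- generate_cohort(4, 4, seed = 121)
  g <- rep(2L, 16); e <- rep(1L, 16)
  names(g) <- names(e) <- ch$members$individual_id
  sc_avg <- noise_free_scenario(beta_ge = 0.5, effect_channel = "average",
                                interaction = interaction_preset("linear"))
  rec <- simulate_trajectories(ch, g, e, sc_avg)
  expect_equal(unique(rec$bmi - 11), 0.5 * 2)  # beta_ge * M[2, 1]
  sc_chg <- noise_free_scenario(beta_gte = 0.01, effect_channel = "change",
                                interaction = interaction_preset("linear"))
  rec2 <- simulate_trajectories(ch, g, e, sc_chg)
  expect_equal(rec2$bmi, 11 + 0.01 * 2 * rec2$age_months)
})

test_that("long records round-trip through CSV", {
  rec <- simulate_cohort_data(scenario_preset("null_average"), 3, 3, seed = 131)
  path <- tempfile(fileext = ".csv")
  write_long_records(rec, path)
  back <- read_long_records(path)
  attr(rec, "cohort") <- NULL
  expect_equal(as.data.frame(rec), as.data.frame(back), tolerance = 1e-12)
  expect_error(read_long_records({
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p2, row.names = FALSE); p2
  }), "missing required columns")
})
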