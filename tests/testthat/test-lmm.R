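small_records <- function(n_mz, n_dz, seed, scenario = NULL) {
  if (is.null(scenario)) scenario <- scenario_preset("null_average", beta_g = 0.5)
  simulate_cohort_data(scenario, n_mz, n_dz, seed = seed)
}

test_that("relationship matrix has the twin block structure", {
  ch <- generate_cohort(2, 2, seed = 221)
  K <- build_kinship(ch)
  expect_equal(unname(diag(K)), rep(1, 8))
  expect_equal(K[1, 2], 1)    # MZ co-twins
  expect_equal(K[5, 6], 0.5)  # DZ co-twins
  expect_true(all(K[1:2, 3:8] == 0))
  expect_true(isSymmetric(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  tab <- kinship_to_table(K)
  expect_equal(nrow(tab), 8 + 4)   # diagonal plus one entry per pair
})

test_that("zero genetic variance collapses the fit to ordinary least squares", {
  rec <- small_records(8, 8, seed = 231)
  fit <- fit_lmm(rec, gamma = 0, time_spec = "visit")
  X <- fit$data$X
  ols <- lm.fit(X, rec$bmi)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
})

test_that("blockwise likelihood equals the dense-matrix likelihood", {
  rec <- small_records(3, 2, seed = 242)
  fit <- fit_lmm(rec, time_spec = "visit")
  ll_dense <- oracle_lmm_loglik(fit$coefficients, fit$sigma2_g,
                                fit$sigma2_res, rec$bmi, fit$data$X,
                                rec$individual_id, rec$family_id,
                                rec$zygosity)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-8)
})

test_that("ML variance estimates agree with a brute-force grid search", {
  rec <- small_records(3, 2, seed = 250)
  fit <- fit_lmm(rec, time_spec = "visit")
  X <- fit$data$X
  grid_g <- seq(0.5, 12, by = 0.25)
  grid_r <- seq(0.5, 6, by = 0.25)
  best <- c(-Inf, NA, NA)
  for (sg in grid_g) for (sr in grid_r) {
    # profile beta by dense GLS at each grid point
    ids <- unique(rec$individual_id)
    Z <- outer(rec$individual_id, ids, `==`) * 1
    K <- diag(1, length(ids))
    for (f in unique(rec$family_id)) {
      ms <- which(ids %in% rec$individual_id[rec$family_id == f])
      k <- if (rec$zygosity[rec$family_id == f][1] == "MZ") 1 else 0.5
      K[ms[1], ms[2]] <- K[ms[2], ms[1]] <- k
    }
    V <- sg * Z %*% K %*% t(Z) + sr * diag(nrow(rec))
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$bmi)
    ll <- dense_mvn_loglik(rec$bmi, drop(X %*% b), V)
    if (ll > best[1]) best <- c(ll, sg, sr)
  }
  expect_gte(fit$loglik, best[1] - 1e-6)      # ML at least as good as grid max
  expect_lt(abs(fit$sigma2_g - best[2]), 0.3)  # within grid resolution
  expect_lt(abs(fit$sigma2_res - best[3]), 0.3)
})

test_that("fixed-effect estimates track the generating coefficients", {
  rec <- small_records(168, 226, seed = 261)
  fit <- fit_lmm(rec, time_spec = "visit")
  expect_lt(abs(coef(fit)["(Intercept)"] - 11), 4 * fit$se["(Intercept)"])
  expect_lt(abs(coef(fit)["T"] - 0.8), 4 * fit$se["T"])
  expect_lt(abs(coef(fit)["Tseg"] + 0.8), 4 * fit$se["Tseg"])
  expect_lt(abs(coef(fit)["E"] - 1.0), 4 * fit$se["E"])
  expect_true(fit$sigma2_g > 0)
})

test_that("GTE designs carry the full interaction hierarchy", {
  rec <- small_records(12, 12, seed = 271)
  fit <- fit_lmm(rec, test_target = "GTE", time_spec = "visit")
  expect_true(all(c("G:T", "E:T", "G:E", "G:E:T") %in% names(fit$terms)))
  tst <- test_effect(fit, "G:E:T")
  expect_equal(tst$test, "Wald")
  expect_true(tst$p.value >= 0 && tst$p.value <= 1)
  # co-dominant interaction is a 2-df LRT
  fit2 <- fit_lmm(rec, test_target = "GE", genetic_coding = "codominant")
  lrt <- test_effect(fit2, "G:E")
  expect_equal(lrt$test, "LRT"); expect_equal(lrt$df, 2)
})

test_that("hinge and visit-rule segmented trends differ only at visit 2", {
  rec <- small_records(6, 6, seed = 281)
  fh <- fit_lmm(rec, time_spec = "hinge")
  fv <- fit_lmm(rec, time_spec = "visit")
  xh <- fh$data$X[, "Tseg"]; xv <- fv$data$X[, "Tseg"]
  same <- rec$visit != 2
  expect_equal(xh[same], xv[same])
  expect_true(all(xh[rec$visit == 2 & rec$age_months > 6] > 0))
  expect_true(all(xv[rec$visit == 2] == 0))
})

test_that("degenerate designs fail loudly and ordering does not matter", {
  rec <- small_records(6, 6, seed = 291)
  rec$genotype <- 0L
  expect_error(fit_lmm(rec), "offending column")
  rec2 <- small_records(6, 6, seed = 292)
  fit1 <- fit_lmm(rec2, time_spec = "visit")
  fit2 <- fit_lmm(rec2[sample(nrow(rec2)), ], time_spec = "visit")
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-7)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-5)
})

test_that("REML fitting runs and reports non-negative variances", {
  rec <- small_records(10, 10, seed = 301)
  fit <- fit_lmm(rec, reml = TRUE)
  expect_true(is.finite(fit$loglik))
  expect_gte(fit$sigma2_g, 0)
  expect_gt(fit$sigma2_res, 0)
})

test_that("an explicit kinship matrix reproduces the zygosity-derived fit", {
  sc <- scenario_preset("null_average", beta_g = 0.5)
  rec <- simulate_cohort_data(sc, 8, 8, seed = 311)
  K <- build_kinship(attr(rec, "cohort"))
  f1 <- fit_lmm(rec, time_spec = "visit")
  f2 <- fit_lmm(rec, time_spec = "visit", kinship = K)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})
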