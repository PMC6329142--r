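make_records <- function(bmi_by_ind, ages_by_ind) {
  rows <- do.call(rbind, lapply(names(bmi_by_ind), function(id) {
    b <- bmi_by_ind[[id]]; a <- ages_by_ind[[id]]
    data.frame(family_id = 1L, individual_id = id, zygosity = "DZ", sex = 0L,
               visit = seq_along(b), age_months = a, bmi = b,
               genotype = 0L, exposure = 0L, stringsAsFactors = FALSE)
  }))
  class(rows) <- c("long_records", "data.frame")
  rows
}

test_that("mean_over_time averages, excludes, and is permutation-invariant", {
  rec <- make_records(list(a = c(14, 14, 14), b = c(12, 16)),
                      list(a = c(0, 6, 20), b = c(0, 6.3)))
  sm <- mean_over_time(rec, min_visits = 1)
  expect_equal(sm$mean_bmi, c(14, 14))
  expect_equal(sm$mean_age[2], 3.15)
  expect_equal(sm$n_visits, c(3L, 2L))
  # visit order irrelevant
  rec2 <- rec[rev(seq_len(nrow(rec))), ]
  sm2 <- mean_over_time(rec2, min_visits = 1)
  expect_equal(sort(sm2$mean_bmi), sort(sm$mean_bmi))
  # an individual with 1 of 6 visits is excluded at the default threshold
  rec3 <- make_records(list(a = rep(15, 6), b = 13),
                       list(a = c(0, 6, 20, 32, 50, 62), b = 0))
  expect_message(sm3 <- mean_over_time(rec3), "dropping 1")
  expect_equal(sm3$individual_id, "a")
  expect_equal(attr(sm3, "dropped"), "b")
  # idempotent on single-visit inputs kept at min_visits = 1
  sm4 <- mean_over_time(rec3, min_visits = 1)
  expect_equal(sm4$mean_bmi[sm4$individual_id == "b"], 13)
})

test_that("codominant coding maps counts to indicator pairs", {
  m <- codominant_coding(c(0, 1, 2, NA))
  expect_equal(unname(m[1, ]), c(0, 0))
  expect_equal(unname(m[2, ]), c(1, 0))
  expect_equal(unname(m[3, ]), c(0, 1))
  expect_true(all(is.na(m[4, ])))
  expect_error(codominant_coding(3), "0, 1, 2")
})

test_that("quartile categorisation uses sample quartiles with ties-low", {
  expect_equal(as.vector(quartile_categorize(1:8)),
               c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_error(quartile_categorize(rep(1, 10)), "distinct")
  x <- c(1, 2, 3, 4, 100)
  q2 <- unname(quantile(x, 0.5))
  expect_equal(quartile_categorize(c(x, q2))[6], 2L)  # boundary -> lower
  expect_true(is.na(quartile_categorize(c(1:7, NA))[8]))
})

test_that("follow-up proportion applies carry-forward and exclusions", {
  expect_equal(followup_proportion(c(1, 1, 1, 1), c(0, 6, 20, 32)), 1)
  expect_equal(followup_proportion(c(1, 0, NA), c(6, 20, 32)), 14 / 26)
  # middle age missing: both touching intervals dropped
  expect_equal(followup_proportion(c(1, 0, 0, NA), c(0, NA, 20, 32)),
               0 / 12)
  expect_warning(p <- followup_proportion(c(NA, NA, 0), c(0, 6, NA)),
                 "no usable")
  expect_true(is.na(p))
  # constant status returns the status value
  expect_equal(followup_proportion(c(0, 0, 0), c(0, 10, 20)), 0)
})

test_that("variant QC filters on MAF, missingness and HWE", {
  set.seed(141)
  n <- 200
  fam <- rep(1:100, each = 2)
  good <- rbinom(n, 2, 0.3)
  rare <- c(rep(1L, 8), rep(0L, n - 8))    # MAF 0.02 by construction
  mono <- rep(0L, n)
  holey <- good; holey[sample(n, 30)] <- NA       # 15% missing
  # exact HWE proportions at q = 0.4 among the 100 founders
  hw <- rep(rep(c(0L, 1L, 2L), c(36, 48, 16)), each = 2)[order(rep(1:100, 2))]
  hw <- rep(c(rep(0L, 36), rep(1L, 48), rep(2L, 16)), each = 2)
  # grossly out-of-HWE variant: all hets
  allhet <- rep(1L, n)
  G <- cbind(good = good, rare = rare, mono = mono, holey = holey,
             hw = hw, allhet = allhet)
  rownames(G) <- paste0("i", sprintf("%03d", 1:n))
  qc <- variant_qc(G, fam)
  expect_true("good" %in% qc$kept)
  expect_false("rare" %in% qc$kept)
  expect_false("mono" %in% qc$kept)
  expect_false("holey" %in% qc$kept)
  expect_true("hw" %in% qc$kept)
  expect_equal(qc$report$hwe_p[qc$report$variant == "hw"], 1)
  expect_equal(qc$report$maf[qc$report$variant == "mono"], 0)
  expect_false("allhet" %in% qc$kept)
  # order independence of the kept set
  qc2 <- variant_qc(G[, rev(colnames(G))], fam)
  expect_setequal(qc$kept, qc2$kept)
  # every variant failing yields an empty set plus a full report
  qc3 <- variant_qc(G[, c("rare", "mono"), drop = FALSE], fam)
  expect_length(qc3$kept, 0)
  expect_equal(nrow(qc3$report), 2)
})

test_that("Bonferroni threshold is alpha over the family size", {
  expect_equal(round(bonferroni_threshold(0.05, 9), 3), 0.006)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
})
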