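#' Partition dispersion statistic
#'
#' Measures the outcome variation explained by splitting a dataset into
#' cells by categorical predictors:
#' \deqn{I = \sum_i \frac{n_i}{n} \cdot
#'   \frac{(\bar y_i - \bar y)^2}{s^2_y / n_i}}
#' summed over non-empty cells, with \eqn{\bar y} the grand mean and
#' \eqn{s^2_y} the (n-1)-divisor sample variance. A constant outcome gives
#' `I = 0` with a warning (every cell mean equals the grand mean).
#'
#' @param y Outcome vector (n >= 2).
#' @param labels Cell assignment (factor or vector coercible to one).
#' @return The dispersion statistic (scalar, >= 0).
#' @examples
#' dispersion_statistic(1:6, rep(c("A", "B"), each = 3))  # 27/14
#' @export
dispersion_statistic <- function(y, labels) {
  stopifnot(length(y) == length(labels), length(y) >= 2)
  s2 <- stats::var(y)
  if (s2 == 0) {
    warning("constant outcome; dispersion statistic defined as 0")
    return(0)
  }
  f <- factor(labels)
  n_i <- tabulate(f, nbins = nlevels(f))
  keep <- n_i > 0
  m_i <- as.vector(rowsum(y, f)) / n_i[keep]
  n <- length(y)
  sum((n_i[keep] / n) * (m_i - mean(y))^2 * n_i[keep] / s2)
}

#' Partition-based score I statistics for a GE pair
#'
#' Computes the dispersion statistic for the dataset partitioned by the
#' crossed genotype x exposure cells (`I_GE`) and by each factor alone
#' (`I_G`, `I_E`), and the interaction statistic
#' \deqn{I_T = I_{GE} - \max(I_G, I_E).}
#' `I_T` may be negative when crossing dilutes the cells; no truncation is
#' applied.
#'
#' @param y Outcome vector.
#' @param g,e Categorical genotype and exposure labels.
#' @return A list of class `pbi_test` (without a p-value) containing
#'   `I_GE`, `I_G`, `I_E`, `I_T` and the per-cell table (`cells`).
#' @examples
#' g <- rep(0:1, each = 4); e <- rep(0:1, times = 4)
#' pbi_statistic(as.numeric(xor(g, e)), g, e)$I_T  # 7/4
#' @export
pbi_statistic <- function(y, g, e) {
  g <- factor(g); e <- factor(e)
  ge <- interaction(g, e, drop = TRUE, sep = "/")
  out <- list(I_GE = dispersion_statistic(y, ge),
              I_G = dispersion_statistic(y, g),
              I_E = dispersion_statistic(y, e))
  out$I_T <- out$I_GE - max(out$I_G, out$I_E)
  cells <- stats::aggregate(y, list(g = g, e = e), mean)
  cells$n <- stats::aggregate(y, list(g = g, e = e), length)$x
  names(cells)[3] <- "mean"
  out$cells <- cells[, c("g", "e", "n", "mean")]
  out$B <- NA_integer_; out$p.value <- NA_real_
  class(out) <- "pbi_test"
  out
}

# vectorised I over a matrix of permuted outcomes; grand mean and variance
# are permutation-invariant (within-family shuffles reorder y only)
.disp_matrix <- function(Yp, f, n, s2, ybar) {
  n_i <- tabulate(f, nbins = nlevels(f))
  keep <- n_i > 0
  S <- rowsum(Yp, f)
  colSums((S / n_i[keep] - ybar)^2 * (n_i[keep]^2 / (n * s2)))
}

#' PBI test with family-constrained permutation
#'
#' The partition-based score I test of a gene-environment interaction on a
#' per-individual summary outcome. The observed `I_T` is compared with its
#' permutation distribution obtained by independently permuting the outcome
#' values within every family (for twin pairs: swapping the two outcomes
#' with probability 1/2), keeping each individual's (G, E) pair intact. The
#' one-sided upper-tail p-value uses the add-one correction
#' \eqn{p = (1 + \#\{I_T^{perm} \ge I_T^{obs}\}) / (B + 1)}.
#'
#' @inheritParams pbi_statistic
#' @param family_id Family identifier per observation.
#' @param B Number of permutation replicates (default 10000).
#' @param seed Optional integer seed.
#' @return A `pbi_test` object with the observed statistics, `p.value` and
#'   `B`.
#' @examples
#' rec <- simulate_cohort_data(scenario_preset("null_average"), 20, 20, seed = 4)
#' sm <- mean_over_time(rec)
#' pbi_test(sm$mean_bmi, sm$genotype, sm$exposure, sm$family_id, B = 200,
#'          seed = 1)
#' @export
pbi_test <- function(y, g, e, family_id, B = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(B >= 1, length(y) == length(family_id))
  out <- pbi_statistic(y, g, e)
  out$B <- as.integer(B)
  fams <- split(seq_along(y), family_id)
  sizes <- lengths(fams)
  if (all(sizes == 1)) {
    warning("all families have size 1; no within-family exchangeability, p = 1")
    out$p.value <- 1
    return(out)
  }
  gf <- factor(g); ef <- factor(e)
  gef <- interaction(gf, ef, drop = TRUE)
  n <- length(y); s2 <- stats::var(y); ybar <- mean(y)
  if (s2 == 0) {
    out$p.value <- 1
    return(out)
  }
  exceed <- 0L
  if (all(sizes <= 2)) {
    pr <- fams[sizes == 2]
    i1 <- vapply(pr, `[`, 1L, 1); i2 <- vapply(pr, `[`, 1L, 2)
    np <- length(i1)
    chunk <- 2000L
    done <- 0L
    while (done < B) {
      Bc <- min(chunk, B - done)
      idx <- matrix(rep(seq_len(n), Bc), n, Bc)
      sw <- matrix(stats::runif(np * Bc) < 0.5, np, Bc)
      I1 <- matrix(rep(i1, Bc), np, Bc); I2 <- matrix(rep(i2, Bc), np, Bc)
      idx[i1, ] <- ifelse(sw, I2, I1)
      idx[i2, ] <- ifelse(sw, I1, I2)
      Yp <- matrix(y[idx], n, Bc)
      it <- .disp_matrix(Yp, gef, n, s2, ybar) -
        pmax(.disp_matrix(Yp, gf, n, s2, ybar),
             .disp_matrix(Yp, ef, n, s2, ybar))
      exceed <- exceed + sum(it >= out$I_T - 1e-12)
      done <- done + Bc
    }
  } else {
    for (b in seq_len(B)) {
      yp <- y
      for (f in fams[sizes > 1]) yp[f] <- yp[sample(f)]
      it <- dispersion_statistic(yp, gef) -
        max(dispersion_statistic(yp, gf), dispersion_statistic(yp, ef))
      if (it >= out$I_T - 1e-12) exceed <- exceed + 1L
    }
  }
  out$p.value <- (1 + exceed) / (B + 1)
  out
}

#' @export
print.pbi_test <- function(x, digits = 4, ...) {
  cat("Partition-based score I test\n")
  cat("  I_GE =", round(x$I_GE, digits), " I_G =", round(x$I_G, digits),
      " I_E =", round(x$I_E, digits), "\n")
  cat("  I_T  =", round(x$I_T, digits), "\n")
  if (!is.na(x$p.value))
    cat("  permutation p =", format(x$p.value, digits = digits),
        " (B =", x$B, "within-family permutations)\n")
  else cat("  (no permutation p-value computed)\n")
  invisible(x)
}
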