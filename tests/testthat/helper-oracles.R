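# Independent brute-force oracles used to validate the likelihood and
# permutation machinery. These deliberately use dense matrix algebra and
# direct enumeration, not the package's blockwise code paths.

# multivariate normal log-density via explicit solve/determinant
dense_mvn_loglik <- function(y, mu, Sigma) {
  r <- y - mu
  -0.5 * (length(y) * log(2 * pi) +
            determinant(Sigma, logarithm = TRUE)$modulus +
            drop(t(r) %*% solve(Sigma) %*% r))
}

# ACE model likelihood assembled family by family from dense 2x2 blocks
oracle_ace_loglik <- function(beta, a, c, e, y, X, family_id, zygosity) {
  v <- a^2 + c^2 + e^2
  mu <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (f in split(seq_along(y), family_id)) {
    if (length(f) == 1) {
      ll <- ll + dense_mvn_loglik(y[f], mu[f], matrix(v, 1, 1))
    } else {
      cv <- if (zygosity[f[1]] == "MZ") a^2 + c^2 else a^2 / 2 + c^2
      ll <- ll + dense_mvn_loglik(y[f], mu[f], matrix(c(v, cv, cv, v), 2))
    }
  }
  as.numeric(ll)
}

# dense-matrix LMM likelihood: Var(Y) = s2g * Z K Z' + s2r * I over all rows
oracle_lmm_loglik <- function(beta, s2g, s2r, y, X, individual_id, family_id,
                              zygosity) {
  ids <- unique(individual_id)
  Z <- outer(individual_id, ids, `==`) * 1
  K <- diag(1, length(ids))
  for (f in unique(family_id)) {
    ms <- which(ids %in% individual_id[family_id == f])
    if (length(ms) == 2) {
      k <- if (zygosity[match(ids[ms[1]], individual_id)] == "MZ") 1 else 0.5
      K[ms[1], ms[2]] <- K[ms[2], ms[1]] <- k
    }
  }
  V <- s2g * Z %*% K %*% t(Z) + s2r * diag(length(y))
  as.numeric(dense_mvn_loglik(y, drop(as.matrix(X) %*% beta), V))
}

# direct evaluation of the dispersion statistic from its definition
oracle_dispersion <- function(y, labels) {
  n <- length(y); s2 <- var(y); yb <- mean(y)
  tot <- 0
  for (lv in unique(labels)) {
    yi <- y[labels == lv]
    tot <- tot + (length(yi) / n) * (mean(yi) - yb)^2 / (s2 / length(yi))
  }
  tot
}

oracle_it <- function(y, g, e) {
  oracle_dispersion(y, paste(g, e)) -
    max(oracle_dispersion(y, g), oracle_dispersion(y, e))
}

# exhaustive within-family swap enumeration for size-2 families: exact
# probability that a uniformly drawn swap pattern gives I_T >= observed
oracle_perm_tail <- function(y, g, e, family_id) {
  fams <- split(seq_along(y), family_id)
  stopifnot(all(lengths(fams) == 2))
  Fn <- length(fams)
  it_obs <- oracle_it(y, g, e)
  hits <- 0
  for (mask in 0:(2^Fn - 1)) {
    yp <- y
    for (j in seq_len(Fn)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0) {
        f <- fams[[j]]
        yp[f] <- yp[rev(f)]
      }
    }
    if (oracle_it(yp, g, e) >= it_obs - 1e-12) hits <- hits + 1
  }
  hits / 2^Fn
}

# small deterministic summary table for prep/fit tests
make_pair_summaries <- function(n_mz, n_dz, a = sqrt(3), c = sqrt(1.5),
                                e = sqrt(1.5), beta = c(11, 0.5),
                                maf = 0.3, pexp = 0.3) {
  n_fam <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  cv <- ifelse(zyg == "MZ", a^2 + c^2, a^2 / 2 + c^2)
  v <- a^2 + c^2 + e^2
  c1 <- rnorm(n_fam, 0, sqrt(v))
  c2 <- (cv / v) * c1 + rnorm(n_fam, 0, sqrt(v - cv^2 / v))
  sex <- rbinom(2 * n_fam, 1, 0.5)
  g <- rbinom(2 * n_fam, 2, maf)
  ev <- rbinom(2 * n_fam, 1, pexp)
  data.frame(
    individual_id = paste0("i", seq_len(2 * n_fam)),
    family_id = rep(seq_len(n_fam), each = 2),
    zygosity = rep(zyg, each = 2),
    sex = sex, genotype = g, exposure = ev,
    mean_bmi = beta[1] + beta[2] * sex + as.vector(rbind(c1, c2)),
    mean_age = rnorm(2 * n_fam, 28, 0.3),
    n_visits = 6L, stringsAsFactors = FALSE)
}
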