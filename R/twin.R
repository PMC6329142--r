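#' ACE twin-model log-likelihood
#'
#' Reference evaluation of the classical twin path model likelihood on
#' per-individual summary outcomes: \eqn{Y_{ij} = x_{ij}\beta + aA_{ij} +
#' cC_{ij} + eE_{ij}} with mutually independent standard-normal latent
#' variables. Complete twin pairs contribute a bivariate normal density with
#' common variance \eqn{a^2 + c^2 + e^2} and covariance \eqn{a^2 + c^2} (MZ)
#' or \eqn{a^2/2 + c^2} (DZ); singleton individuals contribute the univariate
#' normal density. Non-finite parameters or non-positive-definite covariance
#' give `-Inf`, so the function is safe inside an optimiser.
#'
#' @param beta Fixed-effect vector (length = `ncol(X)`).
#' @param a,c,e Path coefficients; variance components are their squares.
#' @param y Outcome vector.
#' @param X Design matrix.
#' @param family_id Family identifier per row.
#' @param zygosity `"MZ"`/`"DZ"` per row.
#' @return The log-likelihood (scalar).
#' @examples
#' ace_loglik(0, 0, 0, 1, c(0, 0), cbind(c(1, 1)), c(1, 1), c("MZ", "MZ"))
#' @export
ace_loglik <- function(beta, a, c, e, y, X, family_id, zygosity) {
  X <- as.matrix(X)
  if (!all(is.finite(c(beta, a, c, e)))) return(-Inf)
  v <- a^2 + c^2 + e^2
  if (v <= 0) return(-Inf)
  r <- y - drop(X %*% beta)
  ll <- 0
  for (f in split(seq_along(y), family_id)) {
    if (length(f) == 1) {
      ll <- ll + stats::dnorm(r[f], 0, sqrt(v), log = TRUE)
    } else if (length(f) == 2) {
      cv <- if (zygosity[f[1]] == "MZ") a^2 + c^2 else a^2 / 2 + c^2
      d <- v^2 - cv^2
      if (d <= 0) return(-Inf)
      q <- (v * (r[f[1]]^2 + r[f[2]]^2) - 2 * cv * r[f[1]] * r[f[2]]) / d
      ll <- ll - log(2 * pi) - 0.5 * log(d) - 0.5 * q
    } else stop("families with more than 2 members are not supported")
  }
  ll
}

# sufficient statistics making each profiled-likelihood evaluation O(p^2)
.ace_suffstats <- function(y, X, family_id, zygosity) {
  fams <- split(seq_along(y), family_id)
  sizes <- lengths(fams)
  if (any(sizes > 2)) stop("families with more than 2 members are not supported")
  pairs <- fams[sizes == 2]
  singles <- unlist(fams[sizes == 1], use.names = FALSE)
  out <- list(p = ncol(X), n = length(y), types = list(),
              n_singletons = length(singles))
  zyg_pair <- vapply(pairs, function(f) zygosity[f[1]], "")
  for (z in c("MZ", "DZ")) {
    pf <- pairs[zyg_pair == z]
    if (!length(pf)) next
    i1 <- vapply(pf, `[`, 1L, 1); i2 <- vapply(pf, `[`, 1L, 2)
    X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
    y1 <- y[i1]; y2 <- y[i2]
    Ac <- crossprod(X1, X2)
    out$types[[z]] <- list(
      m = length(pf),
      A_s = crossprod(X1) + crossprod(X2), A_c = Ac + t(Ac),
      b_s = crossprod(X1, y1) + crossprod(X2, y2),
      b_c = crossprod(X1, y2) + crossprod(X2, y1),
      s_s = sum(y1^2) + sum(y2^2), s_c = 2 * sum(y1 * y2))
  }
  if (length(singles)) {
    Xs <- X[singles, , drop = FALSE]; ys <- y[singles]
    out$single <- list(n0 = length(singles), A0 = crossprod(Xs),
                       b0 = crossprod(Xs, ys), s0 = sum(ys^2))
  }
  out$n_pairs <- c(MZ = sum(zyg_pair == "MZ"), DZ = sum(zyg_pair == "DZ"))
  out
}

# profiled log-likelihood over beta at path coefficients theta = (a, c, e)
.ace_profile <- function(theta, ss) {
  a2 <- theta[1]^2; c2 <- theta[2]^2; e2 <- theta[3]^2
  v <- a2 + c2 + e2
  if (!is.finite(v) || v <= 0) return(list(ll = -Inf))
  p <- ss$p
  XtViX <- matrix(0, p, p); XtViy <- numeric(p)
  ytViy <- 0; logdet <- 0
  for (z in names(ss$types)) {
    t_ <- ss$types[[z]]
    cv <- if (z == "MZ") a2 + c2 else a2 / 2 + c2
    d <- v^2 - cv^2
    if (d <= 0) return(list(ll = -Inf))
    w1 <- v / d; w2 <- -cv / d
    XtViX <- XtViX + w1 * t_$A_s + w2 * t_$A_c
    XtViy <- XtViy + w1 * t_$b_s + w2 * t_$b_c
    ytViy <- ytViy + w1 * t_$s_s + w2 * t_$s_c
    logdet <- logdet + t_$m * log(d)
  }
  if (!is.null(ss$single)) {
    XtViX <- XtViX + ss$single$A0 / v
    XtViy <- XtViy + ss$single$b0 / v
    ytViy <- ytViy + ss$single$s0 / v
    logdet <- logdet + ss$single$n0 * log(v)
  }
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  quad <- ytViy - 2 * sum(beta * XtViy) + sum(beta * (XtViX %*% beta))
  ll <- -0.5 * (ss$n * log(2 * pi) + logdet + quad)
  list(ll = ll, beta = beta, XtViX = XtViX, chol = ch)
}

.ace_fit_core <- function(y, X, family_id, zygosity) {
  ss <- .ace_suffstats(y, X, family_id, zygosity)
  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  starts <- list(sqrt(s2 / 3) * c(1, 1, 1),
                 sqrt(s2 * c(0.1, 0.1, 0.8)),
                 sqrt(s2 * c(0.6, 0.1, 0.3)))
  best <- NULL
  for (st in starts) {
    op <- stats::optim(st, function(th) -.ace_profile(th, ss)$ll,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  prof <- .ace_profile(best$par, ss)
  vcv <- chol2inv(prof$chol)
  dimnames(vcv) <- list(colnames(X), colnames(X))
  theta <- abs(best$par)
  list(coefficients = stats::setNames(prof$beta, colnames(X)),
       se = stats::setNames(sqrt(diag(vcv)), colnames(X)),
       vcov = vcv, path = stats::setNames(theta, c("a", "c", "e")),
       var_comp = stats::setNames(theta^2, c("a2", "c2", "e2")),
       loglik = prof$ll, converged = best$convergence == 0,
       n_pairs = ss$n_pairs, n_singletons = ss$n_singletons)
}

#' Fit the ACE twin model to per-individual summary outcomes
#'
#' Maximum-likelihood fit of the twin path model on time-averaged outcomes,
#' with fixed effects for the requested covariates, the genetic factor
#' (additive count, or co-dominant indicator pair), the exposure, and their
#' product interaction. The path coefficients (a, c, e) enter the likelihood
#' through their squares, so the optimisation is unconstrained and the
#' variance-component boundary a^2 = 0 is reached smoothly; three starting
#' values (equal split of the empirical variance, e-dominant, a-dominant)
#' guard against local maxima. Incomplete pairs are retained as univariate
#' contributions.
#'
#' @param summaries A data frame from [mean_over_time()] (or with the same
#'   columns).
#' @param genetic_coding `"additive"` or `"codominant"`.
#' @param covariates Columns of `summaries` entering as adjustment
#'   covariates; default sex and mean age.
#' @return An object of class `ace_fit` with fixed-effect estimates and
#'   standard errors, path coefficients and variance components, the
#'   log-likelihood and convergence flag. Use [test_effect()] for interaction
#'   tests; `coef()`, `vcov()`, `logLik()`, `print()` and `summary()`
#'   methods are available.
#' @examples
#' rec <- simulate_cohort_data(scenario_preset("null_average"), 40, 40, seed = 2)
#' fit <- fit_twin_model(mean_over_time(rec))
#' test_effect(fit, "G:E")$p.value
#' @export
fit_twin_model <- function(summaries,
                           genetic_coding = c("additive", "codominant"),
                           covariates = c("sex", "mean_age")) {
  genetic_coding <- match.arg(genetic_coding)
  des <- .ge_design(summaries, genetic_coding, covariates)
  .check_full_rank(des$X)
  zy <- summaries$zygosity[!duplicated(summaries$family_id)]
  if (min(table(factor(zy, levels = c("MZ", "DZ"))))  < 10)
    warning("fewer than 10 complete pairs of a zygosity; estimates may be unstable")
  fit <- .ace_fit_core(summaries$mean_bmi, des$X, summaries$family_id,
                       summaries$zygosity)
  fit$terms <- des$terms
  fit$data <- list(y = summaries$mean_bmi, X = des$X,
                   family_id = summaries$family_id,
                   zygosity = summaries$zygosity)
  fit$coding <- genetic_coding
  fit$call <- match.call()
  class(fit) <- "ace_fit"
  fit
}

#' @export
print.ace_fit <- function(x, digits = 4, ...) {
  cat("ACE twin model (", x$coding, " coding)",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("Pairs: MZ", x$n_pairs["MZ"], "DZ", x$n_pairs["DZ"],
      "| singletons:", x$n_singletons, "\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), digits))
  cat("Variance components: a2 =", round(x$var_comp["a2"], digits),
      " c2 =", round(x$var_comp["c2"], digits),
      " e2 =", round(x$var_comp["e2"], digits), "\n")
  cat("logLik:", round(x$loglik, digits), "\n")
  invisible(x)
}

#' @export
summary.ace_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(object$coefficients, object$se, z, 2 * stats::pnorm(-abs(z)))
  dimnames(tab) <- list(names(object$coefficients),
                        c("Estimate", "Std. Error", "z value", "Pr(>|z|)"))
  out <- list(coefficients = tab, var_comp = object$var_comp,
              path = object$path, loglik = object$loglik,
              converged = object$converged, coding = object$coding,
              n_pairs = object$n_pairs, n_singletons = object$n_singletons)
  class(out) <- "summary.ace_fit"
  out
}

#' @export
print.summary.ace_fit <- function(x, digits = 4, ...) {
  cat("ACE twin model (", x$coding, " coding)\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nVariance components:\n")
  print(round(x$var_comp, digits))
  cat("logLik:", round(x$loglik, digits), "\n")
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) object$coefficients

#' @export
vcov.ace_fit <- function(object, ...) object$vcov

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 3,
            class = "logLik")
}

#' Test a fixed effect of a fitted GE interaction model
#'
#' Single-coefficient terms are tested with a Wald z statistic against the
#' standard normal; multi-coefficient terms (e.g. a co-dominant interaction)
#' with a likelihood-ratio test refitting the null model, against the
#' chi-square with as many degrees of freedom as coefficients dropped.
#'
#' @param fit An `ace_fit` or `kinship_lmm`.
#' @param term Term label present in the fitted design (e.g. `"G:E"`,
#'   `"G:E:T"`, `"G"`, `"E"`).
#' @return A list with `term`, `statistic`, `df`, `p.value` and `test`
#'   (`"Wald"` or `"LRT"`). A failed null refit gives `p.value = NA`.
#' @export
test_effect <- function(fit, term) UseMethod("test_effect")

.wald_or_lrt <- function(fit, term, refit_null) {
  cols <- fit$terms[[term]]
  if (is.null(cols)) stop("term '", term, "' is not in the fitted design; ",
                          "available: ", paste(names(fit$terms), collapse = ", "))
  if (!fit$converged)
    return(list(term = term, statistic = NA_real_, df = length(cols),
                p.value = NA_real_, test = "none (fit not converged)"))
  if (length(cols) == 1) {
    z <- unname(fit$coefficients[cols] / fit$se[cols])
    list(term = term, statistic = z, df = 1,
         p.value = 2 * stats::pnorm(-abs(z)), test = "Wald")
  } else {
    null_fit <- tryCatch(refit_null(cols), error = function(e) NULL)
    if (is.null(null_fit) || !null_fit$converged)
      return(list(term = term, statistic = NA_real_, df = length(cols),
                  p.value = NA_real_, test = "LRT (null fit failed)"))
    stat <- 2 * (fit$loglik - null_fit$loglik)
    list(term = term, statistic = stat, df = length(cols),
         p.value = stats::pchisq(max(stat, 0), df = length(cols),
                                 lower.tail = FALSE), test = "LRT")
  }
}

#' @rdname test_effect
#' @export
test_effect.ace_fit <- function(fit, term) {
  .wald_or_lrt(fit, term, function(cols) {
    d <- fit$data
    .ace_fit_core(d$y, d$X[, -cols, drop = FALSE], d$family_id, d$zygosity)
  })
}
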