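#' Build the twin relationship (2 x kinship) matrix
#'
#' Block-diagonal relationship matrix over all individuals of a cohort:
#' diagonal 1, within-pair off-diagonal 1 for MZ and 0.5 for DZ twins, 0
#' across families. MZ blocks are rank 1; the marginal outcome covariance
#' used in fitting adds the residual variance on the diagonal, so no
#' generalised inverse is ever needed.
#'
#' @param cohort A `twin_cohort`.
#' @return A symmetric matrix with individual ids as dimnames.
#' @export
build_kinship <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  mem <- cohort$members
  n <- nrow(mem)
  K <- diag(1, n)
  dimnames(K) <- list(mem$individual_id, mem$individual_id)
  if (n >= 2) {
    i1 <- seq(1, n, by = 2); i2 <- i1 + 1
    k <- ifelse(mem$zygosity[i1] == "MZ", 1, 0.5)
    K[cbind(i1, i2)] <- k
    K[cbind(i2, i1)] <- k
  }
  K
}

#' Export a relationship matrix as a sparse three-column table
#'
#' @param K Relationship matrix with dimnames.
#' @param path Optional TSV path; when `NULL` the data frame is returned
#'   only.
#' @return Data frame with columns `id1`, `id2`, `coefficient` (non-zero
#'   upper-triangle entries including the diagonal).
#' @export
kinship_to_table <- function(K, path = NULL) {
  idx <- which(upper.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
  out <- data.frame(id1 = rownames(K)[idx[, 1]], id2 = colnames(K)[idx[, 2]],
                    coefficient = K[idx], stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

# Per-family structure: for each family, the member row indices, per-member
# observation counts and the within-pair relationship coefficient. Families
# are grouped by (coefficient, n1, n2) so each profiled-likelihood
# evaluation reduces to a handful of O(p^2) sufficient-statistic updates
# (Woodbury on the 2 x 2 member level).
.lmm_structure <- function(y, X, individual_id, family_id, k_coef) {
  fam_of_ind <- tapply(family_id, individual_id, `[`, 1)
  inds <- split(seq_along(y), individual_id)
  fam_members <- split(names(inds), fam_of_ind[names(inds)])
  if (any(lengths(fam_members) > 2))
    stop("families with more than 2 individuals are not supported")
  keys <- character(length(fam_members))
  fams <- vector("list", length(fam_members))
  for (i in seq_along(fam_members)) {
    ms <- sort(fam_members[[i]])
    r1 <- inds[[ms[1]]]
    r2 <- if (length(ms) == 2) inds[[ms[2]]] else integer(0)
    k <- if (length(ms) == 2) k_coef[[names(fam_members)[i]]] else 0
    fams[[i]] <- list(r1 = r1, r2 = r2, k = k)
    keys[i] <- paste(signif(k, 12), length(r1), length(r2))
  }
  groups <- list()
  for (key in unique(keys)) {
    fs <- fams[keys == key]
    n1 <- length(fs[[1]]$r1); n2 <- length(fs[[1]]$r2)
    rows <- unlist(lapply(fs, function(f) c(f$r1, f$r2)))
    Xg <- X[rows, , drop = FALSE]; yg <- y[rows]
    sum_rows <- function(which_member) {
      t(vapply(fs, function(f) {
        r <- if (which_member == 1) f$r1 else f$r2
        colSums(X[r, , drop = FALSE])
      }, numeric(ncol(X))))
    }
    sum_y <- function(which_member)
      vapply(fs, function(f) sum(y[if (which_member == 1) f$r1 else f$r2]),
             0)
    G1 <- sum_rows(1); H1 <- sum_y(1)
    g <- list(nf = length(fs), n1 = n1, n2 = n2, k = fs[[1]]$k,
              N = length(rows),
              Sxx = crossprod(Xg), Sxy = drop(crossprod(Xg, yg)),
              Syy = sum(yg^2),
              P11 = crossprod(G1), q11 = drop(crossprod(G1, H1)),
              h11 = sum(H1^2))
    if (n2 > 0) {
      G2 <- sum_rows(2); H2 <- sum_y(2)
      P12 <- crossprod(G1, G2)
      g$P22 <- crossprod(G2); g$P12s <- P12 + t(P12)
      g$q22 <- drop(crossprod(G2, H2))
      g$q12s <- drop(crossprod(G1, H2)) + drop(crossprod(G2, H1))
      g$h22 <- sum(H2^2); g$h12 <- sum(H1 * H2)
    }
    groups[[length(groups) + 1]] <- g
  }
  list(groups = groups, n = length(y), p = ncol(X),
       n_individuals = length(inds), n_families = length(fam_members))
}

# profiled likelihood at variance ratio gamma = sigma2_g / sigma2_res
.lmm_profile <- function(gamma, st, reml = FALSE) {
  p <- st$p
  XtWX <- matrix(0, p, p); XtWy <- numeric(p); ytWy <- 0; logdet <- 0
  for (g in st$groups) {
    if (g$n2 == 0) {
      a <- 1 + gamma * g$n1
      m11 <- gamma / a
      XtWX <- XtWX + g$Sxx - m11 * g$P11
      XtWy <- XtWy + g$Sxy - m11 * g$q11
      ytWy <- ytWy + g$Syy - m11 * g$h11
      logdet <- logdet + g$nf * log(a)
    } else {
      K2 <- matrix(c(1, g$k, g$k, 1), 2)
      A <- diag(2) + gamma * diag(c(g$n1, g$n2)) %*% K2
      M <- gamma * K2 %*% solve(A)
      XtWX <- XtWX + g$Sxx -
        (M[1, 1] * g$P11 + M[2, 2] * g$P22 + M[1, 2] * g$P12s)
      XtWy <- XtWy + g$Sxy -
        (M[1, 1] * g$q11 + M[2, 2] * g$q22 + M[1, 2] * g$q12s)
      ytWy <- ytWy + g$Syy -
        (M[1, 1] * g$h11 + M[2, 2] * g$h22 + 2 * M[1, 2] * g$h12)
      logdet <- logdet + g$nf * log(det(A))
    }
  }
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- ytWy - 2 * sum(beta * XtWy) + sum(beta * (XtWX %*% beta))
  rss <- max(rss, 1e-300)
  n <- st$n
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + logdet +
                    2 * sum(log(diag(ch))))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + logdet)
  }
  list(ll = ll, beta = beta, sigma2_res = s2, chol = ch, XtWX = XtWX)
}

.lmm_fit_core <- function(y, X, individual_id, family_id, k_coef,
                          reml = FALSE, gamma = NULL) {
  st <- .lmm_structure(y, X, individual_id, family_id, k_coef)
  obj <- function(g) .lmm_profile(g, st, reml)$ll
  if (is.null(gamma)) {
    grid <- c(0, 0.01, 0.1, 0.3, 1, 3, 10, 30, 100, 300)
    vals <- vapply(grid, obj, 0)
    i <- which.max(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    if (lo == hi) hi <- lo + 1
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
    gamma <- if (op$objective >= vals[i]) op$maximum else grid[i]
  }
  prof <- .lmm_profile(gamma, st, reml)
  if (!is.finite(prof$ll)) stop("likelihood evaluation failed")
  vcv <- prof$sigma2_res * chol2inv(prof$chol)
  dimnames(vcv) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(prof$beta, colnames(X)),
       se = stats::setNames(sqrt(diag(vcv)), colnames(X)), vcov = vcv,
       sigma2_g = gamma * prof$sigma2_res, sigma2_res = prof$sigma2_res,
       gamma = gamma, loglik = prof$ll, reml = reml, converged = TRUE,
       n_obs = st$n, n_individuals = st$n_individuals,
       n_families = st$n_families)
}

#' Fit a kinship-covariance linear mixed model to repeated measures
#'
#' Linear mixed model on all longitudinal observations with one random
#' intercept per individual whose between-individual covariance is
#' proportional to the relationship (2 x kinship) matrix:
#' \deqn{\mathrm{Var}(Y) = \sigma^2_g Z K Z^\top + \sigma^2_{res} I.}
#' Fixed effects comprise an intercept, sex, a segmented time trend (age in
#' months plus a second slope after the knot), the genetic factor, the
#' exposure, and the interaction structure for the tested target: `"GE"`
#' adds the G x E product; `"GTE"` adds G x T, E x T and G x E below the
#' tested G x E x T term (hierarchy principle). Estimation is maximum
#' likelihood (so likelihood-ratio tests on fixed effects are valid; set
#' `reml = TRUE` for variance reporting), profiling the fixed effects and
#' the residual variance and optimising the single variance ratio
#' \eqn{\gamma = \sigma^2_g / \sigma^2_{res}} blockwise per family.
#'
#' @param records A `long_records` data frame.
#' @param test_target `"GE"` or `"GTE"`.
#' @param genetic_coding `"additive"` or `"codominant"`.
#' @param time_spec How the post-knot slope term is built: `"hinge"` uses
#'   `max(0, age - knot)`; `"visit"` uses the visit-index rule (0 for the
#'   first two visits, `age - knot` afterwards) matching the trajectory
#'   generator.
#' @param knot Knot age in months (default 6).
#' @param kinship Optional relationship matrix (dimnames = individual ids);
#'   by default within-pair coefficients are derived from zygosity (MZ 1,
#'   DZ 0.5).
#' @param reml Use REML instead of ML.
#' @param gamma Optional fixed variance ratio (e.g. `0` collapses the fit to
#'   ordinary least squares); `NULL` (default) estimates it.
#' @return An object of class `kinship_lmm`; see [test_effect()] and the
#'   `coef`/`vcov`/`logLik`/`fitted`/`residuals`/`print`/`summary` methods.
#' @examples
#' rec <- simulate_cohort_data(scenario_preset("null_average"), 30, 30, seed = 3)
#' fit <- fit_lmm(rec, test_target = "GE")
#' test_effect(fit, "G:E")$p.value
#' @export
fit_lmm <- function(records, test_target = c("GE", "GTE"),
                    genetic_coding = c("additive", "codominant"),
                    time_spec = c("hinge", "visit"), knot = 6,
                    kinship = NULL, reml = FALSE, gamma = NULL) {
  test_target <- match.arg(test_target)
  genetic_coding <- match.arg(genetic_coding)
  time_spec <- match.arg(time_spec)
  tt <- records$age_months
  tseg <- if (time_spec == "hinge") pmax(0, tt - knot)
          else ifelse(records$visit <= 2, 0, tt - knot)
  des <- .ge_design(records, genetic_coding, covariates = "sex",
                    time = tt, timeseg = tseg, gte = test_target == "GTE")
  .check_full_rank(des$X)
  if (is.null(kinship)) {
    zyg_by_fam <- tapply(records$zygosity, records$family_id, `[`, 1)
    k_coef <- ifelse(zyg_by_fam == "MZ", 1, 0.5)
    names(k_coef) <- names(zyg_by_fam)
  } else {
    ids <- unique(records$individual_id)
    if (!all(ids %in% rownames(kinship)))
      stop("every individual in records must appear in the kinship matrix")
    fam_ids <- unique(records$family_id)
    k_coef <- vapply(fam_ids, function(f) {
      ms <- unique(records$individual_id[records$family_id == f])
      if (length(ms) == 2) kinship[ms[1], ms[2]] else 0
    }, 0)
    names(k_coef) <- as.character(fam_ids)
  }
  fit <- .lmm_fit_core(records$bmi, des$X, records$individual_id,
                       as.character(records$family_id), k_coef,
                       reml = reml, gamma = gamma)
  fit$terms <- des$terms
  fit$test_target <- test_target
  fit$coding <- genetic_coding
  fit$time_spec <- time_spec
  fit$data <- list(y = records$bmi, X = des$X,
                   individual_id = records$individual_id,
                   family_id = as.character(records$family_id),
                   k_coef = k_coef, reml = reml)
  fit$call <- match.call()
  class(fit) <- "kinship_lmm"
  fit
}

#' @export
print.kinship_lmm <- function(x, digits = 4, ...) {
  cat("Kinship-covariance linear mixed model (",
      if (x$reml) "REML" else "ML", ", ", x$coding, " coding, target ",
      x$test_target, ")\n", sep = "")
  cat(x$n_obs, "observations,", x$n_individuals, "individuals,",
      x$n_families, "families\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), digits))
  cat("Variance components: sigma2_g =", round(x$sigma2_g, digits),
      " sigma2_res =", round(x$sigma2_res, digits), "\n")
  cat("logLik:", round(x$loglik, digits), "\n")
  invisible(x)
}

#' @export
summary.kinship_lmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(object$coefficients, object$se, z, 2 * stats::pnorm(-abs(z)))
  dimnames(tab) <- list(names(object$coefficients),
                        c("Estimate", "Std. Error", "z value", "Pr(>|z|)"))
  out <- list(coefficients = tab,
              var_comp = c(sigma2_g = object$sigma2_g,
                           sigma2_res = object$sigma2_res),
              loglik = object$loglik, reml = object$reml,
              test_target = object$test_target)
  class(out) <- "summary.kinship_lmm"
  out
}

#' @export
print.summary.kinship_lmm <- function(x, digits = 4, ...) {
  cat("Kinship-covariance linear mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nVariance components:\n"); print(round(x$var_comp, digits))
  cat("logLik:", round(x$loglik, digits), "\n")
  invisible(x)
}

#' @export
coef.kinship_lmm <- function(object, ...) object$coefficients

#' @export
vcov.kinship_lmm <- function(object, ...) object$vcov

#' @export
logLik.kinship_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
fitted.kinship_lmm <- function(object, ...)
  drop(object$data$X %*% object$coefficients)

#' @export
residuals.kinship_lmm <- function(object, ...)
  object$data$y - fitted(object)

#' @rdname test_effect
#' @export
test_effect.kinship_lmm <- function(fit, term) {
  .wald_or_lrt(fit, term, function(cols) {
    d <- fit$data
    .lmm_fit_core(d$y, d$X[, -cols, drop = FALSE], d$individual_id,
                  d$family_id, d$k_coef, reml = d$reml)
  })
}
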