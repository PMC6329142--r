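#' Canonical interaction-effect matrices
#'
#' An interaction matrix assigns a unitless multiplier to each genotype x
#' exposure cell (rows: minor-allele count g = 0, 1, 2; columns: exposure
#' e = 0, 1). It is applied multiplicatively to the interaction effect size,
#' so presets are normalised with max |M| <= 2. Available presets:
#' \describe{
#'   \item{linear}{`M[g, e] = g * e`, the conventional product-term pattern.}
#'   \item{xor}{Opposing genetic trends under the two exposure states
#'     (little marginal genetic signal).}
#'   \item{conditional_dominant}{Additive genetic effect without exposure;
#'     enhanced, immediately plateauing (dominant) effect with exposure.}
#'   \item{small_marginal}{Recessive genetic effect expressed only under
#'     exposure.}
#' }
#' These are declared defaults consistent with the qualitative scenario
#' descriptions; any 3 x 2 matrix can be supplied in their place.
#'
#' @param name Preset name.
#' @return A 3 x 2 numeric matrix of class `interaction_matrix` with
#'   dimnames `g = 0:2`, `e = 0:1` and attribute `"name"`.
#' @examples
#' interaction_preset("xor")
#' @export
interaction_preset <- function(name = c("linear", "xor", "conditional_dominant",
                                        "small_marginal")) {
  presets <- list(
    linear               = c(0, 0, 0, 0, 1, 2),
    xor                  = c(0, 1, 2, 2, 1, 0),
    conditional_dominant = c(0, 1, 2, 0, 2, 2),
    small_marginal       = c(0, 0, 0, 0, 0, 1)
  )
  if (length(name) != 1 || !name %in% names(presets))
    stop("unknown interaction preset; available: ",
         paste(names(presets), collapse = ", "))
  as_interaction_matrix(matrix(presets[[name]], 3, 2), name = name)
}

#' @rdname interaction_preset
#' @param m A 3 x 2 numeric matrix of finite multipliers.
#' @export
as_interaction_matrix <- function(m, name = "custom") {
  m <- as.matrix(m)
  if (!identical(dim(m), c(3L, 2L)) || !all(is.finite(m)))
    stop("interaction matrix must be 3 x 2 with finite entries")
  dimnames(m) <- list(g = 0:2, e = 0:1)
  structure(m, name = name, class = c("interaction_matrix", "matrix", "array"))
}

#' Construct a simulation scenario configuration
#'
#' Bundles every generating parameter of the longitudinal twin BMI simulator:
#' fixed effects (kg/m^2 units; time slopes per month), ACE variance
#' components of the random intercept (`sigma2_a`, `sigma2_c`) and random
#' slope (`tau2_a`, `tau2_c`), residual variance `sigma2_e`, genotype and
#' exposure frequencies, the interaction matrix, and the channel the
#' interaction acts through: `"average"` (a level shift `beta_ge * M[G, E]`)
#' or `"change"` (a slope shift `beta_gte * M[G, E] * T`), or `"none"`.
#'
#' @param beta_0,beta_s,beta_t,beta_tp,beta_g,beta_gt,beta_e Fixed effects:
#'   baseline BMI, sex, time, post-6-month extra time slope, genotype,
#'   genotype-by-time, exposure.
#' @param beta_ge,beta_gte Interaction effect sizes for the average and
#'   change channels.
#' @param sigma2_a,sigma2_c Additive-genetic and common-environment variance
#'   of the random intercept.
#' @param tau2_a,tau2_c The same for the random slope.
#' @param sigma2_e Residual variance.
#' @param maf Minor allele frequency (<= 0.5).
#' @param exposure_freq Exposure frequency.
#' @param interaction An `interaction_matrix`.
#' @param effect_channel One of `"none"`, `"average"`, `"change"`.
#' @param test_target Which interaction term the analysis methods should
#'   test under this scenario: `"GE"` or `"GTE"`.
#' @return A list of class `ge_scenario`.
#' @export
ge_scenario <- function(beta_0 = 11, beta_s = 0.5, beta_t = 0.8, beta_tp = -0.8,
                        beta_g = 0, beta_gt = 0, beta_e = 0,
                        beta_ge = 0, beta_gte = 0,
                        sigma2_a = 3, sigma2_c = 1.5,
                        tau2_a = 0.001, tau2_c = 0.001, sigma2_e = 1.5,
                        maf = 0.3, exposure_freq = 0.3,
                        interaction = interaction_preset("linear"),
                        effect_channel = c("none", "average", "change"),
                        test_target = NULL) {
  effect_channel <- match.arg(effect_channel)
  interaction <- if (inherits(interaction, "interaction_matrix")) interaction
                 else as_interaction_matrix(interaction)
  vars <- c(sigma2_a = sigma2_a, sigma2_c = sigma2_c, tau2_a = tau2_a,
            tau2_c = tau2_c, sigma2_e = sigma2_e)
  if (any(vars < 0)) stop("variance components must be >= 0")
  if (maf < 0 || maf > 0.5) stop("maf must be in [0, 0.5]")
  if (exposure_freq < 0 || exposure_freq > 1)
    stop("exposure_freq must be in [0, 1]")
  if (effect_channel == "average" && (beta_ge == 0 || beta_gte != 0))
    stop("average channel requires beta_ge != 0 and beta_gte == 0")
  if (effect_channel == "change" && (beta_gte == 0 || beta_ge != 0))
    stop("change channel requires beta_gte != 0 and beta_ge == 0")
  if (is.null(test_target))
    test_target <- if (effect_channel == "change") "GTE" else "GE"
  structure(list(beta_0 = beta_0, beta_s = beta_s, beta_t = beta_t,
                 beta_tp = beta_tp, beta_g = beta_g, beta_gt = beta_gt,
                 beta_e = beta_e, beta_ge = beta_ge, beta_gte = beta_gte,
                 sigma2_a = sigma2_a, sigma2_c = sigma2_c, tau2_a = tau2_a,
                 tau2_c = tau2_c, sigma2_e = sigma2_e, maf = maf,
                 exposure_freq = exposure_freq, interaction = interaction,
                 effect_channel = effect_channel,
                 test_target = match.arg(test_target, c("GE", "GTE")),
                 family = "custom"),
            class = "ge_scenario")
}

# legal effect-size grids of the scenario table
.grid_ge  <- function() round(seq(0.1, 1, by = 0.1), 10)
.grid_gte <- function() c(0.001, 0.004, 0.007, 0.010, 0.015, 0.020, 0.025, 0.030)

.check_grid <- function(value, grid, what) {
  if (!isTRUE(any(abs(value - grid) < 1e-9)))
    stop(what, " must be one of: ", paste(format(grid), collapse = ", "))
  invisible(value)
}

#' Named simulation scenario presets
#'
#' Returns a complete [ge_scenario()] for one of the six scenario families of
#' the simulation study, with the shared fixed parameters (beta_0 = 11,
#' beta_s = 0.5, beta_t = 0.8, beta_tp = -0.8, sigma2_a = 3, sigma2_c = 1.5,
#' tau2_a = tau2_c = 0.001, sigma2_e = 1.5, maf = 0.3, exposure frequency
#' 0.3) and the family-specific effect sizes:
#' \describe{
#'   \item{null_average}{No interaction; genetic main effect `beta_g` in
#'     \{0, 0.1, ..., 1\} with `beta_e = 2 * beta_g` (the matched 0.2
#'     increments of the environmental effect).}
#'   \item{null_change}{No interaction; gene-time effect `beta_gt` in
#'     \{0, 0.001, 0.004, 0.007, 0.01, 0.015, 0.02, 0.025, 0.03\} with
#'     `beta_e = 40 * beta_gt`.}
#'   \item{ge_linear}{Interaction on the average, linear pattern,
#'     `beta_g = 0.25`, `beta_e = 0.5`; `beta_ge` on the 0.1..1 grid.}
#'   \item{ge_nonlinear}{Interaction on the average, non-linear pattern
#'     (`interaction` preset name required), main effects 0.}
#'   \item{gte_linear}{Interaction on the rate of change, linear pattern,
#'     `beta_gt = 0.01`, `beta_e = 0.5`; `beta_gte` on the 0.001..0.03 grid.}
#'   \item{gte_nonlinear}{Interaction on the rate of change, non-linear
#'     pattern, main effects 0.}
#' }
#'
#' @param family Scenario family name.
#' @param beta_g,beta_gt,beta_ge,beta_gte The family's tunable effect size
#'   (see above); values must lie on the legal grid.
#' @param interaction Interaction preset name or matrix for the non-linear
#'   families (ignored with the linear ones, which always use `"linear"`).
#' @return A `ge_scenario`.
#' @examples
#' scenario_preset("null_change", beta_gt = 0.015)$beta_e  # 0.6
#' @export
scenario_preset <- function(family = c("null_average", "null_change",
                                       "ge_linear", "ge_nonlinear",
                                       "gte_linear", "gte_nonlinear"),
                            beta_g = 0, beta_gt = 0,
                            beta_ge = 0.5, beta_gte = 0.01,
                            interaction = "xor") {
  family <- match.arg(family)
  im <- if (inherits(interaction, "interaction_matrix")) interaction
        else if (is.matrix(interaction)) as_interaction_matrix(interaction)
        else interaction_preset(interaction)
  sc <- switch(family,
    null_average = {
      .check_grid(beta_g, c(0, .grid_ge()), "beta_g")
      ge_scenario(beta_g = beta_g, beta_e = 2 * beta_g,
                  effect_channel = "none", test_target = "GE")
    },
    null_change = {
      .check_grid(beta_gt, c(0, .grid_gte()), "beta_gt")
      ge_scenario(beta_gt = beta_gt, beta_e = 40 * beta_gt,
                  effect_channel = "none", test_target = "GTE")
    },
    ge_linear = {
      .check_grid(beta_ge, .grid_ge(), "beta_ge")
      ge_scenario(beta_g = 0.25, beta_e = 0.5, beta_ge = beta_ge,
                  interaction = interaction_preset("linear"),
                  effect_channel = "average")
    },
    ge_nonlinear = {
      .check_grid(beta_ge, .grid_ge(), "beta_ge")
      ge_scenario(beta_ge = beta_ge, interaction = im,
                  effect_channel = "average")
    },
    gte_linear = {
      .check_grid(beta_gte, .grid_gte(), "beta_gte")
      ge_scenario(beta_gt = 0.01, beta_e = 0.5, beta_gte = beta_gte,
                  interaction = interaction_preset("linear"),
                  effect_channel = "change")
    },
    gte_nonlinear = {
      .check_grid(beta_gte, .grid_gte(), "beta_gte")
      ge_scenario(beta_gte = beta_gte, interaction = im,
                  effect_channel = "change")
    })
  sc$family <- family
  sc
}

#' @export
print.ge_scenario <- function(x, ...) {
  cat("GE simulation scenario (", x$family, ")\n", sep = "")
  cat("  channel:", x$effect_channel, "| test target:", x$test_target,
      "| interaction:", attr(x$interaction, "name"), "\n")
  b <- unlist(x[c("beta_0", "beta_s", "beta_t", "beta_tp", "beta_g",
                  "beta_gt", "beta_e", "beta_ge", "beta_gte")])
  cat("  fixed effects:", paste(names(b), b, sep = "=", collapse = " "), "\n")
  v <- unlist(x[c("sigma2_a", "sigma2_c", "tau2_a", "tau2_c", "sigma2_e")])
  cat("  variances:", paste(names(v), v, sep = "=", collapse = " "), "\n")
  cat("  maf:", x$maf, "| exposure_freq:", x$exposure_freq, "\n")
  invisible(x)
}
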