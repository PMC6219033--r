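#' Covariate scheme of the default simulation design
#'
#' One subject-level binary covariate (`group`, Bernoulli(0.5), e.g. a
#' treatment arm) and one visit-level standard-normal covariate (`biom`,
#' e.g. a standardized biomarker), shared by the zero and continuous parts.
#'
#' @param n_subjects,n_visits panel dimensions.
#' @return A list with `df` (one row per subject-visit, columns `group`
#'   and `biom`) and the covariate role vectors `z` and `x`.
#' @export
default_covariates <- function(n_subjects, n_visits) {
  group <- rep(stats::rbinom(n_subjects, 1, 0.5), each = n_visits)
  biom <- stats::rnorm(n_subjects * n_visits)
  list(df = data.frame(group = group, biom = biom),
       z = c("group", "biom"), x = c("group", "biom"))
}

#' Simulation design for the replicate study
#'
#' Bundles the generative truth and panel dimensions.  The defaults mirror
#' the replicate study design this package targets: 200 subjects with 9
#' repeated measures and a 30% marginal zero proportion (achieved by
#' calibrating the zero-part intercept), an mTP-gamma truth with moderate
#' covariate effects (`alpha = (a0, 0.4, -0.4)`, `beta = (0.5, 0.3, -0.3)`,
#' gamma shape `k = sigma = 0.7`), random-intercept variances 0.5 with
#' correlation 0.5.  A 50%-zero design with 12 visits is obtained with
#' `target_zero_prop = 0.5, n_visits = 12`.
#'
#' @param n_subjects,n_visits panel dimensions.
#' @param truth a [model_parameters] object, or `NULL` for the default
#'   truth above (with the zero-part intercept calibrated to
#'   `target_zero_prop`).
#' @param spec a [model_spec] for the generative family.
#' @param target_zero_prop desired marginal zero proportion, or `NULL` to
#'   use `truth$alpha` as given.
#' @param covariates a covariate scheme function like [default_covariates].
#' @param n_replicates number of study replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200, n_visits = 9, truth = NULL,
                       spec = model_spec("mtp", "gamma"),
                       target_zero_prop = 0.3,
                       covariates = default_covariates,
                       n_replicates = 100, seed = 1) {
  stopifnot(n_subjects >= 1, n_visits >= 1, n_replicates >= 1)
  if (!is.null(target_zero_prop))
    stopifnot(target_zero_prop > 0, target_zero_prop < 1)
  if (is.null(truth)) {
    truth <- model_parameters(alpha = c(0, 0.4, -0.4),
                              coef = c(0.5, 0.3, -0.3),
                              k = 0.7, sigma = 0.7,
                              re = re_cov(0.5, 0.5, 0.25))
  }
  if (!is.null(target_zero_prop)) {
    a0 <- calibrate_zero_intercept(target_zero_prop, truth$alpha[-1],
                                   truth$re$var1, covariates, n_visits)
    truth$alpha[1] <- a0
  }
  structure(list(n_subjects = n_subjects, n_visits = n_visits,
                 truth = truth, spec = spec,
                 target_zero_prop = target_zero_prop,
                 covariates = covariates,
                 n_replicates = n_replicates, seed = seed),
            class = "sim_config")
}

# run expr under a temporary RNG state
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Calibrate the zero-part intercept to a target zero proportion
#'
#' Solves `E[1 - expit(a0 + z'alpha_rest + u1)] = target` for the
#' intercept `a0`, with the expectation over `u1 ~ N(0, var1)` taken by
#' Gauss-Hermite quadrature and over the covariate distribution by Monte
#' Carlo (a large fixed-seed covariate draw from the scheme).
#'
#' @param target desired marginal zero proportion, in (0, 1).
#' @param alpha_rest zero-part coefficients excluding the intercept.
#' @param var1 variance of the zero-part random intercept.
#' @param covariates covariate scheme function (see [default_covariates]).
#' @param n_visits visits per subject in the design.
#' @param mc_subjects Monte-Carlo subjects for the covariate expectation.
#' @return The calibrated intercept value.
#' @export
calibrate_zero_intercept <- function(target, alpha_rest, var1,
                                     covariates = default_covariates,
                                     n_visits = 9, mc_subjects = 4000) {
  stopifnot(target > 0, target < 1)
  lp0 <- with_preserved_rng(760813, {
    sc <- covariates(mc_subjects, n_visits)
    Z <- as.matrix(sc$df[sc$z])
    drop(Z %*% alpha_rest)
  })
  gh <- gh_rule(25)
  sd1 <- sqrt(var1)
  zero_prob <- function(a0) {
    p <- 0
    for (i in seq_along(gh$x)) {
      u <- sqrt(2) * sd1 * gh$x[i]
      p <- p + gh$w[i] / sqrt(pi) *
        mean(stats::plogis(-(a0 + lp0 + u)))
    }
    p
  }
  f <- function(a0) zero_prob(a0) - target
  lo <- -20; hi <- 20
  if (f(lo) * f(hi) > 0) stop("zero-proportion root not bracketed",
                              call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Simulate a longitudinal semicontinuous panel
#'
#' Draws a panel from the generative model of the configured family: per
#' subject, correlated random intercepts `(u1, u2)` from the bivariate
#' normal; per visit, covariates from the scheme; a non-zero indicator
#' with probability `pi = expit(z'alpha + u1)`; and a positive value from
#' the generalized gamma family at the family's location (the
#' marginal-mean-solving location for an mTP truth, the conditional
#' location for a two-part truth).
#'
#' @param config a [sim_config].
#' @param seed optional seed overriding `config$seed`; `NULL` uses the
#'   current RNG state.
#' @return A [panel_data] object; the underlying data frame (with the
#'   latent intercepts attached) is in attribute `"frame"`.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_subjects; nv <- config$n_visits
  truth <- config$truth; spec <- config$spec
  stopifnot(spec$family %in% c("mtp", "tp_correlated", "tp_uncorrelated"))

  G <- re_cov_matrix(truth$re)
  # bivariate normal via Cholesky (upper-left variance first)
  z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
  s1 <- sqrt(G[1, 1]); s2 <- sqrt(G[2, 2])
  rho <- if (s1 > 0 && s2 > 0) G[1, 2] / (s1 * s2) else 0
  u1 <- s1 * z1
  u2 <- s2 * (rho * z1 + sqrt(1 - rho^2) * z2)

  sc <- config$covariates(ns, nv)
  df <- sc$df
  df$subject <- rep(seq_len(ns), each = nv)
  df$time <- rep(seq_len(nv) - 1L, ns)
  Z <- cbind(1, as.matrix(df[sc$z]))
  X <- cbind(1, as.matrix(df[sc$x]))
  iu <- df$subject

  lp_z <- drop(Z %*% truth$alpha) + u1[iu]
  pi <- stats::plogis(lp_z)
  nonzero <- stats::rbinom(nrow(df), 1, pi) == 1

  mu <- drop(X %*% truth$coef) + u2[iu]
  if (spec$family == "mtp")
    mu <- mu - log_expit(lp_z) - gg_offset(truth$sigma, truth$k)
  y <- numeric(nrow(df))
  y[nonzero] <- rgg(sum(nonzero), mu = mu[nonzero],
                    sigma = truth$sigma, k = truth$k)
  df$y <- y
  df$u1 <- u1[iu]; df$u2 <- u2[iu]

  panel <- panel_data(df, subject = "subject", time = "time", outcome = "y",
                      z = sc$z, x = sc$x,
                      zero_threshold = spec$zero_threshold)
  attr(panel, "frame") <- df
  panel
}
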