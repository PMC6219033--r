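#' Model specification
#'
#' Chooses one of the four model families and the distribution of the
#' continuous part.
#'
#' Families:
#' * `"mtp"` — marginalized two-part model: logistic zero part, generalized
#'   gamma continuous part whose location is solved so the continuous-part
#'   coefficients act multiplicatively on the overall marginal mean (zeros
#'   included); correlated bivariate-normal random intercepts.
#' * `"tp_correlated"` — conventional two-part model, continuous-part
#'   coefficients conditional on a non-zero outcome; correlated random
#'   intercepts.
#' * `"tp_uncorrelated"` — conventional two-part model with independent
#'   random intercepts; the two parts are fit separately.
#' * `"one_part"` — a single log-link model for all outcome values, zeros
#'   replaced by a small positive constant.
#'
#' Distribution constraints: `"gamma"` estimates one shape parameter with
#' `sigma == k`; `"weibull"` fixes `k = 1`; `"lognormal"` is the `k -> 0`
#' limit; `"gg"` leaves `k` and `sigma` both free.
#'
#' @param family one of `"mtp"`, `"tp_correlated"`, `"tp_uncorrelated"`,
#'   `"one_part"`.
#' @param distribution one of `"gamma"`, `"lognormal"`, `"weibull"`, `"gg"`.
#' @param zero_threshold outcome values `<=` this are treated as zeros.
#' @param one_part_constant positive constant substituted for zeros in the
#'   one-part model, or `NULL` (default) for half the smallest positive
#'   outcome value in the data at fit time.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("mtp", "tp_correlated", "tp_uncorrelated",
                                  "one_part"),
                       distribution = c("gamma", "lognormal", "weibull", "gg"),
                       zero_threshold = 0,
                       one_part_constant = NULL) {
  family <- match.arg(family)
  distribution <- match.arg(distribution)
  stopifnot(is.numeric(zero_threshold), zero_threshold >= 0)
  if (!is.null(one_part_constant))
    stopifnot(is.numeric(one_part_constant), one_part_constant > 0)
  structure(list(family = family, distribution = distribution,
                 zero_threshold = zero_threshold,
                 one_part_constant = one_part_constant),
            class = "model_spec")
}

#' Zero/non-zero split of a semicontinuous outcome
#'
#' @param y non-negative outcome values.
#' @param zero_threshold values `<=` this count as zeros.
#' @return Integer vector: 1 for a non-zero observation, 0 for a zero.
#' @export
classify_zero <- function(y, zero_threshold = 0) {
  if (any(!is.finite(y)) || any(y < 0))
    stop("'y' must be finite and >= 0", call. = FALSE)
  as.integer(y > zero_threshold)
}

# distribution -> (k, sigma) free-parameter bookkeeping ----------------------

n_dist_params <- function(distribution) {
  switch(distribution, gamma = 1L, weibull = 1L, lognormal = 1L, gg = 2L)
}

dist_free_names <- function(distribution) {
  switch(distribution,
         gamma = "log(shape)",
         weibull = "log(scale)",
         lognormal = "log(scale)",
         gg = c("shape", "log(scale)"))
}

dist_from_free <- function(theta, distribution) {
  theta <- unname(theta)
  switch(distribution,
         gamma = { k <- exp(theta[1]); c(k = k, sigma = k) },
         weibull = c(k = 1, sigma = exp(theta[1])),
         lognormal = c(k = 0, sigma = exp(theta[1])),
         gg = c(k = theta[1], sigma = exp(theta[2])))
}

dist_to_free <- function(k, sigma, distribution) {
  switch(distribution,
         gamma = base::log(sigma),
         weibull = base::log(sigma),
         lognormal = base::log(sigma),
         gg = c(k, base::log(sigma)))
}

# starting (k, sigma) for each named case
dist_start <- function(distribution, log_resid_sd = 1) {
  s <- max(min(log_resid_sd, 2), 0.2)
  switch(distribution,
         gamma = c(k = s, sigma = s),
         weibull = c(k = 1, sigma = s),
         lognormal = c(k = 0, sigma = s),
         gg = c(k = 1, sigma = s))
}

#' Random-intercept covariance
#'
#' The 2 x 2 covariance of the zero-part and continuous-part random
#' intercepts.  For uncorrelated families the covariance is forced to 0;
#' the one-part model uses only the continuous-part variance slot.
#'
#' @param var1 variance of the zero-part intercept (`>= 0`).
#' @param var2 variance of the continuous-part intercept (`>= 0`).
#' @param cov12 covariance between the two intercepts.
#' @return An object of class `re_cov`.
#' @export
re_cov <- function(var1 = 0, var2 = 0, cov12 = 0) {
  stopifnot(var1 >= 0, var2 >= 0)
  if (var1 > 0 && var2 > 0) {
    rho <- cov12 / sqrt(var1 * var2)
    if (abs(rho) > 1 + 1e-12)
      stop("implied random-effect correlation outside [-1, 1]", call. = FALSE)
  } else if (cov12 != 0) {
    stop("cov12 must be 0 when a variance is 0", call. = FALSE)
  }
  structure(list(var1 = var1, var2 = var2, cov12 = cov12), class = "re_cov")
}

re_cov_matrix <- function(re) {
  matrix(c(re$var1, re$cov12, re$cov12, re$var2), 2, 2)
}

#' Full parameter set of one model
#'
#' Bundles the free parameters of any of the four families: zero-part
#' coefficients `alpha`, continuous-part coefficients `coef` (marginal
#' coefficients for the mTP family, conditional coefficients for the
#' two-part families, overall-mean coefficients for the one-part model),
#' the generalized-gamma shape `k` and scale `sigma`, and the
#' random-intercept covariance.
#'
#' @param alpha zero-part (logistic) coefficients, or `NULL` for the
#'   one-part family.
#' @param coef continuous-part coefficients.
#' @param k,sigma generalized-gamma shape and scale.
#' @param re a [re_cov] object.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(alpha = NULL, coef, k = 1, sigma = 1,
                             re = re_cov()) {
  stopifnot(inherits(re, "re_cov"), is.numeric(coef), sigma > 0 || sigma == 0)
  structure(list(alpha = alpha, coef = coef, k = k, sigma = sigma, re = re),
            class = "model_parameters")
}

# free-parameter vector layout ------------------------------------------------
# mtp / tp_correlated : alpha, coef, dist, log sd1, log sd2, atanh(rho)
# binary sub-model    : alpha, log sd1
# continuous sub-model: coef, dist, log sd2      (also one_part)

free_names <- function(spec, pz, px) {
  d <- dist_free_names(spec$distribution)
  switch(spec$family,
         mtp = ,
         tp_correlated = c(paste0("alpha.", seq_len(pz)),
                           paste0("coef.", seq_len(px)), d,
                           "log(sd1)", "log(sd2)", "atanh(rho)"),
         binary = c(paste0("alpha.", seq_len(pz)), "log(sd1)"),
         continuous = ,
         one_part = c(paste0("coef.", seq_len(px)), d, "log(sd2)"))
}

pack_params <- function(params, spec) {
  d <- dist_to_free(params$k, params$sigma, spec$distribution)
  re <- params$re
  switch(spec$family,
         mtp = ,
         tp_correlated = {
           sd1 <- sqrt(re$var1); sd2 <- sqrt(re$var2)
           rho <- if (sd1 > 0 && sd2 > 0) re$cov12 / (sd1 * sd2) else 0
           c(params$alpha, params$coef, d,
             base::log(max(sd1, 1e-8)), base::log(max(sd2, 1e-8)),
             atanh(min(max(rho, -0.999), 0.999)))
         },
         binary = c(params$alpha, base::log(max(sqrt(re$var1), 1e-8))),
         continuous = ,
         one_part = c(params$coef, d, base::log(max(sqrt(re$var2), 1e-8))))
}

unpack_params <- function(theta, spec, pz, px) {
  theta <- unname(theta)
  nd <- n_dist_params(spec$distribution)
  switch(spec$family,
         mtp = ,
         tp_correlated = {
           alpha <- theta[seq_len(pz)]
           coef <- theta[pz + seq_len(px)]
           ks <- dist_from_free(theta[pz + px + seq_len(nd)], spec$distribution)
           sd1 <- exp(theta[pz + px + nd + 1])
           sd2 <- exp(theta[pz + px + nd + 2])
           rho <- tanh(theta[pz + px + nd + 3])
           model_parameters(alpha, coef, ks[["k"]], ks[["sigma"]],
                            re_cov(sd1^2, sd2^2, rho * sd1 * sd2))
         },
         binary = {
           alpha <- theta[seq_len(pz)]
           sd1 <- exp(theta[pz + 1])
           model_parameters(alpha, coef = numeric(0), re = re_cov(var1 = sd1^2))
         },
         continuous = ,
         one_part = {
           coef <- theta[seq_len(px)]
           ks <- dist_from_free(theta[px + seq_len(nd)], spec$distribution)
           sd2 <- exp(theta[px + nd + 1])
           model_parameters(NULL, coef, ks[["k"]], ks[["sigma"]],
                            re_cov(var2 = sd2^2))
         })
}

# number of free parameters reported for information criteria
count_free_params <- function(spec, pz, px) {
  nd <- n_dist_params(spec$distribution)
  switch(spec$family,
         mtp = ,
         tp_correlated = pz + px + nd + 3L,
         tp_uncorrelated = pz + 1L + px + nd + 1L,
         one_part = px + nd + 1L)
}
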