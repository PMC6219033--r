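#' The generalized gamma family
#'
#' Density, moments, mean/variance, log-scale mean offset and random
#' generation for the three-parameter generalized gamma (GG) distribution in
#' the (location, scale, shape) parameterization used throughout this
#' package: location `mu` (real, the linear-predictor scale), scale
#' `sigma > 0` and shape `k` (real, possibly negative).  Writing
#' `eta = |k|^-2` and `u = sign(k) (log y - mu) / sigma`, the density is
#'
#' \deqn{f(y) = \frac{\eta^\eta}{\sigma y \Gamma(\eta)\sqrt{\eta}}
#'       \exp\{u\sqrt{\eta} - \eta e^{|k| u}\}.}
#'
#' Special cases: `sigma == k` gives the standard gamma distribution with
#' shape `1/k^2` and mean `exp(mu)`; `k == 1` gives the Weibull with shape
#' `1/sigma` and scale `exp(mu)`; `|k| -> 0` gives the lognormal with
#' log-mean `mu` and log-sd `sigma`.  Shapes with `|k|` below
#' [gg_lognormal_threshold] are evaluated in the lognormal limit, where the
#' direct formula is numerically unstable but the limit is analytic.
#'
#' The mean is `exp(mu + C(sigma, k))` with offset
#' `C = sigma log(k^2)/k + log Gamma(1/k^2 + sigma/k) - log Gamma(1/k^2)`;
#' `C(k, k) = 0`, `C(sigma, 1) = log Gamma(1 + sigma)` and the `k -> 0`
#' limit is `sigma^2 / 2`.  All gamma-function arithmetic uses `lgamma`.
#'
#' @param y vector of positive quantiles.
#' @param mu location parameter (log-scale linear predictor).
#' @param sigma scale parameter, `> 0`.
#' @param k shape parameter; may be negative.  `|k|` below the lognormal
#'   threshold selects the lognormal limit.
#' @param log logical; return the log density?
#' @param s moment order (positive real).
#' @param n number of random draws.
#'
#' @return `dgg` the (log) density; `gg_moment` the raw moment `E(Y^s)`;
#'   `gg_mean` and `gg_var` the mean and variance; `gg_offset` the offset
#'   `C(sigma, k)`; `rgg` a vector of `n` positive draws.
#'
#' @examples
#' dgg(1, mu = 0, sigma = 1, k = 1)        # exp(-1): Exponential(1) at 1
#' gg_mean(0, 0.5, 1)                      # gamma(1.5): Weibull mean
#' gg_offset(0.7, 0.7)                     # 0: the gamma special case
#' @name gg_family
NULL

#' Lognormal-limit threshold for the generalized gamma shape
#'
#' Shapes with `|k|` at or below this value are treated as the `k -> 0`
#' (lognormal) limit of the generalized gamma.
#' @export
gg_lognormal_threshold <- 1e-4

check_gg_params <- function(sigma, k) {
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be finite and > 0", call. = FALSE)
  if (!all(is.finite(k)))
    stop("'k' must be finite", call. = FALSE)
  invisible(NULL)
}

is_lognormal_limit <- function(k) abs(k) <= gg_lognormal_threshold

#' @rdname gg_family
#' @export
dgg <- function(y, mu = 0, sigma = 1, k = 1, log = FALSE) {
  check_gg_params(sigma, k)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("'y' must be finite and > 0", call. = FALSE)
  if (is_lognormal_limit(k)) {
    ll <- stats::dlnorm(y, meanlog = mu, sdlog = sigma, log = TRUE)
  } else {
    eta <- abs(k)^(-2)
    u <- sign(k) * (base::log(y) - mu) / sigma
    ll <- eta * base::log(eta) - base::log(sigma) - base::log(y) -
      lgamma(eta) - 0.5 * base::log(eta) + u * sqrt(eta) -
      eta * exp(abs(k) * u)
  }
  if (log) ll else exp(ll)
}

#' @rdname gg_family
#' @export
gg_offset <- function(sigma, k) {
  check_gg_params(sigma, k)
  if (is_lognormal_limit(k)) return(sigma^2 / 2)
  if (sigma == k) return(0)   # gamma case: the offset vanishes identically
  eta <- k^(-2)
  arg <- eta + sigma / k
  if (arg <= 0)
    stop("mean undefined: gamma-function argument 1/k^2 + sigma/k <= 0",
         call. = FALSE)
  sigma * base::log(k^2) / k + lgamma(arg) - lgamma(eta)
}

#' @rdname gg_family
#' @export
gg_moment <- function(s, mu = 0, sigma = 1, k = 1) {
  check_gg_params(sigma, k)
  if (!is.finite(s) || s <= 0) stop("'s' must be > 0", call. = FALSE)
  if (is_lognormal_limit(k)) return(exp(s * mu + s^2 * sigma^2 / 2))
  eta <- k^(-2)
  arg <- eta + s * sigma / k
  if (arg <= 0)
    stop(sprintf("moment undefined: E(Y^%g) does not exist for sigma=%g, k=%g",
                 s, sigma, k), call. = FALSE)
  exp(s * mu + s * sigma * base::log(k^2) / k + lgamma(arg) - lgamma(eta))
}

#' @rdname gg_family
#' @export
gg_mean <- function(mu = 0, sigma = 1, k = 1) {
  exp(mu + gg_offset(sigma, k))
}

#' @rdname gg_family
#' @export
gg_var <- function(mu = 0, sigma = 1, k = 1) {
  gg_moment(2, mu, sigma, k) - gg_mean(mu, sigma, k)^2
}

#' @rdname gg_family
#' @export
rgg <- function(n, mu = 0, sigma = 1, k = 1) {
  check_gg_params(sigma, k)
  if (n == 0) return(numeric(0))
  if (is_lognormal_limit(k)) {
    return(exp(mu + sigma * stats::rnorm(n)))
  }
  # gamma transform: g ~ Gamma(1/k^2, 1), y = exp(mu + (sigma/k) log(k^2 g))
  g <- stats::rgamma(n, shape = k^(-2), rate = 1)
  exp(mu + (sigma / k) * base::log(k^2 * g))
}
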