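#' Two-part and marginalized two-part building blocks
#'
#' Elementary quantities shared by the model likelihoods.  `zero_part_prob`
#' is the probability of a non-zero outcome from the logistic zero part;
#' `tp_conditional_location` is the conditional-on-positive log-scale
#' location of the two-part continuous component; `mtp_location` solves the
#' marginal-mean constraint of the marginalized two-part model for the
#' generalized-gamma location, so that `pi * exp(mu + C) = exp(x'beta + u2)`
#' holds exactly; `tp_marginal_mean` is the overall mean `pi * exp(mu + C)`
#' of a two-part model with a generalized-gamma continuous part;
#' `one_part_location` is the log-link linear predictor of the one-part
#' model.
#'
#' @param z,x,w covariate vector (or matrix, rows = observations) including
#'   the intercept term.
#' @param alpha,delta,beta,gamma coefficient vectors for the respective
#'   model part.
#' @param u1,u2,u0 subject-level random intercepts.
#' @param pi probability of a non-zero outcome.
#' @param mu generalized-gamma location.
#' @param C the log-scale mean offset [gg_offset].
#' @return Numeric vector, one value per observation.
#' @name model_blocks
NULL

lin_pred <- function(m, b, u) {
  if (is.matrix(m)) {
    if (ncol(m) != length(b)) stop("dimension mismatch", call. = FALSE)
    drop(m %*% b) + u
  } else {
    if (length(m) != length(b)) stop("dimension mismatch", call. = FALSE)
    sum(m * b) + u
  }
}

#' @rdname model_blocks
#' @export
zero_part_prob <- function(z, alpha, u1 = 0) {
  stats::plogis(lin_pred(z, alpha, u1))
}

#' @rdname model_blocks
#' @export
tp_conditional_location <- function(x, delta, u2 = 0) {
  lin_pred(x, delta, u2)
}

#' @rdname model_blocks
#' @export
mtp_location <- function(x, beta, u2 = 0, pi, C) {
  if (any(pi <= 0)) stop("'pi' must be > 0", call. = FALSE)
  if (any(pi > 1)) stop("'pi' must be <= 1", call. = FALSE)
  lin_pred(x, beta, u2) - base::log(pi) - C
}

#' @rdname model_blocks
#' @export
tp_marginal_mean <- function(pi, mu, C) {
  stopifnot(all(pi >= 0), all(pi <= 1))
  pi * exp(mu + C)
}

#' @rdname model_blocks
#' @export
one_part_location <- function(w, gamma, u0 = 0) {
  lin_pred(w, gamma, u0)
}

# numerically stable log pi and log(1 - pi) from the linear predictor
log_expit <- function(lp) stats::plogis(lp, log.p = TRUE)

#' Conditional likelihood of one subject given the random intercepts
#'
#' The product over one subject's records of the two-part (or marginalized
#' two-part) observation density, conditional on the random intercepts
#' `u = (u1, u2)`: zeros contribute `1 - pi_ij`, positives contribute
#' `pi_ij * f(y_ij; mu_ij, sigma, k)` where `pi_ij = expit(z'alpha + u1)`
#' and `mu_ij` is the family's location (conditional for the two-part
#' families, marginal-mean-solving for the mTP).  This is the integrand of
#' the marginal likelihood; it is computed in log space.
#'
#' @param records a list with outcome vector `y` and design matrices `Z`
#'   and `X` for one subject (e.g. from a [panel_data] object).
#' @param params a [model_parameters] object.
#' @param spec a [model_spec]; family must be `"mtp"` or `"tp_correlated"`.
#' @param u numeric of length 2, the random intercepts `(u1, u2)`.
#' @param log return the log integrand (default) or the raw value?
#' @return A single numeric value.
#' @export
subject_integrand <- function(records, params, spec, u = c(0, 0), log = TRUE) {
  stopifnot(inherits(spec, "model_spec"),
            spec$family %in% c("mtp", "tp_correlated"))
  y <- records$y
  if (any(!is.finite(y))) stop("non-finite outcome", call. = FALSE)
  lp_z <- drop(records$Z %*% params$alpha) + u[1]
  pos <- y > spec$zero_threshold
  ll <- sum(log_expit(-lp_z[!pos]))          # zeros: log(1 - pi)
  if (any(pos)) {
    log_pi <- log_expit(lp_z[pos])
    lp_x <- drop(records$X[pos, , drop = FALSE] %*% params$coef) + u[2]
    mu <- if (spec$family == "mtp") {
      lp_x - log_pi - gg_offset(params$sigma, params$k)
    } else {
      lp_x
    }
    ll <- ll + sum(log_pi) +
      sum(dgg(y[pos], mu = mu, sigma = params$sigma, k = params$k, log = TRUE))
  }
  if (log) ll else exp(ll)
}
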