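#' Quadrature settings for the marginal likelihood
#'
#' Controls the Gauss-Hermite rule used to integrate the random intercepts
#' out of the likelihood.  With `adaptive = TRUE` (the default) the rule is
#' recentered and rescaled at each subject's posterior mode of the random
#' effects, which keeps few nodes accurate even for informative subjects;
#' when a subject's mode search fails the non-adaptive rule centered at the
#' prior is used for that subject.
#'
#' @param nodes nodes per integration dimension (default 7; 2-D families
#'   use the tensor product).
#' @param adaptive recenter/rescale at the per-subject posterior mode?
#' @param mode_tol gradient tolerance of the per-subject mode search.
#' @return An object of class `quad_config`.
#' @export
quad_config <- function(nodes = 7, adaptive = TRUE, mode_tol = 1e-6) {
  stopifnot(nodes >= 1, mode_tol > 0)
  structure(list(nodes = as.integer(nodes), adaptive = adaptive,
                 mode_tol = mode_tol), class = "quad_config")
}

.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    if (n == 1L) {
      .gh_cache[[key]] <- list(x = 0, w = sqrt(pi))
    } else {
      .gh_cache[[key]] <- pracma::gaussHermite(n)
    }
  }
  .gh_cache[[key]]
}

family_code <- function(family) {
  switch(family, binary = 0L, continuous = 1L, one_part = 1L,
         tp_correlated = 2L, mtp = 3L,
         stop("family '", family, "' has no single likelihood code",
              call. = FALSE))
}

subj_offsets <- function(idx) {
  len <- lengths(idx)
  list(start = as.integer(cumsum(c(0L, len[-length(len)]))),
       len = as.integer(len))
}

# one-part zero substitution: values <= threshold become the small constant
one_part_outcome <- function(panel, spec) {
  y <- panel$y
  pos <- y > panel$zero_threshold
  if (!any(pos)) stop("one-part model needs at least one positive outcome",
                      call. = FALSE)
  c0 <- spec$one_part_constant
  if (is.null(c0)) c0 <- min(y[pos]) / 2
  y[!pos] <- c0
  list(y = y, constant = c0)
}

# positives-only view for the continuous sub-model, keeping every subject
positives_view <- function(panel) {
  pos <- which(panel$y > panel$zero_threshold)
  idx <- lapply(panel$subject_index, function(i) intersect(i, pos))
  len <- lengths(idx)
  ord <- unlist(idx, use.names = FALSE)
  list(y = panel$y[ord], X = panel$X[ord, , drop = FALSE],
       start = as.integer(cumsum(c(0L, len[-length(len)]))),
       len = as.integer(len))
}

# single C++ evaluation for families with one likelihood code
eval_single <- function(panel, params, spec, quad, start_modes = NULL) {
  fam <- spec$family
  code <- family_code(fam)
  re <- params$re
  rho <- if (re$var1 > 0 && re$var2 > 0)
    re$cov12 / sqrt(re$var1 * re$var2) else 0
  gh <- gh_rule(quad$nodes)
  ns <- n_subjects(panel)
  if (is.null(start_modes)) start_modes <- matrix(0, ns, 2)

  if (fam == "one_part") {
    adj <- one_part_outcome(panel, spec)
    off <- subj_offsets(panel$subject_index)
    y <- adj$y; X <- panel$W; Z <- panel$Z
  } else if (fam == "continuous") {
    pv <- positives_view(panel)
    y <- pv$y; X <- pv$X; Z <- matrix(0, length(y), 0)
    off <- list(start = pv$start, len = pv$len)
  } else {
    off <- subj_offsets(panel$subject_index)
    y <- panel$y; X <- panel$X; Z <- panel$Z
  }
  alpha <- if (is.null(params$alpha)) numeric(0) else params$alpha
  agq_loglik_cpp(y, Z, X, off$start, off$len,
                 alpha, params$coef,
                 params$k, params$sigma, code,
                 sqrt(re$var1), sqrt(re$var2), rho,
                 panel$zero_threshold, gh$x, gh$w,
                 quad$adaptive, quad$mode_tol, start_modes)
}

split_uncorrelated <- function(params) {
  list(binary = model_parameters(params$alpha, coef = numeric(0),
                                 re = re_cov(var1 = params$re$var1)),
       continuous = model_parameters(NULL, params$coef, params$k,
                                     params$sigma,
                                     re = re_cov(var2 = params$re$var2)))
}

#' Marginal log-likelihood with the random intercepts integrated out
#'
#' Evaluates the marginal likelihood of a fitted or hypothesized parameter
#' set by (adaptive) Gauss-Hermite quadrature: a 2-D tensor rule over the
#' correlated intercepts for the `"mtp"` and `"tp_correlated"` families,
#' and independent 1-D rules for the two separately-fit parts of
#' `"tp_uncorrelated"` and for the `"one_part"` model.  Random-effect
#' variances of zero reduce exactly to the conditional likelihood at
#' `u = 0`.
#'
#' @param panel a [panel_data] object.
#' @param params a [model_parameters] object.
#' @param spec a [model_spec].
#' @param quad a [quad_config].
#' @return A list: `total` log-likelihood, `subject` per-subject
#'   log-likelihood vector, `modes` the per-subject posterior modes of
#'   `(u1, u2)` used for adaptive centering, `adapted` per-subject flag
#'   (1 = adaptive centering succeeded).
#' @export
marginal_loglik <- function(panel, params, spec, quad = quad_config()) {
  stopifnot(inherits(panel, "panel_data"), inherits(spec, "model_spec"),
            inherits(quad, "quad_config"))
  if (spec$family == "tp_uncorrelated") {
    sub <- split_uncorrelated(params)
    rb <- eval_single(panel, sub$binary, spec_sub(spec, "binary"), quad)
    rc <- eval_single(panel, sub$continuous, spec_sub(spec, "continuous"), quad)
    modes <- cbind(rb$modes[, 1], rc$modes[, 2])
    list(total = rb$total + rc$total, subject = rb$subject + rc$subject,
         modes = modes, adapted = pmin(rb$adapted, rc$adapted))
  } else {
    r <- eval_single(panel, params, spec, quad)
    list(total = r$total, subject = r$subject, modes = r$modes,
         adapted = r$adapted)
  }
}

spec_sub <- function(spec, family) {
  s <- spec
  s$family <- family
  s
}

# negative log-likelihood on the free-parameter scale, with mode caching
# across calls via `state` (an environment holding `modes`)
total_negloglik <- function(theta, panel, spec, quad, state = NULL) {
  pz <- ncol(panel$Z)
  px <- if (spec$family == "one_part") ncol(panel$W) else ncol(panel$X)
  params <- unpack_params(theta, spec, pz, px)
  start <- if (!is.null(state) && !is.null(state$modes)) state$modes else NULL
  r <- tryCatch(
    eval_single(panel, params, spec, quad, start_modes = start),
    error = function(e) NULL)
  if (is.null(r) || !is.finite(r$total)) return(1e10)
  if (!is.null(state)) state$modes <- r$modes
  -r$total
}
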