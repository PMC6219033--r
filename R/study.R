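#' Bias and MSE of replicate estimates
#'
#' Per-parameter bias `mean(est) - truth` and MSE `mean((est - truth)^2)`
#' across study replicates, with the aggregate (mean over parameters)
#' signed bias, absolute bias and MSE, and the x10 scaling commonly used
#' in simulation reports.
#'
#' @param estimates replicate-by-parameter matrix of estimates.
#' @param truth true parameter vector (length = columns of `estimates`).
#' @return A list: `per_parameter` data frame with `bias`, `mse` (and x10
#'   columns), and `aggregate` with `bias`, `abs_bias`, `mse` plus the x10
#'   versions.
#' @export
bias_mse_summary <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != length(truth))
    stop("columns of 'estimates' must match length of 'truth'", call. = FALSE)
  if (nrow(estimates) < 1) stop("need at least one replicate", call. = FALSE)
  err <- sweep(estimates, 2, truth)
  bias <- colMeans(err)
  mse <- colMeans(err^2)
  per <- data.frame(term = colnames(estimates) %||% paste0("p", seq_along(truth)),
                    truth = truth, bias = bias, mse = mse,
                    bias_x10 = 10 * bias, mse_x10 = 10 * mse,
                    row.names = NULL)
  agg <- list(bias = mean(bias), abs_bias = mean(abs(bias)), mse = mean(mse),
              bias_x10 = 10 * mean(bias), mse_x10 = 10 * mean(mse))
  list(per_parameter = per, aggregate = agg, n_replicates = nrow(estimates))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-replicate seed from the master seed (counter scheme,
# kept within the 32-bit integer range)
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) + 62417 * as.numeric(r)) %% 2147483647)
}

#' Replicate bias/MSE study across model families
#'
#' Simulates `config$n_replicates` panels under the configured truth and
#' fits every requested family to each, then summarizes bias and MSE of
#' the continuous-part (marginal-mean) coefficients against the generative
#' truth.  The headline aggregate is taken over the non-intercept
#' continuous-part coefficients, whose generative values are the marginal
#' multiplicative effects all four families try to estimate; per-parameter
#' summaries (intercept included) are also returned.  Replicates whose
#' optimizer did not converge are excluded and counted.
#'
#' @param config a [sim_config].
#' @param families character vector of families to fit.
#' @param quad a [quad_config] used for all fits.
#' @param control optimizer control passed to [fit_model] (standard errors
#'   are disabled for speed unless requested).
#' @param progress print a line per replicate?
#' @return An object of class `sim_study`: per-family list with the
#'   [bias_mse_summary] of the slope coefficients (`slopes`), of all
#'   continuous-part coefficients (`all_coef`), convergence counts, and
#'   the raw estimates matrix.
#' @export
run_replicate_study <- function(config,
                                families = c("mtp", "tp_correlated",
                                             "tp_uncorrelated", "one_part"),
                                quad = quad_config(),
                                control = list(se = FALSE),
                                progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), config$n_replicates >= 2)
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("mtp", "tp_correlated",
                                    "tp_uncorrelated", "one_part"))
  truth_coef <- config$truth$coef
  px <- length(truth_coef)
  est <- lapply(families, function(f)
    matrix(NA_real_, config$n_replicates, px))
  names(est) <- families
  conv <- stats::setNames(integer(length(families)), families)

  for (r in seq_len(config$n_replicates)) {
    panel <- simulate_panel(config, seed = replicate_seed(config$seed, r))
    for (f in families) {
      spec_f <- model_spec(f, config$spec$distribution,
                           zero_threshold = config$spec$zero_threshold)
      fit <- tryCatch(fit_model(panel, spec_f, quad, control),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        cf <- fit$estimates[grepl("^cont\\.", names(fit$estimates))]
        est[[f]][r, ] <- unname(cf)
        conv[f] <- conv[f] + 1L
      }
    }
    if (progress)
      message("replicate ", r, "/", config$n_replicates, " done")
  }

  slope_cols <- seq_len(px)[-1]
  out <- lapply(families, function(f) {
    e <- est[[f]][stats::complete.cases(est[[f]]), , drop = FALSE]
    if (nrow(e) == 0)
      return(list(available = FALSE, n_converged = 0L,
                  n_replicates = config$n_replicates))
    colnames(e) <- paste0("coef.", seq_len(px))
    list(available = TRUE,
         slopes = bias_mse_summary(e[, slope_cols, drop = FALSE],
                                   truth_coef[slope_cols]),
         all_coef = bias_mse_summary(e, truth_coef),
         n_converged = conv[[f]],
         n_replicates = config$n_replicates,
         estimates = e)
  })
  names(out) <- families
  structure(list(families = out, config = config), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Replicate study: %d replicates, %d subjects x %d visits",
              cfg$n_replicates, cfg$n_subjects, cfg$n_visits))
  if (!is.null(cfg$target_zero_prop))
    cat(sprintf(", %.0f%% zeros", 100 * cfg$target_zero_prop))
  cat("\nAggregate over slope coefficients (x10 scale):\n")
  rows <- lapply(names(x$families), function(f) {
    s <- x$families[[f]]
    if (!isTRUE(s$available))
      return(data.frame(model = f, bias_x10 = NA, mse_x10 = NA,
                        converged = s$n_converged))
    data.frame(model = f,
               bias_x10 = round(s$slopes$aggregate$bias_x10, 4),
               mse_x10 = round(s$slopes$aggregate$mse_x10, 4),
               converged = s$n_converged)
  })
  print(do.call(rbind, rows), row.names = FALSE)
  invisible(x)
}

#' Tidy table of a replicate study
#'
#' @param study a [run_replicate_study] result.
#' @return Data frame with one row per model and aggregate bias/MSE
#'   columns (raw and x10), suitable for writing as CSV.
#' @export
study_table <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  rows <- lapply(names(study$families), function(f) {
    s <- study$families[[f]]
    if (!isTRUE(s$available))
      return(data.frame(model = f, bias = NA_real_, abs_bias = NA_real_,
                        mse = NA_real_, bias_x10 = NA_real_,
                        mse_x10 = NA_real_, n_converged = s$n_converged,
                        n_replicates = s$n_replicates))
    a <- s$slopes$aggregate
    data.frame(model = f, bias = a$bias, abs_bias = a$abs_bias, mse = a$mse,
               bias_x10 = a$bias_x10, mse_x10 = a$mse_x10,
               n_converged = s$n_converged, n_replicates = s$n_replicates)
  })
  do.call(rbind, rows)
}
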