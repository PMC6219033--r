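#' Write machine- and human-readable fit reports
#'
#' Emits (a) a JSON file with estimates, standard errors, Wald p-values,
#' the covariance matrix, log-likelihood, AIC/BIC and convergence
#' diagnostics, and (b) a plain-text coefficient table split into zero
#' part, continuous non-zero part and random effects, including
#' exponentiated coefficients (odds ratios for the zero part;
#' multiplicative mean effects for the continuous part).  P-values below
#' 0.0001 print as "< 0.0001".
#'
#' @param fit an [fit_model] result.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<basename>.json` and
#'   `<basename>.txt`.
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, dir, basename = "fit") {
  stopifnot(inherits(fit, "mtp_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, paste0(basename, ".json"))
  txt_path <- file.path(dir, paste0(basename, ".txt"))

  tab <- coef_table(fit)
  payload <- list(
    family = fit$spec$family,
    distribution = fit$spec$distribution,
    converged = fit$converged,
    n_iter = fit$n_iter,
    gradient_norm = fit$gradient_norm,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs,
    n_params = fit$n_params,
    loglik = fit$loglik,
    aic = fit$aic,
    bic = fit$bic,
    estimates = as.list(fit$estimates),
    se = as.list(fit$se),
    p_value = stats::setNames(as.list(tab$p), names(fit$estimates)),
    vcov = fit$vcov
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")

  con <- file(txt_path, "w")
  on.exit(close(con))
  out <- function(...) cat(..., "\n", sep = "", file = con)
  fam_label <- c(mtp = "Marginalized two-part model",
                 tp_correlated = "Two-part model (correlated random intercepts)",
                 tp_uncorrelated = "Two-part model (uncorrelated random intercepts)",
                 one_part = "One-part model")[fit$spec$family]
  out(fam_label, " -- ", fit$spec$distribution, " continuous part")
  out(sprintf("%d subjects, %d records", fit$n_subjects, fit$n_obs))
  out(sprintf("logLik %.4f   AIC %.4f   BIC %.4f   -2logLik %.4f",
              fit$loglik, fit$aic, fit$bic, -2 * fit$loglik))
  if (!fit$converged)
    out("*** NON-CONVERGENCE: optimizer did not meet its criteria; ",
        "estimates below are not maximum-likelihood ***")
  for (section in unique(tab$section)) {
    out("")
    out(section)
    s <- tab[tab$section == section, , drop = FALSE]
    exp_label <- if (section == "Zero part") "odds ratio"
                 else if (section == "Continuous non-zero part") "exp(coef)"
                 else NULL
    hdr <- sprintf("  %-16s %10s %10s %10s", "term", "estimate", "SE", "P")
    if (!is.null(exp_label)) hdr <- paste0(hdr, sprintf(" %10s", exp_label))
    out(hdr)
    for (i in seq_len(nrow(s))) {
      ptxt <- if (is.na(s$p[i])) "-" else if (s$p[i] < 1e-4) "< 0.0001"
              else formatC(s$p[i], format = "f", digits = 4)
      line <- sprintf("  %-16s %10s %10s %10s", s$term[i],
                      formatC(s$estimate[i], format = "f", digits = 4),
                      ifelse(is.na(s$se[i]), "-",
                             formatC(s$se[i], format = "f", digits = 4)),
                      ptxt)
      if (!is.null(exp_label))
        line <- paste0(line, sprintf(" %10s",
                formatC(exp(s$estimate[i]), format = "f", digits = 3)))
      out(line)
    }
  }
  invisible(c(json = json_path, txt = txt_path))
}

#' Read a JSON fit report back
#'
#' @param path path to a JSON report written by [write_fit_report].
#' @return The parsed report list.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
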