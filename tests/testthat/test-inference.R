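# Marginal likelihood by adaptive quadrature, optimization, SEs, EB modes

test_that("zero random-effect variance reduces to the conditional likelihood", {
  panel <- toy_panel(seed = 31)
  cfg <- toy_config(seed = 31)
  p0 <- model_parameters(cfg$truth$alpha, cfg$truth$coef, cfg$truth$k,
                         cfg$truth$sigma, re_cov(0, 0, 0))
  for (fam in c("mtp", "tp_correlated")) {
    spec <- model_spec(fam, "gamma")
    ml <- marginal_loglik(panel, p0, spec)
    direct <- vapply(seq_len(5), function(i)
      subject_integrand(records_of(panel, i), p0, spec, c(0, 0)), numeric(1))
    expect_equal(ml$subject, direct, tolerance = 1e-12)
  }
})

test_that("a single all-zero record with symmetric intercept integrates to 1/2", {
  # E_{u1 ~ N(0,1)}[1 - expit(u1)] = 1/2 by symmetry
  df <- data.frame(subject = c(1, 2), time = c(0, 0), y = c(0, 2),
                   g = c(0, 0))
  panel <- panel_data(df, "subject", "time", "y", z = "g", x = "g")
  p <- model_parameters(alpha = c(0, 0), coef = c(0, 0), k = 1, sigma = 1,
                        re = re_cov(1, 1e-12, 0))
  spec <- model_spec("tp_correlated", "gamma")
  ml <- marginal_loglik(panel, p, spec, quad_config(15))
  expect_equal(ml$subject[1], log(0.5), tolerance = 1e-6)
})

test_that("adaptive quadrature agrees with brute-force grid integration", {
  panel <- toy_panel(n_subjects = 3, seed = 33)
  cfg <- toy_config(n_subjects = 3, seed = 33)
  spec <- cfg$spec
  brute <- vapply(seq_len(3), function(i)
    brute_subject_loglik(records_of(panel, i), cfg$truth, spec), numeric(1))
  agq7 <- marginal_loglik(panel, cfg$truth, spec, quad_config(7))
  agq15 <- marginal_loglik(panel, cfg$truth, spec, quad_config(15))
  nonad7 <- marginal_loglik(panel, cfg$truth, spec,
                            quad_config(7, adaptive = FALSE))
  expect_equal(agq7$subject, brute, tolerance = 1e-4)
  # stability in the node count and adaptivity payoff
  expect_lt(abs(agq15$total - agq7$total) / abs(agq15$total), 1e-5)
  expect_lt(max(abs(agq7$subject - brute)),
            max(abs(nonad7$subject - brute)))
})

test_that("one-part (1-D) marginal likelihood matches a brute-force oracle", {
  panel <- toy_panel(n_subjects = 3, seed = 35)
  spec <- model_spec("one_part", "gamma", one_part_constant = 0.01)
  p <- model_parameters(NULL, c(0.4, 0.2, -0.2), k = 0.8, sigma = 0.8,
                        re = re_cov(var2 = 0.4))
  ml <- marginal_loglik(panel, p, spec)
  for (i in 1:3) {
    rec <- records_of(panel, i)
    yadj <- ifelse(rec$y > 0, rec$y, 0.01)
    g <- seq(-6 * sqrt(0.4), 6 * sqrt(0.4), length.out = 20001)
    f <- vapply(g, function(u)
      exp(sum(dgg(yadj, mu = drop(rec$X %*% p$coef) + u,
                  sigma = 0.8, k = 0.8, log = TRUE))) *
        stats::dnorm(u, 0, sqrt(0.4)), numeric(1))
    expect_equal(ml$subject[i], log(sum(f) * (g[2] - g[1])),
                 tolerance = 1e-5)
  }
})

test_that("log-likelihood is additive over subjects and order-invariant", {
  cfg <- toy_config(n_subjects = 6, seed = 37)
  panel <- simulate_panel(cfg)
  fr <- attr(panel, "frame")
  spec <- cfg$spec
  ml1 <- marginal_loglik(panel, cfg$truth, spec)
  # duplicate every subject under new ids
  fr2 <- rbind(fr, transform(fr, subject = subject + 1000))
  panel2 <- panel_data(fr2, "subject", "time", "y",
                       z = c("group", "biom"), x = c("group", "biom"))
  ml2 <- marginal_loglik(panel2, cfg$truth, spec)
  expect_equal(ml2$total, 2 * ml1$total, tolerance = 1e-10)
  # shuffle subject blocks
  ord <- c(4, 1, 6, 2, 5, 3)
  fr3 <- do.call(rbind, lapply(ord, function(s) fr[fr$subject == s, ]))
  panel3 <- panel_data(fr3, "subject", "time", "y",
                       z = c("group", "biom"), x = c("group", "biom"))
  ml3 <- marginal_loglik(panel3, cfg$truth, spec)
  expect_equal(ml3$total, ml1$total, tolerance = 1e-10)
})

test_that("fit results satisfy their structural invariants", {
  cfg <- toy_config(n_subjects = 60, n_visits = 4, seed = 39)
  panel <- simulate_panel(cfg)
  fit <- fit_model(panel, cfg$spec, quad_config(5))
  expect_true(fit$converged)
  expect_equal(fit$n_params, 10)  # 3 alpha + 3 beta + 1 shape + 3 covariance
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(is.na(fit$se) | fit$se >= 0))
  expect_equal(unname(coef(fit)), unname(fit$estimates))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  ic <- information_criteria(fit$loglik, fit$n_params, fit$n_subjects)
  expect_equal(unname(ic[["aic"]]), fit$aic)
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 0, 50)
  expect_equal(unname(ic), c(200, 200, 200))
  ic2 <- information_criteria(-100, 3, 50)
  expect_equal(ic2[["aic"]] - ic2[["neg2ll"]], 6)
  expect_equal(ic2[["bic"]] - ic2[["neg2ll"]], 3 * log(50))
})

test_that("the separately-fit binary part matches an independent GLMM oracle", {
  skip_if_not_installed("lme4")
  set.seed(51)
  cfg <- toy_config(n_subjects = 150, n_visits = 6, seed = 51)
  panel <- simulate_panel(cfg)
  fit <- fit_model(panel, model_spec("tp_uncorrelated", "gamma"),
                   quad_config(7))
  fr <- attr(panel, "frame")
  fr$pos <- as.numeric(fr$y > 0)
  gl <- lme4::glmer(pos ~ group + biom + (1 | subject), data = fr,
                    family = stats::binomial(), nAGQ = 7)
  ours <- fit$estimates[c("zero.(Intercept)", "zero.group", "zero.biom")]
  theirs <- lme4::fixef(gl)
  expect_equal(unname(ours), unname(theirs), tolerance = 2e-3)
  expect_equal(unname(fit$estimates[["var1"]]),
               unname(as.data.frame(lme4::VarCorr(gl))$vcov[1]),
               tolerance = 0.02)
  se_ours <- fit$se[c("zero.(Intercept)", "zero.group", "zero.biom")]
  se_theirs <- summary(gl)$coefficients[, "Std. Error"]
  expect_equal(unname(se_ours), unname(se_theirs), tolerance = 0.02)
})

test_that("empirical-Bayes modes match an independent per-subject optimizer", {
  cfg <- toy_config(n_subjects = 5, seed = 53)
  panel <- simulate_panel(cfg)
  spec <- cfg$spec
  ml <- marginal_loglik(panel, cfg$truth, spec)
  G <- cfg$truth$re
  for (i in 1:5) {
    rec <- records_of(panel, i)
    negpost <- function(u)
      -subject_integrand(rec, cfg$truth, spec, u) -
        log(dbvn(u[1], u[2], G$var1, G$var2, G$cov12))
    o <- stats::optim(c(0, 0), negpost, method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
    expect_equal(unname(ml$modes[i, ]), o$par, tolerance = 1e-3)
  }
})

test_that("EB predictions shrink to zero without data and track the outcome level", {
  # subject 99 has all-zero outcomes: no information on u2 in the
  # separately-fit continuous part, so its u2 mode is exactly 0
  set.seed(55)
  df <- data.frame(subject = rep(1:20, each = 4), time = rep(0:3, 20),
                   g = stats::rnorm(80))
  df$y <- ifelse(stats::runif(80) < 0.3, 0, rgg(80, 0.5, 0.8, 0.8))
  df$y[df$subject == 7] <- 0
  df$y[df$subject == 8] <- 30 + stats::runif(4)   # far above the mean
  panel <- panel_data(df, "subject", "time", "y", z = "g", x = "g")
  fit <- fit_model(panel, model_spec("tp_uncorrelated", "gamma"),
                   quad_config(5), control = list(se = FALSE))
  eb <- predict_random_effects(fit)
  expect_equal(unname(eb["7", "u2"]), 0)
  expect_gt(eb["8", "u2"], 0)
  expect_lt(eb["7", "u1"], 0)   # all zeros: lowered non-zero propensity
})

test_that("rescaling a covariate rescales its coefficient and keeps the fit", {
  cfg <- toy_config(n_subjects = 80, n_visits = 4, seed = 57)
  panel <- simulate_panel(cfg)
  fr <- attr(panel, "frame")
  fit1 <- fit_model(panel, cfg$spec, quad_config(5),
                    control = list(se = FALSE))
  fr$biom <- fr$biom * 10
  panel2 <- panel_data(fr, "subject", "time", "y",
                       z = c("group", "biom"), x = c("group", "biom"))
  fit2 <- fit_model(panel2, cfg$spec, quad_config(5),
                    control = list(se = FALSE))
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-5)
  expect_equal(fit2$estimates[["cont.biom"]] * 10,
               fit1$estimates[["cont.biom"]], tolerance = 1e-2)
  expect_equal(fit2$estimates[["zero.biom"]] * 10,
               fit1$estimates[["zero.biom"]], tolerance = 1e-2)
})

test_that("freeing the random-effect correlation never lowers the maximum", {
  cfg <- toy_config(n_subjects = 60, n_visits = 4, seed = 59)
  panel <- simulate_panel(cfg)
  fit_corr <- fit_model(panel, model_spec("tp_correlated", "gamma"),
                        quad_config(5), control = list(se = FALSE))
  fit_unc <- fit_model(panel, model_spec("tp_uncorrelated", "gamma"),
                       quad_config(5), control = list(se = FALSE))
  expect_gte(fit_corr$loglik, fit_unc$loglik - 1e-4)
})

test_that("two-part fits refuse degenerate outcomes", {
  df <- data.frame(subject = rep(1:3, each = 2), time = rep(0:1, 3),
                   g = stats::rnorm(6), y = rep(1.5, 6))
  panel <- panel_data(df, "subject", "time", "y", z = "g", x = "g")
  expect_error(fit_model(panel, model_spec("mtp", "gamma")),
               "zero and positive")
})
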