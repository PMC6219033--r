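# fixtures built in code: small simulated panels and hand-built records

toy_config <- function(n_subjects = 5, n_visits = 4, seed = 7,
                       family = "mtp", distribution = "gamma",
                       target_zero_prop = 0.3, ...) {
  sim_config(n_subjects = n_subjects, n_visits = n_visits,
             spec = model_spec(family, distribution),
             target_zero_prop = target_zero_prop,
             n_replicates = 2, seed = seed, ...)
}

toy_panel <- function(...) simulate_panel(toy_config(...))

# records of one subject from a panel, as used by subject_integrand
records_of <- function(panel, i) {
  idx <- panel$subject_index[[i]]
  list(y = panel$y[idx],
       Z = panel$Z[idx, , drop = FALSE],
       X = panel$X[idx, , drop = FALSE])
}

# bivariate normal density (independent of the package internals)
dbvn <- function(u1, u2, var1, var2, cov12) {
  s1 <- sqrt(var1); s2 <- sqrt(var2); r <- cov12 / (s1 * s2)
  a <- u1 / s1; b <- u2 / s2
  exp(-(a^2 - 2 * r * a * b + b^2) / (2 * (1 - r^2))) /
    (2 * pi * s1 * s2 * sqrt(1 - r^2))
}

# brute-force marginal log-likelihood of one subject on a 2-D grid
brute_subject_loglik <- function(rec, params, spec, n_grid = 401, half = 6) {
  g1 <- seq(-half * sqrt(params$re$var1), half * sqrt(params$re$var1),
            length.out = n_grid)
  g2 <- seq(-half * sqrt(params$re$var2), half * sqrt(params$re$var2),
            length.out = n_grid)
  f <- outer(g1, g2, Vectorize(function(a, b)
    subject_integrand(rec, params, spec, c(a, b), log = FALSE) *
      dbvn(a, b, params$re$var1, params$re$var2, params$re$cov12)))
  log(sum(f) * (g1[2] - g1[1]) * (g2[2] - g2[1]))
}
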