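# Generalized gamma family: density, special cases, moments, offset, sampling

test_that("closed-form anchor values of the density and offset hold", {
  # Weibull(1, 1) = Exponential(1) at y = 1
  expect_equal(dgg(1, mu = 0, sigma = 1, k = 1, log = TRUE), -1)
  # gamma special case: zero offset
  expect_identical(gg_offset(0.7, 0.7), 0)
  # Weibull case: C = log Gamma(1 + sigma)
  expect_equal(gg_offset(0.5, 1), lgamma(1.5))
  expect_equal(gg_offset(0.5, 1), -0.12078, tolerance = 1e-4)
  # lognormal limit: C = sigma^2 / 2
  expect_equal(gg_offset(1, 1e-6), 0.5)
  # means: gamma case -> exp(mu); Weibull mean Gamma(1.5) = sqrt(pi)/2
  expect_equal(gg_mean(0, 0.7, 0.7), 1)
  expect_equal(gg_mean(0, 0.5, 1), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(gg_mean(0, 1, 1e-6), exp(0.5))
})

test_that("density normalizes to one over the parameter grid", {
  for (k in c(-1, -0.3, 0.3, 0.7, 1, 1.5)) {
    for (sigma in c(0.3, 1, 2)) {
      for (mu in c(-1, 0, 1)) {
        total <- stats::integrate(function(y) dgg(y, mu, sigma, k),
                                  0, Inf, rel.tol = 1e-9)$value
        expect_equal(total, 1, tolerance = 1e-6,
                     label = sprintf("normalization k=%g sigma=%g mu=%g",
                                     k, sigma, mu))
      }
    }
  }
})

test_that("special cases reduce to Weibull, gamma and lognormal densities", {
  y <- c(0.05, 0.3, 1, 2.5, 8)
  for (sigma in c(0.4, 1, 1.6)) {
    for (mu in c(-0.5, 0.8)) {
      expect_equal(dgg(y, mu, sigma, k = 1, log = TRUE),
                   stats::dweibull(y, shape = 1 / sigma, scale = exp(mu),
                                   log = TRUE),
                   tolerance = 1e-10)
    }
  }
  for (k in c(0.4, 0.9, 1.5)) {
    shape <- 1 / k^2
    # gamma with mean exp(mu): shape/rate parameterization
    expect_equal(dgg(y, mu = 0.3, sigma = k, k = k, log = TRUE),
                 stats::dgamma(y, shape = shape, rate = shape / exp(0.3),
                               log = TRUE),
                 tolerance = 1e-10)
  }
  # lognormal limit at the switch threshold
  expect_equal(dgg(y, 0.2, 0.9, k = 1e-4, log = TRUE),
               stats::dlnorm(y, 0.2, 0.9, log = TRUE),
               tolerance = 1e-4)
  # continuity across the switch: |k| just above the threshold
  expect_equal(dgg(y, 0.2, 0.9, k = 2e-4, log = TRUE),
               stats::dlnorm(y, 0.2, 0.9, log = TRUE),
               tolerance = 1e-3)
})

test_that("density agrees with an independent generalized-gamma oracle", {
  skip_if_not_installed("flexsurv")
  y <- c(0.1, 0.7, 1.3, 4)
  for (k in c(-1.2, -0.4, 0.5, 1, 1.8)) {
    for (sigma in c(0.5, 1.1)) {
      expect_equal(dgg(y, 0.3, sigma, k, log = TRUE),
                   flexsurv::dgengamma(y, mu = 0.3, sigma = sigma, Q = k,
                                       log = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("moments match numerical quadrature and lognormal closed forms", {
  expect_equal(gg_moment(2, 0, 1, 1e-6), exp(2))
  expect_equal(gg_moment(1, 0.3, 0.8, 0.5), gg_mean(0.3, 0.8, 0.5))
  for (s in c(0.5, 1, 2, 3)) {
    m <- gg_moment(s, 0.2, 0.6, 0.9)
    q <- stats::integrate(function(y) y^s * dgg(y, 0.2, 0.6, 0.9),
                          0, Inf, rel.tol = 1e-10)$value
    expect_equal(m, q, tolerance = 1e-6)
  }
  # variance identities
  expect_equal(gg_var(0, 1, 1e-6), (exp(1) - 1) * exp(1))
  expect_equal(gg_var(0, 1, 1), 1)  # Exponential(1)
  v <- gg_var(0.2, 0.9, 0.6)
  qm1 <- stats::integrate(function(y) y * dgg(y, 0.2, 0.9, 0.6),
                          0, Inf, rel.tol = 1e-10)$value
  qm2 <- stats::integrate(function(y) y^2 * dgg(y, 0.2, 0.9, 0.6),
                          0, Inf, rel.tol = 1e-10)$value
  expect_equal(v, qm2 - qm1^2, tolerance = 1e-6)
})

test_that("non-existent moments raise an explicit error", {
  # k < 0: E(Y^s) requires 1/k^2 + s*sigma/k > 0
  expect_error(gg_moment(2, 0, 1, -0.5), "moment undefined")
  expect_error(gg_mean(0, 3, -0.5), "undefined")
  expect_error(dgg(-1, 0, 1, 1), "> 0")
  expect_error(dgg(1, 0, -1, 1), "sigma")
})

test_that("sampling is reproducible and matches the analytic moments", {
  expect_identical(rgg(0, 0, 1, 1), numeric(0))
  set.seed(41)
  a <- rgg(100, 0.2, 0.9, 0.6)
  set.seed(41)
  b <- rgg(100, 0.2, 0.9, 0.6)
  expect_identical(a, b)

  set.seed(42)
  x <- rgg(1e5, 0, 1, 1)           # Exponential(1)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))

  set.seed(43)
  for (p in list(c(k = 0.6, sigma = 0.9, mu = 0.2),
                 c(k = -0.8, sigma = 0.5, mu = -0.1))) {
    y <- rgg(1e5, p[["mu"]], p[["sigma"]], p[["k"]])
    m <- gg_mean(p[["mu"]], p[["sigma"]], p[["k"]])
    v <- gg_var(p[["mu"]], p[["sigma"]], p[["k"]])
    expect_lt(abs(mean(y) - m), 4 * sqrt(v / 1e5))
    expect_lt(abs(stats::var(y) / v - 1), 0.1)
  }
})

test_that("samples follow the density (goodness of fit vs integrated CDF)", {
  skip_if_not_installed("flexsurv")
  set.seed(44)
  y <- rgg(2e4, 0.2, 0.9, 0.6)
  ks <- suppressWarnings(stats::ks.test(
    y, function(q) flexsurv::pgengamma(q, mu = 0.2, sigma = 0.9, Q = 0.6)))
  expect_gt(ks$p.value, 0.01)
})
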