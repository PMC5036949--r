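# Conjugate family updates and predictive densities against independent
# oracles (closed-form marginals, quadrature, enumeration).

test_that("spherical Gaussian posterior update matches the closed form", {
  m <- spherical_gaussian(0, 1, 1)
  # zero points: posterior equals prior exactly
  expect_identical(posterior_update(m, NULL), m)
  expect_equal(posterior_update(m, matrix(numeric(0), 0, 1)), m)
  # one point at 2: sigma_k = 1/2, mu_k = 1
  post <- posterior_update(m, 2)
  expect_equal(post$sigma0sq, 1 / 2)
  expect_equal(post$mu0, 1)
  # general case against a direct transcription of the update
  set.seed(7)
  xs <- rnorm(5, 3, 2)
  m2 <- spherical_gaussian(c(1, -1), 2.5, 0.7)
  X <- cbind(xs, rev(xs))
  post2 <- posterior_update(m2, X)
  sk <- 1 / (1 / 2.5 + 5 / 0.7)
  expect_equal(post2$sigma0sq, sk)
  expect_equal(post2$mu0, unname(sk * (c(1, -1) / 2.5 + colSums(X) / 0.7)))
})

test_that("discrete-family posterior updates follow the conjugate counts", {
  post <- posterior_update(bernoulli_feature(1, 1), c(1, 1, 0))
  expect_equal(post$a0, 3)
  expect_equal(post$b0, 2)
  post <- posterior_update(binomial_feature(4, 2, 3), c(0, 4, 2))
  expect_equal(post$a0, 2 + 6)
  expect_equal(post$b0, 3 + 12 - 6)
  post <- posterior_update(categorical_feature(3), c(1, 1, 3))
  expect_equal(post$alpha0, c(3, 1, 2))
  post <- posterior_update(poisson_feature(2, 1), c(0, 5, 2))
  expect_equal(post$a0, 9)
  expect_equal(post$b0, 4)
})

test_that("incremental add/remove of a point equals batch recomputation", {
  models <- list(
    spherical_gaussian(c(0, 0), 2, 0.5),
    full_gaussian(c(0, 0), 1, 4, diag(2)),
    elliptical_model(list(g = spherical_gaussian(0, 1, 1),
                          b = bernoulli_feature(),
                          p = poisson_feature())))
  datasets <- list(
    matrix(rnorm(20, 1), ncol = 2),
    matrix(rnorm(20, 1), ncol = 2),
    cbind(rnorm(10), rbinom(10, 1, 0.4), rpois(10, 3)))
  set.seed(11)
  for (j in seq_along(models)) {
    model <- models[[j]]
    X <- datasets[[j]]
    # accumulate sufficient statistics; removing point i must reproduce the
    # batch posterior on X[-i, ], and re-adding it the batch posterior on X
    stat <- Reduce(`+`, lapply(seq_len(nrow(X)),
                               function(i) mapdp:::suff_of(model, X[i, ])))
    batch <- posterior_update(model, X)
    for (i in seq_len(nrow(X))) {
      s_i <- mapdp:::suff_of(model, X[i, ])
      excl <- mapdp:::posterior_from_stats(model, stat - s_i, nrow(X) - 1)
      expect_equal(unclass(excl),
                   unclass(posterior_update(model, X[-i, , drop = FALSE])),
                   tolerance = 1e-10)
      restored <- mapdp:::posterior_from_stats(model, (stat - s_i) + s_i, nrow(X))
      expect_equal(unclass(restored), unclass(batch), tolerance = 1e-10)
    }
  }
})

test_that("discrete predictives are normalized over their support", {
  post <- posterior_update(bernoulli_feature(2, 5), c(1, 0, 0))
  expect_equal(sum(exp(sapply(0:1, function(x) log_predictive(post, x)))), 1,
               tolerance = 1e-8)
  post <- posterior_update(binomial_feature(6, 0.5, 2), c(3, 1))
  expect_equal(sum(exp(sapply(0:6, function(x) log_predictive(post, x)))), 1,
               tolerance = 1e-8)
  post <- posterior_update(categorical_feature(4, c(1, 2, 3, 4)), c(2, 2, 4))
  expect_equal(sum(exp(sapply(1:4, function(x) log_predictive(post, x)))), 1,
               tolerance = 1e-8)
  # Poisson predictive (negative binomial): truncate with a generous tail
  post <- posterior_update(poisson_feature(2, 1), c(4, 7))
  expect_equal(sum(exp(sapply(0:500, function(x) log_predictive(post, x)))), 1,
               tolerance = 1e-8)
})

test_that("predictive equals the marginal-likelihood ratio (conjugacy identity)", {
  # Beta-Bernoulli on <= 5 points
  xs <- c(1, 0, 1, 1)
  for (x_new in 0:1) {
    post <- posterior_update(bernoulli_feature(1.5, 2), xs)
    expect_equal(log_predictive(post, x_new),
                 log_marginal_bernoulli(1.5, 2, c(xs, x_new)) -
                   log_marginal_bernoulli(1.5, 2, xs),
                 tolerance = 1e-8)
  }
  # Beta(1,1) prior predictive at 1 is exactly 1/2
  expect_equal(exp(log_predictive(bernoulli_feature(1, 1), 1)), 0.5)
  # spherical Gaussian, marginal by quadrature over the mean
  xs <- c(0.3, -1.1, 2.4)
  m <- spherical_gaussian(0.5, 2, 0.8)
  post <- posterior_update(m, xs)
  for (x_new in c(-0.7, 1.9)) {
    expect_equal(log_predictive(post, x_new),
                 log_marginal_gauss1d(0.5, 2, 0.8, c(xs, x_new)) -
                   log_marginal_gauss1d(0.5, 2, 0.8, xs),
                 tolerance = 1e-8)
  }
})

test_that("Gamma-Poisson predictive matches quadrature over the rate", {
  post <- poisson_feature(2, 1)
  for (x in c(0, 3)) {
    quad <- stats::integrate(function(l) stats::dpois(x, l) * stats::dgamma(l, 2, 1),
                             0, 60, rel.tol = 1e-12)$value
    expect_equal(exp(log_predictive(post, x)), quad, tolerance = 1e-8)
  }
})

test_that("NIW Student-t predictive matches the marginal-likelihood ratio", {
  set.seed(3)
  X <- matrix(rnorm(8), ncol = 2)
  m0 <- c(0.2, -0.3); kappa0 <- 1.4; nu0 <- 4.5
  S0 <- matrix(c(1.2, 0.3, 0.3, 0.8), 2, 2)
  model <- full_gaussian(m0, kappa0, nu0, S0)
  post <- posterior_update(model, X)
  for (i in 1:3) {
    x_new <- rnorm(2)
    expect_equal(log_predictive(post, x_new),
                 log_marginal_niw(m0, kappa0, nu0, S0, rbind(X, x_new)) -
                   log_marginal_niw(m0, kappa0, nu0, S0, X),
                 tolerance = 1e-8)
  }
})

test_that("1-D NIW predictive matches dense-grid integration over (mean, variance)", {
  # univariate case: NIW reduces to normal-inverse-chi-squared; integrate
  # N(x | mu, s2) against the posterior density on a dense grid
  m0 <- 0.5; kappa0 <- 2; nu0 <- 5; S0 <- matrix(1.5)
  model <- full_gaussian(m0, kappa0, nu0, S0)
  xs <- c(0.4, 1.7, -0.2, 0.9)
  post <- posterior_update(model, xs)
  mn <- post$m0; kn <- post$kappa0; nun <- post$nu0; Sn <- post$S0[1, 1]
  # posterior density: s2 ~ Inv-Gamma(nun/2, Sn/2), mu | s2 ~ N(mn, s2/kn)
  mu_grid <- seq(mn - 10, mn + 10, length.out = 1200)
  s2_edges <- exp(seq(log(Sn / nun) - 7, log(Sn / nun) + 7, length.out = 801))
  dmu <- mu_grid[2] - mu_grid[1]
  for (x_new in c(0.0, 2.5)) {
    total <- 0
    for (j in seq_len(length(s2_edges) - 1)) {
      s2 <- sqrt(s2_edges[j] * s2_edges[j + 1])  # midpoint in log space
      ds2 <- s2_edges[j + 1] - s2_edges[j]
      dens_s2 <- exp((nun / 2) * log(Sn / 2) - lgamma(nun / 2) -
                       (nun / 2 + 1) * log(s2) - Sn / (2 * s2))
      dens_mu <- stats::dnorm(mu_grid, mn, sqrt(s2 / kn))
      lik <- stats::dnorm(x_new, mu_grid, sqrt(s2))
      total <- total + dens_s2 * sum(dens_mu * lik) * dmu * ds2
    }
    expect_equal(exp(log_predictive(post, x_new)), total, tolerance = 1e-4)
  }
})

test_that("elliptical log predictive factorizes and marginalizes NAs", {
  g <- spherical_gaussian(0, 1, 1)
  ell1 <- elliptical_model(list(g = g))
  expect_equal(elliptical_log_predictive(ell1, 0.7), log_predictive(g, 0.7))
  g2 <- spherical_gaussian(1, 2, 0.5)
  ell2 <- elliptical_model(list(a = g, b = g2))
  expect_equal(elliptical_log_predictive(ell2, c(0.7, -0.2)),
               log_predictive(g, 0.7) + log_predictive(g2, -0.2))
  expect_identical(elliptical_log_predictive(ell2, c(NA, NA)), 0)
  expect_equal(elliptical_log_predictive(ell2, c(NA, -0.2)),
               log_predictive(g2, -0.2))
  expect_error(elliptical_log_predictive(ell2, c(1, 2, 3)), "schema length")
})

test_that("support violations and invalid states raise informative errors", {
  expect_error(posterior_update(bernoulli_feature(), c(0, 2)), "Bernoulli support")
  expect_error(posterior_update(binomial_feature(4), 5), "0..4")
  expect_error(posterior_update(categorical_feature(3), 4), "levels 1..3")
  expect_error(posterior_update(poisson_feature(), -1), "non-negative count")
  expect_error(posterior_update(poisson_feature(), 2.5), "non-negative count")
  ell <- elliptical_model(list(x = spherical_gaussian(0, 1, 1),
                               flag = bernoulli_feature()))
  expect_error(posterior_update(ell, matrix(c(0, 7), 1, 2)), "flag")
  bad <- spherical_gaussian(0, 1, 1)
  bad$mu0 <- NaN
  expect_error(log_predictive(bad, 0), "non-finite hyperparameters")
})
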