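# Independent oracles used across the suite. Everything here is deliberately
# naive (enumeration, quadrature, closed-form marginals, sequential products)
# and never calls the code paths it is used to check.

# all set partitions of n items as canonical assignment vectors
enumerate_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in enumerate_partitions(n - 1L)) {
    K <- max(p)
    for (k in seq_len(K + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

# CRP partition probability as the product of sequential seating probabilities
seq_partition_log_prob <- function(z, n0) {
  lp <- 0
  sizes <- numeric(0)
  for (i in seq_along(z)) {
    probs <- c(sizes, n0) / (n0 + i - 1)
    k <- z[i]
    lp <- lp + log(probs[min(k, length(probs))])
    if (k > length(sizes)) sizes <- c(sizes, 1) else sizes[k] <- sizes[k] + 1
  }
  lp
}

# marginal likelihood oracles ------------------------------------------------

# Beta-Bernoulli marginal: B(a0 + s, b0 + n - s) / B(a0, b0)
log_marginal_bernoulli <- function(a0, b0, xs) {
  s <- sum(xs)
  lbeta(a0 + s, b0 + length(xs) - s) - lbeta(a0, b0)
}

# 1-D Gaussian (known variance sh) marginal by quadrature over the mean
log_marginal_gauss1d <- function(mu0, s0, sh, xs) {
  f <- function(mu) {
    stats::dnorm(mu, mu0, sqrt(s0)) *
      vapply(mu, function(m) prod(stats::dnorm(xs, m, sqrt(sh))), numeric(1))
  }
  log(stats::integrate(f, mu0 - 15 * sqrt(s0), mu0 + 15 * sqrt(s0),
                       rel.tol = 1e-12)$value)
}

# multivariate log gamma
lmvgamma <- function(a, D) {
  (D * (D - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

# closed-form NIW marginal likelihood of a data matrix (rows = points)
log_marginal_niw <- function(m0, kappa0, nu0, S0, X) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (n == 0) return(0)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))
  kn <- kappa0 + n
  nun <- nu0 + n
  dev <- xbar - m0
  Sn <- S0 + S + (kappa0 * n / kn) * tcrossprod(dev)
  -(n * D / 2) * log(pi) + (D / 2) * (log(kappa0) - log(kn)) +
    (nu0 / 2) * as.numeric(determinant(S0)$modulus) -
    (nun / 2) * as.numeric(determinant(Sn)$modulus) +
    lmvgamma(nun / 2, D) - lmvgamma(nu0 / 2, D)
}

# mutual information from an explicitly built contingency table
nmi_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (i in ua) for (j in ub) {
    nij <- sum(a == i & b == j)
    if (nij > 0)
      mi <- mi + (nij / n) * log(nij * n / (sum(a == i) * sum(b == j)))
  }
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ha <- ent(a); hb <- ent(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# fixtures --------------------------------------------------------------------

# two well-separated spherical blobs in 2-D
two_blob_data <- function(n_per = 30, dist = 10, seed = 42) {
  set.seed(seed)
  rbind(matrix(stats::rnorm(2 * n_per), ncol = 2),
        matrix(stats::rnorm(2 * n_per, mean = dist), ncol = 2))
}

# mixed-type K = 3 clustering problem: two Gaussian features, one Bernoulli,
# one Poisson; separation mainly through the Gaussian features (~4 sd)
mixed_type_data <- function(n = 1000, seed = 1) {
  set.seed(seed)
  props <- c(0.4, 0.35, 0.25)
  counts <- floor(props * n)
  counts[1] <- counts[1] + n - sum(counts)
  g1_mu <- c(0, 4, 8); g2_mu <- c(0, -3, 3)
  bern_p <- c(0.1, 0.5, 0.9); pois_l <- c(2, 8, 20)
  labels <- rep(1:3, counts)
  X <- cbind(
    g1 = stats::rnorm(n, g1_mu[labels], 1),
    g2 = stats::rnorm(n, g2_mu[labels], 1),
    yes = stats::rbinom(n, 1, bern_p[labels]),
    count = stats::rpois(n, pois_l[labels]))
  list(X = X, labels = labels,
       schema = list(
         list(name = "g1", kind = "gaussian", params = list()),
         list(name = "g2", kind = "gaussian", params = list()),
         list(name = "yes", kind = "bernoulli", params = list()),
         list(name = "count", kind = "poisson", params = list())))
}
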