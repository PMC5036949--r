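# Hyperparameter estimation for (theta0, n0).
#
# Default protocol: n0 fixed (3 in the synthetic benchmarks) and theta0 set by
# empirical Bayes, approximated by maximum-likelihood moment matching on the
# pooled data -- the standard parametric-EB point estimate, exact enough here
# because the cluster parameters are already integrated out. The estimation
# routines below (MAP for n0 under a Gamma prior, greedy coordinate search,
# cross-validation) are opt-in.

#' Empirical-Bayes prior for a full Gaussian model
#'
#' `m0` = pooled mean, `kappa0 = 1` (unit information), `nu0 = D + 2` (the
#' smallest integer df giving the inverse-Wishart a finite mean and the
#' Student-t predictive heavy but integrable tails), and `S0` chosen so the
#' prior expected covariance `S0 / (nu0 - D - 1)` equals the pooled covariance.
#'
#' @param X Numeric data matrix.
#' @param kappa0,nu0 Overridable prior strengths.
#' @return A [full_gaussian()] prior.
#' @export
eb_full_gaussian <- function(X, kappa0 = 1, nu0 = ncol(X) + 2) {
  X <- as.matrix(X)
  D <- ncol(X)
  S <- stats::cov(X)
  if (any(diag(S) <= 0))
    stop("zero-variance feature: remove it or supply an explicit prior")
  full_gaussian(colMeans(X), kappa0, nu0, S * (nu0 - D - 1))
}

#' Empirical-Bayes prior for the spherical Gaussian model
#'
#' `mu0` = pooled mean and `sigma0sq` = pooled per-dimension variance
#' (averaged over dimensions). The known cluster variance `sigma_sq` cannot be
#' identified from pooled moments; when not supplied it defaults to a tenth of
#' the pooled variance (clusters assumed to occupy ~1/10 of the global
#' spread), which should be overridden whenever the measurement variance is
#' actually known.
#'
#' @param X Numeric data matrix.
#' @param sigma_sq Known spherical cluster variance (optional).
#' @return A [spherical_gaussian()] prior.
#' @export
eb_spherical_gaussian <- function(X, sigma_sq = NULL) {
  X <- as.matrix(X)
  v <- mean(apply(X, 2, stats::var))
  if (v <= 0) stop("zero-variance data: cannot set an empirical-Bayes prior")
  spherical_gaussian(colMeans(X), v, if (is.null(sigma_sq)) v / 10 else sigma_sq)
}

#' Empirical-Bayes priors for a mixed-type feature schema
#'
#' Per-feature maximum-likelihood moment matching with unit-information prior
#' strength: Gaussian features get `mu0` = feature mean, `sigma0sq` = feature
#' variance (and `sigma_sq` = variance/10 unless declared in the schema);
#' Bernoulli/binomial features get `Beta(p, 1 - p)` matched to the observed
#' frequency; categorical features a Dirichlet proportional to smoothed level
#' frequencies with total strength 1; Poisson features `Gamma(mean, 1)`.
#'
#' @param X Data matrix (columns follow the schema; NAs allowed and skipped).
#' @param schema A feature schema, see [read_schema()]: list of entries with
#'   `name`, `kind` and optional `params`.
#' @return An [elliptical_model()] prior.
#' @export
empirical_bayes_theta0 <- function(X, schema) {
  X <- as.matrix(X)
  if (ncol(X) != length(schema))
    stop("schema covers ", length(schema), " features but data has ", ncol(X))
  feats <- vector("list", length(schema))
  for (m in seq_along(schema)) {
    ent <- schema[[m]]
    x <- X[, m]
    x <- x[!is.na(x)]
    if (!length(x)) stop("feature '", ent$name, "' has no observed values")
    feats[[m]] <- switch(
      ent$kind,
      gaussian = {
        v <- stats::var(x)
        if (!is.finite(v) || v <= 0)
          stop("zero-variance feature '", ent$name,
               "': remove it or supply a known-variance override")
        sh <- ent$params$sigma_sq
        spherical_gaussian(mean(x), v, if (is.null(sh)) v / 10 else sh)
      },
      bernoulli = {
        p <- mean(x)
        if (p <= 0 || p >= 1)
          stop("degenerate Bernoulli feature '", ent$name, "' (all ",
               round(p), "s): remove it")
        bernoulli_feature(p, 1 - p)
      },
      binomial = {
        Tn <- ent$params$n_trials
        p <- mean(x) / Tn
        if (p <= 0 || p >= 1)
          stop("degenerate binomial feature '", ent$name, "': remove it")
        binomial_feature(Tn, p, 1 - p)
      },
      categorical = {
        L <- ent$params$n_levels
        cnt <- tabulate(x, nbins = L)
        categorical_feature(L, (cnt + 1 / L) / (length(x) + 1))
      },
      poisson = {
        m_hat <- mean(x)
        if (m_hat <= 0) stop("all-zero count feature '", ent$name, "': remove it")
        poisson_feature(m_hat, 1)
      },
      stop("unknown feature kind '", ent$kind, "'")
    )
    names(feats)[m] <- ent$name
  }
  elliptical_model(feats)
}

#' MAP estimate of the concentration under a Gamma prior
#'
#' Maximizes the posterior over the concentration,
#' `p(n0 | N, K+) ~ Gamma(n0)/Gamma(n0 + n) * n0^k_plus * n0^(a-1) e^(-b n0)`,
#' by Newton iterations on `u = ln n0` (the log parametrization guarantees
#' positivity, and the log posterior is concave in `u`, so the maximum is
#' unique); on non-convergence a bracketed bisection on the gradient is used
#' with a warning. With a flat prior (`a = 1`, `b` small) the mode approaches
#' the maximizer of the CRP marginal term itself.
#'
#' @param n Number of observations.
#' @param k_plus Observed number of clusters (>= 1).
#' @param a,b Gamma prior shape and rate on `n0` (default 1, 0.1: weakly
#'   informative).
#' @param tol Relative tolerance on `ln n0` (default 1e-8).
#' @return The MAP value of `n0` (positive scalar).
#' @export
map_n0 <- function(n, k_plus, a = 1, b = 0.1, tol = 1e-8) {
  stopifnot(n >= 1, k_plus >= 1, a > 0, b > 0)
  grad <- function(u) {
    n0 <- exp(u)
    n0 * (digamma(n0) - digamma(n0 + n)) + (k_plus + a - 1) - b * n0
  }
  hess <- function(u) {
    n0 <- exp(u)
    n0 * (digamma(n0) - digamma(n0 + n)) +
      n0^2 * (trigamma(n0) - trigamma(n0 + n)) - b * n0
  }
  u <- log(max(k_plus / log(n + 1), 1e-3))  # sensible start: E[K] ~ n0 log n
  ok <- FALSE
  for (it in 1:100) {
    g <- grad(u)
    h <- hess(u)
    step <- -g / h
    if (!is.finite(step)) break
    step <- max(min(step, 5), -5)
    u_new <- u + step
    if (abs(u_new - u) < tol * max(1, abs(u))) { u <- u_new; ok <- TRUE; break }
    u <- u_new
  }
  if (!ok) {
    warning("Newton did not converge; falling back to bisection")
    lo <- -10; hi <- 10
    if (grad(lo) < 0 || grad(hi) > 0)
      return(exp(if (grad(lo) < 0) lo else hi))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (grad(mid) > 0) lo <- mid else hi <- mid
    }
    u <- (lo + hi) / 2
  }
  exp(u)
}

# log of the Gamma-prior concentration posterior at n0 = exp(u), up to a constant
log_post_ln_n0 <- function(u, n, k_plus, a = 1, b = 0.1) {
  n0 <- exp(u)
  lgamma(n0) - lgamma(n0 + n) + (k_plus + a - 1) * u - b * n0
}

#' Greedy coordinate search over hyperparameter grids
#'
#' Coordinate descent over finite grids of prior models and concentrations:
#' each candidate is scored by the converged objective of a MAP-DP fit
#' *including* the `C(n0, N)` constant (required for scores to be comparable
#' across different `n0`), and the coordinate is set to the argmin before
#' moving on, until a full cycle changes nothing.
#'
#' @param X Data matrix.
#' @param theta0_grid List of candidate prior component models.
#' @param n0_grid Numeric vector of candidate concentrations.
#' @param config A [mapdp_config()] used for every candidate fit.
#' @return List with `theta0_index`, `theta0`, `n0`, `score`, and `table`
#'   (a data frame of every evaluated candidate with its score).
#' @export
greedy_restart_search <- function(X, theta0_grid, n0_grid,
                                  config = mapdp_config()) {
  stopifnot(length(theta0_grid) >= 1, length(n0_grid) >= 1)
  N <- nrow(as.matrix(X))
  score_of <- function(ti, n0) {
    fit <- mapdp_fit(X, theta0_grid[[ti]], n0 = n0, config = config)
    fit$nll - crp_constant(n0, N)
  }
  tab <- data.frame(theta0_index = integer(0), n0 = numeric(0), nll = numeric(0))
  memo <- new.env(parent = emptyenv())
  eval_memo <- function(ti, n0) {
    key <- paste(ti, format(n0, digits = 15))
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- score_of(ti, n0)
    memo[[key]] <- s
    tab[nrow(tab) + 1L, ] <<- list(ti, n0, s)
    s
  }
  ti <- 1L
  n0 <- n0_grid[1L]
  repeat {
    s_theta <- vapply(seq_along(theta0_grid), eval_memo, numeric(1), n0 = n0)
    ti_new <- which.min(s_theta)
    s_n0 <- vapply(n0_grid, function(v) eval_memo(ti_new, v), numeric(1))
    n0_new <- n0_grid[which.min(s_n0)]
    if (ti_new == ti && n0_new == n0) break
    ti <- ti_new
    n0 <- n0_new
  }
  list(theta0_index = ti, theta0 = theta0_grid[[ti]], n0 = n0,
       score = eval_memo(ti, n0), table = tab)
}

#' Cross-validated hyperparameter selection
#'
#' Scores each `(theta0, n0)` candidate by the mean held-out negative log
#' likelihood over folds, where the held-out likelihood of a row is its
#' mixture predictive density under the training-fold fit, and returns the
#' argmin.
#'
#' @param X Data matrix.
#' @param candidates List of candidates, each a list with elements `model`
#'   (prior) and `n0`.
#' @param folds Number of folds (>= 2).
#' @param seed Seed for the fold split.
#' @param config A [mapdp_config()] for the training fits.
#' @return List with `best` (candidate index), `candidate`, and `scores`
#'   (mean held-out negative log likelihood per candidate).
#' @export
cv_select <- function(X, candidates, folds = 5, seed = 1,
                      config = mapdp_config()) {
  stopifnot(folds >= 2, length(candidates) >= 1)
  X <- as.matrix(X)
  N <- nrow(X)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = N))
  if (any(tabulate(fold_id, folds) == 0)) stop("a fold has zero points")
  scores <- vapply(candidates, function(cand) {
    per_fold <- vapply(seq_len(folds), function(f) {
      train <- X[fold_id != f, , drop = FALSE]
      test <- X[fold_id == f, , drop = FALSE]
      fit <- mapdp_fit(train, cand$model, n0 = cand$n0, config = config)
      -heldout_loglik(fit, test)
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  best <- which.min(scores)
  list(best = best, candidate = candidates[[best]], scores = scores)
}
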