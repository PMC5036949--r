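# Conjugate exponential-family component models.
#
# Each model object carries the hyperparameters of a conjugate prior (or,
# after updating on data, a posterior -- conjugacy means both have the same
# shape). The collapsed clustering algorithm only ever needs three things
# from a family: a sufficient-statistic representation of a set of points,
# the hyperparameter update given those statistics, and the log posterior
# predictive density ln f(x | theta).

#' Spherical Gaussian component with known cluster variance
#'
#' Normal likelihood with isotropic covariance `sigma_sq * I` (known) and a
#' conjugate Normal prior on the cluster centroid: `mu ~ N(mu0, sigma0sq * I)`.
#' The posterior over the centroid given `n` assigned points with sum `s` has
#' variance `sigma_k = 1 / (1/sigma0sq + n/sigma_sq)` and mean
#' `mu_k = sigma_k * (mu0/sigma0sq + s/sigma_sq)`; the posterior predictive is
#' Gaussian with variance `sigma_k + sigma_sq` in every dimension.
#'
#' @param mu0 Numeric vector, prior centroid location (length = data dimension).
#' @param sigma0sq Positive scalar, prior centroid variance.
#' @param sigma_sq Positive scalar, known within-cluster (spherical) variance.
#' @return A component model object of class `mapdp_spherical`.
#' @examples
#' m <- spherical_gaussian(mu0 = c(0, 0), sigma0sq = 10, sigma_sq = 1)
#' post <- posterior_update(m, matrix(c(2, 0), 1, 2))
#' log_predictive(post, c(2, 0))
#' @export
spherical_gaussian <- function(mu0, sigma0sq, sigma_sq) {
  stopifnot(is.numeric(mu0), length(mu0) >= 1L,
            is.numeric(sigma0sq), length(sigma0sq) == 1L, sigma0sq > 0,
            is.numeric(sigma_sq), length(sigma_sq) == 1L, sigma_sq > 0)
  structure(list(mu0 = as.numeric(mu0), sigma0sq = as.numeric(sigma0sq),
                 sigma_sq = as.numeric(sigma_sq)),
            class = c("mapdp_spherical", "mapdp_model"))
}

#' Full-covariance Gaussian component (Normal-inverse-Wishart prior)
#'
#' Multivariate Normal likelihood with unknown mean and covariance under the
#' conjugate Normal-inverse-Wishart prior NIW(m0, kappa0, nu0, S0). The
#' posterior predictive is a multivariate Student-t distribution.
#'
#' @param m0 Numeric vector, prior mean location.
#' @param kappa0 Positive scalar, prior strength on the mean (pseudo-count).
#' @param nu0 Scalar degrees of freedom, must exceed `length(m0) - 1`.
#' @param S0 Positive-definite scale matrix, `length(m0)` square.
#' @return A component model object of class `mapdp_niw`.
#' @export
full_gaussian <- function(m0, kappa0, nu0, S0) {
  D <- length(m0)
  S0 <- as.matrix(S0)
  stopifnot(is.numeric(m0), kappa0 > 0, nu0 > D - 1,
            nrow(S0) == D, ncol(S0) == D)
  if (any(abs(S0 - t(S0)) > 1e-8) || any(eigen(S0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("S0 must be a symmetric positive-definite matrix")
  structure(list(m0 = as.numeric(m0), kappa0 = as.numeric(kappa0),
                 nu0 = as.numeric(nu0), S0 = S0),
            class = c("mapdp_niw", "mapdp_model"))
}

#' Bernoulli component with Beta prior
#'
#' For binary (yes/no) features: `x ~ Bernoulli(p)` with `p ~ Beta(a0, b0)`.
#'
#' @param a0,b0 Positive Beta prior pseudo-counts for 1 and 0 respectively.
#' @return A component model object of class `mapdp_bernoulli`.
#' @export
bernoulli_feature <- function(a0 = 1, b0 = 1) {
  stopifnot(a0 > 0, b0 > 0)
  structure(list(a0 = as.numeric(a0), b0 = as.numeric(b0)),
            class = c("mapdp_bernoulli", "mapdp_model"))
}

#' Binomial component with Beta prior
#'
#' For ordinal features recorded on a fixed scale 0..`n_trials`:
#' `x ~ Binomial(n_trials, p)` with `p ~ Beta(a0, b0)`. `n_trials` is a fixed,
#' per-feature constant declared up front (e.g. a 0-4 rating scale has
#' `n_trials = 4`).
#'
#' @param n_trials Positive integer, the fixed number of trials (scale maximum).
#' @param a0,b0 Positive Beta prior pseudo-counts.
#' @return A component model object of class `mapdp_binomial`.
#' @export
binomial_feature <- function(n_trials, a0 = 1, b0 = 1) {
  stopifnot(n_trials >= 1, n_trials == as.integer(n_trials), a0 > 0, b0 > 0)
  structure(list(n_trials = as.integer(n_trials), a0 = as.numeric(a0), b0 = as.numeric(b0)),
            class = c("mapdp_binomial", "mapdp_model"))
}

#' Categorical component with Dirichlet prior
#'
#' For nominal features coded as integer levels 1..`n_levels`:
#' `x ~ Categorical(p)` with `p ~ Dirichlet(alpha0)`.
#'
#' @param n_levels Integer >= 2, number of levels.
#' @param alpha0 Positive numeric vector of length `n_levels` (default all 1).
#' @return A component model object of class `mapdp_categorical`.
#' @export
categorical_feature <- function(n_levels, alpha0 = rep(1, n_levels)) {
  stopifnot(n_levels >= 2, length(alpha0) == n_levels, all(alpha0 > 0))
  structure(list(n_levels = as.integer(n_levels), alpha0 = as.numeric(alpha0)),
            class = c("mapdp_categorical", "mapdp_model"))
}

#' Poisson component with Gamma prior
#'
#' For count features: `x ~ Poisson(lambda)` with `lambda ~ Gamma(a0, b0)`
#' (shape/rate). The posterior predictive is negative binomial.
#'
#' @param a0,b0 Positive Gamma shape and rate.
#' @return A component model object of class `mapdp_poisson`.
#' @export
poisson_feature <- function(a0 = 1, b0 = 1) {
  stopifnot(a0 > 0, b0 > 0)
  structure(list(a0 = as.numeric(a0), b0 = as.numeric(b0)),
            class = c("mapdp_poisson", "mapdp_model"))
}

#' Factorized ("elliptical") model over independent features
#'
#' Joint component model for mixed-type data in which the predictive density
#' factorizes across features: `f(x | theta) = prod_m f(x_m | theta_m)`. Each
#' feature has its own conjugate family; missing entries (NA) are marginalized
#' out (contribute 0 to the log predictive).
#'
#' @param features Named list of univariate component models (one data column
#'   each; a `spherical_gaussian` feature must have `length(mu0) == 1`).
#' @return A component model object of class `mapdp_elliptical`.
#' @export
elliptical_model <- function(features) {
  stopifnot(is.list(features), length(features) >= 1L)
  ok <- vapply(features, function(f) inherits(f, "mapdp_model") &&
                 !inherits(f, "mapdp_elliptical") && obs_dim(f) == 1L, logical(1))
  if (!all(ok))
    stop("features must be a list of univariate (single-column) component models")
  if (is.null(names(features)))
    names(features) <- paste0("V", seq_along(features))
  structure(list(features = features),
            class = c("mapdp_elliptical", "mapdp_model"))
}

# ---- internal generics -------------------------------------------------------

#' Number of data columns a component model consumes
#' @param model A component model.
#' @return Integer count of observation columns.
#' @keywords internal
#' @export
obs_dim <- function(model) UseMethod("obs_dim")
#' @export
obs_dim.mapdp_spherical <- function(model) length(model$mu0)
#' @export
obs_dim.mapdp_niw <- function(model) length(model$m0)
#' @export
obs_dim.mapdp_bernoulli <- function(model) 1L
#' @export
obs_dim.mapdp_binomial <- function(model) 1L
#' @export
obs_dim.mapdp_categorical <- function(model) 1L
#' @export
obs_dim.mapdp_poisson <- function(model) 1L
#' @export
obs_dim.mapdp_elliptical <- function(model) length(model$features)

# length of the sufficient-statistic vector per cluster
suff_dim <- function(model) UseMethod("suff_dim")
#' @exportS3Method
suff_dim.mapdp_spherical <- function(model) length(model$mu0)
#' @exportS3Method
suff_dim.mapdp_niw <- function(model) {D <- length(model$m0); D + D * D}
#' @exportS3Method
suff_dim.mapdp_bernoulli <- function(model) 1L
#' @exportS3Method
suff_dim.mapdp_binomial <- function(model) 1L
#' @exportS3Method
suff_dim.mapdp_categorical <- function(model) model$n_levels
#' @exportS3Method
suff_dim.mapdp_poisson <- function(model) 1L
#' @exportS3Method
suff_dim.mapdp_elliptical <- function(model)
  sum(vapply(model$features, suff_dim, numeric(1)))

# sufficient statistic of one observation (vector of length suff_dim);
# NA entries contribute zeros (marginalized) and are tracked separately.
suff_of <- function(model, x) UseMethod("suff_of")
#' @exportS3Method
suff_of.mapdp_spherical <- function(model, x) as.numeric(x)
#' @exportS3Method
suff_of.mapdp_niw <- function(model, x) c(x, as.numeric(tcrossprod(x)))
#' @exportS3Method
suff_of.mapdp_bernoulli <- function(model, x) as.numeric(x)
#' @exportS3Method
suff_of.mapdp_binomial <- function(model, x) as.numeric(x)
#' @exportS3Method
suff_of.mapdp_categorical <- function(model, x) {
  s <- numeric(model$n_levels); s[x] <- 1; s
}
#' @exportS3Method
suff_of.mapdp_poisson <- function(model, x) as.numeric(x)
#' @exportS3Method
suff_of.mapdp_elliptical <- function(model, x) {
  parts <- mapply(function(f, xi) {
    if (is.na(xi)) numeric(suff_dim(f)) else suff_of(f, xi)
  }, model$features, x, SIMPLIFY = FALSE)
  unlist(parts, use.names = FALSE)
}

# support checks -------------------------------------------------------------

check_support <- function(model, x, feature = "x") UseMethod("check_support")
#' @exportS3Method
check_support.mapdp_spherical <- function(model, x, feature = "x") {
  if (length(x) != obs_dim(model) || any(!is.finite(x)))
    stop(sprintf("feature '%s': non-finite or wrong-length observation", feature))
  invisible(TRUE)
}
#' @exportS3Method
check_support.mapdp_niw <- check_support.mapdp_spherical
#' @exportS3Method
check_support.mapdp_bernoulli <- function(model, x, feature = "x") {
  if (!isTRUE(x %in% c(0, 1)))
    stop(sprintf("feature '%s': value %s outside Bernoulli support {0,1}", feature, format(x)))
  invisible(TRUE)
}
#' @exportS3Method
check_support.mapdp_binomial <- function(model, x, feature = "x") {
  if (!isTRUE(x %in% 0:model$n_trials))
    stop(sprintf("feature '%s': value %s outside binomial support 0..%d",
                 feature, format(x), model$n_trials))
  invisible(TRUE)
}
#' @exportS3Method
check_support.mapdp_categorical <- function(model, x, feature = "x") {
  if (!isTRUE(x %in% seq_len(model$n_levels)))
    stop(sprintf("feature '%s': value %s outside categorical levels 1..%d",
                 feature, format(x), model$n_levels))
  invisible(TRUE)
}
#' @exportS3Method
check_support.mapdp_poisson <- function(model, x, feature = "x") {
  if (!isTRUE(is.finite(x) && x >= 0 && x == floor(x)))
    stop(sprintf("feature '%s': value %s is not a non-negative count", feature, format(x)))
  invisible(TRUE)
}
#' @exportS3Method
check_support.mapdp_elliptical <- function(model, x, feature = "x") {
  if (length(x) != obs_dim(model))
    stop("observation length does not match the number of schema features")
  for (m in seq_along(model$features)) {
    if (!is.na(x[m]))
      check_support(model$features[[m]], x[m], feature = names(model$features)[m])
  }
  invisible(TRUE)
}

# ---- posterior update -------------------------------------------------------

#' Conjugate posterior hyperparameters from assigned points
#'
#' Updates a component model's hyperparameters on a set of observations.
#' Because the families are conjugate, the returned object has exactly the
#' same shape (and class) as the prior; with zero points it equals the prior.
#'
#' @param model A component model (interpreted as the prior).
#' @param points Matrix of observations (rows) with `obs_dim(model)` columns,
#'   or a vector for univariate models. `NULL` or zero rows returns the prior
#'   unchanged. For elliptical models, NA entries are excluded per feature.
#' @return A component model of the same family holding the posterior
#'   hyperparameters.
#' @export
posterior_update <- function(model, points) {
  if (is.null(points)) return(model)
  pts <- as.matrix(points)
  if (obs_dim(model) == 1L && ncol(pts) != 1L) pts <- matrix(as.numeric(points), ncol = 1L)
  if (nrow(pts) == 0L) return(model)
  if (ncol(pts) != obs_dim(model))
    stop("points have ", ncol(pts), " columns; model expects ", obs_dim(model))
  nm <- if (inherits(model, "mapdp_elliptical")) names(model$features) else "x"
  for (i in seq_len(nrow(pts))) check_support(model, pts[i, ], nm[1L])
  stat <- numeric(suff_dim(model))
  nobs <- obs_counts_zero(model)
  for (i in seq_len(nrow(pts))) {
    stat <- stat + suff_of(model, pts[i, ])
    nobs <- nobs + obs_counts_of(model, pts[i, ])
  }
  posterior_from_stats(model, stat, nobs)
}

# per-feature observation counts: scalar n for single-family models, a vector
# (one count per feature) for the elliptical model where NAs differ by feature
obs_counts_zero <- function(model)
  if (inherits(model, "mapdp_elliptical")) numeric(length(model$features)) else 0
obs_counts_of <- function(model, x)
  if (inherits(model, "mapdp_elliptical")) as.numeric(!is.na(x)) else 1

# posterior hyperparameters from (sufficient statistic, count); the workhorse
# shared by batch updates and the incremental engine
posterior_from_stats <- function(model, stat, n) UseMethod("posterior_from_stats")

#' @exportS3Method
posterior_from_stats.mapdp_spherical <- function(model, stat, n) {
  sk <- 1 / (1 / model$sigma0sq + n / model$sigma_sq)
  mu <- sk * (model$mu0 / model$sigma0sq + stat / model$sigma_sq)
  spherical_gaussian(mu, sk, model$sigma_sq)
}

#' @exportS3Method
posterior_from_stats.mapdp_niw <- function(model, stat, n) {
  D <- length(model$m0)
  if (n == 0) return(model)
  sumx <- stat[seq_len(D)]
  sumxx <- matrix(stat[-seq_len(D)], D, D)
  xbar <- sumx / n
  scatter <- sumxx - n * tcrossprod(xbar)
  kn <- model$kappa0 + n
  nun <- model$nu0 + n
  mn <- (model$kappa0 * model$m0 + sumx) / kn
  dev <- xbar - model$m0
  Sn <- model$S0 + scatter + (model$kappa0 * n / kn) * tcrossprod(dev)
  Sn <- (Sn + t(Sn)) / 2
  out <- list(m0 = as.numeric(mn), kappa0 = kn, nu0 = nun, S0 = Sn)
  class(out) <- class(model)
  out
}

#' @exportS3Method
posterior_from_stats.mapdp_bernoulli <- function(model, stat, n)
  bernoulli_feature(model$a0 + stat, model$b0 + n - stat)

#' @exportS3Method
posterior_from_stats.mapdp_binomial <- function(model, stat, n)
  binomial_feature(model$n_trials, model$a0 + stat, model$b0 + n * model$n_trials - stat)

#' @exportS3Method
posterior_from_stats.mapdp_categorical <- function(model, stat, n)
  categorical_feature(model$n_levels, model$alpha0 + stat)

#' @exportS3Method
posterior_from_stats.mapdp_poisson <- function(model, stat, n)
  poisson_feature(model$a0 + stat, model$b0 + n)

#' @exportS3Method
posterior_from_stats.mapdp_elliptical <- function(model, stat, n) {
  if (length(n) == 1L) n <- rep(n, length(model$features))
  off <- 0L
  feats <- model$features
  for (m in seq_along(feats)) {
    d <- suff_dim(feats[[m]])
    feats[[m]] <- posterior_from_stats(feats[[m]], stat[off + seq_len(d)], n[m])
    off <- off + d
  }
  elliptical_model(feats)
}

# ---- log predictive density -------------------------------------------------

#' Log posterior predictive density ln f(x | theta)
#'
#' The density of a new observation under the model's current hyperparameters,
#' with the component parameters integrated out: Gaussian with inflated
#' variance (spherical family), multivariate Student-t (NIW), Beta-Bernoulli /
#' Beta-binomial, Dirichlet-categorical and Gamma-Poisson (negative binomial)
#' predictives for the discrete families. Normalizing constants are retained,
#' so exponentiating gives a proper density/mass.
#'
#' @param model A component model (prior or posterior).
#' @param x A single observation: numeric vector of length `obs_dim(model)`.
#'   For elliptical models NA entries are marginalized out (contribute 0).
#' @return Scalar log density (log mass for discrete families).
#' @export
log_predictive <- function(model, x) UseMethod("log_predictive")

check_finite_hyper <- function(model) {
  v <- unlist(model[!vapply(model, is.list, logical(1))], use.names = FALSE)
  if (any(!is.finite(v))) stop("invalid state: non-finite hyperparameters")
  invisible(TRUE)
}

#' @export
log_predictive.mapdp_spherical <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  v <- model$sigma0sq + model$sigma_sq
  sum(stats::dnorm(x, mean = model$mu0, sd = sqrt(v), log = TRUE))
}

#' @export
log_predictive.mapdp_niw <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  D <- length(model$m0)
  df <- model$nu0 - D + 1
  scale <- model$S0 * (model$kappa0 + 1) / (model$kappa0 * df)
  dmvt_ls(as.numeric(x), model$m0, scale, df)
}

#' @export
log_predictive.mapdp_bernoulli <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  p <- model$a0 / (model$a0 + model$b0)
  if (x == 1) log(p) else log1p(-p)
}

#' @export
log_predictive.mapdp_binomial <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  lchoose(model$n_trials, x) +
    lbeta(model$a0 + x, model$b0 + model$n_trials - x) -
    lbeta(model$a0, model$b0)
}

#' @export
log_predictive.mapdp_categorical <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  log(model$alpha0[x]) - log(sum(model$alpha0))
}

#' @export
log_predictive.mapdp_poisson <- function(model, x) {
  check_finite_hyper(model); check_support(model, x)
  a <- model$a0; b <- model$b0
  lgamma(a + x) - lgamma(a) - lgamma(x + 1) + a * (log(b) - log1p(b)) - x * log1p(b)
}

#' @export
log_predictive.mapdp_elliptical <- function(model, x) elliptical_log_predictive(model, x)

#' Factorized log predictive for mixed-type observations
#'
#' Sum of per-feature log predictive densities under an elliptical model.
#' Missing (NA) features are marginalized out and contribute exactly 0, so a
#' fully missing observation has log predictive 0 (the empty product).
#'
#' @param model An `elliptical_model`, prior or posterior.
#' @param x Observation vector, `length(x) == obs_dim(model)`; NAs allowed.
#' @return Scalar log density.
#' @export
elliptical_log_predictive <- function(model, x) {
  if (length(x) != obs_dim(model))
    stop("observation length ", length(x), " does not match schema length ",
         obs_dim(model))
  total <- 0
  for (m in seq_along(model$features)) {
    if (!is.na(x[m])) total <- total + log_predictive(model$features[[m]], x[m])
  }
  total
}

# multivariate Student-t log density, location/scale parametrization
dmvt_ls <- function(x, mu, Sigma, df) {
  D <- length(mu)
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  q <- sum(z * z)
  lgamma((df + D) / 2) - lgamma(df / 2) - (D / 2) * (log(df) + log(pi)) -
    sum(log(diag(ch))) - ((df + D) / 2) * log1p(q / df)
}

# ---- prior predictive draws and predictive modes (used by missing data) -----

# one draw per call from f(x | theta) for a univariate feature model
prior_predictive_draw <- function(model, n = 1L) UseMethod("prior_predictive_draw")
#' @exportS3Method
prior_predictive_draw.mapdp_spherical <- function(model, n = 1L)
  stats::rnorm(n, model$mu0, sqrt(model$sigma0sq + model$sigma_sq))
#' @exportS3Method
prior_predictive_draw.mapdp_bernoulli <- function(model, n = 1L)
  stats::rbinom(n, 1, model$a0 / (model$a0 + model$b0))
#' @exportS3Method
prior_predictive_draw.mapdp_binomial <- function(model, n = 1L)
  stats::rbinom(n, model$n_trials, stats::rbeta(n, model$a0, model$b0))
#' @exportS3Method
prior_predictive_draw.mapdp_categorical <- function(model, n = 1L)
  sample.int(model$n_levels, n, replace = TRUE, prob = model$alpha0 / sum(model$alpha0))
#' @exportS3Method
prior_predictive_draw.mapdp_poisson <- function(model, n = 1L)
  stats::rnbinom(n, size = model$a0, prob = model$b0 / (model$b0 + 1))

# mode of the posterior predictive; `previous` breaks discrete ties (kept if
# it attains the maximum), otherwise the smallest maximizer wins
predictive_mode <- function(model, previous = NULL) UseMethod("predictive_mode")
#' @exportS3Method
predictive_mode.mapdp_spherical <- function(model, previous = NULL) model$mu0
#' @exportS3Method
predictive_mode.mapdp_bernoulli <- function(model, previous = NULL) {
  p <- model$a0 / (model$a0 + model$b0)
  if (abs(p - 0.5) < 1e-12 && !is.null(previous)) return(previous)
  as.numeric(p > 0.5)
}
#' @exportS3Method
predictive_mode.mapdp_binomial <- function(model, previous = NULL) {
  xs <- 0:model$n_trials
  lp <- vapply(xs, function(v) log_predictive(model, v), numeric(1))
  best <- xs[lp >= max(lp) - 1e-12]
  if (!is.null(previous) && previous %in% best) previous else best[1L]
}
#' @exportS3Method
predictive_mode.mapdp_categorical <- function(model, previous = NULL) {
  a <- model$alpha0
  best <- which(a >= max(a) - 1e-12)
  if (!is.null(previous) && previous %in% best) previous else best[1L]
}
#' @exportS3Method
predictive_mode.mapdp_poisson <- function(model, previous = NULL) {
  if (model$a0 > 1) floor((model$a0 - 1) / model$b0) else 0
}

#' @export
print.mapdp_model <- function(x, ...) {
  cls <- setdiff(class(x), "mapdp_model")[1L]
  cat("<", cls, "> component model\n", sep = "")
  if (inherits(x, "mapdp_elliptical")) {
    cat("  features:", paste(names(x$features), collapse = ", "), "\n")
  } else {
    flat <- x[!vapply(x, is.matrix, logical(1))]
    cat(" ", paste(names(flat), vapply(flat, function(v)
      paste(signif(v, 4), collapse = ","), character(1)),
      sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
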