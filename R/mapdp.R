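# MAP-DP: collapsed maximum a-posteriori inference for the CRP mixture.
#
# The algorithm starts from a single cluster holding every point and sweeps
# the data, reassigning each point i to the cluster k (or to a new cluster)
# minimizing d_{i,k} - ln N_k^{-i}, where d_{i,k} = -ln f(x_i | theta_k^{-i})
# is the negative log posterior predictive computed from all points in k
# except i, and the count term is the collapsed CRP prior (N0 for the
# new-cluster option). Convergence is judged on the joint objective
#   E = sum_{k} sum_{i: z_i = k} d_{i,k} - K ln N0 - sum_k ln Gamma(N_k),
# which the sweep cannot increase (up to the numerical precision of the
# lgamma terms, hence the absolute-value convergence test).

#' MAP-DP configuration
#'
#' @param epsilon Convergence threshold on the change in the objective E
#'   between sweeps (> 0; default 1e-6).
#' @param max_iterations Hard iteration cap guarding against cycling caused by
#'   the absolute-value convergence test (default 500).
#' @param restarts Number of additional random-permutation restarts beyond the
#'   first (natural-order) run; the run with the lowest final E wins.
#' @param seed Optional integer seed making restart permutations (and missing
#'   -value initialization) reproducible.
#' @param reinforcement_fix Apply the first-iteration fix that treats the
#'   initial monolithic cluster's count as 1 in the assignment rule, so the
#'   rich-get-richer term cannot trap the algorithm in a single cluster
#'   (default TRUE).
#' @param convergence_mode `"absolute"` tests `|E_old - E_new| < epsilon`
#'   (robust to lgamma round-off); `"signed"` tests `E_old - E_new < epsilon`.
#' @param engine `"auto"` uses the compiled engine for pure Gaussian models on
#'   complete data and the generic R engine otherwise; `"cpp"`/`"r"` force one.
#' @return A list of class `mapdp_config`.
#' @export
mapdp_config <- function(epsilon = 1e-6, max_iterations = 500L, restarts = 0L,
                         seed = NULL, reinforcement_fix = TRUE,
                         convergence_mode = c("absolute", "signed"),
                         engine = c("auto", "cpp", "r")) {
  stopifnot(epsilon > 0, max_iterations >= 1, restarts >= 0)
  structure(list(epsilon = epsilon, max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts), seed = seed,
                 reinforcement_fix = isTRUE(reinforcement_fix),
                 convergence_mode = match.arg(convergence_mode),
                 engine = match.arg(engine)),
            class = "mapdp_config")
}

engine_for <- function(model, config, has_missing) {
  if (config$engine == "r") return("r")
  cpp_ok <- (inherits(model, "mapdp_spherical") || inherits(model, "mapdp_niw")) &&
    !has_missing
  if (config$engine == "cpp") {
    if (!cpp_ok) stop("compiled engine supports only Gaussian models on complete data")
    return("cpp")
  }
  if (cpp_ok) "cpp" else "r"
}

#' Fit a Dirichlet-process mixture by MAP inference
#'
#' Runs the collapsed MAP sweep until the objective E changes by less than
#' `epsilon`, over `restarts + 1` visiting orders (the first is natural order,
#' the rest random permutations), and returns the run with lowest final E.
#' The number of clusters K is inferred; no initial centroids are needed.
#'
#' Missing values: if `X` contains NAs the model must be an
#' [elliptical_model()]. Masked entries are first drawn from their feature's
#' prior predictive, then alternately updated to the posterior-predictive mode
#' of the point's current cluster (excluding the point) after each assignment
#' sweep; the convergence objective then uses observed entries only.
#'
#' @param X Numeric matrix, rows are observations. For elliptical models the
#'   columns follow the feature schema (categorical columns coded 1..L).
#' @param model A component model (the prior), e.g. [full_gaussian()] or
#'   [elliptical_model()].
#' @param n0 Positive concentration (prior count) of the CRP.
#' @param config A [mapdp_config()].
#' @param init_z Optional initial assignment vector (default: all points in
#'   one cluster). Supplying `K > 1` initial clusters disables the
#'   reinforcement fix for those clusters.
#' @param allow_new If FALSE the new-cluster option is removed and K stays
#'   fixed at the initial number of clusters (used e.g. for the K-means
#'   limiting configuration).
#' @return An object of class `mapdp_fit`: assignments `z` (canonical labels),
#'   `K`, cluster sizes `n_k`, final objective `nll`, per-sweep `nll_trace`,
#'   `iterations`, per-restart final objectives `restart_nlls`, the winning
#'   `best_restart`, the completed data matrix `X` (imputed if masked),
#'   `mask`, the prior `model`, `n0`, and the `config` echo.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
#' fit <- mapdp_fit(X, full_gaussian(colMeans(X), 1, 4, cov(X)), n0 = 3)
#' fit$K
#' @export
mapdp_fit <- function(X, model, n0 = 3, config = mapdp_config(),
                      init_z = NULL, allow_new = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(n0 > 0, nrow(X) >= 1)
  if (ncol(X) != obs_dim(model))
    stop("data has ", ncol(X), " columns but the model expects ", obs_dim(model))
  mask <- is.na(X)
  has_missing <- any(mask)
  if (has_missing && !inherits(model, "mapdp_elliptical"))
    stop("missing values require an elliptical (factorized) model")
  if (!has_missing && any(!is.finite(X)))
    stop("non-finite values in data")
  N <- nrow(X)
  if (is.null(init_z)) init_z <- rep(1L, N)
  stopifnot(length(init_z) == N)
  init_z <- canonicalize_partition(init_z)

  eng <- engine_for(model, config, has_missing)

  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(config$seed)
  }

  n_runs <- config$restarts + 1L
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ord <- if (r == 1L) seq_len(N) else sample.int(N)
    Xr <- X
    if (has_missing) Xr <- initialize_missing(X, model, mask = mask)
    runs[[r]] <- if (eng == "cpp") {
      fam <- if (inherits(model, "mapdp_spherical")) 0L else 1L
      hyper <- unclass(model)
      res <- .mapdp_gaussian_cpp(X, fam, hyper, n0, config$epsilon,
                                 config$max_iterations, ord,
                                 config$reinforcement_fix, allow_new, init_z,
                                 as.integer(config$convergence_mode == "absolute"))
      res$X_completed <- X
      res$counts <- tabulate(res$z)
      res
    } else {
      mapdp_engine_r(Xr, model, n0, config$epsilon, config$max_iterations, ord,
                     reinforce = config$reinforcement_fix, allow_new = allow_new,
                     z_init = init_z,
                     conv_abs = config$convergence_mode == "absolute",
                     mask = if (has_missing) mask else NULL)
    }
  }

  finals <- vapply(runs, function(r) r$trace[length(r$trace)], numeric(1))
  best <- which.min(finals)
  win <- runs[[best]]
  z <- canonicalize_partition(win$z)
  structure(list(z = z, K = max(z), n_k = tabulate(z),
                 nll = finals[best], nll_trace = win$trace,
                 iterations = win$iterations, restart_nlls = finals,
                 best_restart = best, n0 = n0, model = model,
                 X = win$X_completed, mask = mask, has_missing = has_missing,
                 engine = eng, config = config),
            class = "mapdp_fit")
}

#' @export
print.mapdp_fit <- function(x, ...) {
  cat("MAP-DP fit: N =", length(x$z), " K =", x$K,
      " NLL =", format(x$nll, digits = 8),
      " iterations =", x$iterations, "\n")
  cat("cluster sizes:", paste(x$n_k, collapse = ", "), "\n")
  invisible(x)
}

#' Assignment costs for one point
#'
#' The negative log posterior predictive `d_{i,k} = -ln f(x_i | theta_k^{-i})`
#' of point `i` under each live cluster (posterior computed from all points
#' assigned to the cluster, excluding `i`), and under the prior
#' (`d_{i,K+1} = -ln f(x_i | theta_0)`, the new-cluster option). Computed
#' naively via [posterior_update()], which is the correctness contract for
#' the incremental engine.
#'
#' @param X Data matrix.
#' @param z Current assignments.
#' @param i Point index.
#' @param model Prior component model.
#' @return Numeric vector of length `K + 1`; the last entry is the
#'   new-cluster cost. A cluster holding no other point has cost equal to the
#'   new-cluster cost (its exclusion posterior is the prior).
#' @export
assignment_cost <- function(X, z, i, model) {
  X <- as.matrix(X)
  K <- max(z)
  d <- numeric(K + 1)
  for (k in seq_len(K)) {
    idx <- setdiff(which(z == k), i)
    post <- posterior_update(model, X[idx, , drop = FALSE])
    d[k] <- -log_predictive(post, X[i, ])
  }
  d[K + 1] <- -log_predictive(model, X[i, ])
  d
}

# C(N0, N) = ln Gamma(N0) - ln Gamma(N0 + N): the assignment-independent CRP
# constant, omitted from E during iteration but required when objectives are
# compared across different N0
crp_constant <- function(n0, n) lgamma(n0) - lgamma(n0 + n)

#' Negative log joint objective of a clustering
#'
#' Recomputes `E = sum_i d_{i,z_i} - K ln n0 - sum_k ln Gamma(N_k)` from
#' scratch for given assignments, using exclusion posteriors built from
#' incremental sufficient statistics. With `include_constant = TRUE` the
#' term `-C(n0, N)`, `C = ln(Gamma(n0)/Gamma(n0+N))`, is added; that variant
#' is comparable across different `n0` and is the score used by the
#' hyperparameter search.
#'
#' @param X Data matrix (no NAs; use the completed matrix of a fit).
#' @param z Assignments (any labels).
#' @param model Prior component model.
#' @param n0 Concentration.
#' @param include_constant Include `-C(n0, N)` (default FALSE, matching the
#'   within-run objective).
#' @return Scalar objective value.
#' @export
mapdp_nll <- function(X, z, model, n0, include_constant = FALSE) {
  X <- as.matrix(X)
  z <- canonicalize_partition(z)
  N <- nrow(X)
  K <- max(z)
  S <- suff_dim(model)
  stats <- matrix(0, K, S)
  counts <- numeric(K)
  sx <- vector("list", N)
  for (i in seq_len(N)) {
    sx[[i]] <- suff_of(model, X[i, ])
    stats[z[i], ] <- stats[z[i], ] + sx[[i]]
    counts[z[i]] <- counts[z[i]] + 1
  }
  E <- 0
  for (i in seq_len(N)) {
    k <- z[i]
    post <- posterior_from_stats(model, stats[k, ] - sx[[i]], counts[k] - 1)
    E <- E - log_predictive(post, X[i, ])
  }
  E <- E - K * log(n0) - sum(lgamma(counts))
  if (include_constant) E <- E - crp_constant(n0, N)
  E
}

#' Cluster centroid hyperparameters after convergence
#'
#' The per-cluster posterior `theta_k` computed from all points assigned to
#' cluster k (no exclusion), plus the mode of each cluster's posterior
#' predictive -- the MAP-DP analogue of K-means centroids. For the spherical
#' family this returns `mu_k, sigma_k` from the conjugate update; for the NIW
#' family the Student-t predictive mode `m_k`; for elliptical models the
#' vector of per-feature predictive modes.
#'
#' @param fit A `mapdp_fit` object.
#' @return List with `posteriors` (list of K posterior model objects) and
#'   `modes` (K x D matrix of predictive modes).
#' @export
extract_centroids <- function(fit) {
  stopifnot(inherits(fit, "mapdp_fit"))
  model <- fit$model
  K <- fit$K
  posts <- vector("list", K)
  modes <- matrix(NA_real_, K, obs_dim(model))
  for (k in seq_len(K)) {
    posts[[k]] <- posterior_update(model, fit$X[fit$z == k, , drop = FALSE])
    modes[k, ] <- centroid_mode(posts[[k]])
  }
  list(posteriors = posts, modes = modes)
}

centroid_mode <- function(post) {
  if (inherits(post, "mapdp_spherical")) return(post$mu0)
  if (inherits(post, "mapdp_niw")) return(post$m0)
  if (inherits(post, "mapdp_elliptical"))
    return(vapply(post$features, function(f) as.numeric(predictive_mode(f)[1L]),
                  numeric(1)))
  as.numeric(predictive_mode(post)[1L])
}
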