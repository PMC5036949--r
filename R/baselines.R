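# Baselines: Lloyd's K-means with K-means++ seeding, full-covariance Gaussian
# mixture E-M, and the BIC-over-K selection protocol (sweep K, many randomized
# restarts, report the K with the best score over all cycles).

# squared Euclidean distances between rows of X and rows of C (N x K)
sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' K-means++ seeding
#'
#' Chooses `k` initial centroids: the first uniformly at random, each
#' subsequent one with probability proportional to the squared distance from
#' the nearest centroid chosen so far.
#'
#' @param X Data matrix.
#' @param k Number of centroids.
#' @return A `k x D` matrix of seed centroids.
#' @export
kmeanspp_seed <- function(X, k) {
  X <- as.matrix(X)
  N <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(N, 1L)
  if (k > 1) {
    d2 <- sqdist(X, X[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(N, 1L)
      else idx[j] <- sample.int(N, 1L, prob = d2)
      d2 <- pmin(d2, sqdist(X, X[idx[j], , drop = FALSE])[, 1])
    }
  }
  X[idx, , drop = FALSE]
}

#' K-means clustering (Lloyd's algorithm)
#'
#' Alternates nearest-centroid assignment and centroid means until the
#' objective `E = 1/2 sum_i ||x_i - mu_{z_i}||^2` decreases by less than
#' `epsilon`. An emptied cluster is re-seeded at the point farthest from its
#' assigned centroid (documented alternative to silently dropping it).
#'
#' @param X Data matrix.
#' @param k Number of clusters (`1 <= k <= N`).
#' @param epsilon Convergence threshold on the decrease of E.
#' @param max_iter Iteration cap.
#' @param init `"kmeanspp"` (default) or `"given"` with `centers`.
#' @param centers Initial centroids when `init = "given"`.
#' @param nstart Number of restarts; the lowest-objective solution is kept.
#' @return List with `centers`, assignments `z`, objective `E`, objective
#'   `trace`, and `iterations` (of the winning restart).
#' @export
kmeans_fit <- function(X, k, epsilon = 1e-8, max_iter = 200,
                       init = c("kmeanspp", "given"), centers = NULL,
                       nstart = 1) {
  X <- as.matrix(X)
  init <- match.arg(init)
  stopifnot(k >= 1, k <= nrow(X))
  one_run <- function(C0) {
    C <- C0
    E_old <- Inf
    trace <- numeric(0)
    iter <- 0L
    z <- integer(nrow(X))
    repeat {
      iter <- iter + 1L
      d2 <- sqdist(X, C)
      z <- max.col(-d2, ties.method = "first")
      for (k_empty in setdiff(seq_len(k), unique(z))) {
        far <- which.max(d2[cbind(seq_len(nrow(X)), z)])
        z[far] <- k_empty
      }
      for (j in seq_len(k)) C[j, ] <- colMeans(X[z == j, , drop = FALSE])
      E <- sum((X - C[z, , drop = FALSE])^2) / 2
      trace <- c(trace, E)
      if (E_old - E < epsilon || iter >= max_iter) break
      E_old <- E
    }
    list(centers = C, z = z, E = E, trace = trace, iterations = iter)
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    C0 <- if (init == "given") as.matrix(centers) else kmeanspp_seed(X, k)
    run <- one_run(C0)
    if (is.null(best) || run$E < best$E) best <- run
  }
  best
}

#' Gaussian mixture model fitted by E-M
#'
#' Full-covariance GMM: the E-step computes responsibilities
#' `gamma_{i,k} = pi_k N(x_i | mu_k, Sigma_k) / sum_j pi_j N(x_i | mu_j, Sigma_j)`
#' and the M-step the weighted ML parameters. The negative log likelihood is
#' non-increasing; covariances are regularized by a small diagonal jitter when
#' near singular.
#'
#' @param X Data matrix.
#' @param k Number of components.
#' @param epsilon Convergence threshold on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @param init `"kmeanspp"` (K-means++ means, pooled covariance, uniform
#'   weights) or `"params"` with an explicit `params` list (e.g. the true
#'   generating parameters for synthetic data).
#' @param params List with `means` (K x D), `covs` (list of K matrices),
#'   `weights` (length K), used when `init = "params"`.
#' @param jitter Diagonal regularization added when a covariance update is not
#'   positive definite.
#' @param fixed_spherical Optional known variance: when set, all covariances
#'   are held at `fixed_spherical * I` and only means and weights are updated
#'   (the restricted model whose small-variance limit is K-means).
#' @return List with `weights`, `means`, `covs`, responsibilities `resp`,
#'   `loglik` trace, and `iterations`.
#' @export
gmm_em <- function(X, k, epsilon = 1e-6, max_iter = 500,
                   init = c("kmeanspp", "params"), params = NULL,
                   jitter = 1e-6, fixed_spherical = NULL) {
  X <- as.matrix(X)
  init <- match.arg(init)
  N <- nrow(X); D <- ncol(X)
  stopifnot(k >= 1, N > k)
  if (init == "params") {
    mu <- as.matrix(params$means)
    covs <- params$covs
    w <- params$weights
  } else {
    mu <- kmeanspp_seed(X, k)
    covs <- replicate(k, stats::cov(X), simplify = FALSE)
    w <- rep(1 / k, k)
  }
  if (!is.null(fixed_spherical))
    covs <- replicate(k, diag(fixed_spherical, D), simplify = FALSE)
  log_dens <- function() {
    L <- matrix(0, N, k)
    for (j in seq_len(k)) {
      ch <- tryCatch(chol(covs[[j]]), error = function(e) {
        covs[[j]] <<- covs[[j]] + diag(jitter, D)
        chol(covs[[j]])
      })
      zc <- backsolve(ch, t(X) - mu[j, ], transpose = TRUE)
      L[, j] <- -0.5 * colSums(zc^2) - sum(log(diag(ch))) - D / 2 * log(2 * pi)
    }
    L
  }
  ll_old <- -Inf
  trace <- numeric(0)
  iter <- 0L
  resp <- NULL
  repeat {
    iter <- iter + 1L
    L <- sweep(log_dens(), 2, log(w), "+")
    m <- apply(L, 1, max)
    ll <- sum(m + log(rowSums(exp(L - m))))
    resp <- exp(L - m - log(rowSums(exp(L - m))))
    trace <- c(trace, ll)
    if (ll - ll_old < epsilon || iter >= max_iter) break
    ll_old <- ll
    Sk <- colSums(resp)
    w <- Sk / N
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / Sk[j]
      if (is.null(fixed_spherical)) {
        Xc <- sweep(X, 2, mu[j, ])
        Cj <- crossprod(Xc * sqrt(resp[, j])) / Sk[j]
        if (min(eigen(Cj, symmetric = TRUE, only.values = TRUE)$values) < jitter)
          Cj <- Cj + diag(jitter, D)
        covs[[j]] <- Cj
      }
    }
  }
  list(weights = w, means = mu, covs = covs, resp = resp, loglik = trace,
       iterations = iter, z = max.col(resp, ties.method = "first"))
}

# BIC score of a K-means solution under the spherical classification
# likelihood implied by K-means: pooled variance MLE sigma^2 = WSS / (N D),
# log L = sum_k N_k ln(N_k / N) - (N D / 2)(ln(2 pi sigma^2) + 1),
# penalized with (K D + 1) free parameters. Larger is better.
kmeans_bic <- function(X, fit) {
  N <- nrow(X); D <- ncol(X)
  wss <- 2 * fit$E
  k <- nrow(fit$centers)
  if (wss <= 0) return(-Inf)  # degenerate exact fit
  sigma2 <- wss / (N * D)
  nk <- tabulate(fit$z, k)
  nk <- nk[nk > 0]
  ll <- sum(nk * log(nk / N)) - N * D / 2 * (log(2 * pi * sigma2) + 1)
  ll - (k * D + 1) / 2 * log(N)
}

#' Select K for K-means by BIC over repeated randomized restarts
#'
#' For each cycle and each K in `k_range`, fits K-means with a fresh K-means++
#' initialization, computes the BIC score under the spherical Gaussian
#' classification likelihood, and reports the K attaining the maximum score
#' over all cycles, with the full score table.
#'
#' @param X Data matrix.
#' @param k_range Candidate K values (default 1:20).
#' @param cycles Number of randomized repetitions per K (default 100).
#' @param epsilon,max_iter Passed to [kmeans_fit()].
#' @return List with `k` (selected), `table` (data frame cycle x K x BIC), and
#'   `best_row` (index of the maximizing row).
#' @export
bic_select <- function(X, k_range = 1:20, cycles = 100, epsilon = 1e-8,
                       max_iter = 200) {
  stopifnot(length(k_range) >= 1)
  X <- as.matrix(X)
  rows <- vector("list", cycles * length(k_range))
  r <- 0L
  for (cyc in seq_len(cycles)) {
    for (k in k_range) {
      fit <- kmeans_fit(X, k, epsilon = epsilon, max_iter = max_iter)
      r <- r + 1L
      rows[[r]] <- data.frame(cycle = cyc, k = k, bic = kmeans_bic(X, fit))
    }
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$bic)
  list(k = tab$k[best], table = tab, best_row = best)
}
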