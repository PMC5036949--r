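# Reference sweep engine, generic over any conjugate component model.
#
# Maintains per-cluster sufficient statistics incrementally (add/remove one
# point) and recomputes every predictive lazily from them, which is
# contract-equal to rebuilding the posterior from scratch. The compiled
# Gaussian engine in src/ is an optimization of exactly this loop and the two
# are tested for equality.

# log predictive of observation x under every live cluster, vectorized over
# clusters: `stats` is a K x suff_dim matrix, `counts` a length-K vector.
lp_clusters <- function(model, stats, counts, x) UseMethod("lp_clusters")

#' @exportS3Method
lp_clusters.mapdp_spherical <- function(model, stats, counts, x) {
  D <- length(model$mu0)
  sk <- 1 / (1 / model$sigma0sq + counts / model$sigma_sq)
  mu <- sk * sweep(stats / model$sigma_sq, 2, model$mu0 / model$sigma0sq, "+")
  v <- sk + model$sigma_sq
  dev2 <- rowSums((matrix(x, nrow(stats), D, byrow = TRUE) - mu)^2)
  -0.5 * D * log(2 * pi * v) - dev2 / (2 * v)
}

#' @exportS3Method
lp_clusters.mapdp_niw <- function(model, stats, counts, x) {
  vapply(seq_along(counts), function(k)
    log_predictive(posterior_from_stats(model, stats[k, ], counts[k]), x),
    numeric(1))
}

#' @exportS3Method
lp_clusters.mapdp_bernoulli <- function(model, stats, counts, x) {
  a <- model$a0 + stats[, 1L]
  b <- model$b0 + counts - stats[, 1L]
  if (x == 1) log(a / (a + b)) else log(b / (a + b))
}

#' @exportS3Method
lp_clusters.mapdp_binomial <- function(model, stats, counts, x) {
  Tn <- model$n_trials
  a <- model$a0 + stats[, 1L]
  b <- model$b0 + counts * Tn - stats[, 1L]
  lchoose(Tn, x) + lbeta(a + x, b + Tn - x) - lbeta(a, b)
}

#' @exportS3Method
lp_clusters.mapdp_categorical <- function(model, stats, counts, x) {
  alpha <- sweep(stats, 2, model$alpha0, "+")
  log(alpha[, x] / rowSums(alpha))
}

#' @exportS3Method
lp_clusters.mapdp_poisson <- function(model, stats, counts, x) {
  a <- model$a0 + stats[, 1L]
  b <- model$b0 + counts
  lgamma(a + x) - lgamma(a) - lgamma(x + 1) + a * (log(b) - log1p(b)) - x * log1p(b)
}

#' @exportS3Method
lp_clusters.mapdp_elliptical <- function(model, stats, counts, x) {
  # counts may be a K-vector (complete data) or a K x M matrix of per-feature
  # observed counts (rows = clusters) when entries are still marginalized
  K <- if (is.matrix(counts)) nrow(counts) else length(counts)
  total <- numeric(K)
  off <- 0L
  for (m in seq_along(model$features)) {
    f <- model$features[[m]]
    d <- suff_dim(f)
    if (!is.na(x[m])) {
      cnt <- if (is.matrix(counts)) counts[, m] else counts
      total <- total + lp_clusters(f, stats[, off + seq_len(d), drop = FALSE],
                                   cnt, x[m])
    }
    off <- off + d
  }
  total
}

# log predictive of a single point against one cluster, restricted to observed
# (non-NA) entries -- used for the observed-data objective under imputation.
# `count` is scalar, or a per-feature vector of observed counts.
lp_point_obs <- function(model, statrow, count, x) {
  if (!inherits(model, "mapdp_elliptical")) {
    if (any(is.na(x))) stop("NA observation for a non-factorized model")
    return(log_predictive(posterior_from_stats(model, statrow, count), x))
  }
  total <- 0
  off <- 0L
  for (m in seq_along(model$features)) {
    f <- model$features[[m]]
    d <- suff_dim(f)
    if (!is.na(x[m])) {
      cnt <- if (length(count) > 1L) count[m] else count
      post <- posterior_from_stats(f, statrow[off + seq_len(d)], cnt)
      total <- total + log_predictive(post, x[m])
    }
    off <- off + d
  }
  total
}

# One full MAP-DP run (single visiting order) in pure R.
#
# X: numeric matrix with masked entries already given concrete initial values
# (prior predictive draws); model: any component model; order: visiting
# permutation; mask: optional logical matrix of latent (missing) entries.
#
# Missing-data alternation: masked entries are marginalized out of all costs
# and sufficient statistics until the first imputation (end of sweep 1); the
# imputation sets each masked entry to the posterior-predictive mode of the
# point's cluster excluding the point (the initial prior draw only breaks
# discrete ties), after which imputed values are treated as observed within a
# sweep and re-imputed after each subsequent sweep. Convergence is judged on
# the observed-entries objective throughout.
mapdp_engine_r <- function(X, model, n0, epsilon, max_iter, order,
                           reinforce = TRUE, allow_new = TRUE,
                           z_init = NULL, conv_abs = TRUE, mask = NULL) {
  N <- nrow(X)
  S <- suff_dim(model)
  if (is.null(z_init)) z_init <- rep(1L, N)
  z <- as.integer(z_init)
  K <- max(z)
  has_missing <- !is.null(mask) && any(mask)
  M <- if (inherits(model, "mapdp_elliptical")) length(model$features) else 1L
  Xw <- X
  if (has_missing) Xw[mask] <- NA  # marginalized until first imputation

  stats <- matrix(0, K, S)
  counts <- numeric(K)
  oc <- matrix(0, K, M)  # per-feature observed counts (== counts if complete)
  obs_of <- function(x) if (M == 1L) 1 else as.numeric(!is.na(x))
  for (i in seq_len(N)) {
    stats[z[i], ] <- stats[z[i], ] + suff_of(model, Xw[i, ])
    counts[z[i]] <- counts[z[i]] + 1
    oc[z[i], ] <- oc[z[i], ] + obs_of(Xw[i, ])
  }
  is_init <- rep(K == 1L, K)
  cnt_for_lp <- function() {
    if (has_missing && M > 1L) oc else counts
  }

  E_old <- Inf
  trace <- numeric(0)
  iter <- 0L
  log_n0 <- log(n0)

  repeat {
    iter <- iter + 1L
    first_iter <- iter == 1L
    for (i in order) {
      x <- Xw[i, ]
      sx <- suff_of(model, x)
      ov <- obs_of(x)
      k_old <- z[i]
      stats[k_old, ] <- stats[k_old, ] - sx
      counts[k_old] <- counts[k_old] - 1
      oc[k_old, ] <- oc[k_old, ] - ov
      if (counts[k_old] < 0.5) {  # drop empty cluster, compact labels
        stats <- stats[-k_old, , drop = FALSE]
        counts <- counts[-k_old]
        oc <- oc[-k_old, , drop = FALSE]
        is_init <- is_init[-k_old]
        z[z > k_old] <- z[z > k_old] - 1L
      }
      K <- length(counts)
      cnt_term <- counts
      if (reinforce && first_iter) cnt_term[is_init] <- 1
      cost <- if (K > 0L) -lp_clusters(model, stats, cnt_for_lp(), x) - log(cnt_term)
              else numeric(0)
      best <- if (K > 0L) which.min(cost) else integer(0)
      take_new <- FALSE
      if (allow_new) {
        cost_new <- -log_predictive(model, x) - log_n0
        take_new <- K == 0L || cost_new < cost[best]
      }
      if (take_new) {
        stats <- rbind(stats, sx)
        counts <- c(counts, 1)
        oc <- rbind(oc, ov)
        is_init <- c(is_init, FALSE)
        z[i] <- length(counts)
      } else {
        stats[best, ] <- stats[best, ] + sx
        counts[best] <- counts[best] + 1
        oc[best, ] <- oc[best, ] + ov
        z[i] <- best
      }
    }
    K <- length(counts)

    if (has_missing) {
      # posterior-mode update of every masked entry, excluding the point; on
      # the first pass this replaces the marginalized NAs with concrete values
      for (i in which(rowSums(mask) > 0)) {
        sx <- suff_of(model, Xw[i, ])
        ov <- obs_of(Xw[i, ])
        stats[z[i], ] <- stats[z[i], ] - sx
        counts[z[i]] <- counts[z[i]] - 1
        oc[z[i], ] <- oc[z[i], ] - ov
        off <- 0L
        for (m in seq_along(model$features)) {
          f <- model$features[[m]]
          d <- suff_dim(f)
          if (mask[i, m]) {
            post <- posterior_from_stats(f, stats[z[i], off + seq_len(d)],
                                         oc[z[i], m])
            prev <- if (is.na(Xw[i, m])) X[i, m] else Xw[i, m]
            Xw[i, m] <- predictive_mode(post, previous = prev)
          }
          off <- off + d
        }
        stats[z[i], ] <- stats[z[i], ] + suff_of(model, Xw[i, ])
        counts[z[i]] <- counts[z[i]] + 1
        oc[z[i], ] <- oc[z[i], ] + obs_of(Xw[i, ])
      }
    }

    # objective re-evaluated at sweep end (observed entries only when imputing)
    E <- 0
    for (i in seq_len(N)) {
      sx <- suff_of(model, Xw[i, ])
      ov <- obs_of(Xw[i, ])
      k <- z[i]
      stats[k, ] <- stats[k, ] - sx
      counts[k] <- counts[k] - 1
      oc[k, ] <- oc[k, ] - ov
      xi <- Xw[i, ]
      if (has_missing) xi[mask[i, ]] <- NA
      cnt <- if (has_missing && M > 1L) oc[k, ] else counts[k]
      E <- E - lp_point_obs(model, stats[k, ], cnt, xi)
      stats[k, ] <- stats[k, ] + sx
      counts[k] <- counts[k] + 1
      oc[k, ] <- oc[k, ] + ov
    }
    E <- E - K * log_n0 - sum(lgamma(counts))
    trace <- c(trace, E)

    delta <- if (conv_abs) abs(E_old - E) else E_old - E
    if (delta < epsilon || iter >= max_iter) break
    E_old <- E
  }

  list(z = z, K = K, trace = trace, iterations = iter, counts = counts,
       X_completed = Xw)
}
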