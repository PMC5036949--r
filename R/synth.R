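# Synthetic Gaussian benchmark scenarios and evaluation.
#
# Six two-dimensional mixture-of-three-Gaussians scenarios (N = 4000 points by
# default) exercising the classic failure modes of K-means: unequal radii,
# unequal density, outliers, rotation, and overlap. The generating parameters
# are fixed constants chosen to satisfy each scenario's qualitative
# description (separation, radius ratios, stated mixing proportions); they are
# versioned here so benchmark results are stable.

rot_cov <- function(theta, a, b) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  R %*% diag(c(a, b)) %*% t(R)
}

scenario_table <- function(n = 4000) {
  list(
    # three well-separated spherical clusters with radii 1:2:3, equal thirds
    s5_1 = list(
      name = "s5_1", n = n,
      means = rbind(c(0, 0), c(15, 0), c(0, 15)),
      covs = list(diag(2), diag(2) * 4, diag(2) * 9),
      props = c(1, 1, 1) / 3, outliers = NULL,
      description = "spherical, unequal radii, equal counts, well separated"),
    # equal radii, unequal density 69/29/2%
    s5_2 = list(
      name = "s5_2", n = n,
      means = rbind(c(0, 0), c(8, 0), c(4, 7)),
      covs = list(diag(2), diag(2), diag(2)),
      props = c(0.69, 0.29, 0.02), outliers = NULL,
      description = "spherical, equal radii, unequal density"),
    # equal radii and density plus two far outlier pairs (own truth labels)
    s5_3 = list(
      name = "s5_3", n = n,
      means = rbind(c(0, 0), c(6, 0), c(3, 5)),
      covs = list(diag(2), diag(2), diag(2)),
      props = c(1, 1, 1) / 3,
      outliers = list(centers = rbind(c(90, 95), c(-60, 65)),
                      per_group = 2L, jitter_sd = 0.5),
      description = "spherical, equal radii and density, two outlier pairs"),
    # equal-volume, equal-density ellipses, one rotated
    s5_4 = list(
      name = "s5_4", n = n,
      means = rbind(c(0, 0), c(14, 0), c(7, 12)),
      covs = list(rot_cov(0, 8, 1), rot_cov(0, 8, 1), rot_cov(pi / 3, 8, 1)),
      props = c(1, 1, 1) / 3, outliers = NULL,
      description = "elliptical, equal volume and density, one rotated"),
    # trivially separated ellipses with 12/28/60% proportions
    s5_5 = list(
      name = "s5_5", n = n,
      means = rbind(c(0, 0), c(25, 6), c(8, 25)),
      covs = list(rot_cov(0, 2, 0.5), rot_cov(pi / 4, 6, 1), rot_cov(0, 1, 4)),
      props = c(0.12, 0.28, 0.60), outliers = NULL,
      description = "elliptical, unequal everything, trivially separated"),
    # unequal ellipses with significant overlap, 30/5/65%
    s5_6 = list(
      name = "s5_6", n = n,
      means = rbind(c(0, 0), c(4, 4), c(8, 0)),
      covs = list(rot_cov(pi / 9, 6, 1), rot_cov(-2 * pi / 9, 2, 0.7),
                  rot_cov(7 * pi / 18, 5, 1.5)),
      props = c(0.30, 0.05, 0.65), outliers = NULL,
      description = "elliptical, unequal volume and density, significant overlap")
  )
}

#' Synthetic benchmark scenario definition
#'
#' Returns the frozen generative description of one of the six benchmark
#' scenarios: component means, covariances and mixing proportions of a
#' three-component 2-D Gaussian mixture, plus an outlier specification for
#' `s5_3` (two groups of two points far from all clusters, each group carrying
#' its own ground-truth label).
#'
#' @param name One of `"s5_1" ... "s5_6"`.
#' @param n Total number of points (default 4000).
#' @return A list of class `mapdp_scenario`.
#' @export
mapdp_scenario <- function(name = c("s5_1", "s5_2", "s5_3", "s5_4", "s5_5", "s5_6"),
                           n = 4000) {
  name <- match.arg(name)
  sc <- scenario_table(n)[[name]]
  class(sc) <- "mapdp_scenario"
  sc
}

rmvnorm_chol <- function(n, mean, Sigma) {
  D <- length(mean)
  Z <- matrix(stats::rnorm(n * D), n, D)
  sweep(Z %*% chol(Sigma), 2, mean, "+")
}

#' Generate a labeled dataset from a scenario
#'
#' Component counts are the fixed rounded proportions of `n` (the scenario's
#' stated composition, not a multinomial draw); outlier points are appended
#' with distinct truth labels.
#'
#' @param scenario A [mapdp_scenario()] (or its name).
#' @param seed Optional seed; the same seed yields an identical dataset.
#' @return List with `X` (n x 2 matrix), `labels` (truth, 1..K_true), and
#'   `scenario`.
#' @export
generate_scenario <- function(scenario, seed = NULL) {
  if (is.character(scenario)) scenario <- mapdp_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  n_out <- if (is.null(scenario$outliers)) 0L else
    nrow(scenario$outliers$centers) * scenario$outliers$per_group
  n_main <- scenario$n - n_out
  counts <- floor(scenario$props * n_main)
  counts[1] <- counts[1] + n_main - sum(counts)
  K <- length(counts)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    rmvnorm_chol(counts[k], scenario$means[k, ], scenario$covs[[k]])))
  labels <- rep(seq_len(K), counts)
  if (n_out > 0) {
    oc <- scenario$outliers
    for (g in seq_len(nrow(oc$centers))) {
      pts <- rmvnorm_chol(oc$per_group, oc$centers[g, ],
                          diag(oc$jitter_sd^2, 2))
      X <- rbind(X, pts)
      labels <- c(labels, rep(K + g, oc$per_group))
    }
  }
  list(X = X, labels = labels, scenario = scenario)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table normalized by the
#' arithmetic mean of the two entropies, giving a label-permutation-invariant
#' score in `0..1`: 1 iff the partitions are identical up to relabeling, 0
#' when one partition carries no information about the other (in particular
#' whenever either partition is a single block and the other is not).
#'
#' @param a,b Equal-length label vectors.
#' @return NMI between 0 and 1.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors have different lengths")
  n <- length(a)
  ct <- table(a, b)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * (log(pij[nz]) - log(outer(pi_, pj_))[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 && hb == 0) return(1)   # two identical trivial partitions
  if (ha == 0 || hb == 0) return(0)
  val <- mi / ((ha + hb) / 2)
  min(max(val, 0), 1)
}

#' Run the synthetic benchmark
#'
#' For each scenario x seed, generates the data, fits MAP-DP (full-Gaussian
#' Student-t predictive model, empirical-Bayes prior, `n0 = 3`, random-order
#' restarts) and optionally the K-means (true K, K-means++, many restarts) and
#' E-M baselines, and scores each against the ground truth by NMI.
#'
#' @param scenarios Character vector of scenario names.
#' @param methods Subset of `c("mapdp", "kmeans", "em")`.
#' @param seeds Integer vector of generation/fit seeds (one row per seed).
#' @param n Points per dataset (default 4000).
#' @param n0 Concentration for MAP-DP (default 3, the benchmark protocol).
#' @param mapdp_restarts Extra random-permutation restarts (default 9, i.e.
#'   10 visiting orders in total).
#' @param kmeans_restarts K-means++ restarts (default 100).
#' @return Data frame with one row per scenario x seed x method: `nmi`,
#'   estimated/used `k`, and `iterations`.
#' @export
run_benchmark <- function(scenarios = paste0("s5_", 1:6),
                          methods = c("mapdp", "kmeans"),
                          seeds = 1:5, n = 4000, n0 = 3,
                          mapdp_restarts = 9, kmeans_restarts = 100) {
  methods <- match.arg(methods, c("mapdp", "kmeans", "em"), several.ok = TRUE)
  rows <- list()
  for (sc_name in scenarios) {
    for (seed in seeds) {
      dat <- generate_scenario(sc_name, seed = seed)
      X <- dat$X
      truth <- dat$labels
      if ("mapdp" %in% methods) {
        prior <- eb_full_gaussian(X)
        fit <- mapdp_fit(X, prior, n0 = n0,
                         config = mapdp_config(restarts = mapdp_restarts,
                                               seed = seed))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc_name, seed = seed, method = "mapdp",
          nmi = nmi(truth, fit$z), k = fit$K, iterations = fit$iterations)
      }
      if ("kmeans" %in% methods) {
        set.seed(seed)
        km <- kmeans_fit(X, 3, nstart = kmeans_restarts)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc_name, seed = seed, method = "kmeans",
          nmi = nmi(truth, km$z), k = 3, iterations = km$iterations)
      }
      if ("em" %in% methods) {
        set.seed(seed)
        em <- gmm_em(X, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc_name, seed = seed, method = "em",
          nmi = nmi(truth, em$z), k = 3, iterations = em$iterations)
      }
    }
  }
  do.call(rbind, rows)
}
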