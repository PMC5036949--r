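# Out-of-sample prediction for a fitted model. The cluster indicator of a new
# point is either integrated out against its collapsed CRP prior (mixture
# predictive) or set to its MAP value. In both cases theta_k is the posterior
# from all N training points of cluster k (the new point is not in the
# training set, so no exclusion is needed).

cluster_posteriors <- function(fit) {
  lapply(seq_len(fit$K), function(k)
    posterior_update(fit$model, fit$X[fit$z == k, , drop = FALSE]))
}

predictive_weights <- function(fit) {
  N <- length(fit$z)
  c(fit$n_k, fit$n0) / (fit$n0 + N)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mixture predictive density for a new observation
#'
#' Integrates the unknown indicator out:
#' `p(x) = sum_{k=1}^{K+1} w_k f(x | theta_k)` with prior assignment weights
#' `w_k = N_k / (n0 + N)` for existing clusters and `w_{K+1} = n0 / (n0 + N)`
#' for a new one (whose predictive is the prior predictive). Computed with
#' log-sum-exp stabilization.
#'
#' @param fit A `mapdp_fit` object.
#' @param x A single new observation (vector; NAs marginalized for elliptical
#'   models).
#' @return A predictive report: list with `assign_prob` (the K+1 prior
#'   assignment probabilities, summing to 1), `component_log_densities`,
#'   `log_density` (the mixture log density), `map_cluster` and
#'   `map_log_density` (as in [map_predictive()]).
#' @export
mixture_predictive <- function(fit, x) {
  stopifnot(inherits(fit, "mapdp_fit"))
  w <- predictive_weights(fit)
  posts <- c(cluster_posteriors(fit), list(fit$model))
  lp <- vapply(posts, function(p) log_predictive(p, x), numeric(1))
  map_k <- which.min(-lp - log(w))
  structure(list(assign_prob = w, component_log_densities = lp,
                 log_density = logsumexp(log(w) + lp),
                 map_cluster = map_k, map_log_density = lp[map_k]),
            class = "mapdp_predictive")
}

#' MAP predictive for a new observation
#'
#' Point-estimates the indicator:
#' `k* = argmin_k [-ln f(x | theta_k) - ln w_k]` over the K existing clusters
#' and the new-cluster option (index K+1), and reports `f(x | theta_{k*})`.
#'
#' @inheritParams mixture_predictive
#' @return A predictive report as in [mixture_predictive()]; `map_cluster` is
#'   `k*` and `map_log_density` the log density of its component.
#' @export
map_predictive <- function(fit, x) {
  mixture_predictive(fit, x)  # same report; MAP fields are the point estimate
}

#' Held-out log-likelihood of new data
#'
#' Sum of per-row mixture predictive log densities -- the score used by
#' cross-validation over hyperparameters.
#'
#' @param fit A `mapdp_fit`.
#' @param Xnew Matrix of new observations (rows).
#' @return Scalar total log density.
#' @export
heldout_loglik <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  w <- predictive_weights(fit)
  posts <- c(cluster_posteriors(fit), list(fit$model))
  lw <- log(w)
  total <- 0
  for (i in seq_len(nrow(Xnew))) {
    lp <- vapply(posts, function(p) log_predictive(p, Xnew[i, ]), numeric(1))
    total <- total + logsumexp(lw + lp)
  }
  total
}

#' Predict method for MAP-DP fits
#'
#' @param object A `mapdp_fit`.
#' @param newdata Matrix of new observations.
#' @param type `"map"` returns the MAP cluster per row; `"mixture"` the
#'   mixture log density per row.
#' @param ... Unused.
#' @return Data frame with columns `map_cluster` and `mixture_log_density`.
#' @export
predict.mapdp_fit <- function(object, newdata, type = c("map", "mixture"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  reports <- lapply(seq_len(nrow(newdata)),
                    function(i) mixture_predictive(object, newdata[i, ]))
  data.frame(map_cluster = vapply(reports, `[[`, numeric(1), "map_cluster"),
             mixture_log_density = vapply(reports, `[[`, numeric(1), "log_density"))
}
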