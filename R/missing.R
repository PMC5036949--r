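# Missing data as latent variables: masked entries are initialized by a draw
# from their feature's prior predictive, then updated to the posterior
# predictive mode of the point's current cluster (excluding the point itself)
# after every assignment sweep. The missingness mechanism is assumed
# ignorable. The alternation itself lives in the engine (R/engine.R); the
# helpers here are its entry points and are also usable standalone.

#' Initialize masked entries from the prior predictive
#'
#' Each masked entry is drawn from `f(x | theta_{0,m})`, the prior predictive
#' of its feature under an elliptical model. Entries respect the feature's
#' support (a Bernoulli feature is imputed in {0,1}, etc.).
#'
#' @param X Numeric matrix, possibly with NAs.
#' @param model An [elliptical_model()] covering all columns of `X`.
#' @param mask Logical matrix of entries to impute (default `is.na(X)`).
#' @param seed Optional seed for reproducible draws (otherwise the current RNG
#'   state is used, e.g. the one seeded by [mapdp_fit()]).
#' @return The completed matrix (unchanged if nothing is masked).
#' @export
initialize_missing <- function(X, model, mask = is.na(X), seed = NULL) {
  if (!any(mask)) return(X)
  if (!inherits(model, "mapdp_elliptical"))
    stop("missing-value imputation requires an elliptical model")
  if (!is.null(seed)) set.seed(seed)
  for (m in seq_len(ncol(X))) {
    idx <- which(mask[, m])
    if (length(idx))
      X[idx, m] <- prior_predictive_draw(model$features[[m]], length(idx))
  }
  X
}

#' One posterior-mode update of masked entries
#'
#' Given current assignments, sets each masked entry to the mode of its
#' feature's posterior predictive under the point's cluster, computed from all
#' other points in that cluster (the point's own imputed values are excluded).
#' Gaussian features are imputed at the predictive mean; discrete features at
#' the predictive mode, with ties keeping the previous imputed value.
#'
#' @param X Completed data matrix (output of [initialize_missing()] or a
#'   previous update).
#' @param z Current cluster assignments.
#' @param mask Logical matrix of imputed entries.
#' @param model The prior [elliptical_model()].
#' @return The updated completed matrix.
#' @export
update_missing <- function(X, z, mask, model) {
  if (!any(mask)) return(X)
  if (!inherits(model, "mapdp_elliptical"))
    stop("missing-value imputation requires an elliptical model")
  K <- max(z)
  S <- suff_dim(model)
  stats <- matrix(0, K, S)
  counts <- numeric(K)
  for (i in seq_len(nrow(X))) {
    stats[z[i], ] <- stats[z[i], ] + suff_of(model, X[i, ])
    counts[z[i]] <- counts[z[i]] + 1
  }
  for (i in which(rowSums(mask) > 0)) {
    sx <- suff_of(model, X[i, ])
    stats[z[i], ] <- stats[z[i], ] - sx
    counts[z[i]] <- counts[z[i]] - 1
    off <- 0L
    for (m in seq_along(model$features)) {
      f <- model$features[[m]]
      d <- suff_dim(f)
      if (mask[i, m]) {
        post <- posterior_from_stats(f, stats[z[i], off + seq_len(d)], counts[z[i]])
        X[i, m] <- predictive_mode(post, previous = X[i, m])
      }
      off <- off + d
    }
    stats[z[i], ] <- stats[z[i], ] + suff_of(model, X[i, ])
    counts[z[i]] <- counts[z[i]] + 1
  }
  X
}
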