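# Dataset and schema I/O. Feature tables are RFC-4180 CSV with a JSON schema
# sidecar: a list of {name, kind, params} entries, one per data column, where
# kind is one of gaussian, bernoulli, binomial (params$n_trials), categorical
# (params$n_levels), poisson. Missing values are empty fields or a
# configurable token (default "NA").

#' Read a feature schema from a JSON sidecar
#'
#' @param path Path to a JSON file: an array of objects with fields `name`,
#'   `kind` and optional `params` (`n_trials` for binomial, `n_levels` for
#'   categorical, optional `sigma_sq` for gaussian).
#' @return A validated schema: list of entries.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_schema(raw)
}

validate_schema <- function(schema) {
  kinds <- c("gaussian", "bernoulli", "binomial", "categorical", "poisson")
  for (i in seq_along(schema)) {
    ent <- schema[[i]]
    if (is.null(ent$name) || is.null(ent$kind))
      stop("schema entry ", i, " lacks a name or kind")
    if (!ent$kind %in% kinds)
      stop("schema entry '", ent$name, "': unknown kind '", ent$kind, "'")
    if (is.null(ent$params)) schema[[i]]$params <- list()
    if (ent$kind == "binomial") {
      nt <- ent$params$n_trials
      if (is.null(nt) || nt < 1 || nt != as.integer(nt))
        stop("binomial feature '", ent$name, "' needs integer n_trials >= 1")
    }
    if (ent$kind == "categorical") {
      nl <- ent$params$n_levels
      if (is.null(nl) || nl < 2)
        stop("categorical feature '", ent$name, "' needs n_levels >= 2")
    }
  }
  names(schema) <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(names(schema))) stop("duplicate feature names in schema")
  schema
}

#' Write a feature schema to JSON
#' @param schema A schema list.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unname(schema), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build an elliptical component model from a schema
#'
#' Uses prior hyperparameters declared in each entry's `params` where present
#' (`mu0`, `sigma0sq`, `sigma_sq`, `a0`, `b0`, `alpha0`) and neutral defaults
#' otherwise. For data-driven priors use [empirical_bayes_theta0()] instead.
#'
#' @param schema A schema (see [read_schema()]).
#' @return An [elliptical_model()].
#' @export
schema_model <- function(schema) {
  schema <- validate_schema(schema)
  feats <- lapply(schema, function(ent) {
    p <- ent$params
    switch(ent$kind,
      gaussian = spherical_gaussian(p$mu0 %||% 0, p$sigma0sq %||% 1,
                                    p$sigma_sq %||% 1),
      bernoulli = bernoulli_feature(p$a0 %||% 1, p$b0 %||% 1),
      binomial = binomial_feature(p$n_trials, p$a0 %||% 1, p$b0 %||% 1),
      categorical = categorical_feature(p$n_levels,
                                        unlist(p$alpha0) %||% rep(1, p$n_levels)),
      poisson = poisson_feature(p$a0 %||% 1, p$b0 %||% 1))
  })
  elliptical_model(feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a CSV feature table against a schema
#'
#' Columns are matched to schema entries by header name (all schema columns
#' must be present; extra columns are an error). Cells equal to
#' `missing_token` or empty become masked entries. Values are validated
#' against each feature's support (e.g. a categorical cell outside the
#' declared levels is an error naming the row and column).
#'
#' @param path CSV file path (header row required). An optional `id` column is
#'   preserved as row identifiers.
#' @param schema A schema or path to one.
#' @param missing_token String treated as missing in addition to empty fields
#'   (default `"NA"`).
#' @return List with `X` (numeric matrix, categorical levels as integers),
#'   `mask` (logical matrix of missing entries), `ids`, and `schema`.
#' @export
read_dataset <- function(path, schema, missing_token = "NA") {
  if (is.character(schema) && length(schema) == 1L && file.exists(schema))
    schema <- read_schema(schema)
  schema <- validate_schema(schema)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  ids <- if ("id" %in% names(df)) df[["id"]] else as.character(seq_len(nrow(df)))
  df <- df[, setdiff(names(df), "id"), drop = FALSE]
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop("CSV lacks schema column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    stop("unknown column(s) not in schema: ", paste(extra, collapse = ", "))
  df <- df[, names(schema), drop = FALSE]
  n <- nrow(df)
  X <- matrix(NA_real_, n, length(schema),
              dimnames = list(ids, names(schema)))
  model <- schema_model(schema)
  for (m in seq_along(schema)) {
    raw <- trimws(df[[m]])
    raw[is.na(raw)] <- missing_token  # read.csv may pre-convert the NA token
    miss <- raw == "" | raw == missing_token
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(vals))
    if (length(bad))
      stop("unparseable cell at row ", bad[1L], ", column '",
           names(schema)[m], "': '", raw[bad[1L]], "'")
    for (i in which(!miss))
      check_support(model$features[[m]], vals[i], feature = names(schema)[m])
    X[!miss, m] <- vals[!miss]
  }
  list(X = X, mask = is.na(X), ids = ids, schema = schema)
}

#' Write a CSV feature table
#'
#' Round-trip companion of [read_dataset()]: masked entries are written as the
#' missing token.
#'
#' @param X Numeric matrix with column names.
#' @param path Output CSV path.
#' @param ids Optional row identifiers (written as an `id` column).
#' @param missing_token Token for NA entries (default `"NA"`).
#' @export
write_dataset <- function(X, path, ids = NULL, missing_token = "NA") {
  df <- as.data.frame(X)
  if (!is.null(ids)) df <- cbind(id = ids, df)
  utils::write.csv(df, path, row.names = FALSE, na = missing_token)
  invisible(path)
}

#' Write fit results to an output directory
#'
#' Writes `assignments.csv` (row id, cluster label) and `summary.json` with
#' K, the final objective, iteration count, per-restart objectives, the seed
#' and a config echo sufficient to reproduce the run.
#'
#' @param fit A `mapdp_fit`.
#' @param dir Output directory (created if needed).
#' @param ids Optional row identifiers.
#' @return Invisibly, the two file paths.
#' @export
write_result <- function(fit, dir, ids = NULL) {
  stopifnot(inherits(fit, "mapdp_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(ids)) ids <- seq_along(fit$z)
  apath <- file.path(dir, "assignments.csv")
  utils::write.csv(data.frame(id = ids, cluster = fit$z), apath,
                   row.names = FALSE)
  spath <- file.path(dir, "summary.json")
  cfg <- fit$config
  jsonlite::write_json(list(
    K = fit$K, final_nll = fit$nll, iterations = fit$iterations,
    restart_nlls = fit$restart_nlls, best_restart = fit$best_restart,
    n0 = fit$n0, seed = cfg$seed,
    config = list(epsilon = cfg$epsilon, max_iterations = cfg$max_iterations,
                  restarts = cfg$restarts, seed = cfg$seed,
                  reinforcement_fix = cfg$reinforcement_fix,
                  convergence_mode = cfg$convergence_mode)),
    spath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(assignments = apath, summary = spath))
}
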