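#' Random-forest hyperparameters
#'
#' Regression forests throughout: the response is a continuous dependency
#' score.  `mtry = NULL` applies the regression convention of p/3 candidate
#' features per split, rounded up, where p is the width of the design matrix
#' actually fit.
#'
#' @param n_trees trees per forest.
#' @param mtry candidate features per split (`NULL` = ceiling(p/3)).
#' @param min_node minimal node size still considered for splitting
#'   (nodes smaller than `2 * min_node` become leaves).
#' @param seed forest RNG seed (32-bit integer); same seed and inputs give
#'   bit-identical importances.
#' @export
forest_config <- function(n_trees = 500L, mtry = NULL, min_node = 5L,
                          seed = 1L) {
  stopifnot(n_trees >= 1, min_node >= 1,
            is.null(mtry) || mtry >= 1)
  list(n_trees = as.integer(n_trees),
       mtry = if (is.null(mtry)) NULL else as.integer(mtry),
       min_node = as.integer(min_node),
       seed = as.integer(seed))
}

resolve_mtry <- function(cfg, p) {
  if (is.null(cfg$mtry)) as.integer(ceiling(p / 3)) else min(cfg$mtry, p)
}

#' Per-feature random-forest importance
#'
#' Fits a regression forest of `y` on `X` and returns one importance score
#' per column of `X` under the requested metric:
#' \describe{
#'   \item{gini}{mean (over trees) total decrease of variance impurity --
#'     sum of squared errors -- attributed to the feature's splits.}
#'   \item{permutation_raw}{mean increase of out-of-bag squared error when
#'     the feature's values are permuted within the OOB rows; unscaled.}
#'   \item{gini_corrected}{bias-corrected impurity importance: the forest is
#'     fit on `X` augmented with a row-permuted copy of every column, and
#'     each feature's impurity importance is debiased by subtracting the
#'     importance its permuted copy earns (its expectation under no
#'     association).}
#' }
#'
#' @param X numeric predictor matrix (>= 2 columns, no missing values).
#' @param y numeric response (finite, non-constant, length = nrow(X) >= 10).
#' @param method importance metric.
#' @param cfg a [forest_config()].
#' @return named numeric vector of importances, one per column of `X`.
#' @export
rf_importance <- function(X, y,
                          method = c("permutation_raw", "gini",
                                     "gini_corrected"),
                          cfg = forest_config()) {
  method <- match.arg(method)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) < 2) stop("X needs >= 2 columns", call. = FALSE)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (length(y) < 10) stop("need >= 10 samples", call. = FALSE)
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  if (stats::var(y) == 0)
    stop("response has zero variance", call. = FALSE)

  if (method == "gini_corrected") {
    perm <- with_local_seed(cfg$seed, {
      apply(X, 2, sample)
    })
    design <- cbind(X, perm)
    fit <- .rf_forest_cpp(design, y, cfg$n_trees,
                          resolve_mtry(cfg, ncol(design)), cfg$min_node,
                          cfg$seed, FALSE)
    p <- ncol(X)
    out <- fit$gini[seq_len(p)] - fit$gini[p + seq_len(p)]
  } else {
    fit <- .rf_forest_cpp(X, y, cfg$n_trees, resolve_mtry(cfg, ncol(X)),
                          cfg$min_node, cfg$seed,
                          method == "permutation_raw")
    out <- if (method == "gini") fit$gini else fit$permutation
  }
  names(out) <- colnames(X)
  out
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
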