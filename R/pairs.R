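#' Pearson correlation for pair direction
#'
#' Plain product-moment correlation, pairwise-complete on missing values.
#' Constant input gives `NA` with a warning; such pairs are dropped by the
#' direction filter.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in \[-1, 1\], or `NA` for degenerate input.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("constant or insufficient input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Candidate pairs for one target gene
#'
#' Fits the all-relevant selection of the feature cohort against the
#' target's dependency profile.  Confirmed features (optionally Tentative
#' ones) become candidate pairs carrying the median importance over the
#' selection run and the Pearson correlation between the feature column and
#' the dependency score.
#'
#' Samples with a missing dependency score for this target are dropped from
#' this model only.  Remaining missing predictor cells are median-imputed
#' per column for the forest; correlations use the original, non-imputed
#' values (pairwise complete).
#'
#' @param target gene symbol, must be a column of `dep`.
#' @param dep dependency [omics_matrix()].
#' @param features predictor [omics_matrix()] (mutation_binary or
#'   expression), sample-aligned with `dep`.
#' @param feature_type `"mutation"` or `"expression"`.
#' @param method importance metric, see [rf_importance()].
#' @param bcfg,fcfg selection-loop and forest parameters.
#' @param min_mutated_samples for mutation features: minimum number of
#'   mutated cell lines a column needs to enter the model (default 1, i.e.
#'   only all-zero columns are dropped).
#' @param include_tentative also emit Tentative features (default FALSE).
#' @return data.frame of candidate pairs (possibly 0 rows) with columns
#'   `target_gene`, `feature_gene`, `feature_type`, `method`, `importance`,
#'   `pcc`, `n_samples`.  Self-pairs are still present; remove them with
#'   [drop_self_pairs()].
#' @export
run_target <- function(target, dep, features, feature_type, method,
                       bcfg = boruta_config(), fcfg = forest_config(),
                       min_mutated_samples = 1L,
                       include_tentative = FALSE) {
  stopifnot(feature_type %in% c("mutation", "expression"))
  if (!target %in% gene_ids(dep))
    stop("target not in dependency matrix: ", target, call. = FALSE)
  if (!identical(sample_ids(dep), sample_ids(features)))
    stop("matrices are not sample-aligned", call. = FALSE)

  y <- dep$values[, target]
  keep <- !is.na(y)
  y <- y[keep]
  X <- features$values[keep, , drop = FALSE]
  if (feature_type == "mutation") {
    X <- X[, colSums(X) >= min_mutated_samples, drop = FALSE]
  }
  empty <- data.frame(target_gene = character(), feature_gene = character(),
                      feature_type = character(), method = character(),
                      importance = numeric(), pcc = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (ncol(X) < 2 || length(y) < 10 || stats::var(y) == 0) return(empty)

  Xfit <- X
  if (anyNA(Xfit)) {
    for (j in which(colSums(is.na(Xfit)) > 0)) {
      med <- stats::median(Xfit[, j], na.rm = TRUE)
      Xfit[is.na(Xfit[, j]), j] <- med
    }
  }
  bcfg2 <- bcfg
  bcfg2$importance_method <- method
  res <- boruta_select(Xfit, y, bcfg2, fcfg)
  wanted <- c("Confirmed", if (include_tentative) "Tentative")
  sel <- names(res$decision)[res$decision %in% wanted]
  if (!length(sel)) return(empty)

  pcc <- vapply(sel, function(g)
    suppressWarnings(pearson_cor(X[, g], y)), numeric(1))
  data.frame(target_gene = target, feature_gene = sel,
             feature_type = feature_type, method = method,
             importance = unname(res$final_importance[sel]),
             pcc = unname(pcc), n_samples = length(y),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove self-pairs
#' @param pairs candidate-pair data.frame.
#' @return `pairs` without rows where the feature gene equals the target
#'   gene; row order otherwise preserved.
#' @export
drop_self_pairs <- function(pairs) {
  pairs[pairs$target_gene != pairs$feature_gene, , drop = FALSE]
}

#' Keep pairs whose correlation matches the synthetic-lethal reading
#'
#' A deficiency should increase dependency: mutation pairs must correlate
#' positively with the dependency score, expression pairs negatively (low
#' expression, high dependency).  Pairs with undefined correlation are
#' dropped when the filter is on.
#'
#' @param pairs candidate-pair data.frame with `pcc`.
#' @param enabled bypass switch; `FALSE` returns the input unchanged.
#' @return filtered pairs.
#' @export
apply_direction_filter <- function(pairs, enabled = TRUE) {
  if (!enabled) return(pairs)
  keep <- !is.na(pairs$pcc) &
    ((pairs$feature_type == "mutation" & pairs$pcc > 0) |
     (pairs$feature_type == "expression" & pairs$pcc < 0))
  pairs[keep, , drop = FALSE]
}

#' Min-max scale importances within (method, feature_type) groups
#'
#' Scores are scaled to \[0, 1\] within each scoring group so that the
#' strongest pair of a group sits at 1.  Zero-span (all-equal or singleton)
#' groups map to 1.
#'
#' @param pairs candidate-pair data.frame with `importance`.
#' @return `pairs` with a `scaled_importance` column.
#' @export
scale_by_group <- function(pairs) {
  if (!nrow(pairs)) {
    pairs$scaled_importance <- numeric(0)
    return(pairs)
  }
  key <- interaction(pairs$method, pairs$feature_type, drop = TRUE)
  scaled <- stats::ave(pairs$importance, key, FUN = function(x) {
    span <- max(x) - min(x)
    if (span == 0) rep(1, length(x)) else (x - min(x)) / span
  })
  pairs$scaled_importance <- scaled
  pairs
}

#' Dependency statistics and essentiality per gene
#'
#' A gene whose dependency distribution has coefficient of variation
#' (sd / |mean|) below the threshold is uniformly required across lines --
#' pan-essential -- and is excluded from SL prioritization (it stays
#' available as a network node).  Zero-mean columns have undefined CV and
#' are treated as non-essential with a warning.
#'
#' @param dep dependency [omics_matrix()].
#' @param cv_threshold essentiality cut-off on the CV (default 0.3).
#' @return list with `eligible` (non-essential gene symbols) and `stats`, a
#'   data.frame of per-gene `median_dependency`, `cv`, `sd`, `range`,
#'   `is_essential`.
#' @export
essentiality_filter <- function(dep, cv_threshold = 0.3) {
  stopifnot(inherits(dep, "omics_matrix"), ncol(dep$values) > 0)
  stats_df <- do.call(rbind, lapply(gene_ids(dep), function(g) {
    v <- dep$values[, g]
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- stats::sd(v)
    cv <- if (m == 0) NA_real_ else s / abs(m)
    data.frame(gene = g, median_dependency = stats::median(v),
               cv = cv, sd = s, range = max(v) - min(v),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(stats_df$cv))
    warning("zero-mean dependency column(s); CV undefined, treated as ",
            "non-essential: ",
            paste(stats_df$gene[is.na(stats_df$cv)], collapse = ", "))
  stats_df$is_essential <- !is.na(stats_df$cv) & stats_df$cv < cv_threshold
  list(eligible = stats_df$gene[!stats_df$is_essential], stats = stats_df)
}

# Stable 32-bit string hash (polynomial, mod 2^31 - 1) for per-target seeds.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run the full per-target selection over a cohort
#'
#' For every target x feature cohort x scoring method: all-relevant
#' selection, self-pair removal, correlation, direction filter; then global
#' min-max scaling per (method, feature_type) group and essentiality-based
#' prioritization of the target side.  Each target gets its own forest seed
#' derived from the master seed plus a stable hash of the gene symbol, so
#' results are reproducible and independent of target order.
#'
#' @param targets target gene symbols (subset of `dep` genes).
#' @param dep,mut,expr sample-aligned dependency / mutation / expression
#'   matrices; `mut` and/or `expr` may be `NULL` to skip a cohort.
#' @param methods importance metrics to run (see [rf_importance()]).
#' @param bcfg,fcfg selection and forest parameters (seed in `fcfg` is
#'   ignored; `master_seed` governs).
#' @param master_seed cohort seed.
#' @param direction_filter apply [apply_direction_filter()] (default TRUE).
#' @param cv_threshold essentiality CV cut-off (default 0.3).
#' @param drop_essential remove pairs whose target is essential from the
#'   prioritized table (default TRUE).
#' @param min_mutated_samples see [run_target()].
#' @param include_tentative see [run_target()].
#' @return list with `pairs` (scaled, prioritized pair table) and
#'   `node_stats` (per-gene dependency statistics from
#'   [essentiality_filter()]).
#' @export
run_cohort <- function(targets, dep, mut = NULL, expr = NULL,
                       methods = "permutation_raw",
                       bcfg = boruta_config(), fcfg = forest_config(),
                       master_seed = 1L, direction_filter = TRUE,
                       cv_threshold = 0.3, drop_essential = TRUE,
                       min_mutated_samples = 1L, include_tentative = FALSE) {
  stopifnot(all(targets %in% gene_ids(dep)))
  cohorts <- list()
  if (!is.null(mut)) cohorts$mutation <- mut
  if (!is.null(expr)) cohorts$expression <- expr
  if (!length(cohorts)) stop("no feature cohort supplied", call. = FALSE)

  chunks <- list()
  for (target in targets) {
    base <- (as.numeric(master_seed) + stable_hash(target)) %% 2147483647
    k <- 0L
    for (ft in names(cohorts)) {
      for (method in methods) {
        k <- k + 1L
        fcfg_t <- fcfg
        fcfg_t$seed <- as.integer((base + 131 * k) %% 2147483647 + 1)
        chunks[[length(chunks) + 1L]] <- run_target(
          target, dep, cohorts[[ft]], ft, method, bcfg, fcfg_t,
          min_mutated_samples = min_mutated_samples,
          include_tentative = include_tentative)
      }
    }
  }
  pairs <- if (length(chunks))
    do.call(rbind, c(chunks, list(make.row.names = FALSE)))
  else
    data.frame(target_gene = character(), feature_gene = character(),
               feature_type = character(), method = character(),
               importance = numeric(), pcc = numeric(),
               n_samples = integer(), stringsAsFactors = FALSE)
  pairs <- drop_self_pairs(pairs)
  pairs <- apply_direction_filter(pairs, direction_filter)
  pairs <- scale_by_group(pairs)

  ess <- essentiality_filter(dep, cv_threshold)
  if (drop_essential)
    pairs <- pairs[pairs$target_gene %in% ess$eligible, , drop = FALSE]
  ord <- order(-if (nrow(pairs)) pairs$scaled_importance else numeric(0),
               pairs$target_gene, pairs$feature_gene)
  list(pairs = pairs[ord, , drop = FALSE], node_stats = ess$stats)
}
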