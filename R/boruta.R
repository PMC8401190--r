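#' All-relevant selection-loop parameters
#'
#' @param max_iter iteration cap of the selection loop (default 500).
#' @param alpha familywise significance cut-off for the binomial decisions
#'   (default 0.01), applied after Bonferroni adjustment.
#' @param adjust multiple-testing adjustment; only `"bonferroni"` is
#'   implemented.  The multiplicity is the number of features at the start
#'   of the run (fixed, not the shrinking undecided count).
#' @param min_shadow minimum number of shadow (permuted-probe) columns per
#'   iteration; small designs are padded with extra permuted copies.
#' @param importance_method forest importance metric, see [rf_importance()].
#' @export
boruta_config <- function(max_iter = 500L, alpha = 0.01,
                          adjust = "bonferroni", min_shadow = 5L,
                          importance_method = c("permutation_raw", "gini",
                                                "gini_corrected")) {
  stopifnot(max_iter >= 1, alpha > 0, alpha < 1, min_shadow >= 1,
            identical(adjust, "bonferroni"))
  list(max_iter = as.integer(max_iter), alpha = alpha, adjust = adjust,
       min_shadow = as.integer(min_shadow),
       importance_method = match.arg(importance_method))
}

#' Augment a design matrix with shadow features
#'
#' Every column is copied and independently row-permuted; the permuted
#' copies ("shadows") act as random probes whose maximum importance
#' (shadowMax) calibrates what an uninformative feature can score.  If fewer
#' than `min_shadow` columns exist, additional permuted copies are added
#' (cycling over the originals) until `min_shadow` shadows are present.
#'
#' Uses the current R RNG stream; seed at the caller.
#'
#' @param X numeric matrix.
#' @param min_shadow minimum shadow count.
#' @return list with `values` (original columns then shadows) and
#'   `shadow_idx` (column indices of the shadows).
#' @export
shadow_extend <- function(X, min_shadow = 5L) {
  stopifnot(is.matrix(X), ncol(X) >= 1)
  p <- ncol(X)
  src <- seq_len(p)
  if (p < min_shadow)
    src <- c(src, rep_len(src, min_shadow - p))
  shadows <- vapply(src, function(j) sample(X[, j]), numeric(nrow(X)))
  colnames(shadows) <- paste0("shadow_", seq_along(src), "_",
                              colnames(X)[src])
  list(values = cbind(X, shadows), shadow_idx = p + seq_along(src))
}

#' Binomial confirm/reject decision for hit counts
#'
#' Under the null, a feature beats shadowMax with probability 1/2 per
#' iteration, so its hit count is Binomial(trials, 0.5).  The upper-tail
#' probability P(X >= hits) tests for confirmation, the lower tail
#' P(X <= hits) for rejection; both are Bonferroni-adjusted by the number of
#' features tested.
#'
#' @param hits,trials integer vectors (recycled), `0 <= hits <= trials`.
#' @param n_features_tested Bonferroni multiplicity (>= 1).
#' @param alpha adjusted-p cut-off.
#' @return character vector in `{"Confirmed", "Rejected", "Undecided"}`.
#' @export
binomial_decision <- function(hits, trials, n_features_tested, alpha = 0.01) {
  stopifnot(all(hits >= 0), all(hits <= trials), all(trials >= 1),
            n_features_tested >= 1)
  p_up <- stats::pbinom(hits - 1, trials, 0.5, lower.tail = FALSE)
  p_down <- stats::pbinom(hits, trials, 0.5)
  out <- rep("Undecided", length(p_up))
  out[p_up * n_features_tested < alpha] <- "Confirmed"
  out[p_down * n_features_tested < alpha] <- "Rejected"
  out
}

#' All-relevant feature selection for one continuous response
#'
#' Iterates: shadow-augment the surviving design, score it with a fresh
#' random forest, award a hit to every undecided feature whose importance
#' strictly exceeds shadowMax (the best shadow), then apply
#' [binomial_decision()].  Rejected features are removed from subsequent
#' designs; Confirmed features stay in the model (keeping shadowMax
#' calibrated against real signal) but stop accruing hits and trials.  The
#' loop ends when nothing is Undecided or `max_iter` is reached; leftovers
#' are reported Tentative.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y continuous response.
#' @param bcfg a [boruta_config()].
#' @param fcfg a [forest_config()]; `fcfg$seed` drives the whole run.
#' @return object of class `boruta_result`: per-feature `decision`
#'   (Confirmed/Rejected/Tentative), `hits`, `trials`, `final_importance`
#'   (median over the iterations the feature participated in),
#'   `importance_history` (features x iterations, NA once removed),
#'   `shadow_max_history`, and `n_iter`.
#' @export
boruta_select <- function(X, y, bcfg = boruta_config(),
                          fcfg = forest_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  decision <- rep("Undecided", p)
  hits <- integer(p)
  trials <- integer(p)
  hist <- matrix(NA_real_, p, 0, dimnames = list(colnames(X), NULL))
  shadow_max <- numeric(0)

  with_local_seed(fcfg$seed, {
    for (iter in seq_len(bcfg$max_iter)) {
      und <- decision == "Undecided"
      if (!any(und)) break
      active <- decision != "Rejected"
      ext <- shadow_extend(X[, active, drop = FALSE], bcfg$min_shadow)
      it_cfg <- fcfg
      it_cfg$seed <- sample.int(2147483646L, 1L)
      imp <- rf_importance(ext$values, y, bcfg$importance_method, it_cfg)
      sm <- max(imp[ext$shadow_idx])
      real <- imp[seq_len(sum(active))]

      col <- rep(NA_real_, p)
      col[active] <- real
      hist <- cbind(hist, col)
      shadow_max <- c(shadow_max, sm)

      gained <- col > sm
      hits[und] <- hits[und] + as.integer(gained[und])
      trials[und] <- trials[und] + 1L
      decision[und] <- binomial_decision(hits[und], trials[und], p,
                                         bcfg$alpha)
    }
  })

  decision[decision == "Undecided"] <- "Tentative"
  final <- apply(hist, 1, function(r)
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE))
  structure(list(decision = stats::setNames(decision, colnames(X)),
                 hits = stats::setNames(hits, colnames(X)),
                 trials = stats::setNames(trials, colnames(X)),
                 final_importance = stats::setNames(final, colnames(X)),
                 importance_history = hist,
                 shadow_max_history = shadow_max,
                 n_iter = length(shadow_max)),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decision,
                      levels = c("Confirmed", "Tentative", "Rejected")))
  cat(sprintf(
    "<boruta_result: %d features, %d iterations; %d confirmed, %d tentative, %d rejected>\n",
    length(x$decision), x$n_iter, tab[1], tab[2], tab[3]))
  invisible(x)
}
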