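#' Head/tail-breaks partition of a heavy-tailed score distribution
#'
#' Recursive mean-splitting: the mean divides the current values into a head
#' (strictly above) and a tail; while the head stays a minority -- the ratio
#' of head size to the reference size is at most `stop_ratio` -- the mean is
#' recorded as a break and the recursion continues on the head.
#'
#' Two ratio conventions are offered: `head_over_tail` (|head| / |tail|,
#' the default here) and `head_over_all` (|head| / |current|, the canonical
#' head/tail-breaks formulation).
#'
#' @param values nonempty finite numeric vector.
#' @param stop_ratio minority bound (default 0.40).
#' @param mode ratio convention.
#' @return object of class `break_set`: ascending `breaks`, `head_counts`
#'   (head size at each recorded break), `stop_ratio`, `mode`.
#' @export
head_tail_breaks <- function(values, stop_ratio = 0.40,
                             mode = c("head_over_tail", "head_over_all")) {
  mode <- match.arg(mode)
  stopifnot(length(values) >= 1, all(is.finite(values)),
            stop_ratio > 0)
  breaks <- numeric(0)
  head_counts <- integer(0)
  cur <- values
  repeat {
    m <- mean(cur)
    head <- cur[cur > m]
    if (!length(head)) break
    denom <- if (mode == "head_over_tail") length(cur) - length(head)
             else length(cur)
    ratio <- if (denom == 0) Inf else length(head) / denom
    if (ratio > stop_ratio) break
    breaks <- c(breaks, m)
    head_counts <- c(head_counts, length(head))
    cur <- head
  }
  structure(list(breaks = breaks, head_counts = head_counts,
                 stop_ratio = stop_ratio, mode = mode),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set (%s, ratio %.2f): %d break(s)%s>\n",
              x$mode, x$stop_ratio, length(x$breaks),
              if (length(x$breaks))
                paste0(" at ", paste(signif(x$breaks, 4), collapse = ", "))
              else ""))
  invisible(x)
}

#' High-confidence threshold from a break set
#'
#' The last (largest) break separates the highest-confidence pairs.  When
#' the distribution produced no break, `NULL` is returned and callers fall
#' back to a configured absolute cut-off.
#'
#' @param bs a [head_tail_breaks()] result.
#' @return numeric threshold or `NULL`.
#' @export
high_confidence_threshold <- function(bs) {
  if (!length(bs$breaks)) NULL else max(bs$breaks)
}

#' Per-group confidence thresholds for a pair table
#'
#' Computes head/tail breaks of the scaled importances within every
#' (method, feature_type) group and takes the last break; groups without a
#' break use the absolute fallback for their feature cohort.
#'
#' @param pairs scaled pair table (see [scale_by_group()]).
#' @param stop_ratio,mode see [head_tail_breaks()].
#' @param fallback named fallback thresholds per feature type.
#' @return data.frame with `method`, `feature_type`, `threshold`,
#'   `n_breaks`.
#' @export
group_thresholds <- function(pairs, stop_ratio = 0.40,
                             mode = "head_over_tail",
                             fallback = c(expression = 0.4,
                                          mutation = 0.5)) {
  groups <- unique(pairs[, c("method", "feature_type")])
  if (!nrow(groups))
    return(data.frame(method = character(), feature_type = character(),
                      threshold = numeric(), n_breaks = integer(),
                      stringsAsFactors = FALSE))
  rownames(groups) <- NULL
  groups$threshold <- NA_real_
  groups$n_breaks <- 0L
  for (i in seq_len(nrow(groups))) {
    sel <- pairs$method == groups$method[i] &
      pairs$feature_type == groups$feature_type[i]
    bs <- head_tail_breaks(pairs$scaled_importance[sel], stop_ratio, mode)
    th <- high_confidence_threshold(bs)
    groups$n_breaks[i] <- length(bs$breaks)
    groups$threshold[i] <- if (is.null(th))
      unname(fallback[groups$feature_type[i]]) else th
  }
  groups
}

#' Label pairs high/low confidence across scoring methods
#'
#' A gene pair -- identified by (target, feature, feature_type) -- is
#' high-confidence if its scaled importance strictly exceeds its group's
#' threshold under at least one method, and low-confidence if it stays at or
#' below the threshold under every method where it appears.
#'
#' @param pairs scaled pair table covering one or more methods.
#' @param thresholds data.frame from [group_thresholds()] (or manually
#'   built, same columns).
#' @return `pairs` with a `confidence` column (`"high"`/`"low"`).
#' @export
label_confidence <- function(pairs, thresholds) {
  if (!nrow(pairs)) {
    pairs$confidence <- character(0)
    return(pairs)
  }
  th <- merge(pairs[, c("target_gene", "feature_gene", "feature_type",
                        "method", "scaled_importance")],
              thresholds, by = c("method", "feature_type"), all.x = TRUE)
  if (anyNA(th$threshold))
    stop("missing threshold for some (method, feature_type) group",
         call. = FALSE)
  th$above <- th$scaled_importance > th$threshold
  key <- function(d) paste(d$target_gene, d$feature_gene, d$feature_type,
                           sep = "\r")
  high_keys <- unique(key(th)[th$above])
  pairs$confidence <- ifelse(key(pairs) %in% high_keys, "high", "low")
  pairs
}

#' Ordinal confidence tiers from a break set
#'
#' Scores are graded into `n_tiers` ordinal levels by counting how many of
#' the top `n_tiers - 1` breaks they strictly exceed (tier `n_tiers - 1` =
#' top).  With fewer breaks than needed, the lower tiers collapse.
#'
#' @param scores numeric vector (same group the break set was computed on).
#' @param bs a [head_tail_breaks()] result.
#' @param n_tiers number of levels (default 3).
#' @return integer tiers in `0:(n_tiers - 1)`.
#' @export
assign_tiers <- function(scores, bs, n_tiers = 3L) {
  cuts <- utils::tail(sort(bs$breaks), n_tiers - 1L)
  if (!length(cuts)) return(rep(0L, length(scores)))
  vapply(scores, function(s) sum(s > cuts), integer(1))
}
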