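#' Build the directed vulnerability network
#'
#' Edges run from the deficient gene (mutated or dysregulated feature) to
#' the dependent target gene.  Presentation attributes are stored as data:
#' `width_weight` (|PCC|, edge width) and per-node `median_dependency`
#' (grey-scale shade).  Node statistics may be absent for feature-only
#' genes; their stat cells stay `NA`.
#'
#' @param pairs self-free pair table with `target_gene`, `feature_gene`,
#'   `feature_type`, `method`, `pcc`, `scaled_importance` and optionally
#'   `tier` / `confidence`.
#' @param node_stats per-gene statistics (see [essentiality_filter()]).
#' @return object of class `sl_network` with `nodes` and `edges` data
#'   frames.
#' @export
build_network <- function(pairs, node_stats) {
  if (nrow(pairs) && any(pairs$target_gene == pairs$feature_gene))
    stop("self-loop in pair table; run drop_self_pairs() first",
         call. = FALSE)
  key <- paste(pairs$feature_gene, pairs$target_gene, pairs$feature_type,
               pairs$method, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (source, target, feature_type, method) edge(s)",
         call. = FALSE)
  edges <- data.frame(source = pairs$feature_gene,
                      target = pairs$target_gene,
                      feature_type = pairs$feature_type,
                      method = pairs$method,
                      pcc = pairs$pcc,
                      scaled_importance = pairs$scaled_importance,
                      tier = if ("tier" %in% names(pairs)) pairs$tier
                             else rep(NA_integer_, nrow(pairs)),
                      width_weight = abs(pairs$pcc),
                      stringsAsFactors = FALSE)
  genes <- unique(c(edges$source, edges$target))
  nodes <- data.frame(gene = genes, stringsAsFactors = FALSE)
  nodes <- merge(nodes, node_stats, by = "gene", all.x = TRUE, sort = TRUE)
  structure(list(nodes = nodes, edges = edges), class = "sl_network")
}

#' @export
print.sl_network <- function(x, ...) {
  cat(sprintf("<sl_network: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Filter the network like the interactive explorer does
#'
#' @param net an `sl_network`.
#' @param min_scaled_importance named per-feature-type thresholds; edges
#'   with `scaled_importance >= threshold` for their cohort survive.
#' @param feature_types cohorts to keep.
#' @param methods scoring methods to keep (`NULL` = all).
#' @param direction_filter re-apply the correlation-sign rule to edges.
#' @return filtered `sl_network`; orphan nodes are dropped.
#' @export
filter_network <- function(net,
                           min_scaled_importance = c(mutation = 0,
                                                     expression = 0),
                           feature_types = c("mutation", "expression"),
                           methods = NULL,
                           direction_filter = FALSE) {
  e <- net$edges
  keep <- e$feature_type %in% feature_types
  thr <- min_scaled_importance[e$feature_type]
  thr[is.na(thr)] <- 0
  keep <- keep & e$scaled_importance >= thr
  if (!is.null(methods)) keep <- keep & e$method %in% methods
  if (direction_filter)
    keep <- keep & !is.na(e$pcc) &
      ((e$feature_type == "mutation" & e$pcc > 0) |
       (e$feature_type == "expression" & e$pcc < 0))
  e <- e[keep, , drop = FALSE]
  genes <- unique(c(e$source, e$target))
  structure(list(nodes = net$nodes[net$nodes$gene %in% genes, ,
                                   drop = FALSE],
                 edges = e), class = "sl_network")
}

edge_order <- function(e) {
  order(-e$scaled_importance, e$source, e$target, e$feature_type, e$method)
}

#' Export a network as edges/nodes CSV plus GraphML
#'
#' Writes `<prefix>_edges.csv`, `<prefix>_nodes.csv` (Cytoscape-compatible)
#' and `<prefix>.graphml` with identical attributes.  Edge rows are sorted
#' by scaled importance (descending), then lexicographically.
#'
#' @param net an `sl_network`.
#' @param out_prefix path prefix for the three files.
#' @return character vector of the written paths, invisibly.
#' @export
export_network <- function(net, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  e <- net$edges[edge_order(net$edges), , drop = FALSE]
  n <- net$nodes[order(net$nodes$gene), , drop = FALSE]
  paths <- c(edges = paste0(out_prefix, "_edges.csv"),
             nodes = paste0(out_prefix, "_nodes.csv"),
             graphml = paste0(out_prefix, ".graphml"))
  utils::write.csv(e, paths["edges"], row.names = FALSE, na = "")
  utils::write.csv(n, paths["nodes"], row.names = FALSE, na = "")
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) e else data.frame(source = character(),
                                   target = character()),
    directed = TRUE,
    vertices = if (nrow(n)) n else NULL)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Re-import a network exported by [export_network()]
#'
#' The CSV pair is authoritative (GraphML is a convenience copy).
#'
#' @param out_prefix prefix used at export time.
#' @return an `sl_network`.
#' @export
import_network <- function(out_prefix) {
  e <- utils::read.csv(paste0(out_prefix, "_edges.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(source = "character",
                                      target = "character"))
  n <- utils::read.csv(paste0(out_prefix, "_nodes.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(gene = "character"))
  structure(list(nodes = n, edges = e), class = "sl_network")
}

#' Cross-method agreement of scaled importances
#'
#' Pairs are matched by (target, feature, feature_type); the Pearson
#' correlation of the two scaled importance scores over the common pairs
#' measures how concordant two scoring methods are.
#'
#' @param pairs_a,pairs_b scaled pair tables.
#' @return list with `n_common` and `r` (`NA` below 3 common pairs).
#' @export
method_concordance <- function(pairs_a, pairs_b) {
  key <- function(d) paste(d$target_gene, d$feature_gene, d$feature_type,
                           sep = "\r")
  m <- merge(data.frame(k = key(pairs_a), a = pairs_a$scaled_importance,
                        stringsAsFactors = FALSE),
             data.frame(k = key(pairs_b), b = pairs_b$scaled_importance,
                        stringsAsFactors = FALSE), by = "k")
  r <- if (nrow(m) < 3) NA_real_
       else suppressWarnings(pearson_cor(m$a, m$b))
  list(n_common = nrow(m), r = r)
}

#' Interaction-score enrichment per pair group
#'
#' Joins pairs against a user-supplied gene-pair score table (e.g. STRING
#' combined scores; unordered key) and summarizes, per group, how many
#' pairs have any score and the distribution of the scores present.
#'
#' @param pairs pair table with a grouping column.
#' @param score_table data.frame with `gene_a`, `gene_b`, `combined_score`.
#' @param group_col name of the grouping column (default `"confidence"`).
#' @return data.frame per group: `n_pairs`, `n_scored`, `fraction`,
#'   `q25`/`median`/`q75` of scores present (`NA` when none).
#' @export
interaction_enrichment <- function(pairs, score_table,
                                   group_col = "confidence") {
  stopifnot(group_col %in% names(pairs))
  pkey <- function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- stats::setNames(score_table$combined_score,
                         pkey(score_table$gene_a, score_table$gene_b))
  scores <- lut[pkey(pairs$feature_gene, pairs$target_gene)]
  groups <- unique(pairs[[group_col]])
  out <- lapply(groups, function(g) {
    s <- scores[pairs[[group_col]] == g]
    present <- s[!is.na(s)]
    qs <- if (length(present))
      stats::quantile(present, c(0.25, 0.5, 0.75), names = FALSE)
    else rep(NA_real_, 3)
    data.frame(group = g, n_pairs = length(s), n_scored = length(present),
               fraction = if (length(s)) length(present) / length(s) else 0,
               q25 = qs[1], median = qs[2], q75 = qs[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
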