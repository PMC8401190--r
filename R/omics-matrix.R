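#' Cell-line-by-gene omics matrix
#'
#' The universal data carrier of the pipeline: a numeric matrix with cell
#' lines (samples) as rows and genes as columns, tagged with the kind of
#' measurement it holds.
#'
#' @param values numeric matrix, rows = samples, columns = genes, with
#'   `rownames` (sample identifiers) and `colnames` (gene symbols) set.
#' @param kind one of `"dependency"` (CRISPR knockout gene-effect or
#'   dependency-probability scores), `"expression"` (log2(TPM+1)) or
#'   `"mutation_binary"` (0/1 pathogenic-mutation indicator).
#'
#' @return an object of class `omics_matrix`: a list with elements `values`,
#'   `kind`, and accessors `sample_ids`/`gene_ids` via the helper functions.
#'
#' @details Invariants enforced at construction: unique sample and gene
#'   identifiers, matching dimnames, no all-missing gene column, and strictly
#'   0/1 (no missing) values for `kind = "mutation_binary"`.
#' @export
omics_matrix <- function(values,
                         kind = c("dependency", "expression",
                                  "mutation_binary")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample (row) and gene (column) names",
         call. = FALSE)
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  dup_g <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  if (ncol(values) > 0 && any(colSums(!is.na(values)) == 0))
    stop("all-missing gene column(s): ",
         paste(colnames(values)[colSums(!is.na(values)) == 0],
               collapse = ", "), call. = FALSE)
  if (kind == "mutation_binary") {
    if (anyNA(values) || !all(values %in% c(0, 1)))
      stop("mutation_binary values must be 0/1 with no missing cells",
           call. = FALSE)
  }
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix kind=%s: %d samples x %d genes>\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample identifiers of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of cell-line identifiers, in matrix order
#' @export
sample_ids <- function(x) rownames(x$values)

#' Gene identifiers of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of gene symbols, in matrix order
#' @export
gene_ids <- function(x) colnames(x$values)

#' Restrict matrices to their common cell lines
#'
#' Response and predictor matrices must share cell lines before any model is
#' fit.  Samples are restricted to the intersection, ordered as in the first
#' matrix; gene columns are untouched.
#'
#' @param ... one or more `omics_matrix` objects (or a single list of them).
#' @return a list of the same matrices restricted to the common samples, in
#'   identical order.  A single matrix is returned unchanged (in a list).
#' @export
align_samples <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && !inherits(mats[[1]], "omics_matrix"))
    mats <- mats[[1]]
  if (!length(mats)) stop("no matrices supplied", call. = FALSE)
  if (!all(vapply(mats, inherits, logical(1), "omics_matrix")))
    stop("all inputs must be omics_matrix objects", call. = FALSE)
  common <- sample_ids(mats[[1]])
  for (m in mats[-1]) common <- common[common %in% sample_ids(m)]
  if (!length(common))
    stop("no cell lines shared by all matrices", call. = FALSE)
  message(sprintf("align_samples: %d common cell lines", length(common)))
  lapply(mats, function(m)
    omics_matrix(m$values[common, , drop = FALSE], m$kind))
}
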