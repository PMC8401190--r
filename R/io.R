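#' CSV dialect for DepMap-style matrix files
#'
#' DepMap matrix downloads put the cell-line identifier in the first column
#' and label genes as `"SYMBOL (ENTREZID)"`.  The dialect controls the
#' identifier column name used on write and which cell contents count as
#' missing.
#'
#' @param sample_col name of the sample-identifier column written by
#'   [write_omics_matrix()]; on read the first column is always taken as the
#'   identifier regardless of its header.
#' @param na_strings cell contents mapped to missing on read.
#' @export
omics_dialect <- function(sample_col = "DepMap_ID",
                          na_strings = c("", "NA", "NaN")) {
  list(sample_col = sample_col, na_strings = na_strings)
}

#' Read a cell-line-by-gene matrix from CSV
#'
#' Gene headers of the form `"SYMBOL (ENTREZID)"` are normalized to the bare
#' symbol (text before the first `" ("`).  A symbol collision after
#' normalization is an error, as is any non-numeric cell that is not a
#' declared missing marker.
#'
#' @param path CSV file; first column = sample identifier, remaining
#'   columns = genes.
#' @param kind matrix kind, see [omics_matrix()].
#' @param dialect see [omics_dialect()].
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, kind, dialect = omics_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = dialect$na_strings)
  if (ncol(raw) < 2) stop("matrix CSV needs >= 2 columns: ", path,
                          call. = FALSE)
  samples <- raw[[1]]
  genes <- normalize_gene_labels(colnames(raw)[-1])
  vals <- matrix(NA_real_, nrow(raw), length(genes),
                 dimnames = list(samples, genes))
  for (j in seq_along(genes)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   bad[1], genes[j], path), call. = FALSE)
    vals[, j] <- num
  }
  omics_matrix(vals, kind)
}

normalize_gene_labels <- function(labels) {
  out <- sub(" \\(.*$", "", labels)
  dup <- unique(out[duplicated(out)])
  if (length(dup))
    stop("duplicate gene symbol(s) after normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  out
}

#' Write an omics matrix in the CSV dialect `read_omics_matrix` reads
#'
#' @param x an [omics_matrix()]
#' @param path destination CSV
#' @param dialect see [omics_dialect()]
#' @return `path`, invisibly
#' @export
write_omics_matrix <- function(x, path, dialect = omics_dialect()) {
  df <- data.frame(sample = sample_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- dialect$sample_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Column mapping for MAF-like mutation call tables
#'
#' @param sample_col,gene_col mandatory identifier columns.
#' @param score_col column holding the variant-pathogenicity coding score in
#'   \[0,1\] (FATHMM-style); `NA` if the file has none.
#' @param damaging_col,hotspot_col columns flagging variants annotated as
#'   damaging / as TCGA hotspots; `NA` if absent.
#' @param truthy strings (case-sensitive) parsed as TRUE in flag columns.
#' @param na_strings missing markers for the score column.
#' @export
mutation_dialect <- function(sample_col = "DepMap_ID",
                             gene_col = "Hugo_Symbol",
                             score_col = "CScore",
                             damaging_col = "isDeleterious",
                             hotspot_col = "isTCGAhotspot",
                             truthy = c("TRUE", "True", "true", "1", "yes"),
                             na_strings = c("", "NA", "NaN")) {
  list(sample_col = sample_col, gene_col = gene_col, score_col = score_col,
       damaging_col = damaging_col, hotspot_col = hotspot_col,
       truthy = truthy, na_strings = na_strings)
}

#' Read a mutation call table
#'
#' One row per variant call; multiple calls per sample-gene are allowed and
#' are collapsed later by [build_binary_matrix()].  Evidence columns declared
#' absent in the dialect yield missing scores / FALSE flags.
#'
#' @param path CSV file.
#' @param dialect see [mutation_dialect()].
#' @return a `data.frame` with columns `sample_id`, `gene_id`,
#'   `coding_score`, `damaging_flag`, `hotspot_flag`.
#' @export
read_mutation_calls <- function(path, dialect = mutation_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = dialect$na_strings)
  need <- c(dialect$sample_col, dialect$gene_col)
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("mutation table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  get_flag <- function(colname) {
    if (is.na(colname) || !colname %in% colnames(raw))
      return(rep(FALSE, n))
    v <- raw[[colname]]
    !is.na(v) & v %in% dialect$truthy
  }
  score <- if (!is.na(dialect$score_col) &&
               dialect$score_col %in% colnames(raw)) {
    s <- suppressWarnings(as.numeric(raw[[dialect$score_col]]))
    if (any(!is.na(s) & (s < 0 | s > 1)))
      stop("coding scores outside [0,1] in ", path, call. = FALSE)
    s
  } else rep(NA_real_, n)
  data.frame(sample_id = raw[[dialect$sample_col]],
             gene_id = raw[[dialect$gene_col]],
             coding_score = score,
             damaging_flag = get_flag(dialect$damaging_col),
             hotspot_flag = get_flag(dialect$hotspot_col),
             stringsAsFactors = FALSE)
}
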