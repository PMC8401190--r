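#' Pathogenicity call rule
#'
#' A variant call is pathogenic when its coding score exceeds the threshold
#' (strictly), or it is annotated as damaging, or it is a TCGA hotspot.
#' Missing evidence never contributes.
#'
#' @param coding_score_threshold strict lower bound on the coding score
#'   (default 0.7).
#' @param use_damaging_flag,use_hotspot_flag whether the respective
#'   annotations count as evidence.
#' @export
pathogenicity_rule <- function(coding_score_threshold = 0.7,
                               use_damaging_flag = TRUE,
                               use_hotspot_flag = TRUE) {
  stopifnot(is.numeric(coding_score_threshold),
            coding_score_threshold >= 0, coding_score_threshold <= 1)
  list(coding_score_threshold = coding_score_threshold,
       use_damaging_flag = isTRUE(use_damaging_flag),
       use_hotspot_flag = isTRUE(use_hotspot_flag))
}

#' Label mutation calls as pathogenic
#'
#' @param calls a call table from [read_mutation_calls()] (or any data frame
#'   with `coding_score`, `damaging_flag`, `hotspot_flag`).
#' @param rule a [pathogenicity_rule()].
#' @return logical vector, one element per call.
#' @export
is_pathogenic <- function(calls, rule = pathogenicity_rule()) {
  score_hit <- !is.na(calls$coding_score) &
    calls$coding_score > rule$coding_score_threshold
  dam_hit <- rule$use_damaging_flag & calls$damaging_flag %in% TRUE
  hot_hit <- rule$use_hotspot_flag & calls$hotspot_flag %in% TRUE
  score_hit | dam_hit | hot_hit
}

#' Build the binary pathogenic-mutation matrix
#'
#' Cell (s, g) is 1 iff at least one pathogenic call exists for sample s and
#' gene g (OR over calls); everything else is 0.  Genes without pathogenic
#' calls are kept as all-zero columns; they are removed just before model
#' fitting by the minimum-mutated-samples filter.
#'
#' @param calls call table, see [read_mutation_calls()].
#' @param samples,genes row / column universe of the output matrix.
#' @param rule a [pathogenicity_rule()].
#' @return an [omics_matrix()] of kind `mutation_binary`.
#' @export
build_binary_matrix <- function(calls, samples, genes,
                                rule = pathogenicity_rule()) {
  stopifnot(length(samples) > 0, length(genes) > 0)
  vals <- matrix(0, length(samples), length(genes),
                 dimnames = list(samples, genes))
  if (nrow(calls)) {
    hit <- is_pathogenic(calls, rule)
    keep <- hit & calls$sample_id %in% samples & calls$gene_id %in% genes
    if (any(keep))
      vals[cbind(calls$sample_id[keep], calls$gene_id[keep])] <- 1
  }
  omics_matrix(vals, "mutation_binary")
}
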