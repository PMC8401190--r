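#' Synthetic-cohort configuration
#'
#' Defines a cohort with known (planted) synthetic-lethal structure.  The
#' defaults describe the reference validation world: 300 cell lines, 20
#' dependency targets, 20 binary mutation features at 15% mutation
#' frequency, 20 expression features (log2(TPM+1)-like), 5 planted
#' mutation pairs and 5 planted expression pairs at effect size 1.5 (in
#' units of the residual noise SD), a 5-feature collinear expression block
#' (r = 0.7) among the noise features, and 10% pan-essential genes with CV
#' below 0.3 by construction.
#'
#' @param n_samples cell lines.
#' @param n_targets dependency target genes (named T01, T02, ...).
#' @param n_mut_features,n_expr_features feature counts (MG.., EG..).
#' @param planted_pairs data.frame with `target`, `feature`,
#'   `feature_type`, `effect_size`; `NULL` builds the default plan:
#'   `n_planted_mut` mutation pairs on the first targets, then
#'   `n_planted_expr` expression pairs on the following targets.
#' @param n_planted_mut,n_planted_expr planted pair counts for the default
#'   plan.
#' @param effect_size planted effect, in multiples of `noise_sd`.
#' @param mutation_frequency Bernoulli rate of mutation columns.
#' @param noise_sd residual SD of the dependency response (CERES-like 0.25).
#' @param baseline_mean mean dependency of non-essential targets.
#' @param collinear_block `c(size, correlation)` of the correlated
#'   expression-noise block.
#' @param essential_fraction,essential_mean,essential_sd pan-essential
#'   genes appended to the dependency matrix (ESS..); defaults give CV 0.05.
#' @param seed mandatory RNG seed.
#' @export
sim_config <- function(n_samples = 300L, n_targets = 20L,
                       n_mut_features = 20L, n_expr_features = 20L,
                       planted_pairs = NULL,
                       n_planted_mut = 5L, n_planted_expr = 5L,
                       effect_size = 1.5, mutation_frequency = 0.15,
                       noise_sd = 0.25, baseline_mean = -0.2,
                       collinear_block = c(size = 5, correlation = 0.7),
                       essential_fraction = 0.1, essential_mean = -1,
                       essential_sd = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(mutation_frequency > 0, mutation_frequency < 1,
            essential_fraction >= 0, essential_fraction < 1,
            noise_sd > 0, is.finite(effect_size))
  if (is.null(planted_pairs)) {
    stopifnot(n_planted_mut <= n_mut_features,
              n_planted_expr <= n_expr_features,
              n_planted_mut + n_planted_expr <= n_targets)
    planted_pairs <- rbind(
      if (n_planted_mut > 0)
        data.frame(target = sprintf("T%02d", seq_len(n_planted_mut)),
                   feature = sprintf("MG%02d", seq_len(n_planted_mut)),
                   feature_type = "mutation", effect_size = effect_size,
                   stringsAsFactors = FALSE),
      if (n_planted_expr > 0)
        data.frame(target = sprintf("T%02d",
                                    n_planted_mut + seq_len(n_planted_expr)),
                   feature = sprintf("EG%02d", seq_len(n_planted_expr)),
                   feature_type = "expression", effect_size = effect_size,
                   stringsAsFactors = FALSE))
  }
  list(n_samples = as.integer(n_samples), n_targets = as.integer(n_targets),
       n_mut_features = as.integer(n_mut_features),
       n_expr_features = as.integer(n_expr_features),
       planted_pairs = planted_pairs,
       mutation_frequency = mutation_frequency, noise_sd = noise_sd,
       baseline_mean = baseline_mean, collinear_block = collinear_block,
       essential_fraction = essential_fraction,
       essential_mean = essential_mean, essential_sd = essential_sd,
       seed = as.integer(seed))
}

#' Generate a synthetic cohort with planted SL structure
#'
#' Mutation columns are Bernoulli(frequency); expression columns are
#' Gaussian with gene-specific mean in \[1, 8\] and SD in \[0.5, 1.5\]
#' (log2(TPM+1)-like), with the configured collinear block sharing a latent
#' factor.  Each target's dependency is
#' `baseline + sum(beta * mut) - sum(gamma * z(expr)) + N(0, noise_sd)`,
#' with `beta`/`gamma` the planted effect sizes times `noise_sd` -- so
#' mutation of a planted partner raises the dependency score and low
#' expression of a planted partner raises it too.  Pan-essential genes get
#' uniformly strong dependency with low CV.  A mutation-call table
#' consistent with the binary matrix (pathogenic calls for every 1, plus
#' scattered benign calls) is included so the pathogenicity filter can be
#' exercised end-to-end.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sl_simulation`: `dependency`, `expression`,
#'   `mutation` ([omics_matrix()]s), `calls` (call table), `truth`
#'   (planted-pair data.frame), `config`.
#' @export
simulate_cohort <- function(cfg) {
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    samples <- sprintf("SIM-%04d", seq_len(n))
    targets <- sprintf("T%02d", seq_len(cfg$n_targets))
    mut_genes <- sprintf("MG%02d", seq_len(cfg$n_mut_features))
    expr_genes <- sprintf("EG%02d", seq_len(cfg$n_expr_features))
    truth <- cfg$planted_pairs
    stopifnot(all(truth$target %in% targets),
              all(truth$feature[truth$feature_type == "mutation"] %in%
                    mut_genes),
              all(truth$feature[truth$feature_type == "expression"] %in%
                    expr_genes))

    ## mutation matrix
    M <- matrix(as.numeric(stats::rbinom(n * cfg$n_mut_features, 1,
                                         cfg$mutation_frequency)),
                n, cfg$n_mut_features,
                dimnames = list(samples, mut_genes))
    for (g in truth$feature[truth$feature_type == "mutation"]) {
      if (sum(M[, g]) %in% c(0, n))
        M[, g] <- stats::rbinom(n, 1, cfg$mutation_frequency)
      if (sum(M[, g]) %in% c(0, n))
        stop("degenerate planted mutation column after resampling: ", g,
             call. = FALSE)
    }

    ## expression matrix with a collinear noise block
    mu <- stats::runif(cfg$n_expr_features, 1, 8)
    sdg <- stats::runif(cfg$n_expr_features, 0.5, 1.5)
    E <- sapply(seq_len(cfg$n_expr_features), function(j)
      stats::rnorm(n, mu[j], sdg[j]))
    dimnames(E) <- list(samples, expr_genes)
    blk_size <- min(as.integer(cfg$collinear_block[[1]]),
                    cfg$n_expr_features)
    rho <- cfg$collinear_block[[2]]
    if (blk_size >= 2) {
      # use the last columns so the block never overlaps planted features
      blk <- utils::tail(seq_len(cfg$n_expr_features), blk_size)
      latent <- stats::rnorm(n)
      for (j in blk)
        E[, j] <- mu[j] + sdg[j] * (sqrt(rho) * latent +
                                      sqrt(1 - rho) * stats::rnorm(n))
    }

    ## dependency responses
    D <- matrix(NA_real_, n, cfg$n_targets,
                dimnames = list(samples, targets))
    for (t in targets) {
      y <- cfg$baseline_mean + stats::rnorm(n, 0, cfg$noise_sd)
      tp <- truth[truth$target == t, , drop = FALSE]
      for (i in seq_len(nrow(tp))) {
        eff <- tp$effect_size[i] * cfg$noise_sd
        if (tp$feature_type[i] == "mutation") {
          y <- y + eff * M[, tp$feature[i]]
        } else {
          z <- as.numeric(scale(E[, tp$feature[i]]))
          y <- y - eff * z
        }
      }
      D[, t] <- y
    }
    n_ess <- round(cfg$essential_fraction * cfg$n_targets)
    if (n_ess > 0) {
      ess_genes <- sprintf("ESS%02d", seq_len(n_ess))
      Dess <- sapply(ess_genes, function(g)
        stats::rnorm(n, cfg$essential_mean, cfg$essential_sd))
      dimnames(Dess) <- list(samples, ess_genes)
      D <- cbind(D, Dess)
    }

    ## mutation-call table consistent with M
    ones <- which(M == 1, arr.ind = TRUE)
    calls <- data.frame(
      sample_id = samples[ones[, 1]], gene_id = mut_genes[ones[, 2]],
      coding_score = stats::runif(nrow(ones), 0.75, 0.995),
      damaging_flag = stats::runif(nrow(ones)) < 0.3,
      hotspot_flag = stats::runif(nrow(ones)) < 0.1,
      stringsAsFactors = FALSE)
    n_benign <- ceiling(0.02 * n * cfg$n_mut_features)
    bs <- sample.int(n, n_benign, replace = TRUE)
    bg <- sample.int(cfg$n_mut_features, n_benign, replace = TRUE)
    benign <- data.frame(
      sample_id = samples[bs], gene_id = mut_genes[bg],
      coding_score = stats::runif(n_benign, 0, 0.65),
      damaging_flag = FALSE, hotspot_flag = FALSE,
      stringsAsFactors = FALSE)
    calls <- rbind(calls, benign)
    calls <- calls[order(calls$sample_id, calls$gene_id), , drop = FALSE]
    rownames(calls) <- NULL

    structure(list(dependency = omics_matrix(D, "dependency"),
                   expression = omics_matrix(E, "expression"),
                   mutation = omics_matrix(M, "mutation_binary"),
                   calls = calls,
                   truth = truth,
                   config = cfg),
              class = "sl_simulation")
  })
}

#' @export
print.sl_simulation <- function(x, ...) {
  cat(sprintf(
    "<sl_simulation: %d lines, %d dependency genes, %d mut + %d expr features, %d planted pairs, seed %d>\n",
    x$config$n_samples, ncol(x$dependency$values),
    x$config$n_mut_features, x$config$n_expr_features, nrow(x$truth),
    x$config$seed))
  invisible(x)
}

#' Write a simulated cohort as the CSV fixtures the readers consume
#'
#' @param sim an `sl_simulation`.
#' @param dir destination directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(dependency = file.path(dir, "dependency.csv"),
             expression = file.path(dir, "expression.csv"),
             calls = file.path(dir, "mutation_calls.csv"),
             truth = file.path(dir, "truth.csv"))
  write_omics_matrix(sim$dependency, paths["dependency"])
  write_omics_matrix(sim$expression, paths["expression"])
  calls <- sim$calls
  colnames(calls) <- c("DepMap_ID", "Hugo_Symbol", "CScore",
                       "isDeleterious", "isTCGAhotspot")
  utils::write.csv(calls, paths["calls"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Score recovery of planted pairs
#'
#' Pairs with scaled importance strictly above the threshold are the
#' predictions; precision and recall are computed against the planted
#' truth, matching on (target, feature, feature_type).
#'
#' @param pairs scaled pair table.
#' @param truth planted-pair data.frame (`target`, `feature`,
#'   `feature_type`).
#' @param threshold scalar, or named per-feature-type vector
#'   (`c(mutation =, expression =)`), or a [group_thresholds()] data.frame.
#' @return list with `precision` (`NA` when nothing is predicted),
#'   `recall`, `n_predicted`, and `hits` (truth table with a `recovered`
#'   flag).
#' @export
evaluate_recovery <- function(pairs, truth, threshold) {
  if (is.data.frame(threshold)) {
    m <- merge(pairs, threshold[, c("method", "feature_type", "threshold")],
               by = c("method", "feature_type"), all.x = TRUE)
    m$threshold[is.na(m$threshold)] <- Inf
    pred <- m[m$scaled_importance > m$threshold, , drop = FALSE]
  } else {
    th <- if (length(threshold) == 1 && is.null(names(threshold)))
      stats::setNames(rep(threshold, 2), c("mutation", "expression"))
    else threshold
    pred <- pairs[pairs$scaled_importance >
                    th[pairs$feature_type], , drop = FALSE]
  }
  key <- function(t, f, ft) paste(t, f, ft, sep = "\r")
  pred_keys <- unique(key(pred$target_gene, pred$feature_gene,
                          pred$feature_type))
  truth_keys <- key(truth$target, truth$feature, truth$feature_type)
  hits <- truth
  hits$recovered <- truth_keys %in% pred_keys
  tp <- sum(pred_keys %in% truth_keys)
  list(precision = if (length(pred_keys)) tp / length(pred_keys)
                   else NA_real_,
       recall = if (nrow(truth)) sum(hits$recovered) / nrow(truth) else 0,
       n_predicted = length(pred_keys),
       hits = hits)
}
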