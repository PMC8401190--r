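# Shared in-code fixtures.  Everything is generated at test time; no binary
# data ships with the package.

tiny_matrix <- function(kind = "dependency", n = 4, genes = c("A", "B", "C"),
                        seed = 1) {
  set.seed(seed)
  vals <- matrix(round(rnorm(n * length(genes)), 3), n, length(genes),
                 dimnames = list(sprintf("L%d", seq_len(n)), genes))
  if (kind == "mutation_binary") vals[] <- rbinom(length(vals), 1, 0.4)
  omics_matrix(vals, kind)
}

# small planted regression problem: y driven by the first column
planted_xy <- function(n = 150, p = 6, effect = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  list(X = X, y = effect * X[, 1] + rnorm(n))
}

# small full cohort for pipeline-level tests (scaled down from the
# reference world to keep the unit tier fast)
small_sim <- function(seed = 7, n = 150, effect = 2.5) {
  sim_config(n_samples = n, n_targets = 6, n_mut_features = 8,
             n_expr_features = 8, n_planted_mut = 2, n_planted_expr = 2,
             effect_size = effect, seed = seed)
}

fast_bcfg <- function(...) boruta_config(max_iter = 50, ...)
fast_fcfg <- function(seed = 1) forest_config(n_trees = 48, seed = seed)
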