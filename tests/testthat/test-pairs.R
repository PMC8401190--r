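test_that("pearson correlation: hand-computed cases", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  # pairwise-complete on missing values
  expect_equal(pearson_cor(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1.0)
})

test_that("self pairs are removed, order preserved", {
  p <- data.frame(target_gene = c("A", "A", "B"),
                  feature_gene = c("A", "B", "B"))
  out <- drop_self_pairs(p)
  expect_equal(out$feature_gene, "B")
  expect_equal(out$target_gene, "A")
  expect_equal(nrow(drop_self_pairs(p[2, ])), 1)   # identity
  expect_equal(nrow(drop_self_pairs(p[c(1, 3), ])), 0)  # all self
})

test_that("direction filter keeps mut+/expr- and can be bypassed", {
  p <- data.frame(target_gene = "T", feature_gene = letters[1:4],
                  feature_type = c("mutation", "mutation", "expression",
                                   "expression"),
                  pcc = c(0.3, -0.3, -0.4, 0.4))
  out <- apply_direction_filter(p)
  expect_equal(out$feature_gene, c("a", "c"))
  expect_identical(apply_direction_filter(p, enabled = FALSE), p)
  # NA correlations are dropped when the filter is active
  p$pcc[1] <- NA
  expect_equal(apply_direction_filter(p)$feature_gene, "c")
})

test_that("group scaling is min-max within (method, feature_type)", {
  p <- data.frame(target_gene = "T", feature_gene = paste0("g", 1:5),
                  feature_type = c(rep("mutation", 3), "expression",
                                   "mutation"),
                  method = c(rep("gini", 3), "gini", "permutation_raw"),
                  importance = c(2, 5, 10, 7, 3))
  out <- scale_by_group(p)
  expect_equal(out$scaled_importance[1:3], c(0, 0.375, 1))  # [2,5,10]
  expect_equal(out$scaled_importance[4], 1)                  # singleton
  expect_equal(out$scaled_importance[5], 1)                  # singleton
  # all-equal group maps to 1
  q <- scale_by_group(data.frame(target_gene = "T",
                                 feature_gene = c("a", "b"),
                                 feature_type = "mutation",
                                 method = "gini", importance = c(3, 3)))
  expect_equal(q$scaled_importance, c(1, 1))
  # rank order preserved within groups
  expect_equal(order(out$scaled_importance[1:3]),
               order(p$importance[1:3]))
})

test_that("essentiality filter flags low-CV genes, hand-checked", {
  v <- cbind(ess = c(-1.0, -0.9, -1.1),          # cv = 0.1
             ok = c(0.1, 0.9, 0.5))              # cv = 0.8
  rownames(v) <- paste0("L", 1:3)
  dep <- omics_matrix(v, "dependency")
  out <- essentiality_filter(dep)
  st <- out$stats
  expect_equal(st$cv[st$gene == "ess"], 0.1)
  expect_equal(st$cv[st$gene == "ok"], 0.8)
  expect_equal(out$eligible, "ok")
  expect_equal(st$range[st$gene == "ok"], 0.8)
  expect_equal(st$median_dependency[st$gene == "ess"], -1.0)
  # threshold 0 filters nothing
  expect_setequal(essentiality_filter(dep, 0)$eligible, c("ess", "ok"))
  # zero-mean column: undefined cv, non-essential with warning
  v0 <- cbind(zero = c(-1, 0, 1), ok = c(0.1, 0.9, 0.5))
  rownames(v0) <- paste0("L", 1:3)
  expect_warning(z <- essentiality_filter(omics_matrix(v0, "dependency")),
                 "zero-mean")
  expect_true("zero" %in% z$eligible)
})

test_that("run_target keeps the self column before filtering", {
  set.seed(21)
  n <- 120
  # dependency target T1 doubles as an expression feature
  dep_v <- matrix(rnorm(2 * n), n, 2,
                  dimnames = list(sprintf("L%03d", 1:n), c("T1", "T2")))
  feat_v <- cbind(T1 = dep_v[, "T1"], F1 = rnorm(n), F2 = rnorm(n))
  rownames(feat_v) <- rownames(dep_v)
  dep <- omics_matrix(dep_v, "dependency")
  feat <- omics_matrix(feat_v, "expression")
  pairs <- run_target("T1", dep, feat, "expression", "permutation_raw",
                      fast_bcfg(), fast_fcfg())
  expect_true("T1" %in% pairs$feature_gene)          # self-pair pre-filter
  expect_false("T1" %in% drop_self_pairs(pairs)$feature_gene)
})

test_that("cohort bookkeeping: empty targets, multiple methods, seeds", {
  sim <- simulate_cohort(small_sim(seed = 31))
  # empty target list -> empty but well-formed table
  out0 <- run_cohort(character(0), sim$dependency, sim$mutation,
                     sim$expression, bcfg = fast_bcfg(),
                     fcfg = fast_fcfg(), master_seed = 1)
  expect_equal(nrow(out0$pairs), 0)
  expect_true(all(c("target_gene", "scaled_importance") %in%
                    colnames(out0$pairs)))

  # two methods produce independently scaled groups; determinism
  tg <- sim$truth$target[1:2]
  a <- run_cohort(tg, sim$dependency, sim$mutation, sim$expression,
                  methods = c("gini", "permutation_raw"),
                  bcfg = fast_bcfg(), fcfg = fast_fcfg(), master_seed = 5)
  b <- run_cohort(tg, sim$dependency, sim$mutation, sim$expression,
                  methods = c("gini", "permutation_raw"),
                  bcfg = fast_bcfg(), fcfg = fast_fcfg(), master_seed = 5)
  expect_identical(a$pairs, b$pairs)
  expect_setequal(unique(a$pairs$method), c("gini", "permutation_raw"))
  for (m in unique(a$pairs$method)) {
    for (ft in unique(a$pairs$feature_type[a$pairs$method == m])) {
      grp <- a$pairs$scaled_importance[a$pairs$method == m &
                                         a$pairs$feature_type == ft]
      expect_equal(max(grp), 1)
    }
  }
  # direction filter invariant on everything emitted
  expect_true(all(a$pairs$pcc[a$pairs$feature_type == "mutation"] > 0))
  expect_true(all(a$pairs$pcc[a$pairs$feature_type == "expression"] < 0))
})

test_that("target order does not change cohort results", {
  sim <- simulate_cohort(small_sim(seed = 33))
  tg <- sim$truth$target[1:2]
  a <- run_cohort(tg, sim$dependency, sim$mutation, NULL,
                  bcfg = fast_bcfg(), fcfg = fast_fcfg(), master_seed = 9)
  b <- run_cohort(rev(tg), sim$dependency, sim$mutation, NULL,
                  bcfg = fast_bcfg(), fcfg = fast_fcfg(), master_seed = 9)
  ka <- with(a$pairs, paste(target_gene, feature_gene, method))
  kb <- with(b$pairs, paste(target_gene, feature_gene, method))
  expect_setequal(ka, kb)
  expect_equal(a$pairs$importance[order(ka)], b$pairs$importance[order(kb)])
})
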