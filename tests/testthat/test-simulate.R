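test_that("simulation is bit-reproducible from its seed", {
  a <- simulate_cohort(small_sim(seed = 5))
  b <- simulate_cohort(small_sim(seed = 5))
  expect_identical(a$dependency$values, b$dependency$values)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$mutation$values, b$mutation$values)
  expect_identical(a$calls, b$calls)
  c <- simulate_cohort(small_sim(seed = 6))
  expect_false(identical(a$dependency$values, c$dependency$values))
})

test_that("matrices are sample-aligned and truth references real genes", {
  sim <- simulate_cohort(small_sim(seed = 8))
  expect_identical(sample_ids(sim$dependency), sample_ids(sim$expression))
  expect_identical(sample_ids(sim$dependency), sample_ids(sim$mutation))
  expect_true(all(sim$truth$target %in% gene_ids(sim$dependency)))
  mt <- sim$truth[sim$truth$feature_type == "mutation", ]
  expect_true(all(mt$feature %in% gene_ids(sim$mutation)))
  # mutation columns are plausible Bernoulli(f) draws
  f <- colMeans(sim$mutation$values)
  expect_true(all(f > 0.02 & f < 0.4))
})

test_that("planted mutation pairs correlate positively with dependency", {
  # reduced Monte-Carlo: 25 seeds at effect 2, every one positive
  signs <- vapply(1:25, function(s) {
    sim <- simulate_cohort(small_sim(seed = s, effect = 2))
    mt <- sim$truth[sim$truth$feature_type == "mutation", ][1, ]
    cor(sim$mutation$values[, mt$feature],
        sim$dependency$values[, mt$target])
  }, numeric(1))
  expect_true(all(signs > 0))
  # and expression pairs negatively
  nsig <- vapply(1:25, function(s) {
    sim <- simulate_cohort(small_sim(seed = s, effect = 2))
    et <- sim$truth[sim$truth$feature_type == "expression", ][1, ]
    cor(sim$expression$values[, et$feature],
        sim$dependency$values[, et$target])
  }, numeric(1))
  expect_true(all(nsig < 0))
})

test_that("constructed essential genes are all flagged essential", {
  sim <- simulate_cohort(sim_config(n_samples = 120, seed = 9))
  ess <- grep("^ESS", gene_ids(sim$dependency), value = TRUE)
  expect_gt(length(ess), 0)
  st <- essentiality_filter(sim$dependency)$stats
  expect_true(all(st$is_essential[st$gene %in% ess]))
  # and the planted targets are not essential
  expect_true(all(!st$is_essential[st$gene %in% sim$truth$target]))
})

test_that("the collinear expression block has the configured correlation", {
  sim <- simulate_cohort(sim_config(n_samples = 400, seed = 10))
  blk <- utils::tail(gene_ids(sim$expression), 5)
  cm <- cor(sim$expression$values[, blk])
  off <- cm[upper.tri(cm)]
  expect_gt(mean(off), 0.55)
  expect_lt(mean(off), 0.85)
})

test_that("zero effect sizes carry no recoverable signal", {
  sim <- simulate_cohort(small_sim(seed = 11, effect = 0))
  mt <- sim$truth[sim$truth$feature_type == "mutation", ][1, ]
  r <- cor(sim$mutation$values[, mt$feature],
           sim$dependency$values[, mt$target])
  expect_lt(abs(r), 0.25)
})

test_that("recovery scoring counts hits exactly", {
  truth <- data.frame(target = paste0("T", 1:5),
                      feature = paste0("F", 1:5),
                      feature_type = "mutation")
  pairs <- data.frame(target_gene = paste0("T", 1:6),
                      feature_gene = paste0("F", 1:6),
                      feature_type = "mutation",
                      method = "permutation_raw",
                      scaled_importance = c(rep(0.9, 6)))
  ev <- evaluate_recovery(pairs, truth, 0.5)
  expect_equal(ev$precision, 5 / 6)
  expect_equal(ev$recall, 1.0)
  # identical sets
  ev2 <- evaluate_recovery(pairs[1:5, ], truth, 0.5)
  expect_equal(ev2$precision, 1.0)
  expect_equal(ev2$recall, 1.0)
  # threshold above 1 predicts nothing
  ev3 <- evaluate_recovery(pairs, truth, 1.1)
  expect_true(is.na(ev3$precision))
  expect_equal(ev3$recall, 0)
  expect_equal(ev3$n_predicted, 0)
})

test_that("recall is non-decreasing in effect size (reduced design)", {
  # reduced from the 3-effect x 10-seed reference sweep: one small cohort
  # per effect in {0, 2.5}, fixed threshold
  recalls <- vapply(c(0, 2.5), function(eff) {
    sim <- simulate_cohort(small_sim(seed = 17, effect = eff))
    out <- run_cohort(sim$truth$target, sim$dependency, sim$mutation,
                      sim$expression, bcfg = fast_bcfg(),
                      fcfg = fast_fcfg(), master_seed = 17)
    evaluate_recovery(out$pairs, sim$truth, 0.05)$recall
  }, numeric(1))
  expect_lte(recalls[1], recalls[2])
  expect_lt(recalls[1], 0.5)   # null world: essentially nothing recovered
  expect_gt(recalls[2], 0.5)   # strong world: most pairs recovered
})

test_that("cohort fixtures round-trip through the readers", {
  sim <- simulate_cohort(small_sim(seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_sim_cohort(sim, dir)
  dep <- read_omics_matrix(paths[["dependency"]], "dependency")
  expect_equal(dep$values, sim$dependency$values)
  calls <- read_mutation_calls(paths[["calls"]])
  m <- build_binary_matrix(calls, sample_ids(dep),
                           gene_ids(sim$mutation))
  expect_identical(m$values, sim$mutation$values)
})
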