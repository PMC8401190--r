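example_pairs <- function() {
  data.frame(target_gene = c("T1", "T1", "T2"),
             feature_gene = c("A", "B", "A"),
             feature_type = c("mutation", "expression", "mutation"),
             method = "permutation_raw",
             pcc = c(0.5, -0.7, 0.2),
             scaled_importance = c(1, 0.8, 0.3),
             tier = c(2L, 1L, 0L),
             stringsAsFactors = FALSE)
}

example_stats <- function(genes = c("T1", "T2", "A")) {
  data.frame(gene = genes,
             median_dependency = seq(-0.9, by = 0.2,
                                     length.out = length(genes)),
             cv = 0.5, sd = 0.2, range = 1,
             is_essential = FALSE, stringsAsFactors = FALSE)
}

test_that("network assembly: direction, attributes, missing stats", {
  net <- build_network(example_pairs(), example_stats())
  expect_s3_class(net, "sl_network")
  expect_equal(nrow(net$edges), 3)
  # 2 pairs share target T1 -> both arrive at T1
  expect_equal(sum(net$edges$target == "T1"), 2)
  expect_setequal(net$nodes$gene, c("T1", "T2", "A", "B"))
  expect_equal(net$edges$width_weight, abs(net$edges$pcc))
  # feature-only gene B has no stats -> NA cells, row kept
  expect_true(is.na(net$nodes$median_dependency[net$nodes$gene == "B"]))

  empty <- build_network(example_pairs()[0, ], example_stats())
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)

  expect_error(build_network(rbind(example_pairs(), example_pairs()[1, ]),
                             example_stats()), "duplicate")
  self <- example_pairs(); self$feature_gene[1] <- "T1"
  expect_error(build_network(self, example_stats()), "self-loop")
})

test_that("network filtering honours cohort thresholds and drops orphans", {
  net <- build_network(example_pairs(), example_stats())
  f <- filter_network(net, c(mutation = 0.5, expression = 0.4))
  expect_setequal(paste(f$edges$source, f$edges$target),
                  c("A T1", "B T1"))          # A->T2 at 0.3 < 0.5 dropped
  expect_false("T2" %in% f$nodes$gene)        # orphan removed
  mut_only <- filter_network(net, feature_types = "mutation")
  expect_true(all(mut_only$edges$feature_type == "mutation"))
  ident <- filter_network(net)
  expect_equal(nrow(ident$edges), 3)
  # monotone: tightening never adds edges
  n_prev <- Inf
  for (th in c(0, 0.4, 0.9, 1.1)) {
    n_cur <- nrow(filter_network(net, c(mutation = th,
                                        expression = th))$edges)
    expect_lte(n_cur, n_prev)
    n_prev <- n_cur
  }
})

test_that("export/import round trip preserves the network", {
  dir <- withr::local_tempdir()
  net <- build_network(example_pairs(), example_stats())
  prefix <- file.path(dir, "net")
  paths <- export_network(net, prefix)
  expect_true(all(file.exists(paths)))
  back <- import_network(prefix)
  ord <- function(e) e[order(e$source, e$target, e$feature_type), ,
                       drop = FALSE]
  for (col in c("source", "target", "feature_type", "method")) {
    expect_equal(ord(back$edges)[[col]], ord(net$edges)[[col]])
  }
  expect_equal(ord(back$edges)$scaled_importance,
               ord(net$edges)$scaled_importance)
  expect_setequal(back$nodes$gene, net$nodes$gene)
  # graphml is readable and isomorphic
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))

  # empty network -> header-only CSVs
  e0 <- export_network(build_network(example_pairs()[0, ],
                                     example_stats()),
                       file.path(dir, "empty"))
  expect_equal(nrow(utils::read.csv(e0[["edges"]])), 0)
})

test_that("method concordance matches by pair key and is symmetric", {
  a <- data.frame(target_gene = c("T1", "T1", "T2", "T3"),
                  feature_gene = c("A", "B", "C", "D"),
                  feature_type = "expression",
                  scaled_importance = c(1, 3, 2, 4) / 4)
  b <- a
  b$scaled_importance <- c(1, 2, 3, 4) / 4
  out <- method_concordance(a, b)
  expect_equal(out$n_common, 4)
  expect_equal(out$r, 0.8)   # same hand computation as the pearson case
  expect_equal(method_concordance(b, a)$r, 0.8)
  expect_equal(method_concordance(a, a)$r, 1.0)
  disj <- a
  disj$target_gene <- paste0("X", 1:4)
  out2 <- method_concordance(a, disj)
  expect_equal(out2$n_common, 0)
  expect_true(is.na(out2$r))
})

test_that("interaction enrichment joins on unordered gene pairs", {
  pairs <- data.frame(target_gene = c("T1", "T1", "T2", "T2"),
                      feature_gene = c("A", "B", "A", "C"),
                      confidence = c("high", "high", "high", "high"))
  # table rows deliberately in swapped order for two pairs
  tab <- data.frame(gene_a = c("T1", "A"), gene_b = c("A", "T2"),
                    combined_score = c(900, 400))
  out <- interaction_enrichment(pairs, tab)
  expect_equal(out$n_pairs, 4)
  expect_equal(out$n_scored, 2)
  expect_equal(out$fraction, 0.5)
  expect_equal(out$median, 650)
  # empty score table -> all fractions zero
  none <- interaction_enrichment(pairs, tab[0, ])
  expect_equal(none$fraction, 0)
  expect_true(is.na(none$median))
  # groups are summarized independently
  pairs$confidence <- c("high", "low", "low", "high")
  two <- interaction_enrichment(pairs, tab)
  expect_equal(sort(two$fraction), c(0.5, 0.5))
})
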