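test_that("confusion counts cover all ordered pairs", {
  gold <- edge_set(data.frame(regulator = "G1", target = "G2", label = 1L),
                   universe = sprintf("G%d", 1:3))
  perfect <- grn_network(data.frame(regulator = "G1", target = "G2",
                                    weight = 1), universe = gold$universe)
  r <- score_network(perfect, gold)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(1, 0, 5, 0))
  expect_equal(r$accuracy, 1)
  expect_equal(r$tp + r$fp + r$tn + r$fn, 3 * 2)

  # direction error costs one fp and one fn
  flipped <- grn_network(data.frame(regulator = "G2", target = "G1",
                                    weight = 1), universe = gold$universe)
  r <- score_network(flipped, gold)
  expect_equal(c(r$tp, r$fp, r$fn, r$tn), c(0, 1, 1, 4))
  expect_equal(r$accuracy, 4 / 6)
  expect_equal(r$accuracy_unordered, 1)   # unordered variant forgives it

  # empty vs empty is all true negatives
  r <- score_network(grn_network(universe = c("A", "B")),
                     edge_set(universe = c("A", "B")))
  expect_equal(r$accuracy, 1)
  expect_equal(r$tn, 2)
})

test_that("scoring is invariant to gene relabeling and edge order", {
  set.seed(41)
  ids <- sprintf("G%d", 1:8)
  gold_df <- data.frame(regulator = c("G1", "G3", "G5"),
                        target = c("G2", "G4", "G6"), label = 1L)
  pred_df <- data.frame(regulator = c("G1", "G4", "G7"),
                        target = c("G2", "G3", "G8"), weight = 1)
  r1 <- score_network(grn_network(pred_df, ids), edge_set(gold_df, ids))
  # permute labels consistently
  relabel <- setNames(sprintf("H%d", sample(8)), ids)
  gold2 <- gold_df; pred2 <- pred_df
  gold2$regulator <- relabel[gold2$regulator]; gold2$target <- relabel[gold2$target]
  pred2$regulator <- relabel[pred2$regulator]; pred2$target <- relabel[pred2$target]
  r2 <- score_network(grn_network(pred2, unname(relabel)),
                      edge_set(gold2, unname(relabel)))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$tp, r2$tp)
  # shuffled edge rows score identically
  r3 <- score_network(grn_network(pred_df[c(3, 1, 2), ], ids),
                      edge_set(gold_df[c(2, 3, 1), ], ids))
  expect_equal(r3$accuracy, r1$accuracy)
})

test_that("a network scored against itself as gold is perfect", {
  cfg <- sim_config(m = 12, edge_density = 0.1, n_series = 3,
                    n_timepoints = 10, seed = 55)
  gold <- sample_network(cfg)
  as_net <- grn_network(data.frame(
    regulator = gold$edges$regulator, target = gold$edges$target,
    weight = 1), universe = gold$universe)
  expect_equal(score_network(as_net, gold)$accuracy, 1)
})

test_that("average accuracy is the unweighted mean", {
  expect_equal(average_accuracy(rep(0.9, 5)), 0.9)
  expect_equal(average_accuracy(c(1.0, 0.8)), 0.9)
  reports <- list(structure(list(accuracy = 0.95), class = "tdm_eval"),
                  structure(list(accuracy = 0.85), class = "tdm_eval"))
  expect_equal(average_accuracy(reports), 0.9)
  expect_error(average_accuracy(list()), class = "tdminfer_validation_error")
})

test_that("the separation test matches the textbook t statistic", {
  a <- c(4.1, 3.9, 4.5, 4.0, 3.8)
  b <- c(3.1, 3.3, 2.9, 3.6)
  res <- separation_test(a, b)
  expect_equal(res$statistic, oracle_t_statistic(a, b), tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(abs(res$statistic), length(a) + length(b) - 2,
                      lower.tail = FALSE),
               tolerance = 1e-12)

  res <- separation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(42)
  res <- separation_test(rnorm(4, 0, 0.01), 10 + rnorm(4, 0, 0.01))
  expect_lt(res$p_value, 0.05)

  # degenerate constant groups
  expect_equal(separation_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(separation_test(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("the signed-rank test matches exact enumeration", {
  d <- c(1.5, -0.3, 2.2, 0.7, -1.1, 0.4, 3.0, -0.9)
  expect_equal(paired_rank_test(d), oracle_signed_rank_p(d),
               tolerance = 1e-12)
  d2 <- c(0.2, 0.5, -0.1, 1.4, 0.9, -2.3, 0.35)
  expect_equal(paired_rank_test(d2), oracle_signed_rank_p(d2),
               tolerance = 1e-12)

  expect_lt(paired_rank_test(1:10 + 0.5), 0.05)     # all positive, large
  expect_equal(paired_rank_test(rep(0, 6)), 1)
  d_sym <- c(1.1, -1.2, 0.6, -0.5, 2.0, -1.9)
  expect_gt(paired_rank_test(d_sym), 0.5)
})

test_that("threshold separations are computable from a dataset", {
  cfg <- sim_config(m = 14, edge_density = 0.2, seed = 3)
  d <- simulate_timeseries(sample_network(cfg), cfg)
  es <- expression_separation(d, tau = 1.2)
  expect_true(es$n_induced > 0 && es$n_repressed > 0)
  expect_true(es$p_value >= 0 && es$p_value <= 1)
  isep <- influence_separation(influence_table(d), epsilon = 0.5)
  expect_true(isep$n_present > 0 && isep$n_absent > 0)
})

test_that("benchmarking over file pairs reports per-dataset and mean accuracy", {
  dir <- withr::local_tempdir()
  expr_paths <- gold_paths <- character(2)
  for (i in 1:2) {
    cfg <- sim_config(m = 8, edge_density = 0.15, n_series = 3,
                      n_timepoints = 12, seed = 60 + i)
    gold <- sample_network(cfg)
    d <- simulate_timeseries(gold, cfg)
    expr_paths[i] <- file.path(dir, sprintf("expr%d.tsv", i))
    gold_paths[i] <- file.path(dir, sprintf("gold%d.tsv", i))
    write_timeseries(d, expr_paths[i])
    write_gold_standard(gold, gold_paths[i])
  }
  bench <- run_benchmark(expr_paths, gold_paths, epsilon = 0.5)
  expect_length(bench$accuracies, 2)
  expect_equal(bench$mean_accuracy, mean(bench$accuracies))
  expect_equal(bench$params$epsilon, 0.5)
})
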