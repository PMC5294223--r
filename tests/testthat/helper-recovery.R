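# Recovery benchmark shared by several tests: 10 seeded 20-gene
# simulations at the default study conditions, inferred with default
# parameters.  Computed once per test run and memoised.

recovery_cache <- new.env(parent = emptyenv())

recovery_results <- function() {
  if (!is.null(recovery_cache$res)) return(recovery_cache$res)
  res <- lapply(1:10, function(seed) {
    cfg <- sim_config(m = 20, edge_density = 0.05, n_series = 10,
                      n_timepoints = 21, noise_sd = 0.1, seed = seed)
    gold <- sample_network(cfg)
    dataset <- simulate_timeseries(gold, cfg)
    run <- infer_network(dataset, algorithm = "M2")
    report <- score_network(run$network, gold)
    influences <- influence_table(dataset)
    ik <- paste(influences$source, influences$target, sep = ">")
    true_fwd <- paste(gold$edges$regulator, gold$edges$target, sep = ">")
    true_rev <- paste(gold$edges$target, gold$edges$regulator, sep = ">")
    is_true_pair <- ik %in% true_fwd | ik %in% true_rev
    m <- report$universe_size
    n_true <- sum(gold$edges$label == 1L)
    list(dataset = dataset, gold = gold, network = run$network,
         report = report, influences = influences,
         true_pair_influence = influences$influence[is_true_pair],
         null_pair_influence = influences$influence[!is_true_pair],
         all_absent_accuracy = (m * (m - 1) - n_true) / (m * (m - 1)))
  })
  recovery_cache$res <- res
  res
}
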