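# Scoring inferred networks against gold standards, plus the significance
# tests used to justify the default thresholds.

#' Score an inferred network against a gold standard
#'
#' Every ordered pair `(x, y)`, `x != y`, over the shared gene universe is
#' labelled predicted present/absent (an edge in the network or not) and
#' gold present/absent; accuracy is `(tp + tn) / (m * (m - 1))`.  A
#' direction error therefore costs one false positive plus one false
#' negative.  For transparency an unordered variant is also reported, in
#' which a pair counts as present when either direction carries an edge.
#'
#' @param predicted a [grn_network()].
#' @param gold an [edge_set()]; unlisted ordered pairs count as absent.
#' @param universe optional explicit shared universe; defaults to the
#'   union of the two objects' universes, which must overlap.
#' @return list of class `tdm_eval`: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `accuracy_unordered`, `universe_size`.
#' @export
score_network <- function(predicted, gold, universe = NULL) {
  stopifnot(inherits(predicted, "tdm_network"), inherits(gold, "tdm_edgeset"))
  if (is.null(universe)) {
    if (!length(intersect(predicted$universe, gold$universe)) &&
        length(predicted$universe) && length(gold$universe)) {
      stop_validation("predicted and gold universes are disjoint")
    }
    universe <- union(predicted$universe, gold$universe)
  }
  universe <- natural_sort(unique(universe))
  m <- length(universe)
  pred_keys <- paste(predicted$edges$regulator, predicted$edges$target,
                     sep = ">")
  gold_keys <- present_keys(gold)

  ordered <- expand.grid(target = universe, regulator = universe,
                         stringsAsFactors = FALSE)
  ordered <- ordered[ordered$regulator != ordered$target, ]
  keys <- paste(ordered$regulator, ordered$target, sep = ">")
  p <- keys %in% pred_keys
  g <- keys %in% gold_keys
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)

  # unordered variant: a pair is "present" if any direction has an edge
  und <- generate_pairs(universe)
  ukeys_f <- paste(und$gene_a, und$gene_b, sep = ">")
  ukeys_r <- paste(und$gene_b, und$gene_a, sep = ">")
  pu <- ukeys_f %in% pred_keys | ukeys_r %in% pred_keys
  gu <- ukeys_f %in% gold_keys | ukeys_r %in% gold_keys
  acc_u <- if (nrow(und)) mean(pu == gu) else 1

  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / max(tp + fp + tn + fn, 1),
                 accuracy_unordered = acc_u,
                 universe_size = m),
            class = "tdm_eval")
}

#' @export
print.tdm_eval <- function(x, ...) {
  cat(sprintf("Network score over %d genes: accuracy %.4f (tp=%d fp=%d tn=%d fn=%d; unordered %.4f)\n",
              x$universe_size, x$accuracy, x$tp, x$fp, x$tn, x$fn,
              x$accuracy_unordered))
  invisible(x)
}

#' Mean accuracy across datasets
#'
#' Unweighted arithmetic mean of per-dataset accuracies, the summary used
#' when benchmarking over a collection of networks.
#'
#' @param reports list of `tdm_eval` reports (or a numeric vector of
#'   accuracies).
#' @return scalar mean accuracy.
#' @export
average_accuracy <- function(reports) {
  if (!length(reports)) stop_validation("need at least one report")
  acc <- if (is.numeric(reports)) reports
         else vapply(reports, function(r) r$accuracy, numeric(1))
  mean(acc)
}

#' Two-sample separation test
#'
#' Student's two-sample t-test for a difference in means, used to check
#' that the thresholds actually separate what they are meant to separate:
#' expression at induced vs repressed time points (for tau) and influence
#' of predicted-present vs predicted-absent edges (for epsilon).  The
#' equal-variance form is the default; Welch's correction is available.
#' If both groups are constant the test is degenerate: p = 1 when the
#' means are equal, p = 0 otherwise.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param var_equal pool the variances (classic Student's test, default
#'   `TRUE`) or use the Welch approximation.
#' @return list with `statistic` (t) and `p_value` (two-sided).
#' @export
separation_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_validation("each group needs at least 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, p_value = 1))
    }
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                p_value = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test for comparing accuracies of two parameter
#' settings across the same datasets.  All-zero differences give p = 1 by
#' convention.
#'
#' @param differences numeric vector of paired score differences.
#' @return two-sided p-value.
#' @export
paired_rank_test <- function(differences) {
  differences <- differences[is.finite(differences)]
  if (!length(differences) || all(differences == 0)) return(1)
  stats::wilcox.test(differences, mu = 0, alternative = "two.sided")$p.value
}

#' Threshold-separation diagnostics
#'
#' `expression_separation()` pools, over all genes, the expression values
#' observed at induced time points and at repressed time points (per the
#' tau rule) and tests whether their means differ.
#' `influence_separation()` splits an [influence_table()] at epsilon and
#' tests predicted-present against predicted-absent influences.
#'
#' @param dataset a [timeseries_dataset()].
#' @param tau ratio threshold.
#' @return the [separation_test()] result, plus group sizes.
#' @export
expression_separation <- function(dataset, tau = 1.2) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  ind <- rep <- numeric(0)
  for (g in dataset$gene_ids) {
    prof <- dataset$profiles[[g]]
    r <- compute_sce(prof, tau = tau, gene = g)
    if (nrow(r$induced)) {
      ind <- c(ind, prof[cbind(r$induced$series, r$induced$t)])
    }
    if (nrow(r$repressed)) {
      rep <- c(rep, prof[cbind(r$repressed$series, r$repressed$t)])
    }
  }
  c(separation_test(ind, rep),
    list(n_induced = length(ind), n_repressed = length(rep)))
}

#' @rdname expression_separation
#' @param influences data frame from [influence_table()].
#' @param epsilon influence threshold.
#' @export
influence_separation <- function(influences, epsilon = 0.96) {
  pres <- influences$influence[influences$influence > epsilon]
  abs_ <- influences$influence[influences$influence <= epsilon]
  c(separation_test(pres, abs_),
    list(n_present = length(pres), n_absent = length(abs_)))
}

#' Benchmark the pipeline over paired expression/gold-standard files
#'
#' Runs the full inference on each expression file (DREAM4 dialect),
#' scores it against the matching gold standard, and reports per-dataset
#' accuracy plus the unweighted mean — the protocol used for multi-network
#' benchmark suites such as the five DREAM4 100-gene challenges.
#'
#' @param expr_paths character vector of time-series file paths.
#' @param gold_paths matching character vector of gold-standard paths.
#' @param dialect time-series dialect (see [read_timeseries()]).
#' @inheritParams infer_network
#' @return list with `reports` (per-dataset `tdm_eval`), `accuracies`,
#'   `mean_accuracy` and the parameter set used.
#' @export
run_benchmark <- function(expr_paths, gold_paths, dialect = "dream4",
                          algorithm = "M2", tau = 1.2, epsilon = 0.96,
                          mi = mi_config(), n_workers = 1, n_reducers = 20) {
  stopifnot(length(expr_paths) == length(gold_paths), length(expr_paths) >= 1)
  reports <- vector("list", length(expr_paths))
  for (i in seq_along(expr_paths)) {
    dataset <- read_timeseries(expr_paths[i], dialect = dialect)
    gold <- read_gold_standard(gold_paths[i], universe = dataset$gene_ids)
    run <- infer_network(dataset, algorithm = algorithm, tau = tau,
                         epsilon = epsilon, mi = mi, n_workers = n_workers,
                         n_reducers = n_reducers)
    reports[[i]] <- score_network(run$network, gold)
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  list(reports = reports, accuracies = acc,
       mean_accuracy = average_accuracy(reports),
       params = list(algorithm = algorithm, tau = tau, epsilon = epsilon,
                     max_lag = mi$max_lag, n_bins = mi$n_bins,
                     binning = mi$binning, log_base = mi$log_base))
}
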