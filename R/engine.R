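# Local map/shuffle/reduce execution of the three inference steps.  The
# four algorithms M0-M3 assign the steps to the "mapper" or "reducer"
# role in all four possible prefix splits; because each step is a pure
# function of its record, every split yields the same network, and the
# choice only matters for load balance on a real distributed backend.

ALGORITHM_STEPS <- list(
  M0 = character(0),
  M1 = "step1",
  M2 = c("step1", "step2"),
  M3 = c("step1", "step2", "step3"))

KEY_SCHEMAS <- list(
  M0 = "key = unordered gene pair; value = both expression profiles",
  M1 = "key = unordered gene pair; value = profiles + Step-1 case tag",
  M2 = "key = ordered gene pair; value = influence(gx, gy)",
  M3 = "key = edge gx->gy; value = influence exceeding epsilon")

#' Plan a map/reduce inference job
#'
#' Returns the mapper/reducer step assignment for one of the four
#' partitioning algorithms: M0 (mappers do nothing, reducers run all three
#' steps), M1 (mappers run Step 1), M2 (Steps 1-2; the recommended
#' default), M3 (mappers run everything, reducers only collect).
#'
#' @param algorithm one of `"M0"`, `"M1"`, `"M2"`, `"M3"` (case-insensitive).
#' @param n_workers mapper-side parallelism M (local worker processes).
#' @param n_reducers number of reducer partitions R (default 20).
#' @return list of class `tdm_jobplan` with `algorithm`, `mapper_steps`,
#'   `reducer_steps`, `n_workers`, `n_reducers`, `key_schema`.
#' @export
plan_job <- function(algorithm = "M2", n_workers = 1, n_reducers = 20) {
  algorithm <- toupper(as.character(algorithm)[1])
  if (!algorithm %in% names(ALGORITHM_STEPS)) {
    stop_validation("unknown algorithm '%s' (expected M0, M1, M2 or M3)",
                    algorithm)
  }
  if (n_workers < 1 || n_reducers < 1) {
    stop_validation("n_workers and n_reducers must be >= 1")
  }
  mapper <- ALGORITHM_STEPS[[algorithm]]
  all_steps <- c("step1", "step2", "step3")
  structure(list(algorithm = algorithm,
                 mapper_steps = mapper,
                 reducer_steps = setdiff(all_steps, mapper),
                 n_workers = as.integer(n_workers),
                 n_reducers = as.integer(n_reducers),
                 key_schema = KEY_SCHEMAS[[algorithm]]),
            class = "tdm_jobplan")
}

#' @export
print.tdm_jobplan <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "(none)"
  cat(sprintf("Job plan %s: mappers run %s; reducers run %s\n", x$algorithm,
              fmt(x$mapper_steps), fmt(x$reducer_steps)))
  cat(sprintf("  %d workers, %d reducers; %s\n", x$n_workers, x$n_reducers,
              x$key_schema))
  invisible(x)
}

# Stable string hash (djb2 reduced mod a Mersenne prime), fixed across
# processes and runs so the shuffle is reproducible.
stable_hash <- function(keys) {
  vapply(keys, function(k) {
    h <- 5381
    for (b in utf8ToInt(k)) h <- (h * 33 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Partition keyed records among reducers
#'
#' Deterministic shuffle: each record goes to the partition selected by a
#' stable hash of its key, so the same stream always partitions the same
#' way and the partitions are jointly exhaustive and disjoint.
#'
#' @param records list of records.
#' @param n_reducers number of partitions R.
#' @param keys character vector of keys, one per record; defaults to the
#'   records' own keys when they come from the inference pipeline.
#' @return list of `n_reducers` lists of records.
#' @export
partition_by_key <- function(records, n_reducers, keys = NULL) {
  if (n_reducers < 1) stop_validation("n_reducers must be >= 1")
  if (is.null(keys)) keys <- vapply(records, record_key, character(1))
  stopifnot(length(keys) == length(records))
  part <- (stable_hash(keys) %% n_reducers) + 1L
  lapply(seq_len(n_reducers), function(r) records[part == r])
}

record_key <- function(rec) {
  if (!is.null(rec$source)) paste(rec$source, rec$target, sep = ">")
  else paste(rec$gene_a, rec$gene_b, sep = "|")
}

# --- step execution ---------------------------------------------------------

make_context <- function(dataset, tau, epsilon, mi) {
  list(dataset = dataset, tau = tau, epsilon = epsilon, mi = mi,
       sce_cache = new.env(parent = emptyenv()),
       sym_cache = new.env(parent = emptyenv()))
}

gene_sce <- function(ctx, g) {
  if (is.null(ctx$sce_cache[[g]])) {
    ctx$sce_cache[[g]] <- compute_sce(ctx$dataset$profiles[[g]],
                                      tau = ctx$tau, gene = g)
  }
  ctx$sce_cache[[g]]
}

gene_syms <- function(ctx, g) {
  if (is.null(ctx$sym_cache[[g]])) {
    ctx$sym_cache[[g]] <- discretize_profile(ctx$dataset$profiles[[g]], ctx$mi)
  }
  ctx$sym_cache[[g]]
}

# Apply a sequence of steps to one pair record.  Returns NULL when Step 3
# predicts the edge absent (the record leaves the stream).
run_steps <- function(rec, steps, ctx) {
  for (st in steps) {
    rec <- switch(st,
      step1 = {
        rec$case <- classify_pair(gene_sce(ctx, rec$gene_a),
                                  gene_sce(ctx, rec$gene_b))
        rec
      },
      step2 = {
        genes <- unique(unlist(rec$case$ordered_pairs))
        syms <- stats::setNames(lapply(genes, gene_syms, ctx = ctx), genes)
        compute_influence(rec$case, syms, ctx$mi)
      },
      step3 = {
        d <- decide_edge(rec, ctx$epsilon)
        if (d$present) d else NULL
      })
    if (is.null(rec)) return(NULL)
  }
  rec
}

apply_phase <- function(records, steps, ctx, n_workers) {
  if (!length(records) || !length(steps)) return(records)
  runner <- function(chunk) {
    out <- lapply(chunk, run_steps, steps = steps, ctx = ctx)
    out[!vapply(out, is.null, logical(1))]
  }
  n_workers <- min(n_workers, length(records))
  if (n_workers > 1 && .Platform$OS.type == "unix") {
    chunks <- split(records, cut(seq_along(records), n_workers, labels = FALSE))
    res <- parallel::mclapply(chunks, runner, mc.cores = n_workers)
    for (r in res) if (inherits(r, "try-error")) stop(r)
    unlist(res, recursive = FALSE, use.names = FALSE)
  } else {
    runner(records)
  }
}

#' Run the full inference pipeline
#'
#' Generates all unordered gene pairs, executes the mapper steps of the
#' chosen algorithm on a local worker pool, shuffles the key-value records
#' among `n_reducers` partitions by a stable key hash, executes the
#' remaining steps reducer-side, and assembles the surviving edges into a
#' network.  The result is identical for all four algorithms and for any
#' worker/reducer counts on the same input and parameters; the algorithm
#' choice only reallocates work.
#'
#' @param dataset a [timeseries_dataset()].
#' @param algorithm partitioning algorithm, `"M0"`..`"M3"` (default `"M2"`).
#' @param tau ratio threshold for substantial change (default 1.2).
#' @param epsilon influence threshold for edge presence (default 0.96).
#' @param mi a [mi_config()].
#' @param n_workers local mapper parallelism (default 1).
#' @param n_reducers number of reducer partitions (default 20).
#' @return list of class `tdm_run` with `network` (a [grn_network()]),
#'   `plan`, `counts` (`n_pairs`, `records_to_reducers`, `n_edges`) and
#'   `timing` (elapsed seconds per phase).
#' @examples
#' d <- simulate_timeseries(sample_network(sim_config(m = 6, seed = 1)),
#'                          sim_config(m = 6, seed = 1))
#' run <- infer_network(d, algorithm = "M2")
#' run$network
#' @export
infer_network <- function(dataset, algorithm = "M2", tau = 1.2,
                          epsilon = 0.96, mi = mi_config(),
                          n_workers = 1, n_reducers = 20) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  plan <- plan_job(algorithm, n_workers, n_reducers)
  ctx <- make_context(dataset, tau, epsilon, mi)
  params <- list(tau = tau, epsilon = epsilon, max_lag = mi$max_lag,
                 n_bins = mi$n_bins, binning = mi$binning,
                 log_base = if (mi$log_base == 2) "2" else "e",
                 algorithm = plan$algorithm)

  pairs <- generate_pairs(dataset)
  records <- lapply(seq_len(nrow(pairs)),
                    function(i) list(gene_a = pairs$gene_a[i],
                                     gene_b = pairs$gene_b[i]))
  t0 <- proc.time()[["elapsed"]]
  mapped <- apply_phase(records, plan$mapper_steps, ctx, plan$n_workers)
  t1 <- proc.time()[["elapsed"]]
  partitions <- partition_by_key(mapped, plan$n_reducers)
  t2 <- proc.time()[["elapsed"]]
  reduced <- unlist(lapply(partitions, apply_phase, steps = plan$reducer_steps,
                           ctx = ctx, n_workers = 1L),
                    recursive = FALSE, use.names = FALSE)
  t3 <- proc.time()[["elapsed"]]

  network <- assemble_network(reduced %||% list(), dataset$gene_ids, params)
  structure(list(network = network, plan = plan,
                 counts = list(n_pairs = nrow(pairs),
                               records_to_reducers = length(mapped),
                               n_edges = nrow(network$edges)),
                 timing = c(map = t1 - t0, shuffle = t2 - t1,
                            reduce = t3 - t2, total = t3 - t0)),
            class = "tdm_run")
}

#' @export
print.tdm_run <- function(x, ...) {
  cat(sprintf("Inference run (%s): %d pairs -> %d records to reducers -> %d edges in %.2fs\n",
              x$plan$algorithm, x$counts$n_pairs, x$counts$records_to_reducers,
              x$counts$n_edges, x$timing[["total"]]))
  print(x$network)
  invisible(x)
}

#' Influence values for every unordered gene pair
#'
#' Runs Steps 1-2 sequentially and tabulates the winning ordered pair of
#' every unordered pair with its influence, best lag and Step-1 case tag.
#' Useful for threshold diagnostics and for scoring influence separation
#' between true and false edges.
#'
#' @inheritParams infer_network
#' @return data frame with columns `source`, `target`, `case_tag`,
#'   `influence`, `best_lag`.
#' @export
influence_table <- function(dataset, tau = 1.2, mi = mi_config()) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  ctx <- make_context(dataset, tau, NA_real_, mi)
  pairs <- generate_pairs(dataset)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    rec <- list(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i])
    rec <- run_steps(rec, "step1", ctx)
    tag <- rec$case$case_tag
    ir <- run_steps(rec, "step2", ctx)
    data.frame(source = ir$source, target = ir$target, case_tag = tag,
               influence = ir$influence, best_lag = ir$best_lag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source = character(), target = character(),
                      case_tag = character(), influence = numeric(),
                      best_lag = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
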