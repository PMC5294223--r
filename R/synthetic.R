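# Synthetic benchmark generator: random directed networks plus
# regulator-driven lagged time series with known ground truth, shaped
# like the DREAM4 challenges (m genes, s series of n time points).

#' Simulation configuration
#'
#' Defaults produce a DREAM4-shaped recovery benchmark at desk scale:
#' 20 genes, 10 series of 21 time points, 5% of unordered pairs carrying
#' a true directed edge, threefold activation/repression effects and mild
#' log-normal noise.
#'
#' @param m number of genes.
#' @param edge_density probability that an unordered gene pair carries a
#'   true directed edge (one direction only), in (0, 1).
#' @param n_timepoints time points per series n (>= 2).
#' @param n_series independent series s.
#' @param lag_range integer lags a regulator may act over (within the
#'   default search window 1..3).
#' @param effect_size multiplicative strength of activation (and, inverted,
#'   repression); must exceed 1 to be detectable by the ratio rule.
#' @param noise_sd standard deviation of multiplicative log-normal noise
#'   (0 = noiseless).
#' @param seed RNG seed; every generator draw is derived from it.
#' @return list of class `tdm_simconfig`.
#' @export
sim_config <- function(m = 20, edge_density = 0.05, n_timepoints = 21,
                       n_series = 10, lag_range = 1:3, effect_size = 3,
                       noise_sd = 0.1, seed = 1) {
  if (m < 1) stop_validation("m must be >= 1")
  if (edge_density < 0 || edge_density >= 1) {
    stop_validation("edge_density must be in [0, 1)")
  }
  if (n_timepoints < 2) stop_validation("n_timepoints must be >= 2")
  if (n_series < 1) stop_validation("n_series must be >= 1")
  if (any(lag_range < 1)) stop_validation("lags must be >= 1")
  if (max(lag_range) >= n_timepoints) {
    stop_validation("largest lag (%d) must be smaller than n_timepoints (%d)",
                    max(lag_range), n_timepoints)
  }
  if (effect_size <= 1) stop_validation("effect_size must be > 1")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  structure(list(m = as.integer(m), edge_density = edge_density,
                 n_timepoints = as.integer(n_timepoints),
                 n_series = as.integer(n_series),
                 lag_range = as.integer(lag_range),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tdm_simconfig")
}

#' Sample a random true network
#'
#' Genes are assigned a random topological order; each unordered pair
#' independently carries an edge with probability `edge_density`, oriented
#' along the topological order, so the graph is acyclic and no pair is
#' reciprocal.  Each edge is given a regulatory lag (from `lag_range`) and
#' a sign (activation/repression, equiprobable), stored in the
#' `"mechanism"` attribute for the simulator.
#'
#' @param config a [sim_config()].
#' @return an [edge_set()] whose listed edges are the present (label 1)
#'   true edges; all other ordered pairs are absent.
#' @export
sample_network <- function(config = sim_config()) {
  stopifnot(inherits(config, "tdm_simconfig"))
  set.seed(config$seed)
  ids <- sprintf("G%d", seq_len(config$m))
  topo <- sample(ids)                      # position = topological rank
  rank <- match(ids, topo)
  pairs <- generate_pairs(ids)
  keep <- if (nrow(pairs)) stats::runif(nrow(pairs)) < config$edge_density
          else logical(0)
  pairs <- pairs[keep, , drop = FALSE]
  reg <- ifelse(rank[match(pairs$gene_a, ids)] < rank[match(pairs$gene_b, ids)],
                pairs$gene_a, pairs$gene_b)
  tgt <- ifelse(reg == pairs$gene_a, pairs$gene_b, pairs$gene_a)
  mech <- data.frame(regulator = reg, target = tgt,
                     lag = if (length(reg)) sample(config$lag_range,
                                                   length(reg), replace = TRUE)
                           else integer(0),
                     sign = if (length(reg)) sample(c(1, -1), length(reg),
                                                    replace = TRUE)
                            else numeric(0),
                     stringsAsFactors = FALSE)
  gold <- edge_set(data.frame(regulator = reg, target = tgt,
                              label = rep(1L, length(reg)),
                              stringsAsFactors = FALSE),
                   universe = ids)
  attr(gold, "mechanism") <- mech
  gold
}

#' Simulate lagged time-series expression from a true network
#'
#' Unregulated genes follow a gene-specific baseline with one randomly
#' timed substantial shift per series (up or down by `effect_size`), so
#' their ScE is well defined.  A regulated gene's value at time `t` is its
#' baseline modulated by each regulator's fold change at `t - lag`, raised
#' to the edge sign, so activation propagates the regulator's shift
#' `lag` steps later and repression inverts it.  All values are positive;
#' multiplicative log-normal noise with `noise_sd` is applied throughout.
#' Deterministic for a fixed `config$seed`.
#'
#' @param network an [edge_set()] of true edges, typically from
#'   [sample_network()] (whose per-edge lags/signs are reused); edges of a
#'   hand-built edge set are assigned lags and signs by drawing from the
#'   config.
#' @param config a [sim_config()].
#' @return a [timeseries_dataset()] with `config$m` genes.
#' @export
simulate_timeseries <- function(network, config = sim_config()) {
  stopifnot(inherits(network, "tdm_edgeset"), inherits(config, "tdm_simconfig"))
  n <- config$n_timepoints
  s <- config$n_series
  ids <- sprintf("G%d", seq_len(config$m))
  set.seed(config$seed + 1L)

  mech <- attr(network, "mechanism")
  if (is.null(mech)) {
    pres <- network$edges[network$edges$label == 1L, , drop = FALSE]
    mech <- data.frame(regulator = pres$regulator, target = pres$target,
                       lag = if (nrow(pres)) sample(config$lag_range,
                                                    nrow(pres), replace = TRUE)
                             else integer(0),
                       sign = if (nrow(pres)) sample(c(1, -1), nrow(pres),
                                                     replace = TRUE)
                              else numeric(0),
                       stringsAsFactors = FALSE)
  }
  if (nrow(mech) && max(mech$lag) >= n) {
    stop_validation("regulatory lag %d must be smaller than n_timepoints %d",
                    max(mech$lag), n)
  }

  baseline <- stats::setNames(stats::runif(length(ids), 0.8, 1.2), ids)
  # Autonomous shift schedule for every gene (used only by unregulated
  # ones).  Shifts land in the first two-thirds of the window so the
  # pre-shift, shifted-up and shifted-down states are roughly balanced --
  # the three states a B = 3 discretization is meant to resolve -- and so
  # lagged propagation to targets stays inside the observed window.
  t0_max <- max(2L, min(n - max(config$lag_range), floor(2 * n / 3)))
  shift_t <- matrix(sample(2:t0_max, length(ids) * s, replace = TRUE),
                    nrow = length(ids), dimnames = list(ids, NULL))
  shift_dir <- matrix(sample(c(1, -1), length(ids) * s, replace = TRUE),
                      nrow = length(ids), dimnames = list(ids, NULL))
  noise <- lapply(stats::setNames(ids, ids), function(g) {
    if (config$noise_sd == 0) matrix(1, s, n)
    else matrix(exp(stats::rnorm(s * n, 0, config$noise_sd)), s, n)
  })

  regulators <- split(mech, mech$target)
  profiles <- lapply(stats::setNames(ids, ids), function(g) matrix(NA_real_, s, n))
  for (sr in seq_len(s)) {
    for (t in seq_len(n)) {
      for (g in ids) {
        reg <- regulators[[g]]
        val <- if (is.null(reg) || t == 1) {
          # unregulated trajectory (all genes share time point 1 as baseline)
          fold <- if (!is.null(reg)) 1
                  else if (t >= shift_t[g, sr]) config$effect_size^shift_dir[g, sr]
                  else 1
          baseline[[g]] * fold
        } else {
          fold <- 1
          for (e in seq_len(nrow(reg))) {
            tl <- t - reg$lag[e]
            if (tl >= 1) {
              r <- reg$regulator[e]
              fold <- fold * (profiles[[r]][sr, tl] / baseline[[r]])^reg$sign[e]
            }
          }
          baseline[[g]] * fold
        }
        profiles[[g]][sr, t] <- val * noise[[g]][sr, t]
      }
    }
  }
  timeseries_dataset(profiles)
}
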