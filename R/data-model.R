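# Core domain containers: time-series expression datasets, gold-standard
# edge sets, and inferred networks.  All are lightweight S3 lists; gene
# iteration order is always the natural identifier order.

#' Construct a time-series expression dataset
#'
#' The central input container: `m` genes, each observed in `s` independent
#' time series of `n` time points.  Every gene must have the same series
#' structure.  Genes are stored and iterated in natural identifier order
#' (see [natural_order()]).
#'
#' @param profiles named list, one element per gene, each an `s x n` numeric
#'   matrix (rows = series, columns = time points).  A plain numeric vector
#'   is accepted for a single-series gene.
#' @return an object of class `tdm_dataset` with elements `gene_ids`,
#'   `profiles` (named list of `s x n` matrices), `n_series` and
#'   `n_timepoints`.
#' @examples
#' d <- timeseries_dataset(list(G1 = rbind(c(1, 2, 3)), G2 = rbind(c(3, 2, 1))))
#' d$n_timepoints
#' @export
timeseries_dataset <- function(profiles) {
  if (length(profiles) == 0 || is.null(names(profiles)) ||
      any(!nzchar(names(profiles)))) {
    stop_validation("profiles must be a non-empty named list of matrices")
  }
  if (anyDuplicated(names(profiles))) {
    stop_format("duplicate gene id: %s",
                names(profiles)[duplicated(names(profiles))][1])
  }
  profiles <- lapply(profiles, function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    storage.mode(p) <- "double"
    p
  })
  dims <- vapply(profiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("all genes must have the same number of series and time points")
  }
  if (dims[2, 1] < 2) {
    stop_validation("at least 2 time points per series are required, got %d",
                    dims[2, 1])
  }
  if (any(!vapply(profiles, function(p) all(is.finite(p)), logical(1)))) {
    stop_validation("expression values must be finite numbers")
  }
  ids <- natural_sort(names(profiles))
  structure(list(gene_ids = ids,
                 profiles = profiles[ids],
                 n_series = unname(dims[1, 1]),
                 n_timepoints = unname(dims[2, 1])),
            class = "tdm_dataset")
}

#' @export
print.tdm_dataset <- function(x, ...) {
  cat(sprintf("Time-series expression dataset: %d genes, %d series x %d time points\n",
              length(x$gene_ids), x$n_series, x$n_timepoints))
  invisible(x)
}

#' Construct a gold-standard edge set
#'
#' Ground-truth labels over ordered gene pairs.  Pairs not listed are
#' treated as absent, so a sparse list of true edges plus a gene universe
#' fully labels all `m * (m - 1)` ordered pairs.
#'
#' @param edges data frame with columns `regulator`, `target`, `label`
#'   (1 = present, 0 = absent).  May have zero rows.
#' @param universe character vector of gene identifiers; defaults to the
#'   genes appearing in `edges`.
#' @return object of class `tdm_edgeset`.
#' @export
edge_set <- function(edges = data.frame(regulator = character(),
                                        target = character(),
                                        label = integer()),
                     universe = NULL) {
  edges <- as.data.frame(edges)[, c("regulator", "target", "label")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$label <- as.integer(edges$label)
  if (any(!edges$label %in% c(0L, 1L))) {
    stop_format("edge labels must be 0 or 1")
  }
  if (any(edges$regulator == edges$target)) {
    bad <- edges$regulator[edges$regulator == edges$target][1]
    stop_validation("self-loop edge on gene %s is not allowed", bad)
  }
  key <- paste(edges$regulator, edges$target)
  if (anyDuplicated(key)) {
    stop_validation("ordered pair listed more than once: %s",
                    key[duplicated(key)][1])
  }
  universe <- natural_sort(unique(c(universe, edges$regulator, edges$target)))
  ord <- order(natural_key(edges$regulator), natural_key(edges$target))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, universe = universe), class = "tdm_edgeset")
}

#' @export
print.tdm_edgeset <- function(x, ...) {
  cat(sprintf("Gold-standard edge set: %d listed edges (%d present), %d genes\n",
              nrow(x$edges), sum(x$edges$label == 1L), length(x$universe)))
  invisible(x)
}

# Present edges of an edge set as "reg>tgt" keys
present_keys <- function(gold) {
  pres <- gold$edges[gold$edges$label == 1L, , drop = FALSE]
  paste(pres$regulator, pres$target, sep = ">")
}

#' Construct an inferred network
#'
#' Holds the predicted present edges (weight = influence value) together
#' with the gene universe and the parameter settings that produced them.
#' Ordered pairs without an edge are predicted absent.  Because pair
#' orientation selects a single direction per unordered pair, reciprocal
#' edges are rejected.
#'
#' @param edges data frame with columns `regulator`, `target`, `weight`.
#' @param universe character vector of gene identifiers.
#' @param params named list of inference parameters (`tau`, `epsilon`,
#'   `max_lag`, `n_bins`, `binning`, `log_base`); free-form but recorded in
#'   all file output.
#' @return object of class `tdm_network`.
#' @export
grn_network <- function(edges = data.frame(regulator = character(),
                                           target = character(),
                                           weight = numeric()),
                        universe = character(), params = list()) {
  edges <- as.data.frame(edges)[, c("regulator", "target", "weight")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$regulator == edges$target)) {
    stop_validation("self-loop edge on gene %s",
                    edges$regulator[edges$regulator == edges$target][1])
  }
  key <- paste(edges$regulator, edges$target, sep = ">")
  if (anyDuplicated(key)) {
    stop_validation("duplicate ordered pair in network: %s",
                    key[duplicated(key)][1])
  }
  rev_key <- paste(edges$target, edges$regulator, sep = ">")
  if (any(rev_key %in% key)) {
    stop_validation("reciprocal edges are not allowed: %s",
                    key[match(TRUE, rev_key %in% key)])
  }
  universe <- natural_sort(unique(c(universe, edges$regulator, edges$target)))
  ord <- order(natural_key(edges$regulator), natural_key(edges$target))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, universe = universe, params = params),
            class = "tdm_network")
}

#' @export
print.tdm_network <- function(x, ...) {
  cat(sprintf("Inferred regulatory network: %d directed edges over %d genes\n",
              nrow(x$edges), length(x$universe)))
  if (length(x$params)) {
    cat("  params:",
        paste(names(x$params), unlist(lapply(x$params, format)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
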