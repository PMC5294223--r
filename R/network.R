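# Step 3: threshold influence values and assemble the directed network.

#' Decide edge presence for one influence record
#'
#' An edge is created exactly when the influence strictly exceeds the
#' threshold epsilon; influence equal to epsilon is a predicted absent
#' edge.
#'
#' @param record a `tdm_influence` from [compute_influence()], or any list
#'   with `source`, `target`, `influence`.
#' @param epsilon influence threshold (>= 0; default 0.96).
#' @return list with `source`, `target`, `influence`, `epsilon` and
#'   logical `present`.
#' @examples
#' decide_edge(list(source = "G1", target = "G2", influence = 0.97), 0.96)
#' @export
decide_edge <- function(record, epsilon = 0.96) {
  if (!is.numeric(epsilon) || epsilon < 0) {
    stop_validation("epsilon must be a non-negative number")
  }
  list(source = record$source, target = record$target,
       influence = record$influence, epsilon = epsilon,
       present = record$influence > epsilon)
}

#' Assemble the inferred network from edge decisions
#'
#' Collects the present edges (weight = influence) over the gene universe
#' into a [grn_network()], recording the parameters used.  At most one
#' decision per ordered pair is allowed; duplicates are an error.
#'
#' @param decisions list of edge decisions from [decide_edge()].
#' @param universe character vector of all gene identifiers.
#' @param params named list of inference parameters to record.
#' @return a [grn_network()] with deterministic (natural-sorted) edge order.
#' @export
assemble_network <- function(decisions, universe, params = list()) {
  if (length(decisions)) {
    keys <- vapply(decisions, function(d) paste(d$source, d$target, sep = ">"),
                   character(1))
    if (anyDuplicated(keys)) {
      stop_validation("duplicate decision for ordered pair %s",
                      keys[duplicated(keys)][1])
    }
  }
  present <- Filter(function(d) isTRUE(d$present), decisions)
  edges <- data.frame(
    regulator = vapply(present, `[[`, character(1), "source"),
    target = vapply(present, `[[`, character(1), "target"),
    weight = vapply(present, `[[`, numeric(1), "influence"),
    stringsAsFactors = FALSE)
  grn_network(edges, universe = universe, params = params)
}
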