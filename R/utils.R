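# Internal helpers shared across the package: typed error conditions and
# natural ordering of gene identifiers.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tdminfer_format_error", "tdminfer_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tdminfer_validation_error", "tdminfer_error")))
}

#' Natural ordering of gene identifiers
#'
#' Orders identifier strings so that embedded integers compare numerically:
#' `G2 < G10 < G100`, as intended by benchmark naming schemes, instead of the
#' lexicographic `G10 < G100 < G2`.  All pair orientation and output sorting
#' in the package uses this ordering.
#'
#' @param ids character vector of identifiers.
#' @return `natural_order()` returns an integer permutation (like [order()]);
#'   `natural_sort()` returns the sorted vector.
#' @examples
#' natural_sort(c("G10", "G2", "G100", "G1"))
#' @export
natural_order <- function(ids) {
  order(natural_key(ids), method = "radix")
}

#' @rdname natural_order
#' @export
natural_sort <- function(ids) {
  ids[natural_order(ids)]
}

# Sortable key: zero-pad every integer run to a fixed width so radix string
# order coincides with natural order.  20 digits exceeds any realistic id.
natural_key <- function(ids) {
  vapply(ids, function(id) {
    chunks <- regmatches(id, gregexpr("[0-9]+|[^0-9]+", id))[[1]]
    num <- grepl("^[0-9]", chunks)
    chunks[num] <- formatC(sub("^0+(?=.)", "", chunks[num], perl = TRUE),
                           width = 20, flag = "0")
    paste(chunks, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if a natural-precedes b
natural_lt <- function(a, b) natural_key(a) < natural_key(b)

`%||%` <- function(a, b) if (is.null(a)) b else a
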