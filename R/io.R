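# Readers and writers for the plain-text formats the tool exchanges:
# DREAM4-style time-series tables, generic gene x time TSVs, gold-standard
# edge lists, materialised gene-pair files, and inferred networks
# (edge TSV / Graphviz dot).

#' Read a time-series expression dataset
#'
#' Two dialects are supported.  `dream4`: a header row whose first column
#' is `Time` followed by gene names, then one row per time point; a new
#' series starts at a blank line or wherever the time value fails to
#' increase (DREAM4 files concatenate 10 series of 21 time points this
#' way).  `generic-tsv`: no header, one row per gene with the identifier
#' in the first column and a single series of expression values in the
#' remaining columns.
#'
#' @param path file path.
#' @param dialect `"dream4"` or `"generic-tsv"`.
#' @return a [timeseries_dataset()].
#' @export
read_timeseries <- function(path, dialect = c("dream4", "generic-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "dream4") read_dream4(lines, path) else read_generic_tsv(lines, path)
}

read_dream4 <- function(lines, path) {
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop_format("%s: empty file", path)
  header <- strsplit(lines[nonblank[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || tolower(trimws(header[1])) != "time") {
    stop_format("%s: expected a header row starting with 'Time'", path)
  }
  genes <- trimws(header[-1])
  if (anyDuplicated(genes)) {
    stop_format("%s: duplicate gene id %s in header", path,
                genes[duplicated(genes)][1])
  }
  m <- length(genes)
  series <- list()          # list of numeric matrices, rows = time points
  cur <- NULL
  prev_time <- -Inf
  for (li in seq_along(lines)) {
    if (li <= nonblank[1]) next
    line <- lines[li]
    if (!nzchar(trimws(line))) {       # blank line ends the current series
      if (!is.null(cur)) { series[[length(series) + 1L]] <- cur; cur <- NULL }
      prev_time <- -Inf
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != m + 1L) {
      stop_format("%s:%d: row has %d fields, expected %d", path, li,
                  length(fields), m + 1L)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop_format("%s:%d: non-numeric value", path, li)
    if (vals[1] <= prev_time) {        # time reset also ends the series
      if (!is.null(cur)) { series[[length(series) + 1L]] <- cur; cur <- NULL }
    }
    prev_time <- vals[1]
    cur <- rbind(cur, vals[-1])
  }
  if (!is.null(cur)) series[[length(series) + 1L]] <- cur
  if (!length(series)) stop_format("%s: no data rows", path)
  n <- nrow(series[[1]])
  lens <- vapply(series, nrow, integer(1))
  if (any(lens != n)) {
    stop_format("%s: series %d has %d time points but series 1 has %d",
                path, which(lens != n)[1], lens[lens != n][1], n)
  }
  profiles <- lapply(seq_len(m), function(j) {
    do.call(rbind, lapply(series, function(s) s[, j]))
  })
  names(profiles) <- genes
  timeseries_dataset(profiles)
}

read_generic_tsv <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("%s: empty file", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(rows[[1]])
  profiles <- list()
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != width) {
      stop_format("%s:%d: row has %d fields, expected %d", path, i,
                  length(f), width)
    }
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) stop_format("%s:%d: non-numeric value", path, i)
    id <- trimws(f[1])
    if (id %in% names(profiles)) stop_format("%s:%d: duplicate gene id %s",
                                             path, i, id)
    profiles[[id]] <- matrix(vals, nrow = 1)
  }
  timeseries_dataset(profiles)
}

#' Write a dataset in the DREAM4 time-series dialect
#'
#' Series are separated by a blank line and the time column restarts at 0,
#' so files round-trip through [read_timeseries()] with either separator
#' convention.
#'
#' @param dataset a [timeseries_dataset()].
#' @param path output file path.
#' @export
write_timeseries <- function(dataset, path) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  n <- dataset$n_timepoints
  times <- seq(0, by = 50, length.out = n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Time", dataset$gene_ids), collapse = "\t"), con)
  for (s in seq_len(dataset$n_series)) {
    block <- vapply(seq_len(n), function(t) {
      vals <- vapply(dataset$gene_ids,
                     function(g) fmt_num(dataset$profiles[[g]][s, t]),
                     character(1))
      paste(c(fmt_num(times[t]), vals), collapse = "\t")
    }, character(1))
    writeLines(block, con)
    if (s < dataset$n_series) writeLines("", con)
  }
  invisible(path)
}

# shortest decimal representation that round-trips a double
fmt_num <- function(x) sprintf("%.17g", x)

#' Enumerate unordered gene pairs
#'
#' Emits every unordered pair exactly once, with `gene_a` preceding
#' `gene_b` in natural identifier order, in deterministic sorted order:
#' `m * (m - 1) / 2` rows for `m` genes.
#'
#' @param dataset a [timeseries_dataset()] (or a character vector of ids).
#' @return data frame with columns `gene_a`, `gene_b`.
#' @export
generate_pairs <- function(dataset) {
  ids <- if (inherits(dataset, "tdm_dataset")) dataset$gene_ids
         else natural_sort(as.character(dataset))
  m <- length(ids)
  if (m < 2) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(matrix(NA, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Materialise and re-read gene-pair files
#'
#' A pair file carries one unordered gene pair per line together with both
#' genes' full expression profiles, `m * (m - 1) / 2` lines in total.  The
#' dialect is tab-delimited fields `gene_a`, `gene_b`, `profiles_a`,
#' `profiles_b`; each profile is its series joined by `;`, values within a
#' series joined by `,`, printed with enough digits to round-trip doubles
#' bit-exactly.
#'
#' @param dataset a [timeseries_dataset()].
#' @param path file path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` returns
#'   a list of records, each with `gene_a`, `gene_b` and the two profile
#'   matrices.
#' @export
write_pairs <- function(dataset, path) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  pairs <- generate_pairs(dataset)
  enc <- vapply(dataset$gene_ids, function(g) encode_profile(dataset$profiles[[g]]),
                character(1))
  lines <- sprintf("%s\t%s\t%s\t%s", pairs$gene_a, pairs$gene_b,
                   enc[pairs$gene_a], enc[pairs$gene_b])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop_validation("pair file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) stop_format("%s:%d: expected 4 tab-separated fields",
                                    path, i)
    list(gene_a = f[1], gene_b = f[2],
         profiles_a = decode_profile(f[3]),
         profiles_b = decode_profile(f[4]))
  })
}

encode_profile <- function(mat) {
  paste(apply(mat, 1, function(r) paste(fmt_num(r), collapse = ",")),
        collapse = ";")
}

decode_profile <- function(txt) {
  rows <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Read a gold-standard edge list
#'
#' Three-column TSV in the DREAM4 convention: regulator, target, 0/1
#' label.  Ordered pairs absent from the file are labelled absent.
#'
#' @param path file path.
#' @param universe optional character vector extending the gene universe
#'   beyond the identifiers seen in the file.
#' @return an [edge_set()].
#' @export
read_gold_standard <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_validation("gold-standard file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(edge_set(universe = universe))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad)) stop_format("%s:%d: expected 3 tab-separated columns",
                               path, bad[1])
  tab <- do.call(rbind, rows)
  lab <- suppressWarnings(as.numeric(tab[, 3]))
  if (anyNA(lab) || any(!lab %in% c(0, 1))) {
    stop_format("%s: edge label must be 0 or 1, got '%s'",
                path, tab[which(is.na(lab) | !lab %in% c(0, 1))[1], 3])
  }
  edge_set(data.frame(regulator = tab[, 1], target = tab[, 2],
                      label = as.integer(lab), stringsAsFactors = FALSE),
           universe = universe)
}

#' Write a gold-standard edge list
#'
#' @param gold an [edge_set()].
#' @param path file path.
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "tdm_edgeset"))
  writeLines(sprintf("%s\t%s\t%d", gold$edges$regulator, gold$edges$target,
                     gold$edges$label), path)
  invisible(path)
}

#' Write an inferred network
#'
#' `edge-tsv` writes one `regulator<TAB>target<TAB>weight` line per edge
#' (weights to 6 decimal places, rows sorted by regulator then target);
#' `dot` writes a Graphviz digraph.  Both begin with comment lines
#' recording the inference parameters.
#'
#' @param network a [grn_network()].
#' @param path output file path.
#' @param format `"edge-tsv"` or `"dot"`.
#' @export
write_network <- function(network, path, format = c("edge-tsv", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "tdm_network"))
  p <- network$params
  hdr <- sprintf("params: %s",
                 paste(names(p), vapply(p, base::format, character(1)),
                       sep = "=", collapse = " "))
  if (format == "edge-tsv") {
    lines <- c(paste("#", hdr),
               sprintf("# genes: %s", paste(network$universe, collapse = ",")),
               sprintf("%s\t%s\t%.6f", network$edges$regulator,
                       network$edges$target, network$edges$weight))
  } else {
    lines <- c(paste("//", hdr),
               "digraph grn {",
               sprintf("  \"%s\";", network$universe),
               sprintf("  \"%s\" -> \"%s\" [weight=%.6f];",
                       network$edges$regulator, network$edges$target,
                       network$edges$weight),
               "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an inferred network from edge-TSV
#'
#' Inverse of [write_network()] for the `edge-tsv` format; the gene
#' universe is recovered from the `# genes:` header comment.
#'
#' @param path file path.
#' @return a [grn_network()] (parameter values are not parsed back).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop_validation("network file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  universe <- character()
  gl <- grep("^# genes:", lines, value = TRUE)
  if (length(gl)) {
    universe <- strsplit(sub("^# genes:\\s*", "", gl[1]), ",", fixed = TRUE)[[1]]
  }
  data <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(data)) return(grn_network(universe = universe))
  rows <- strsplit(data, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad)) stop_format("%s: malformed edge line: %s", path, data[bad[1]])
  tab <- do.call(rbind, rows)
  grn_network(data.frame(regulator = tab[, 1], target = tab[, 2],
                         weight = as.numeric(tab[, 3]),
                         stringsAsFactors = FALSE),
              universe = universe)
}
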