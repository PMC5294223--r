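# Programmatic fixtures shared across test files.

# A tiny deterministic dataset: values chosen by hand, 2 series x 4 points.
tiny_dataset <- function() {
  timeseries_dataset(list(
    G1 = rbind(c(1.0, 1.1, 1.3, 0.8), c(1.0, 1.5, 1.2, 1.1)),
    G2 = rbind(c(2.0, 2.1, 2.0, 2.1), c(2.0, 1.9, 2.0, 2.05)),
    G3 = rbind(c(1.0, 0.5, 3.0, 1.0), c(1.0, 1.0, 0.4, 1.0))))
}

# Write a DREAM4-dialect file: m gene columns, s blocks of n rows,
# separated by blank lines (or by time reset when blank = FALSE).
write_dream4_fixture <- function(path, m = 3, s = 2, n = 4, blank = TRUE,
                                 seed = 42) {
  set.seed(seed)
  genes <- sprintf("G%d", seq_len(m))
  lines <- paste(c("Time", genes), collapse = "\t")
  for (b in seq_len(s)) {
    block <- vapply(seq_len(n), function(t) {
      paste(c((t - 1) * 50, sprintf("%.4f", runif(m, 0.1, 3))), collapse = "\t")
    }, character(1))
    if (b > 1 && blank) lines <- c(lines, "")
    lines <- c(lines, block)
  }
  writeLines(lines, path)
  path
}

# ScE result with a fixed value, for pair-classification tests.
fake_sce <- function(gene, sce) {
  structure(list(gene = gene,
                 induced = data.frame(series = integer(), t = integer()),
                 repressed = data.frame(series = integer(), t = integer()),
                 sce = sce),
            class = "tdm_sce")
}

# Symbol matrices for a perfectly lag-1-coupled pair over one series.
coupled_symbols <- function() {
  x <- c(0, 1, 0, 1, 0, 1)
  y <- c(0, x[-6])          # y_{i+1} = x_i
  list(x = x, y = y)
}

edge_keys <- function(network) {
  paste(network$edges$regulator, network$edges$target, sep = ">")
}
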