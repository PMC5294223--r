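test_that("equal-frequency discretization cuts at pooled quantiles", {
  expect_equal(discretize_profile(1:6, mi_config(n_bins = 3)),
               c(0, 0, 1, 1, 2, 2))
  expect_equal(discretize_profile(c(5, 5, 5), mi_config(n_bins = 4)),
               c(0, 0, 0))
  # ties go to the lower bin
  expect_equal(discretize_profile(c(1, 2, 2, 3), mi_config(n_bins = 2)),
               c(0, 0, 0, 1))
  # matrix input keeps its shape, boundaries pooled over all series
  m <- rbind(1:3, 4:6)
  s <- discretize_profile(m, mi_config(n_bins = 3))
  expect_equal(dim(s), dim(m))
  expect_equal(s, rbind(c(0, 0, 1), c(1, 2, 2)), ignore_attr = TRUE)
})

test_that("equal-width discretization partitions the range uniformly", {
  expect_equal(discretize_profile(c(0, 10), mi_config(n_bins = 2,
                                                      binning = "width")),
               c(0, 1))
  expect_equal(discretize_profile(c(0, 4.9, 5, 5.1, 10),
                                  mi_config(n_bins = 2, binning = "width")),
               c(0, 0, 0, 1, 1))
  expect_equal(discretize_profile(rep(2, 5), mi_config(n_bins = 3,
                                                       binning = "width")),
               rep(0, 5))
})

test_that("lag alignment never crosses series boundaries", {
  one <- matrix(0L, 1, 21)
  expect_equal(nrow(lagged_samples(one, one, 2)), 19)
  many <- matrix(0L, 10, 21)
  expect_equal(nrow(lagged_samples(many, many, 1)), 200)
  short <- matrix(0L, 1, 3)
  expect_equal(nrow(lagged_samples(short, short, 3)), 0)
  # the pairing really is (x_i, y_{i+k}) within each series
  x <- rbind(1:4, 5:8)
  y <- rbind(11:14, 15:18)
  s <- lagged_samples(x, y, 2)
  expect_equal(s[, "x"], c(1L, 2L, 5L, 6L))
  expect_equal(s[, "y"], c(13L, 14L, 17L, 18L))
})

test_that("hand-computed MI values are reproduced", {
  cfg <- mi_config(n_bins = 2)
  # constant x carries no information
  expect_equal(time_delayed_mi(rep(0, 10), rep(c(0, 1), 5), 1, cfg), 0)
  # perfect lag-1 dependence: MI equals the marginal entropy
  cs <- coupled_symbols()
  expect_equal(time_delayed_mi(cs$x, cs$y, 1, cfg),
               -(3 / 5) * log2(3 / 5) - (2 / 5) * log2(2 / 5),
               tolerance = 1e-12)
  # empirically independent table: joint = product of marginals
  x <- c(0, 0, 1, 1, 0)
  y <- c(9, 0, 1, 0, 1)   # lagged pairs: (0,0),(0,1),(1,0),(1,1)
  expect_equal(time_delayed_mi(x, y, 1, cfg), 0)
  # a lag too large for the series is an error
  expect_error(time_delayed_mi(c(0, 1), c(0, 1), 5, cfg),
               class = "tdminfer_validation_error")
})

test_that("plug-in MI matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    B <- sample(2:5, 1)
    s <- sample(1:3, 1)
    n <- sample(5:50, 1)
    k <- sample(1:3, 1)
    if (k >= n) next
    base <- sample(c(2, exp(1)), 1)
    cfg <- mi_config(n_bins = B, log_base = base)
    x <- matrix(sample(0:(B - 1), s * n, replace = TRUE), s, n)
    y <- matrix(sample(0:(B - 1), s * n, replace = TRUE), s, n)
    got <- time_delayed_mi(x, y, k, cfg)
    expect_equal(got, max(oracle_lagged_mi(x, y, k, B, base), 0),
                 tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, log(B, base) + 1e-12)
  }
})

test_that("MI is invariant under symbol relabeling of either variable", {
  set.seed(102)
  B <- 3
  cfg <- mi_config(n_bins = B)
  x <- matrix(sample(0:2, 40, replace = TRUE), 2, 20)
  y <- matrix(sample(0:2, 40, replace = TRUE), 2, 20)
  ref <- time_delayed_mi(x, y, 2, cfg)
  for (i in 1:5) {
    px <- sample(0:2)
    py <- sample(0:2)
    xr <- matrix(px[x + 1], nrow = 2)
    yr <- matrix(py[y + 1], nrow = 2)
    expect_equal(time_delayed_mi(xr, yr, 2, cfg), ref, tolerance = 1e-12)
  }
})

test_that("influence is the maximum over lags, smallest lag wins ties", {
  set.seed(103)
  x <- matrix(sample(0:2, 63, replace = TRUE), 3, 21)
  y <- matrix(sample(0:2, 63, replace = TRUE), 3, 21)
  pc <- classify_pair(fake_sce("ga", 2), fake_sce("gb", 4))
  syms <- list(ga = x, gb = y)
  rec <- compute_influence(pc, syms, mi_config(max_lag = 3))
  expect_equal(length(rec$mi_by_lag), 3)
  expect_equal(rec$influence, max(rec$mi_by_lag))
  expect_equal(rec$best_lag,
               as.integer(names(rec$mi_by_lag)[which.max(rec$mi_by_lag)]))
  expect_equal(rec$source, "ga")
  expect_equal(rec$target, "gb")
  # lag window is clipped to n - 1
  short <- matrix(c(0L, 1L, 2L), 1, 3)
  rec2 <- compute_influence(pc, list(ga = short, gb = short),
                            mi_config(max_lag = 5))
  expect_equal(length(rec2$mi_by_lag), 2)
})

test_that("growing the lag window never decreases influence", {
  set.seed(104)
  for (i in 1:10) {
    x <- matrix(sample(0:2, 42, replace = TRUE), 2, 21)
    y <- matrix(sample(0:2, 42, replace = TRUE), 2, 21)
    pc <- classify_pair(fake_sce("a", 2), fake_sce("b", 3))
    syms <- list(a = x, b = y)
    infl <- vapply(1:6, function(h) {
      compute_influence(pc, syms, mi_config(max_lag = h))$influence
    }, numeric(1))
    expect_true(all(diff(infl) >= 0))
  }
})

test_that("Case 3 keeps the stronger direction and breaks ties toward (a, b)", {
  cs <- coupled_symbols()
  pc3 <- classify_pair(fake_sce("ga", 3), fake_sce("gb", 3))
  # x drives y at lag 1, so (ga -> gb) must beat the reverse
  rec <- compute_influence(pc3, list(ga = cs$x, gb = cs$y),
                           mi_config(n_bins = 2, max_lag = 1))
  expect_equal(rec$source, "ga")
  fwd <- time_delayed_mi(cs$x, cs$y, 1, mi_config(n_bins = 2))
  expect_equal(rec$influence, fwd)

  # exactly symmetric profiles tie; the ordering (ga, gb) wins
  sym <- c(0, 1, 0, 1, 0, 1)
  rec <- compute_influence(pc3, list(ga = sym, gb = sym),
                           mi_config(n_bins = 2, max_lag = 2))
  expect_equal(rec$source, "ga")
  expect_equal(rec$target, "gb")
})
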