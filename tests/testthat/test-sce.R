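test_that("ratio classification uses strict inequalities around the band", {
  expect_equal(classify_ratio(1.3, 1.0, 1.2), "INDUCED")
  expect_equal(classify_ratio(1.2, 1.0, 1.2), "NEUTRAL")   # boundary in band
  expect_equal(classify_ratio(1 / 1.2, 1.0, 1.2), "NEUTRAL")
  expect_equal(classify_ratio(0.8, 1.0, 1.2), "REPRESSED") # 0.8 < 1/1.2
  expect_error(classify_ratio(Inf, 1, 1.2), class = "tdminfer_validation_error")
  expect_error(classify_ratio(1, 1, 1), class = "tdminfer_validation_error")
})

test_that("zero baselines fall back to sign logic", {
  expect_equal(classify_ratio(0.5, 0, 1.2), "INDUCED")
  expect_equal(classify_ratio(0, 0, 1.2), "NEUTRAL")
  expect_equal(classify_ratio(-0.5, 0, 1.2), "REPRESSED")
})

test_that("the band partitions all positive ratios into three intervals", {
  set.seed(11)
  for (tau in c(1.05, 1.2, 2)) {
    ratios <- exp(runif(300, -3, 3))
    cls <- vapply(ratios, function(r) classify_ratio(r, 1, tau), character(1))
    expect_true(all(cls[ratios > tau] == "INDUCED"))
    expect_true(all(cls[ratios < 1 / tau] == "REPRESSED"))
    expect_true(all(cls[ratios >= 1 / tau & ratios <= tau] == "NEUTRAL"))
  }
})

test_that("raising tau never shrinks the neutral band", {
  set.seed(12)
  ratios <- exp(runif(200, -2, 2))
  for (pair in list(c(1.1, 1.5), c(1.2, 2), c(1.5, 3))) {
    c1 <- vapply(ratios, function(r) classify_ratio(r, 1, pair[1]), character(1))
    c2 <- vapply(ratios, function(r) classify_ratio(r, 1, pair[2]), character(1))
    expect_true(all(c2[c1 == "NEUTRAL"] == "NEUTRAL"))
  }
})

test_that("ScE is the first time point of substantial change", {
  r <- compute_sce(c(1.0, 1.1, 1.3, 0.8), tau = 1.2)
  expect_equal(r$induced$t, 3)
  expect_equal(r$repressed$t, 4)
  expect_equal(r$sce, 3)

  r <- compute_sce(c(1.0, 1.1, 1.0, 1.15), tau = 1.2)
  expect_equal(nrow(r$induced) + nrow(r$repressed), 0)
  expect_identical(r$sce, Inf)

  r <- compute_sce(c(2.0, 1.0, 3.0), tau = 1.2)
  expect_equal(r$repressed$t, 2)
  expect_equal(r$induced$t, 3)
  expect_equal(r$sce, 2)
})

test_that("a flat profile has undefined ScE and members stay in [2, n]", {
  r <- compute_sce(rep(5, 8), tau = 1.2)
  expect_identical(r$sce, Inf)
  set.seed(13)
  for (i in 1:20) {
    prof <- matrix(exp(rnorm(3 * 6, 0, 0.5)), 3, 6)
    r <- compute_sce(prof, tau = 1.2)
    members <- c(r$induced$t, r$repressed$t)
    expect_true(all(members >= 2 & members <= 6))
    # disjoint (series, t) membership
    expect_equal(anyDuplicated(rbind(r$induced, r$repressed)), 0)
    if (length(members)) expect_equal(r$sce, min(members))
  }
})

test_that("each series is classified against its own first time point", {
  # series 2 never leaves the band relative to ITS baseline of 10,
  # although all its values dwarf series 1
  prof <- rbind(c(1.0, 1.0, 1.5), c(10, 10.5, 9.8))
  r <- compute_sce(prof, tau = 1.2)
  expect_equal(r$induced$series, 1)
  expect_equal(r$induced$t, 3)
  expect_equal(r$sce, 3)
})

test_that("negative values are shifted before the ratio rule is applied", {
  prof <- c(-1, -1.05, 2)      # range 3.05, shifted baseline ~ tiny
  r <- compute_sce(prof, tau = 1.2)
  expect_true(is.finite(r$sce))
  expect_true(3 %in% r$induced$t)
})

test_that("pairs are routed to cases by ScE order, undefined acting as +Inf", {
  pc <- classify_pair(fake_sce("a", 2), fake_sce("b", 5))
  expect_equal(pc$case_tag, "CASE1")
  expect_equal(pc$ordered_pairs, list(c("a", "b")))

  pc <- classify_pair(fake_sce("a", 7), fake_sce("b", 4))
  expect_equal(pc$case_tag, "CASE2")
  expect_equal(pc$ordered_pairs, list(c("b", "a")))

  pc <- classify_pair(fake_sce("a", 3), fake_sce("b", 3))
  expect_equal(pc$case_tag, "CASE3")
  expect_equal(pc$ordered_pairs, list(c("a", "b"), c("b", "a")))

  # undefined ScE can never be the earlier-changing gene
  pc <- classify_pair(fake_sce("a", 4), fake_sce("b", Inf))
  expect_equal(pc$case_tag, "CASE1")
  expect_equal(pc$ordered_pairs, list(c("a", "b")))
  pc <- classify_pair(fake_sce("a", Inf), fake_sce("b", Inf))
  expect_equal(pc$case_tag, "CASE3")
})

test_that("case routing agrees with brute-force enumeration over ScE values", {
  vals <- c(2, 3, 5, Inf)
  for (sa in vals) {
    for (sb in vals) {
      pc <- classify_pair(fake_sce("a", sa), fake_sce("b", sb))
      expected <- if (sa < sb) "CASE1" else if (sb < sa) "CASE2" else "CASE3"
      expect_equal(pc$case_tag, expected)
    }
  }
})
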