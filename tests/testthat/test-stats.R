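test_that("condition summaries report box-plot order statistics", {
  s <- summarize_condition(c(1, 2, 3, 4, 5), "five")
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  s0 <- summarize_condition(c(0, 0, 0, 0))
  expect_true(all(unlist(s0[c("median", "q25", "q75", "min", "max")]) == 0))
  s1 <- summarize_condition(7)
  expect_true(all(unlist(s1[c("median", "q25", "q75", "min", "max")]) == 7))
  expect_error(summarize_condition(numeric(0)), "empty")
})

test_that("summary order-statistic invariants hold for random samples", {
  set.seed(42)
  for (i in 1:50) {
    vals <- stats::rlnorm(sample(1:40, 1))
    s <- summarize_condition(vals)
    expect_true(s$min <= s$q25 && s$q25 <= s$median &&
                  s$median <= s$q75 && s$q75 <= s$max)
    expect_gte(s$n, 1)
  }
})

test_that("Mann-Whitney p-values match exhaustive rank enumeration", {
  # fully separated 3 vs 3: the most extreme of the 20 rank assignments
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  pw <- pairwise_significance(list(low = a, high = b))
  expect_equal(pw$p, 0.1)
  expect_equal(pw$p, mw_exact_p(a, b))
  expect_equal(pw$statistic, 0)
  # random tie-free samples of several sizes
  set.seed(7)
  for (i in 1:10) {
    x <- round(stats::runif(sample(3:5, 1)), 6)
    y <- round(stats::runif(sample(3:5, 1)) + 0.3, 6)
    pw <- pairwise_significance(list(x = x, y = y))
    expect_equal(pw$p, mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("a group compared with itself is not significant", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  pw <- pairwise_significance(g)
  expect_equal(pw$p_adj, 1)
})

test_that("Holm adjustment matches the hand computation and its invariants", {
  expect_equal(stats::p.adjust(c(0.01, 0.04), method = "holm"), c(0.02, 0.04))
  groups <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(1.5, 2.5, 3.5),
                 d = c(20, 21, 22))
  pw <- pairwise_significance(groups)
  ok <- !pw$flagged
  # adjusted >= raw, within [0, 1], monotone in the raw ordering
  expect_true(all(pw$p_adj[ok] >= pw$p[ok]))
  expect_true(all(pw$p_adj[ok] <= 1 & pw$p_adj[ok] >= 0))
  o <- order(pw$p[ok])
  expect_true(all(diff(pw$p_adj[ok][o]) >= -1e-15))
  # hand Holm on the raw p-values
  p <- pw$p[ok]
  n <- length(p)
  hand <- p
  o <- order(p)
  adj <- cummax(pmin((n - seq_len(n) + 1) * p[o], 1))
  hand[o] <- adj
  expect_equal(pw$p_adj[ok], hand, tolerance = 1e-12)
})

test_that("undersized groups are flagged, not dropped", {
  groups <- list(a = c(1, 2), b = c(3, 4, 5), c = c(6, 7, 8))
  pw <- pairwise_significance(groups)
  expect_equal(nrow(pw), 3L)
  expect_true(pw$flagged[pw$group_a == "a" & pw$group_b == "b"])
  expect_true(is.na(pw$p[pw$flagged][1]))
  expect_false(any(pw$flagged[pw$group_a == "b"]))
})

test_that("Welch alternative is available", {
  groups <- list(a = c(1, 2, 3, 4), b = c(9, 10, 11, 13))
  pw <- pairwise_significance(groups, method = "welch")
  ht <- stats::t.test(groups$a, groups$b)
  expect_equal(pw$p, ht$p.value)
  expect_equal(pw$method, "welch_t")
})

test_that("summaries of many conditions stack into one table", {
  vals <- c(1, 2, 3, 10, 11, 12)
  cond <- rep(c("x", "y"), each = 3)
  s <- summarize_conditions(vals, cond)
  expect_equal(nrow(s), 2L)
  expect_equal(s$median[s$condition == "y"], 11)
})
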