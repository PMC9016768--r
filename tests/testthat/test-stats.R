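test_that("Welch's t handles identical, degenerate and typical samples", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(welch_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  a <- c(1.1, 0.9, 1.0); b <- c(2.1, 1.9, 2.0)
  r <- welch_t(a, b)
  o <- welch_oracle(a, b)
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
})

test_that("one-way ANOVA matches its classical identities", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- anova_oneway(g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # two groups: F equals the square of the pooled-variance t statistic
  a <- c(1.2, 0.8, 1.1, 0.9); b <- c(1.6, 1.4, 1.3, 1.8)
  r2 <- anova_oneway(list(a, b))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(r2$statistic, unname(t_pooled)^2, tolerance = 1e-10)
  # equal means, different spread: no evidence against equality
  set.seed(21)
  g3 <- list(rnorm(6, 5, 0.1), rnorm(6, 5, 0.5), rnorm(6, 5, 1))
  g3 <- lapply(g3, function(x) x - mean(x) + 5)  # force exact equal means
  r3 <- anova_oneway(g3)
  expect_gt(r3$p_value, 0.5)
  expect_error(anova_oneway(list(c(1, 2))), "at least 2")
})

test_that("one-sided t against a threshold behaves at its landmarks", {
  x <- c(0.4, 0.5, 0.6)
  r <- t_greater(x, 0.5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
  x2 <- c(0.9, 1.0, 1.1)
  r2 <- t_greater(x2, 0.5)
  o <- t_greater_oracle(x2, 0.5)
  expect_equal(r2$statistic, o$t, tolerance = 1e-12)
  expect_equal(r2$p_value, o$p, tolerance = 1e-12)
  expect_equal(r2$statistic, (1.0 - 0.5) / (0.1 / sqrt(3)),
               tolerance = 1e-12)
  # all values below the threshold: wrong-direction p
  expect_gt(t_greater(c(0.1, 0.2, 0.3), 0.5)$p_value, 0.5)
})

test_that("Grubbs flags a single extreme point against the t-derived cutoff", {
  g <- grubbs(c(1, 1, 1, 10))
  expect_equal(g$result$statistic, (10 - 3.25) / sd(c(1, 1, 1, 10)),
               tolerance = 1e-12)
  o <- grubbs_oracle(c(1, 1, 1, 10))
  expect_equal(g$result$critical, o$crit, tolerance = 1e-12)
  expect_identical(!is.na(g$outlier_index), o$flagged)
  if (o$flagged) expect_identical(g$outlier_index, 4L)
  # a symmetric small sample is never flagged at alpha = 0.05
  expect_true(is.na(grubbs(c(1, 2, 3))$outlier_index))
  # zero variance: undefined G, no outlier
  g0 <- grubbs(c(2, 2, 2))
  expect_true(is.na(g0$outlier_index))
  expect_false(g0$result$g_defined)
})

test_that("all tests agree with textbook formulas on random samples", {
  set.seed(77)
  for (k in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- rlnorm(n1, 0, 0.4); b <- rlnorm(n2, 0.3, 0.6)
    w <- welch_t(a, b); wo <- welch_oracle(a, b)
    expect_equal(w$statistic, wo$t, tolerance = 1e-8)
    expect_equal(w$p_value, wo$p, tolerance = 1e-8)
    g <- list(a, b, rlnorm(sample(3:8, 1), 0.1, 0.5))
    an <- anova_oneway(g); ao <- anova_oracle(g)
    expect_equal(an$statistic, ao$f, tolerance = 1e-8)
    expect_equal(an$p_value, ao$p, tolerance = 1e-8)
    tg <- t_greater(a, 1); to <- t_greater_oracle(a, 1)
    expect_equal(tg$statistic, to$t, tolerance = 1e-8)
    expect_equal(tg$p_value, to$p, tolerance = 1e-8)
    gr <- grubbs(a); go <- grubbs_oracle(a)
    expect_equal(gr$result$statistic, go$G, tolerance = 1e-8)
    expect_identical(!is.na(gr$outlier_index), go$flagged)
  }
})

test_that("grubbs stays near its nominal false-positive rate on clean data", {
  set.seed(303)
  hits <- 0L
  n_trials <- 400L
  for (k in seq_len(n_trials)) {
    x <- rlnorm(5, 0, 0.1)
    if (!is.na(grubbs(x, alpha = 0.05)$outlier_index)) hits <- hits + 1L
  }
  expect_lt(hits / n_trials, 0.05 + 0.02)
})

test_that("grubbs detects an injected fivefold outlier in replicates", {
  set.seed(404)
  found <- 0L
  n_trials <- 200L
  for (k in seq_len(n_trials)) {
    x <- rlnorm(5, 0, 0.1)
    idx <- sample(5, 1)
    x[idx] <- x[idx] * 5
    g <- grubbs(x, alpha = 0.05)
    if (identical(g$outlier_index, idx)) found <- found + 1L
  }
  expect_gte(found / n_trials, 0.95)
})

test_that("batch_tests runs declared comparisons over an endpoint table", {
  ep <- data.frame(
    condition = rep(c("a", "b", "c"), each = 4),
    replicate = rep(1:4, 3),
    endpoint_uM = c(1.0, 1.1, 0.9, 1.0, 2.0, 2.1, 1.9, 2.0,
                    1.0, 1.05, 0.95, 5.0))
  res <- batch_tests(ep, list(
    list(test = "welch_t", conditions = c("a", "b")),
    list(test = "anova_oneway", conditions = c("a", "b", "c")),
    list(test = "t_greater", conditions = "b", mu0 = 0.5),
    list(test = "grubbs", conditions = "c")))
  expect_equal(nrow(res), 4L)
  expect_true(res$significant[1])            # a vs b clearly differ
  expect_true(res$significant[3])            # b well above 0.5
  expect_identical(res$outlier_index[4], 4L) # the 5.0 replicate
})
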