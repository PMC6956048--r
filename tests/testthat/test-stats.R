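test_that("identical samples give t = 0 and p = 1", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x, "student")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 1)
})

test_that("both t variants agree with stats::t.test on raw data", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(6, 0, 1); y <- rnorm(8, 0.5, 1.7)
    st <- two_sample_t(x, y, "student")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(st$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(st$p_two_sided, ref$p.value, tolerance = 1e-12)
    we <- two_sample_t(x, y, "welch")
    ref2 <- t.test(x, y)
    expect_equal(we$statistic, unname(ref2$statistic), tolerance = 1e-12)
    expect_equal(we$df, unname(ref2$parameter), tolerance = 1e-12)
    expect_equal(we$p_two_sided, ref2$p.value, tolerance = 1e-12)
  }
})

test_that("summary-statistics input reproduces the Td group comparison", {
  # group summaries (mean, SD, n) for denaturation temperature
  res <- two_sample_t(list(mean = 66.8, sd = 0.27, n = 3),
                      list(mean = 62.57, sd = 1.11, n = 3), "welch")
  se <- sqrt(0.27^2 / 3 + 1.11^2 / 3)
  expect_equal(res$statistic, (66.8 - 62.57) / se, tolerance = 1e-12)
  # p-value against numerical integration of the t density
  p_oracle <- 2 * integrate(function(u) dt(u, res$df), -Inf,
                            -abs(res$statistic))$value
  expect_equal(res$p_two_sided, p_oracle, tolerance = 1e-6)
  expect_lt(res$p_two_sided, 0.05)
})

test_that("Welch df collapses to the Student df for equal variances and n", {
  x <- c(1, 2, 3, 4, 5); y <- x + 10   # same variance, same n
  expect_equal(two_sample_t(x, y, "welch")$df,
               two_sample_t(x, y, "student")$df, tolerance = 1e-12)
})

test_that("one-way ANOVA matches stats::aov and the F = t^2 identity", {
  set.seed(21)
  for (i in 1:5) {
    g <- list(rnorm(6), rnorm(6, 0.5), rnorm(7, 1, 2))
    res <- one_way_anova(g)
    dat <- data.frame(y = unlist(g),
                      grp = factor(rep(seq_along(g), lengths(g))))
    ref <- summary(aov(y ~ grp, dat))[[1]]
    expect_equal(res$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p_two_sided, ref[["Pr(>F)"]][1], tolerance = 1e-10)
    # two groups: F equals the squared Student t
    x <- rnorm(6); y <- rnorm(9)
    expect_equal(one_way_anova(list(x, y))$statistic,
                 two_sample_t(x, y, "student")$statistic^2,
                 tolerance = 1e-10)
  }
})

test_that("degenerate inputs raise undefined-statistic errors", {
  expect_error(two_sample_t(c(2, 2, 2), c(2, 2, 2)), "undefined")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(one_way_anova(list(c(1, 2), c(3))), "n >= 2")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("a shifted group is detected by ANOVA with high power", {
  # five groups, one shifted by 3 x noise SD
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    g <- c(lapply(1:4, function(i) rnorm(6, 0, 1)), list(rnorm(6, 3, 1)))
    if (one_way_anova(g)$p_two_sided < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 38)
})
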