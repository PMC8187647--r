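test_that("variance gate is an F test, symmetric, with degenerate handling", {
  expect_equal(varianceGate(0.5, 10, 0.5, 12), "equal")
  ## decidua/villi histidine SDs: F ~ 4.86, clearly unequal
  expect_equal(varianceGate(0.049, 29, 0.108, 30), "unequal")
  expect_equal((0.108 / 0.049)^2, 4.858, tolerance = 1e-3)
  ## symmetry over a grid of cases
  set.seed(1)
  for (i in 1:20) {
    s1 <- runif(1, 0.1, 3); s2 <- runif(1, 0.1, 3)
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    expect_identical(varianceGate(s1, n1, s2, n2),
                     varianceGate(s2, n2, s1, n1))
  }
  expect_message(v <- varianceGate(0, 5, 0, 5), "zero")
  expect_equal(v, "equal")
  ## cross-check against var.test on raw data
  set.seed(2)
  x <- rnorm(20, sd = 1); y <- rnorm(25, sd = 2.5)
  vt <- stats::var.test(x, y)
  gate <- varianceGate(sd(x), 20, sd(y), 25)
  expect_identical(gate, if (vt$p.value < 0.05) "unequal" else "equal")
})

test_that("summary t test agrees with t.test on raw data in both modes", {
  set.seed(42)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x <- rnorm(n1, mean = 1, sd = runif(1, 0.5, 2))
    y <- rnorm(n2, mean = 1.3, sd = runif(1, 0.5, 2))
    for (welch in c(FALSE, TRUE)) {
      ref <- stats::t.test(x, y, var.equal = !welch)
      got <- tTestSummary(mean1 = mean(x), sd1 = sd(x), n1 = n1,
                          mean2 = mean(y), sd2 = sd(y), n2 = n2,
                          mode = if (welch) "welch" else "pooled")
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("identical groups give t = 0, p = 1; equal n and SD collapse the modes", {
  res <- tTestSummary(mean1 = 2, sd1 = 0.5, n1 = 10,
                      mean2 = 2, sd2 = 0.5, n2 = 10)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  ## pooled and Welch coincide exactly (t, df and p) when n1=n2, s1=s2
  p1 <- tTestSummary(mean1 = 1, sd1 = 0.7, n1 = 12, mean2 = 1.5,
                     sd2 = 0.7, n2 = 12, mode = "pooled")
  p2 <- tTestSummary(mean1 = 1, sd1 = 0.7, n1 = 12, mean2 = 1.5,
                     sd2 = 0.7, n2 = 12, mode = "welch")
  expect_equal(p1$t, p2$t, tolerance = 1e-12)
  expect_equal(p1$df, p2$df, tolerance = 1e-12)   # W-S reduces to 2n-2
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
  expect_error(tTestSummary(mean1 = 1, sd1 = 1, n1 = 1,
                            mean2 = 2, sd2 = 1, n2 = 5), "n >= 2")
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(bhAdjust(0.2), 0.2)                         # single p
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ## hand-computed step-up on an unsorted input
  p <- c(0.03, 0.002, 0.8, 0.04)
  ## sorted: .002 .03 .04 .8; m/j: *4/1 *4/2 *4/3 *4/4 -> .008 .06 .0533 .8
  ## step-up mins: .008, min(.06,.0533,.8)=.0533, .0533, .8
  expect_equal(bhAdjust(p), c(0.0533333333333333, 0.008, 0.8,
                              0.0533333333333333), tolerance = 1e-12)
  expect_true(all(bhAdjust(p) >= p))
  ## permutation equivariance
  o <- sample(4)
  expect_equal(bhAdjust(p[o]), bhAdjust(p)[o])
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("percent change uses the reference-group convention", {
  expect_equal(round(percentChange(3.367, 2.881), 1), 14.4)
  expect_equal(percentChange(2, 1), 50)
  expect_equal(percentChange(5, 5), 0)
  ## a higher case group gives a negative (i.e. 'higher') change
  expect_lt(percentChange(0.146, 0.174), 0)
  expect_error(percentChange(0, 1), "non-zero")
})

test_that("two-sample power matches a Monte-Carlo oracle and is monotone", {
  m1 <- 1; m2 <- 1.4; sdp <- 0.6; n <- 12; alpha <- 0.05
  got <- powerTwoSample(m1, sdp, m2, sdp, n, alpha)
  ## Monte-Carlo oracle: pooled t test on simulated normal groups
  set.seed(9)
  R <- 40000
  x <- matrix(rnorm(R * n, m1, sdp), R)
  y <- matrix(rnorm(R * n, m2, sdp), R)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (n - 1)
  tt <- (mx - my) / sqrt((vx + vy) / n)
  crit <- qt(1 - alpha / 2, 2 * n - 2)
  mc <- mean(abs(tt) > crit)
  expect_equal(got, mc, tolerance = 3 * sqrt(mc * (1 - mc) / R) / mc)
  ## null case returns alpha; monotone in n and effect size
  expect_equal(powerTwoSample(1, 0.5, 1, 0.5, 10), 0.05)
  pw <- vapply(c(5, 10, 20, 40), function(n)
    powerTwoSample(1, 0.5, 1.3, 0.5, n), numeric(1))
  expect_true(all(diff(pw) > 0))
  pe <- vapply(c(1.1, 1.3, 1.6), function(m2)
    powerTwoSample(1, 0.5, m2, 0.5, 15), numeric(1))
  expect_true(all(diff(pe) > 0))
  expect_message(p1 <- powerTwoSample(1, 0, 2, 0, 10), "degenerate")
  expect_equal(p1, 1)
})

test_that("one-way ANOVA matches the hand decomposition and the t test", {
  res <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_equal(res$dfBetween, 2)
  expect_equal(res$dfWithin, 6)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  ## identical group means: F ~ 0, p ~ 1
  res0 <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
  expect_equal(res0$F, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  ## two groups: F = t^2 and identical p
  set.seed(5)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  a <- oneWayAnova(list(x, y))
  tt <- tTestSummary(mean1 = mean(x), sd1 = sd(x), n1 = 8,
                     mean2 = mean(y), sd2 = sd(y), n2 = 10, mode = "pooled")
  expect_equal(a$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p, tolerance = 1e-10)
  expect_error(oneWayAnova(list(c(1, 2), c(3))), "n >= 2")
})

test_that("fetal loss rate follows R/(R+V) x 100", {
  expect_equal(fetalLossRate(3, 7), 30)
  expect_equal(fetalLossRate(0, 5), 0)
  expect_equal(fetalLossRate(1, 2), 100 / 3)
  expect_error(fetalLossRate(0, 0), ">= 1")
})

test_that("differential tables are permutation-invariant with BH over rows", {
  t1 <- readSummaryTable(table1Path())
  cmp <- differentialTable(t1)
  expect_equal(nrow(cmp), 31L)
  ## succinate has the smallest raw p of the panel
  expect_equal(cmp$metabolite[which.min(cmp$p)], "Succinate")
  ## shuffling rows permutes output without changing values
  set.seed(3)
  o <- sample(31)
  cmpO <- differentialTable(t1[o, ])
  expect_identical(cmpO$metabolite, cmp$metabolite[o])
  expect_equal(cmpO$p, cmp$p[o], tolerance = 1e-15)
  expect_equal(cmpO$adjusted_p, cmp$adjusted_p[o], tolerance = 1e-15)
  ## single-metabolite input: adjusted = raw
  one <- differentialTable(t1[3, ])
  expect_equal(one$adjusted_p, one$p)
  ## invariants
  expect_true(all(cmp$adjusted_p >= cmp$p & cmp$adjusted_p <= 1))
  ## raw-data inputs are summarized first; mismatched sets rejected
  d <- data.frame(metabolite = c("A", "B"), mean = c(1, 2), sd = c(0.1, 0.2))
  a <- sampleCohort(d, 6, seed = 1, group = "g1")
  b <- sampleCohort(d, 6, seed = 2, group = "g2")
  raw <- differentialTable(a, b)
  expect_equal(raw$n1, c(6L, 6L))
  bBad <- b; bBad$B <- NULL
  expect_error(differentialTable(a, bBad), "differ")
})

test_that("null type-I error is calibrated and BH controls false rejections", {
  nm <- 2000
  d <- data.frame(metabolite = paste0("M", seq_len(nm)), mean = 1, sd = 0.2)
  a <- sampleCohort(d, 10, seed = 101, group = "A")
  b <- sampleCohort(d, 10, seed = 202, group = "B")
  cmp <- differentialTable(a, b)
  expect_lt(abs(mean(cmp$p < 0.05) - 0.05), 0.01)
  expect_lte(mean(cmp$adjusted_p < 0.05), 0.05)
})
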