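# Rank-based population comparisons, box summaries, mixture analysis.

test_that("exact rank-sum p-values match full enumeration", {
  cmp <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(pValue(cmp), 2 / 6, tolerance = 1e-12)
  expect_equal(pValue(cmp), oracleRankSumP(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_identical(cmp@statisticValue, 0)

  set.seed(61)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_equal(pValue(rankSumTest(a, b)), oracleRankSumP(a, b),
                 tolerance = 1e-10, label = sprintf("case %d", i))
  }
})

test_that("normal approximation stays within 0.05 of enumeration for small n", {
  # exhaustive over every achievable U for all group sizes with at least
  # 3 observations per group and n_a + n_b <= 10 (with 1 or 2 observations
  # in a group the continuity-corrected normal approximation is off by up
  # to ~0.13 at extreme U; such sizes always take the exact path anyway)
  for (na in 3:5) for (nb in na:(10 - na)) {
    if (nb < 3) next
    for (U in 0:(na * nb)) {
      # untied integer data realizing exactly this U via the ranks of
      # group a: sum(ranks_a) = U + na(na+1)/2
      shift <- integer(na); left <- U
      for (i in na:1) { s <- min(left, nb); shift[i] <- s; left <- left - s }
      a <- seq_len(na) + shift
      b <- setdiff(seq_len(na + nb), a)
      pApprox <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
      expect_lt(abs(pApprox - oracleRankSumP(a, b)), 0.05,
                label = sprintf("na=%d nb=%d U=%d", na, nb, U))
    }
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(63)
  a <- rlnorm(25); b <- rlnorm(30, 0.4)
  p0 <- pValue(rankSumTest(a, b))
  expect_identical(pValue(rankSumTest(log(a), log(b))), p0)
  expect_identical(pValue(rankSumTest(a^3, b^3)), p0)
  expect_identical(pValue(rankSumTest(exp(a), exp(b))), p0)
})

test_that("identical and degenerate groups are handled", {
  x <- c(1, 2, 3, 4)
  same <- rankSumTest(x, x)
  expect_equal(pValue(same), 1.0, tolerance = 1e-9)
  expect_identical(significanceCode(same), "n.s.")
  expect_false(same@degenerate)

  flat <- rankSumTest(c(2, 2, 2), c(2, 2))
  expect_identical(pValue(flat), 1)
  expect_true(flat@degenerate)
  expect_error(rankSumTest(numeric(), 1:3), "non-empty")
})

test_that("significance codes follow the 0.05 / 0.001 / 0.0001 thresholds", {
  code <- chromobility:::.significanceCode
  expect_identical(code(0.2), "n.s.")
  expect_identical(code(0.049), "*")
  expect_identical(code(0.0009), "**")
  expect_identical(code(0.00009), "***")
  expect_identical(code(0.05), "n.s.")  # boundary: thresholds are strict
})

test_that("box summaries follow the quartile and fence conventions", {
  b <- boxSummary(c(1, 2, 3, 4, 5))
  expect_identical(b@median, 3)
  expect_identical(b@q1, 2)
  expect_identical(b@q3, 4)
  expect_identical(length(b@outliers), 0L)
  expect_identical(c(b@whiskerLow, b@whiskerHigh), c(1, 5))

  o <- boxSummary(c(1, 2, 3, 4, 100))
  expect_identical(o@outliers, 100)
  expect_identical(o@whiskerHigh, 4)

  s <- boxSummary(7)
  expect_true(all(c(s@median, s@q1, s@q3, s@whiskerLow, s@whiskerHigh) == 7))
  expect_identical(length(s@outliers), 0L)
})

test_that("mixture analysis edge fractions behave as contracts say", {
  set.seed(64)
  dam <- rlnorm(120, log(0.088), 0.25)
  und <- rlnorm(120, log(0.049), 0.25)
  expect_error(mixtureAnalysis(dam, und, fractionUndamaged = 1.2), "fraction")

  # fraction 0: mixed is a resample of damaged-only; null calibration
  null0 <- mixtureAnalysis(dam, und, fractionUndamaged = 0,
                           nReplicates = 400L, seed = 7L)
  expect_lt(null0$significantFraction, 0.12)

  # fraction 1 reproduces the damaged-vs-undamaged comparison in kind
  full <- mixtureAnalysis(dam, und, fractionUndamaged = 1,
                          nReplicates = 200L, seed = 7L)
  expect_lt(pValue(full$baseComparison), 0.001)
  expect_gt(full$significantFraction, 0.9)

  # contamination loses power monotonically relative to a full swap
  part <- mixtureAnalysis(dam, und, fractionUndamaged = 0.2,
                          nReplicates = 200L, seed = 7L)
  expect_lt(part$significantFraction, full$significantFraction)
  expect_gt(part$meanMixed, min(part$meanUndamaged, part$meanDamaged))
  expect_lt(part$meanMixed, max(part$meanUndamaged, part$meanDamaged))
})

test_that("identical source populations never exceed the nominal type-I rate", {
  set.seed(65)
  pool <- rlnorm(150, log(0.05), 0.3)
  res <- mixtureAnalysis(pool, pool, fractionUndamaged = 0.2,
                         nReplicates = 400L, seed = 9L)
  expect_lt(res$significantFraction, 0.05 + 2 * sqrt(0.05 * 0.95 / 400) + 0.02)
})
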