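test_that("Welch's t-test matches the reference implementation", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welchT(a, b)
  ref <- t.test(a, b)
  expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res@df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res@pValue, ref$p.value, tolerance = 1e-10)

  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    res <- welchT(x, y)
    ref <- t.test(x, y)
    expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res@pValue, ref$p.value, tolerance = 1e-10)
    # antisymmetry in the sample order
    rev <- welchT(y, x)
    expect_equal(rev@statistic, -res@statistic)
    expect_equal(rev@pValue, res@pValue)
  }
})

test_that("Welch degenerate branches follow the contract", {
  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  flat <- welchT(c(0, 0, 0), c(1, 1, 1))
  expect_true(flat@degenerate)
  expect_equal(flat@pValue, 0)

  equalFlat <- welchT(c(2, 2), c(2, 2))
  expect_true(equalFlat@degenerate)
  expect_equal(equalFlat@pValue, 1)

  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("the paired t-test matches its closed form and handles degeneracy", {
  expect_equal(pairedT(c(1, 2, 3), c(1, 2, 3))@pValue, 1)

  deg <- pairedT(c(2, 3, 4, 5), c(1, 2, 3, 4))  # differences all 1
  expect_true(deg@degenerate)
  expect_equal(deg@pValue, 0)

  set.seed(23)
  a <- rnorm(7, mean = 1); b <- rnorm(7)  # n = 7 pairs
  res <- pairedT(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res@df, 6)
  expect_equal(res@pValue, ref$p.value, tolerance = 1e-10)

  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("group comparisons are made against the intact reference", {
  set.seed(3)
  mkRows <- function(group, combined) {
    data.frame(group = group, sample = paste0(group, seq_along(combined)),
               window = "w01", class_2 = combined, combined = combined)
  }
  sameA <- mkRows("intact", c(0.5, 0.6, 0.7, 0.8))
  sameB <- mkRows("regen", c(0.5, 0.6, 0.7, 0.8))
  res <- compareToIntact(rbind(sameA, sameB), "intact")
  expect_true(all(res$p == 1))
  expect_true(all(res$n_intact == 4) && all(res$n_group == 4))

  shifted <- rbind(mkRows("intact", rnorm(12, 0.5, 0.03)),
                   mkRows("regen", rnorm(12, 0.9, 0.03)))
  res2 <- compareToIntact(shifted, "intact")
  expect_equal(unique(res2$n_intact), 12L)
  expect_true(all(res2$p < 0.05))
  direct <- welchT(shifted$combined[shifted$group == "regen"],
                   shifted$combined[shifted$group == "intact"])
  expect_equal(res2$p[res2$metric == "combined"], direct@pValue)

  res3 <- compareToIntact(shifted, "intact", bh = TRUE)
  expect_true("p_bh" %in% colnames(res3))
  expect_equal(res3$p_bh, p.adjust(res3$p, method = "BH"))

  expect_error(compareToIntact(shifted, "nope"), "not present")
})

test_that("outcome rates are exact fractions that sum to 100", {
  tbl <- table1Outcomes()
  rates <- outcomeRates(tbl)
  expect_equal(rates$regress_pct + rates$bump_pct + rates$limb_pct,
               rep(100, nrow(tbl)))
  # exactness: a condition with all events in one category
  one <- outcomeRates(data.frame(condition = "x", N = 10, regress = 10,
                                 bump = 0, limb = 0))
  expect_identical(unname(unlist(one[, 6:8])), c(100, 0, 0))

  expect_error(outcomeRates(data.frame(condition = "x", N = 0, regress = 0,
                                       bump = 0, limb = 0)), "positive")
  expect_error(outcomeRates(data.frame(condition = "x", N = 5, regress = 1,
                                       bump = 1, limb = 1)), "must equal N")
})

test_that("the Fisher exact test matches enumeration and the reference", {
  expect_equal(fisher2x2(matrix(c(0, 0, 4, 9), 2)), 1)
  expect_equal(fisher2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)

  # limb outcomes of the dorsal wound conditions with and without the
  # opposite-side graft
  dor <- matrix(c(1, 7, 11, 7), 2)
  expect_equal(fisher2x2(dor), bruteFisher2x2(dor), tolerance = 1e-12)
  expect_equal(fisher2x2(dor), fisher.test(dor)$p.value, tolerance = 1e-10)

  set.seed(41)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6), 2)
    p <- fisher2x2(m)
    expect_equal(p, bruteFisher2x2(m), tolerance = 1e-12)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-10)
    # invariance under row and column swaps
    expect_equal(p, fisher2x2(m[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher2x2(m[, 2:1]), tolerance = 1e-12)
  }
})
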