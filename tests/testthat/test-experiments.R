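test_that("percentage compositions reproduce the reference quadruple", {
  expect_identical(compositionFromPercentages(20, 6, 100),
                   c(19L, 1L, 5L, 75L))
  expect_identical(compositionFromPercentages(0, 0, 100),
                   c(0L, 0L, 0L, 100L))
  expect_identical(compositionFromPercentages(100, 100, 50),
                   c(0L, 50L, 0L, 0L))
  expect_error(compositionFromPercentages(120, 6), "percentages")

  # non-negative integers summing to the total, across the sweep grid
  for (sp in c(1, 2, 13, 34, 77)) {
    for (cp in c(0, 3, 6, 13, 50, 100)) {
      q <- compositionFromPercentages(sp, cp, 100)
      expect_true(all(q >= 0L))
      expect_identical(sum(q), 100L)
      expect_identical(q[1] + q[2], as.integer(round(sp)))
    }
  }
})

test_that("exponential fits recover noise-free rates within 1%", {
  for (rate in c(0.01, 0.05, 0.1, 0.2)) {
    df <- data.frame(day = 0:60, n_total = 100 * exp(rate * 0:60))
    f <- fitExponential(df, window = c(0, 60))
    expect_lt(abs(f$rate - rate) / rate, 0.01)
    expect_gt(f$r2, 1 - 1e-9)
  }
  # the default window skips the sub-2x founder stretch
  df <- data.frame(day = 0:100, n_total = 100 * exp(0.05 * 0:100))
  f <- fitExponential(df)
  expect_equal(f$window, c(14, 100))  # first day above 200 cells
  expect_lt(abs(f$rate - 0.05) / 0.05, 0.01)
  # constant series: zero rate by convention, r2 undefined
  const <- data.frame(day = 0:10, n_total = rep(300, 11))
  f <- fitExponential(const, window = c(0, 10))
  expect_identical(f$rate, 0)
  expect_true(is.na(f$r2))
  # degenerate windows are errors
  expect_error(fitExponential(data.frame(day = 0:1, n_total = c(1, 9)),
                              window = c(0, 1)), "fewer than 3")
  bad <- data.frame(day = 0:5, n_total = c(100, 300, 0, 400, 500, 600))
  expect_error(fitExponential(bad, window = c(0, 5)), "zero cell counts")
})

test_that("ensembles are reproducible and fully labelled", {
  p <- smallParams(maxDays = 5L, initCounts = c(2L, 0L, 0L, 8L))
  one <- runEnsemble(p, nReplicates = 1L, baseSeed = 50L)
  expect_identical(nrow(one$series), 6L)  # days 0..5
  expect_identical(unique(one$series$condition), "default")

  a <- runEnsemble(p, nReplicates = 2L, baseSeed = 50L,
                   sweep = list(pProlifProg = c(0.2, 0.8)))
  b <- runEnsemble(p, nReplicates = 2L, baseSeed = 50L,
                   sweep = list(pProlifProg = c(0.2, 0.8)))
  expect_identical(a$series, b$series)
  expect_identical(sort(unique(a$series$seed)), 50:53)
  expect_identical(length(a$snapshots), 2L)

  # composition pseudo-parameters rebalance initCounts
  cmp <- runEnsemble(tumorParams(maxDays = 1L), nReplicates = 1L,
                     baseSeed = 5L, sweep = list(stemPct = c(2, 34),
                                                 ccr5Pct = 13))
  expect_identical(cmp$series$n_stem[cmp$series$day == 0], c(2L, 34L))
})

test_that("ensemble outputs are written and checksummed", {
  out <- file.path(tempdir(), "ens-test")
  unlink(out, recursive = TRUE)
  p <- smallParams(maxDays = 3L, initCounts = c(1L, 0L, 0L, 4L))
  runEnsemble(p, nReplicates = 2L, baseSeed = 9L, outputDir = out)
  expect_true(file.exists(file.path(out, "series_c01_r01.csv")))
  expect_true(file.exists(file.path(out, "mean_curves.csv")))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(summ$n_replicates, 2L)
  expect_true(length(summ$checksums) >= 4L)
  ts <- read.csv(file.path(out, "series_c01_r01.csv"))
  expect_identical(names(ts)[1:10],
    c("day", "n_total", "n_stem", "n_progenitor", "n_ccr5_high",
      "n_quiescent", "n_senescent", "n_hypoxic", "births", "deaths"))
})

test_that("condition comparisons summarize and test against the reference", {
  mk <- function(seedBase) do.call(rbind, lapply(1:3, function(r) {
    set.seed(seedBase + r)
    data.frame(day = 0:10, n_total = round(100 * exp(0.1 * (0:10))) +
                 sample(0:5, 11, TRUE), replicate = r)
  }))
  same <- conditionComparison(list(a = mk(1), b = mk(100)), day = 10)
  expect_lt(abs(same$tests$diff_mean), 10)
  expect_gt(same$tests$p_value, 0.05)

  big <- mk(7); big$n_total <- big$n_total * 3
  comp <- conditionComparison(list(control = mk(1), treated = big),
                              day = 10,
                              alternatives = c(treated = "greater"))
  expect_lt(comp$tests$p_value, 0.01)
  expect_identical(comp$tests$alternative, "greater")
  expect_identical(comp$summary$n_replicates, c(3L, 3L))
  expect_error(conditionComparison(list(a = mk(1)), day = 5), "2")
})
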