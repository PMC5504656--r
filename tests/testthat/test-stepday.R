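test_that("senescent death is a binomial sweep at the configured rate", {
  g <- expand.grid(i = 0:99, j = 0:99, k = 0L)
  cells <- data.frame(i = g$i, j = g$j, k = g$k, lineage = "progenitor",
                      state = "senescent", divisions = 12L)

  # edge rates
  s0 <- simFromCells(cells, tumorParams(pSenescentDeath = 0))
  set.seed(1)
  expect_identical(nCells(applySenescentDeath(s0)), 10000L)
  s1 <- simFromCells(cells, tumorParams(pSenescentDeath = 1))
  set.seed(2)
  expect_identical(nCells(applySenescentDeath(s1)), 0L)

  # default 10%/day, one day
  s <- simFromCells(cells, tumorParams())
  set.seed(303)
  s2 <- stepDay(s)
  frac <- 1 - nCells(s2) / 10000
  expect_lt(abs(frac - 0.10), binomTol(0.10, 10000))
  expect_identical(timeSeries(s2)$deaths[2], 10000L - nCells(s2))
})

test_that("an empty population still advances the clock with zero counts", {
  sim <- simFromCells(data.frame(i = 1, j = 1, k = 1), smallParams())
  sim@cells <- sim@cells[0, , drop = FALSE]
  sim@log <- sim@log[0, ]
  sim@log <- rbind(sim@log, data.frame(day = 0L, n_total = 0L, n_stem = 0L,
    n_progenitor = 0L, n_ccr5_high = 0L, n_quiescent = 0L,
    n_senescent = 0L, n_hypoxic = 0L, births = 0L, deaths = 0L))
  set.seed(1)
  sim2 <- stepDay(sim)
  expect_identical(simDay(sim2), 1L)
  rec <- timeSeries(sim2)[2, ]
  expect_true(all(rec[c("n_total", "births", "deaths")] == 0L))
})

test_that("a lone progenitor with certain division doubles in one day", {
  sim <- oneCellSim(smallParams(pProlifProg = 1))
  set.seed(4)
  sim2 <- stepDay(sim)
  expect_identical(nCells(sim2), 2L)
  expect_identical(timeSeries(sim2)$births[2], 1L)
  expect_true(all(cellTable(sim2)$lineage == "progenitor"))
})

test_that("a fully packed lattice yields no births and all-quiescent cells", {
  p <- tumorParams(dims = c(5L, 5L, 5L), pProlifProg = 1,
                   pSenescentDeath = 0)
  g <- expand.grid(i = 0:4, j = 0:4, k = 0:4)
  sim <- simFromCells(g, p)
  set.seed(5)
  sim2 <- stepDay(sim)
  ts <- timeSeries(sim2)
  expect_identical(ts$births[2], 0L)
  expect_identical(ts$n_quiescent[2], 125L)
  expect_identical(nCells(sim2), 125L)
})

test_that("bookkeeping is exactly conservative and occupancy stays exclusive", {
  p <- smallParams(seed = 77L, maxDays = 25L)
  sim <- initPopulation(p)
  for (d in 1:25) {
    sim <- stepDay(sim)
    expect_true(validObject(sim))  # bounds, exclusivity, state invariants
  }
  ts <- timeSeries(sim)
  expect_identical(diff(ts$n_total), (ts$births - ts$deaths)[-1])
  expect_identical(ts$n_stem + ts$n_progenitor, ts$n_total)
})

test_that("identical parameters and seed give bitwise-identical runs", {
  p <- smallParams(seed = 123L, maxDays = 15L)
  a <- runSimulation(p)
  b <- runSimulation(p)
  expect_identical(timeSeries(a), timeSeries(b))
  expect_identical(a@cells, b@cells)
})
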