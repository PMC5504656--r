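test_that("a progenitor at its division limit senesces instead of dividing", {
  # the 12th division pushes the parent to the limit...
  sim <- oneCellSim(divisions = 11L)
  set.seed(1)
  res <- attemptDivision(sim, 1, forceProb = 1)
  expect_true(res$divided)
  ct <- cellTable(res$sim)
  expect_identical(as.character(ct$state[1]), "senescent")
  # ...after which further attempts produce no daughter
  res2 <- attemptDivision(res$sim, 1, forceProb = 1)
  expect_false(res2$divided)
  expect_identical(nCells(res2$sim), 2L)
  expect_identical(cellTable(res2$sim)$divisions[1], 12L)
})

test_that("a cell with no free Moore neighbor cannot divide", {
  sim <- enclosedSim(smallParams(pProlifProg = 1))
  set.seed(2)
  res <- attemptDivision(sim, 1, forceProb = 1)
  expect_false(res$divided)
  expect_identical(nCells(res$sim), 27L)
})

test_that("stem divisions are symmetric at the configured 5% rate", {
  sim <- oneCellSim(lineage = "stem")
  set.seed(404)
  n <- 10000L
  sym <- vapply(seq_len(n), function(r) {
    res <- attemptDivision(sim, 1, forceProb = 1)
    as.character(cellTable(res$sim)$lineage[2]) == "stem"
  }, logical(1))
  expect_lt(abs(mean(sym) - 0.05), binomTol(0.05, n))
})

test_that("cycle counts: compartment daughters share the post-increment count, stem-derived progenitors start fresh", {
  # progenitor -> progenitor
  sim <- oneCellSim(divisions = 5L)
  set.seed(3)
  res <- attemptDivision(sim, 1, forceProb = 1)
  ct <- cellTable(res$sim)
  expect_identical(ct$divisions, c(6L, 6L))

  # stem -> progenitor (asymmetric): fresh clone founder
  pAsym <- smallParams(pSymmetric = 0)
  simS <- oneCellSim(pAsym, lineage = "stem", divisions = 30L)
  set.seed(4)
  res <- attemptDivision(simS, 1, forceProb = 1)
  ct <- cellTable(res$sim)
  expect_identical(as.character(ct$lineage), c("stem", "progenitor"))
  expect_identical(ct$divisions, c(31L, 0L))
  expect_identical(as.character(ct$state[2]), "proliferative")

  # stem -> stem (symmetric): daughter shares the stem's count
  pSym <- smallParams(pSymmetric = 1)
  simS2 <- oneCellSim(pSym, lineage = "stem", divisions = 7L)
  set.seed(5)
  res <- attemptDivision(simS2, 1, forceProb = 1)
  ct <- cellTable(res$sim)
  expect_identical(as.character(ct$lineage), c("stem", "stem"))
  expect_identical(ct$divisions, c(8L, 8L))

  # a progenitor daughter born at the limit is senescent at birth
  simL <- oneCellSim(divisions = 11L)
  set.seed(6)
  res <- attemptDivision(simL, 1, forceProb = 1)
  ct <- cellTable(res$sim)
  expect_identical(ct$divisions, c(12L, 12L))
  expect_identical(as.character(ct$state), c("senescent", "senescent"))
})

test_that("CCR5 conversion happens only on symmetric divisions, at the microenvironment's rate", {
  # forced conversion on a symmetric division
  p1 <- smallParams(pCcr5Convert = 1)
  set.seed(7)
  res <- attemptDivision(oneCellSim(p1), 1, forceProb = 1)
  expect_identical(as.character(cellTable(res$sim)$ccr5), c("low", "high"))

  # asymmetric stem divisions never convert, even at rate 1
  p2 <- smallParams(pCcr5Convert = 1, pCcr5ConvertHypoxic = 1,
                    pSymmetric = 0)
  set.seed(8)
  res <- attemptDivision(oneCellSim(p2, lineage = "stem"), 1,
                         forceProb = 1)
  expect_identical(as.character(cellTable(res$sim)$ccr5), c("low", "low"))

  # hypoxic conversion rate ~25% among realized divisions
  sim <- oneCellSim()
  set.seed(505)
  got <- integer(0)
  while (length(got) < 4000L) {
    res <- attemptDivision(sim, 1, hypoxic = TRUE, forceProb = 1)
    if (res$divided)
      got <- c(got, as.integer(
        as.character(cellTable(res$sim)$ccr5[2]) == "high"))
  }
  expect_lt(abs(mean(got) - 0.25), binomTol(0.25, length(got)))
})

test_that("hypoxia halves the division probability", {
  sim <- oneCellSim()
  set.seed(9)
  n <- 4000L
  div <- vapply(seq_len(n), function(r)
    attemptDivision(sim, 1, hypoxic = TRUE, forceProb = 1)$divided,
    logical(1))
  expect_lt(abs(mean(div) - 0.5), binomTol(0.5, n))
})

test_that("one progenitor clone is capped at 2^divisionLimit cells", {
  p <- tumorParams(dims = c(30L, 30L, 30L), pProlifProg = 1,
                   divisionLimit = 3L, pSenescentDeath = 0,
                   stepsCcr5Low = 0L, stepsCcr5High = 0L)
  sim <- oneCellSim(p, at = c(15L, 15L, 15L))
  set.seed(10)
  for (d in 1:10) sim <- stepDay(sim)
  expect_identical(nCells(sim), 8L)  # 2^3
  expect_true(all(cellTable(sim)$state == "senescent"))
})
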