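test_that("daily step counts follow CCR5 class, hypoxia and maraviroc", {
  p <- tumorParams()
  expect_identical(migrationSteps(p, "low"), 1L)
  expect_identical(migrationSteps(p, "high"), 2L)
  expect_identical(migrationSteps(p, "low", hypoxic = TRUE), 3L)
  expect_identical(migrationSteps(p, "high", hypoxic = TRUE), 6L)

  pm <- modifyParams(p, maravirocOn = TRUE)
  expect_identical(migrationSteps(pm, "high"), 1L)
  expect_identical(migrationSteps(pm, "high", hypoxic = TRUE), 3L)
  expect_identical(migrationSteps(pm, "low"), 1L)

  # hard cap at 20 steps/day
  pf <- modifyParams(p, stepsCcr5High = 10L)
  expect_identical(migrationSteps(pf, "high", hypoxic = TRUE), 20L)
})

test_that("a fully surrounded cell cannot move", {
  sim <- enclosedSim()
  set.seed(1)
  res <- migrateCell(sim, 1, 5)
  expect_identical(res$sim@cells[1, 1:3], sim@cells[1, 1:3])
  expect_identical(nrow(res$path), 1L)
})

test_that("single steps are uniform over the 26 Moore directions", {
  sim <- oneCellSim()
  start <- sim@cells[1, 1:3]
  set.seed(202)
  n <- 10400L
  moves <- t(vapply(seq_len(n), function(r) {
    migrateCell(sim, 1, 1)$sim@cells[1, 1:3] - start
  }, integer(3)))
  expect_true(all(rowSums(abs(moves)) > 0))       # always moves
  expect_true(all(abs(moves) <= 1))               # one voxel only
  key <- paste(moves[, 1], moves[, 2], moves[, 3])
  counts <- table(key)
  expect_identical(length(counts), 26L)
  chi <- suppressWarnings(chisq.test(as.integer(counts)))
  expect_gt(chi$p.value, 1e-3)
})

test_that("multi-step walks never backtrack to the previous voxel", {
  sim <- oneCellSim()
  set.seed(7)
  for (r in 1:300) {
    path <- migrateCell(sim, 1, 3)$path
    expect_identical(nrow(path), 4L)
    for (s in 3:nrow(path)) {
      expect_false(all(path[s, ] == path[s - 2, ]))
    }
  }
})

test_that("maraviroc makes CCR5-high daily displacement match CCR5-low", {
  dispOneDay <- function(ccr5, maraviroc, seed) {
    p <- smallParams(maravirocOn = maraviroc)
    sim <- oneCellSim(p, ccr5 = ccr5)
    start <- sim@cells[1, 1:3]
    set.seed(seed)
    vapply(1:2000, function(r) {
      steps <- migrationSteps(p, ccr5)
      pos <- migrateCell(sim, 1, steps)$sim@cells[1, 1:3]
      sqrt(sum((pos - start)^2))
    }, numeric(1))
  }
  dHighM <- dispOneDay("high", TRUE, 31)
  dLow <- dispOneDay("low", FALSE, 32)
  expect_identical(migrationSteps(smallParams(maravirocOn = TRUE), "high"),
                   migrationSteps(smallParams(), "low"))
  ks <- suppressWarnings(ks.test(dHighM, dLow))
  expect_gt(ks$p.value, 1e-3)
  # and without maraviroc, CCR5-high cells displace farther
  dHigh <- dispOneDay("high", FALSE, 33)
  expect_gt(mean(dHigh), mean(dLow))
})
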