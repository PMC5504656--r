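# Oracle shapes are digitized analytic solids; expected values are
# either closed-form or brute-force enumerations computed in-line.

test_that("surface extraction finds the outer shell", {
  # single voxel: its own surface
  single <- tumorMask(cbind(3L, 3L, 3L), dims = c(7L, 7L, 7L))
  expect_identical(extractSurface(single), single@coords)

  # solid 5x5x5 cube: 98 shell voxels (125 - 27 interior)
  cube <- tumorMask(as.matrix(expand.grid(1:5, 1:5, 1:5)))
  surf <- extractSurface(cube)
  expect_identical(nrow(surf), 98L)
  expect_true(all(apply(surf, 1, function(v) any(v == 1 | v == 5))))

  # 1xAxN rod: every voxel touches free space
  rod <- generateFixture("rod", length = 16)
  expect_identical(nrow(extractSurface(rod)), 16L)

  # a mask that fills its lattice has no free-facing surface
  full <- tumorMask(as.matrix(expand.grid(0:2, 0:2, 0:2)),
                    dims = c(3L, 3L, 3L))
  expect_identical(nrow(extractSurface(full)), 0L)
})

test_that("interior cavities are not periphery", {
  b <- generateFixture("ball", radius = 6)
  center <- colMeans(b@coords)
  keep <- rowSums(sweep(b@coords, 2, center)^2) > 0.1  # drop center voxel
  hollow <- tumorMask(b@coords[keep, , drop = FALSE], dims = b@dims)
  surf <- extractSurface(hollow)
  dc <- sqrt(rowSums(sweep(surf, 2, center)^2))
  expect_gt(min(dc), 2)  # no cavity-wall voxel reported as surface
  expect_identical(nrow(surf), nrow(extractSurface(b)))
})

test_that("radial profiles measure surface-to-centroid distances", {
  single <- tumorMask(cbind(2L, 2L, 2L), dims = c(5L, 5L, 5L))
  prof <- radialProfile(single)
  expect_identical(prof$distances, 0)

  two <- tumorMask(rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)))
  prof <- radialProfile(two)
  expect_equal(prof$centroid, c(1.5, 1, 1))
  expect_equal(prof$distances, c(0.5, 0.5))

  # digitized ball of radius 10: distances match a brute-force
  # enumeration of the ball's shell (in-ball voxels with an out-of-ball
  # Moore neighbor; for a convex solid this is the outer boundary)
  b <- generateFixture("ball", radius = 10)
  d <- sort(radialProfile(b)$distances)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  rel <- sweep(b@coords, 2, colMeans(b@coords))
  onShell <- apply(rel, 1, function(v)
    any(colSums((v + t(off))^2) > 100))
  expect_equal(d, sort(sqrt(rowSums(rel[onShell, ]^2))))
})

test_that("ball metrics approach the analytic sphere as the radius grows", {
  # brute-force shell statistics are the oracle at every radius; the
  # +-0.08 band around the perfect sphere is reached by radius ~10
  # (smaller digitized balls have coarser shells)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  shellStats <- function(R) {
    g <- as.matrix(expand.grid(-R:R, -R:R, -R:R))
    g <- g[rowSums(g^2) <= R^2, ]
    onShell <- apply(g, 1, function(v)
      any(colSums((v + t(off))^2) > R^2))
    d <- sqrt(rowSums(g[onShell, ]^2))
    list(cr = mean(d) / (3 * nrow(g) / (4 * pi))^(1 / 3),
         cl = mean(d) / max(d),
         moi = sqrt(mean((d - mean(d))^2)) / mean(d))
  }
  err <- sapply(c(5, 10, 15), function(R) {
    b <- generateFixture("ball", radius = R)
    oracle <- shellStats(R)
    expect_equal(chordRatio(b), oracle$cr, tolerance = 1e-10)
    expect_equal(chordLength(b), oracle$cl, tolerance = 1e-10)
    expect_equal(momentOfInertia(b), oracle$moi, tolerance = 1e-10)
    abs(chordRatio(b) - 1)
  })
  expect_true(all(diff(err) < 0))  # discretization error shrinks with R
  for (R in c(10, 15)) {
    b <- generateFixture("ball", radius = R)
    expect_lt(abs(chordRatio(b) - 1), 0.08)
    expect_lt(abs(chordLength(b) - 1), 0.08)
    expect_lt(momentOfInertia(b), 0.1)
    expect_gt(circularity(b), 10)
  }
})

test_that("rod metrics match the uniform radial profile", {
  rod <- generateFixture("rod", length = 64)
  # distances are |k - 31.5| for k = 0..63: mean 16, max 31.5
  d <- abs(seq_len(64) - 32.5)
  mu <- mean(d); sdev <- sqrt(mean((d - mu)^2))
  expect_equal(chordRatio(rod), mu / (3 * 64 / (4 * pi))^(1 / 3),
               tolerance = 1e-10)
  expect_gt(chordRatio(rod), 6)
  expect_equal(chordLength(rod), mu / max(d), tolerance = 1e-10)
  expect_equal(chordLength(rod), 0.5079, tolerance = 1e-3)
  expect_equal(momentOfInertia(rod), sdev / mu, tolerance = 1e-10)
  expect_equal(momentOfInertia(rod), 0.577, tolerance = 1e-3)
  expect_equal(circularity(rod), mu / sdev, tolerance = 1e-10)
  expect_equal(circularity(rod), 1.733, tolerance = 1e-3)
})

test_that("circularity is the exact reciprocal of the moment of inertia", {
  for (mask in list(generateFixture("ball", radius = 7),
                    generateFixture("rod", length = 40),
                    generateFixture("ellipsoid", axes = c(12, 6, 6)))) {
    expect_equal(circularity(mask) * momentOfInertia(mask), 1,
                 tolerance = 1e-12)
  }
})

test_that("elongation drives the metrics in the finger-like direction", {
  aspects <- c(1, 2, 4, 8)
  masks <- lapply(aspects, function(a)
    generateFixture("ellipsoid", axes = c(6 * a, 6, 6)))
  cr <- vapply(masks, chordRatio, numeric(1))
  cl <- vapply(masks, chordLength, numeric(1))
  moi <- vapply(masks, momentOfInertia, numeric(1))
  expect_true(all(diff(cr) > 0))
  expect_true(all(diff(moi) > 0))
  expect_true(all(diff(cl) < 0))
})

test_that("metrics are invariant to translation and axis permutation", {
  base <- generateFixture("ellipsoid", axes = c(10, 5, 4))
  vals <- function(m) c(chordRatio(m), chordLength(m), momentOfInertia(m),
                        fractalDimension(m)$dimension)
  ref <- vals(base)
  shifted <- tumorMask(sweep(base@coords, 2, c(7L, 3L, 9L), "+"))
  expect_equal(vals(shifted), ref, tolerance = 1e-12)
  permuted <- tumorMask(base@coords[, c(3, 1, 2)])
  expect_equal(vals(permuted), ref, tolerance = 1e-12)
})

test_that("box counting matches closed-form counts and known dimensions", {
  # rod of 64: N(s) = 64/s exactly, slope exactly 1
  rod <- generateFixture("rod", length = 64)
  fd <- fractalDimension(rod)
  expect_identical(fd$counts$n, 64 / fd$counts$size)
  expect_equal(fd$dimension, 1, tolerance = 1e-12)
  expect_equal(fd$r2, 1, tolerance = 1e-12)

  # 64^3 cube shell: for s | 64, boxes missing the shell are exactly the
  # (64/s - 2)^3 boxes interior on every axis, so
  # N(s) = (64/s)^3 - (64/s - 2)^3 (closed form, independent oracle)
  shell <- generateFixture("cube_shell", length = 64)
  fd <- fractalDimension(shell)
  m <- 64 / fd$counts$size
  expect_identical(fd$counts$n, m^3 - (m - 2)^3)
  oracle <- lm(log(m^3 - (m - 2)^3) ~ log(1 / fd$counts$size))
  expect_equal(fd$dimension, unname(coef(oracle)[2]), tolerance = 1e-10)
  # at scales fine relative to the cavity the slope is the surface's ~2;
  # coarse boxes see the enclosed volume and steepen the overall fit
  fine <- lm(log(n) ~ log(1 / size), data = fd$counts[1:3, ])
  expect_lt(abs(unname(coef(fine)[2]) - 2), 0.15)
  expect_gt(fd$dimension, 2)
  expect_lt(fd$dimension, 3)
})

test_that("undefined metrics are signalled, not fabricated", {
  single <- tumorMask(cbind(2L, 2L, 2L), dims = c(5L, 5L, 5L))
  expect_true(is.na(chordLength(single)))
  expect_true(is.na(momentOfInertia(single)))
  sr <- shapeReport(single)
  expect_true(is.na(sr@chordLength))
  expect_identical(sr@nCells, 1L)
})

test_that("disconnected tumors can be analyzed per component", {
  two <- generateFixture("two_clusters", radius = 10, separation = 30)
  comps <- connectedComponents(two)
  expect_length(comps, 2L)
  expect_identical(nCells(comps[[1]]),
                   nCells(generateFixture("ball", radius = 10)))
  df <- shapeReport(two, perComponent = TRUE)
  expect_identical(nrow(df), 2L)
  expect_true(all(abs(df$chord_ratio - 1) < 0.08))
  # the union, by contrast, is strongly non-spherical
  expect_gt(chordRatio(two), 1.3)
})
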