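test_that("rasterization fills integer-aligned shapes exactly", {
  sq <- squarePoly(0, 0, 10)
  expect_equal(sum(maskGrid(rasterize(sq, 100, 100))), 100L)
  expect_equal(sum(maskGrid(rasterize(list(), 50, 40))), 0L)
  expect_error(rasterize(sq, -1, 10), "positive")
  expect_error(rasterize(rbind(c(0, 0), c(1, 1)), 10, 10), "3 vertices")
})

test_that("rasterization agrees exactly with the point-in-polygon oracle", {
  set.seed(11)
  for (rep in 1:3) {
    # random (generally non-convex) 12-gon
    ang <- sort(runif(12, 0, 2 * pi))
    rad <- runif(12, 5, 28)
    poly <- cbind(32 + rad * cos(ang), 32 + rad * sin(ang))
    grid <- maskGrid(rasterize(poly, 64, 64))
    oracle <- matrix(FALSE, 64, 64)
    for (i in 1:64) for (j in 1:64)
      oracle[i, j] <- pipOracle(j - 0.5, i - 0.5, poly)
    expect_identical(grid, oracle)
  }
})

test_that("dice matches closed forms and is a proper overlap score", {
  a <- rasterize(squarePoly(0, 0, 10), 100, 100)
  b <- rasterize(squarePoly(5, 0, 10), 100, 100)
  c <- rasterize(squarePoly(40, 40, 10), 100, 100)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, c), 0)
  expect_equal(dice(a, b), 0.5)                     # 2*50/(100+100)
  expect_equal(dice(a, b), dice(b, a))
  empty <- rasterize(list(), 100, 100)
  expect_equal(dice(a, empty), 0)
  expect_true(is.na(dice(empty, empty)))
  expect_equal(dice(empty, empty, bothEmpty = 1), 1)
  expect_error(dice(a, rasterize(list(), 50, 50)), "dimension mismatch")

  # disks r=20, centres 10 px apart, vs the analytic lens-area Dice
  da <- rasterize(diskPolygon(95, 100, 20, 256), 200, 200)
  db <- rasterize(diskPolygon(105, 100, 20, 256), 200, 200)
  expect_lt(abs(dice(da, db) - analyticDiceDisks(20, 20, 10)), 0.01)
})

test_that("directed Hausdorff equals the exhaustive double loop", {
  ch <- resampleChain(rbind(c(0, 10), c(50, 10)), 0.5)
  expect_equal(directedHausdorff(ch, ch), 0)
  ch2 <- resampleChain(rbind(c(0, 30), c(50, 30)), 0.5)
  expect_equal(directedHausdorff(ch, ch2), 20)
  set.seed(22)
  for (rep in 1:5) {
    a <- matrix(runif(30, 0, 100), 15, 2)
    b <- matrix(runif(30, 0, 100), 15, 2)
    expect_equal(directedHausdorff(a, b), bruteDirectedHausdorff(a, b))
    expect_equal(directedHausdorff(b, a), bruteDirectedHausdorff(b, a))
  }
  expect_error(directedHausdorff(matrix(numeric(0), 0, 2), a), "empty")
})

test_that("hausdorff score normalizes, symmetrizes and clamps correctly", {
  a <- resampleChain(rbind(c(0, 0), c(100, 0)), 0.5)
  b <- resampleChain(rbind(c(0, 100), c(100, 100)), 0.5)
  expect_equal(hausdorffScore(a, a, 100, 100), 0)
  expect_equal(hausdorffScore(a, b, 100, 100), 1)   # separation = max side
  expect_lt(hausdorffScore(a, b, 100, 100, denominator = "diagonal"), 1)
  # short chain lying on a long chain: one-directional distance vanishes
  long <- resampleChain(rbind(c(0, 50), c(100, 50)), 0.5)
  short <- resampleChain(rbind(c(40, 50), c(60, 50)), 0.5)
  expect_equal(hausdorffScore(short, long, 100, 100, symmetrize = FALSE), 0)
  expect_gt(hausdorffScore(short, long, 100, 100, symmetrize = TRUE), 0)
  expect_equal(directedHausdorff(chainPoints(long), chainPoints(short)),
               bruteDirectedHausdorff(chainPoints(long), chainPoints(short)))
})

test_that("resampling bounds consecutive gaps and stays on the curve", {
  expect_equal(nrow(chainPoints(resampleChain(rbind(c(0, 0), c(10, 0)), 1))), 11L)
  ends <- chainPoints(resampleChain(rbind(c(0, 0), c(3, 4)), 99))
  expect_equal(ends, rbind(c(0, 0), c(3, 4)), ignore_attr = TRUE)
  L <- rbind(c(0, 0), c(10, 0), c(10, 10))
  ch <- chainPoints(resampleChain(L, 0.5))
  gaps <- sqrt(rowSums(diff(ch)^2))
  expect_true(all(gaps <= 0.5 + 1e-12))
  # every point of the underlying curve is within half a gap of a sample
  dense <- chainPoints(resampleChain(L, 0.01))
  expect_lte(directedHausdorff(dense, ch), 0.25)
  expect_error(resampleChain(rbind(c(1, 1)), 0.5), ">= 2 vertices")
  expect_error(resampleChain(L, 0), "spacing")
})

test_that("symmetric Hausdorff behaves as a metric and is rigid-motion stable", {
  set.seed(33)
  symH <- function(a, b) max(directedHausdorff(a, b), directedHausdorff(b, a))
  for (rep in 1:20) {
    a <- matrix(runif(20, 0, 50), 10, 2)
    b <- matrix(runif(20, 0, 50), 10, 2)
    c <- matrix(runif(20, 0, 50), 10, 2)
    expect_gte(symH(a, b), 0)
    expect_equal(symH(a, b), symH(b, a))
    expect_equal(symH(a, a), 0)
    expect_lte(symH(a, c), symH(a, b) + symH(b, c) + 1e-12)
  }
  a <- resampleChain(rbind(c(10, 10), c(40, 30)), 0.5)
  b <- resampleChain(rbind(c(12, 25), c(45, 18)), 0.5)
  shift <- function(ch, dx, dy) {
    m <- chainPoints(ch); m[, 1] <- m[, 1] + dx; m[, 2] <- m[, 2] + dy; m
  }
  expect_equal(hausdorffScore(a, b, 100, 100),
               hausdorffScore(shift(a, 7, -3), shift(b, 7, -3), 100, 100))
})
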