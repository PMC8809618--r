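test_that("resampling keeps exact grid samples and refuses interpolation", {
  tr <- randomToyTraj(n = 601, dt = 1, seed = 2)
  expect_identical(positions(resamplePositions(tr, 1)), positions(tr))
  fpm <- resamplePositions(tr, 60)
  expect_identical(sampleTimes(fpm), seq(0, 600, by = 60))
  expect_identical(positions(fpm), positions(tr)[seq(1, 601, by = 60), ])
  tr2 <- makeTraj(seq(0, 20, by = 2), rnorm(11), rnorm(11),
                  arenaRadius = 100)
  expect_error(resamplePositions(tr2, 7), "not a multiple")
})

test_that("displacements are Euclidean distances with exclusion flags", {
  tr <- makeTraj(c(0, 60), c(0, 300), c(0, 400), arenaRadius = 1000)
  ds <- displacementSeries(tr, 60)
  expect_equal(displacements(ds), 500)
  still <- makeTraj(0:10, rep(5, 11), rep(-3, 11), arenaRadius = 10)
  expect_true(all(displacements(displacementSeries(still, 1)) == 0))
  # brute-force oracle on a random 10-minute trajectory
  tr <- randomToyTraj(n = 601, dt = 1, seed = 9)
  p <- positions(tr)
  for (iv in c(1, 60)) {
    ds <- displacementSeries(tr, iv)
    idx <- seq(1, 601, by = iv)
    brute <- sqrt(diff(p[idx, 1])^2 + diff(p[idx, 2])^2)
    expect_equal(displacements(ds), brute)
    expect_identical(sampleTimes(ds), sampleTimes(tr)[idx[-length(idx)]])
  }
})

test_that("entries spanning an exclusion window are flagged, not dropped", {
  ew <- cbind(start = 120, end = 240)
  tr <- randomToyTraj(n = 601, dt = 1, seed = 4, ew = ew)
  ds <- displacementSeries(tr, 60)
  expect_identical(length(displacements(ds)), 10L)
  expect_identical(excludedMask(ds), sampleTimes(ds) < 240 &
                     sampleTimes(ds) + 60 > 120)
  # boundary-touching entries are retained
  expect_false(excludedMask(ds)[sampleTimes(ds) == 240])
})

test_that("net displacement uses acquired frames and obeys the triangle chain", {
  loop <- makeTraj(c(0, 30, 60), c(0, 300, 0), c(0, 400, 0),
                   arenaRadius = 1000)
  expect_equal(netDisplacement(loop, 0, 60), 0)
  line <- makeTraj(0:10, (0:10) * 30, rep(0, 11), arenaRadius = 1000)
  ds <- displacementSeries(line, 1)
  expect_equal(netDisplacement(line, 0, 10), sum(displacements(ds)))
  expect_error(netDisplacement(line, 5, 5), "t0")
  expect_error(netDisplacement(line, -5, 5), "span")
  # finer total >= coarser total >= net over random windows
  tr <- randomToyTraj(n = 1201, dt = 1, seed = 12)
  for (w in list(c(0, 300), c(120, 720), c(600, 1200))) {
    fine <- displacementSeries(tr, 1)
    coarse <- displacementSeries(tr, 60)
    inw <- function(ds, w) {
      sel <- sampleTimes(ds) >= w[1] & sampleTimes(ds) < w[2]
      sum(displacements(ds)[sel])
    }
    net <- netDisplacement(tr, w[1], w[2])
    expect_gte(inw(fine, w), inw(coarse, w) - 1e-9)
    expect_gte(inw(coarse, w), net - 1e-9)
  }
})

test_that("block totals sum retained entries in mm with exclusion bookkeeping", {
  # 180 one-minute displacements of 1000 um in one 3-h block
  t <- seq(0, 180 * 60 - 1, by = 60)
  ds <- makeDS(t, rep(1000, 180), 60)
  bs <- blockTotals(ds, 10800)
  expect_equal(totals(bs), 180)
  expect_identical(nContributing(bs), 180L)
  # 30 min of the block excluded
  ds2 <- makeDS(t, rep(1000, 180), 60, excluded = t < 1800)
  bs2 <- blockTotals(ds2, 10800)
  expect_equal(totals(bs2), 150)
  expect_identical(nContributing(bs2), 150L)
  expect_error(blockTotals(ds, 30), "blockDuration")
})

test_that("block totals match brute-force masked sums on simulated data", {
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 8L), 0)
  ds <- displacementSeries(tr, 60)
  bs <- blockTotals(ds, 10800)
  d <- displacements(ds)
  tt <- sampleTimes(ds)
  keep <- !excludedMask(ds)
  for (k in seq_along(totals(bs))) {
    lo <- blockStarts(bs)[k]
    sel <- keep & tt >= lo & tt < lo + 10800
    expect_equal(totals(bs)[k], sum(d[sel]) / 1000)
    expect_identical(nContributing(bs)[k], sum(sel))
  }
})

test_that("block totals are additive and monotone under exclusions", {
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 13L), 0)
  ds <- displacementSeries(tr, 60)
  b3 <- blockTotals(ds, 10800)
  b15 <- blockTotals(ds, 5400)
  resummed <- colSums(matrix(totals(b15), nrow = 2))
  expect_equal(resummed, totals(b3))
  # adding an exclusion window never increases any block total
  ds2 <- ds
  ds2@excluded <- ds@excluded | (sampleTimes(ds) >= 7200 &
                                 sampleTimes(ds) < 9000)
  expect_true(all(totals(blockTotals(ds2, 10800)) <=
                  totals(b3) + 1e-12))
})

test_that("daily totals are day-anchored sums consistent with blocks", {
  t <- seq(0, 86400 * 2 - 60, by = 60)
  ds <- makeDS(t, rep(1, length(t)), 60)   # 1 um per minute
  dt <- dailyTotals(ds)
  expect_identical(dt$day, c(1L, 2L))
  expect_equal(dt$total_mm, rep(1440 / 1000, 2))
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 21L), 0)
  dsr <- displacementSeries(tr, 60)
  expect_equal(dailyTotals(dsr)$total_mm, sum(totals(blockTotals(dsr))))
})
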