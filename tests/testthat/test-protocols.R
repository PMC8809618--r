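test_that("snapshot at the native interval reproduces the displacement series", {
  tr <- randomToyTraj(n = 301, dt = 60, step = 30, seed = 3)
  ss <- scoreSingleSnapshot(tr, 60)
  ds <- displacementSeries(tr, 60)
  expect_equal(scores(ss), displacements(ds) / 1000)
  expect_identical(sampleTimes(ss), sampleTimes(ds))
  still <- makeTraj(seq(0, 600, 60), rep(1, 11), rep(2, 11),
                    arenaRadius = 10)
  expect_true(all(scores(scoreSingleSnapshot(still, 120)) == 0))
  expect_error(scoreSingleSnapshot(still, 1200), "span")
})

test_that("snapshot timepoints inside exclusion windows are dropped", {
  ew <- cbind(start = 0, end = 1800)
  tr <- randomToyTraj(n = 7201, dt = 1, seed = 5, ew = ew)
  ss <- scoreSingleSnapshot(tr, 900)
  # images at 900 s (inside the window) are unusable; scores touching them go
  expect_false(any(sampleTimes(ss) %in% c(0, 900)))
  expect_true(1800 %in% sampleTimes(ss))
})

test_that("daily video sums within-bout 1-fpm movement and shifts off stimuli", {
  # uniform 1000 um/min for a full day at 1 fpm
  t <- seq(0, 86400, by = 60)
  tr <- makeTraj(t, t / 60 * 1000, rep(0, length(t)),
                 arenaRadius = 2 * 86400 / 60 * 1000)
  dv <- scoreDailyVideo(tr, 1, 900)
  expect_equal(scores(dv), 15)            # 15 mm in a 15-min bout
  expect_identical(sampleTimes(dv), 0)
  # an exclusion window at the day boundary shifts the bout, not drops it
  ew <- cbind(start = 0, end = 1800)
  tr2 <- makeTraj(t, t / 60 * 1000, rep(0, length(t)),
                  arenaRadius = 2 * 86400 / 60 * 1000, ew = ew)
  dv2 <- scoreDailyVideo(tr2, 1, 900)
  expect_identical(sampleTimes(dv2), 1800)
  expect_equal(scores(dv2), 15)
})

test_that("a 24-hour bout reduces daily video to the daily totals", {
  tr <- randomToyTraj(n = 1441, dt = 60, step = 200, radius = 5000, seed = 6)
  dv <- scoreDailyVideo(tr, 1, 86400)
  dt <- dailyTotals(displacementSeries(tr, 60))
  expect_equal(scores(dv), dt$total_mm)
})

test_that("hybrid bouts sum pairwise image displacements", {
  # collinear constant velocity: 100 um/min -> 1.8 mm per 18-min bout
  t <- seq(0, 4 * 10800, by = 60)
  tr <- makeTraj(t, t / 60 * 100, rep(0, length(t)),
                 arenaRadius = 1e7)
  hy <- scoreHybrid(tr)
  expect_equal(scores(hy), rep(100 * 18 / 1000, length(scores(hy))))
  hy9 <- scoreHybrid(tr, imagesPerBout = 9)
  expect_equal(scores(hy9)[1], 100 * 24 / 1000)
  # two images per bout reduces to a single snapshot at the spacing
  tr2 <- randomToyTraj(n = 10801, dt = 1, seed = 11)
  hy2 <- scoreHybrid(tr2, imagesPerBout = 2, intraBoutSpacing = 180,
                     interTimepointInterval = 3600)
  snap <- scoreSingleSnapshot(tr2, 180)
  m <- match(sampleTimes(hy2), sampleTimes(snap))
  expect_equal(scores(hy2), scores(snap)[m])
  # brute-force oracle on simulated data
  tr3 <- simulateIndividual(testConfig(nDays = 1, seed = 31L), 0)
  hy3 <- scoreHybrid(tr3)
  p <- positions(tr3)
  tt <- sampleTimes(tr3)
  for (k in seq_along(sampleTimes(hy3))) {
    imgT <- sampleTimes(hy3)[k] + (0:6) * 180
    ii <- match(imgT, tt)
    expect_equal(scores(hy3)[k],
                 sum(sqrt(diff(p[ii, 1])^2 + diff(p[ii, 2])^2)) / 1000)
  }
  expect_error(scoreHybrid(tr, intraBoutSpacing = 90), "multiple")
})

test_that("protocol scores never exceed the gold-standard path length", {
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 17L), 0)
  fine <- displacementSeries(tr, 60)
  d <- displacements(fine)
  tt <- sampleTimes(fine)
  specs <- list(singleSnapshotProtocol(900), dailyVideoProtocol(1),
                hybridProtocol())
  for (spec in specs) {
    ss <- scoreProtocol(tr, spec)
    period <- switch(protocolKind(ss), single_snapshot = 900,
                     daily_video = 86400, hybrid_multipass = 10800)
    for (k in seq_along(scores(ss))) {
      t0 <- sampleTimes(ss)[k]
      sel <- tt >= t0 & tt < t0 + period
      expect_lte(scores(ss)[k], sum(d[sel]) / 1000 + 1e-9)
    }
  }
})

test_that("the protocol sweep reports fidelity and decline per individual", {
  cohort <- simulateCohort(testConfig(nDays = 2, seed = 19L), 3)
  sw <- protocolSweep(cohort, list(continuousProtocol(),
                                   singleSnapshotProtocol(900),
                                   hybridProtocol()))
  expect_identical(nrow(sw), 9L)
  cont <- sw[sw$protocol == "continuous", ]
  expect_equal(cont$fidelity_r2, rep(1, 3))
  expect_true(all(is.finite(sw$fidelity_r2)))
  expect_true(is.logical(sw$decline_detected))
})
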