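test_that("simulation is deterministic and substreams are order-independent", {
  cfg <- testConfig(nDays = 1)
  a <- simulateIndividual(cfg, 3)
  b <- simulateIndividual(cfg, 3)
  expect_identical(positions(a), positions(b))
  expect_identical(sampleTimes(a), sampleTimes(b))
  cohort <- simulateCohort(cfg, 4)
  expect_identical(positions(cohort[[4]]), positions(a))
  expect_identical(positions(cohort[[1]]),
                   positions(simulateIndividual(cfg, 0)))
  other <- simulateIndividual(generatorConfig(nDays = 1, seed = 99L), 3)
  expect_false(identical(positions(a), positions(other)))
})

test_that("trajectories respect confinement and the speed bound", {
  cfg <- testConfig(nDays = 1, seed = 2L)
  cohort <- simulateCohort(cfg, 3)
  for (tr in cohort) {
    p <- positions(tr)
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    expect_lte(max(r), arenaRadius(tr) * (1 + 1e-9))
    step <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    expect_lte(max(step) / cfg@frameInterval, 500 + 1e-9)
  }
})

test_that("zero activity scale yields a perfectly stationary animal", {
  cfg <- testConfig(nDays = 1, activeSpeedScale = 0)
  tr <- simulateIndividual(cfg, 0)
  p <- positions(tr)
  expect_identical(length(unique(p[, 1])), 1L)
  expect_identical(length(unique(p[, 2])), 1L)
  ds <- displacementSeries(tr, 60)
  expect_identical(sum(displacements(ds)), 0)
})

test_that("trajectory geometry matches the configuration", {
  cfg <- testConfig(nDays = 2, seed = 3L)
  tr <- simulateIndividual(cfg, 1)
  tt <- sampleTimes(tr)
  expect_identical(tt[1], 0)
  expect_identical(tt[length(tt)], 2 * 86400)
  expect_identical(unique(diff(tt)), cfg@frameInterval)
  ew <- excludedWindows(tr)
  expect_identical(nrow(ew), sum(cfg@stimTimes <= 2 * 86400))
  expect_true(all(ew[, 2] - ew[, 1] <= 1800 + 1e-9))
  expect_true(all(ew[, 1] %in% cfg@stimTimes))
})

test_that("per-minute path length always bounds per-minute net displacement", {
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 7L), 0)
  tt <- sampleTimes(tr)
  p <- positions(tr)
  for (m in seq(0, 86340, by = 600)) {
    sel <- which(tt >= m & tt <= m + 60)
    tot <- sum(sqrt(diff(p[sel, 1])^2 + diff(p[sel, 2])^2))
    net <- sqrt((p[sel[length(sel)], 1] - p[sel[1], 1])^2 +
                (p[sel[length(sel)], 2] - p[sel[1], 2])^2)
    expect_gte(tot, net - 1e-9)
  }
})

test_that("invalid generator configurations are rejected by field name", {
  expect_error(generatorConfig(arenaRadius = -1), "arenaRadius")
  expect_error(generatorConfig(frameInterval = 0), "frameInterval")
  expect_error(generatorConfig(turningKappa = -2), "turningKappa")
  expect_error(generatorConfig(stateTransitionRates = c(roamToDwell = 0.5)),
               "stateTransitionRates")
  expect_error(simulateCohort(testConfig(), 0), "n")
  expect_error(simulateIndividual(testConfig(), -1), "individualIndex")
})
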