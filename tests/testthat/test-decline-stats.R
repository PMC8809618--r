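test_that("decline fits recover exact and degenerate relationships", {
  expect_warning(fit <- fitDecline(c(0, 1, 2), values = c(1, 3, 5)),
                 "perfect")
  expect_equal(declineSlope(fit), 2)
  expect_equal(fit@intercept, 1)
  expect_equal(rSquared(fit), 1)
  expect_equal(pValue(fit), 0)
  expect_warning(flat <- fitDecline(c(0, 1, 2, 3), values = rep(4, 4)),
                 "constant")
  expect_equal(declineSlope(flat), 0)
  expect_equal(rSquared(flat), 0)
  expect_equal(pValue(flat), 1)
  expect_error(fitDecline(c(0, 1), values = c(1, 2)), "3")
  expect_error(fitDecline(rep(1, 5), values = rnorm(5)), "variance")
})

test_that("decline fits equal the closed-form OLS oracle on random inputs", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:48, 1)
    t <- sort(runif(n, 0, 6))
    y <- 60 - 7.8 * t + rnorm(n, 0, runif(1, 0.5, 15))
    fit <- fitDecline(t, values = y)
    orc <- oracleOLS(t, y)
    expect_equal(declineSlope(fit), orc$slope, tolerance = 1e-10)
    expect_equal(fit@intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(rSquared(fit), orc$r2, tolerance = 1e-10)
    expect_equal(pValue(fit), orc$p, tolerance = 1e-10)
    expect_equal(fit@slopeSE, orc$se, tolerance = 1e-10)
  }
})

test_that("decline classification needs a negative slope and Bonferroni-scaled p", {
  up <- new("DeclineFit", slope = 2, intercept = 0, rSquared = 0.8,
            pValue = 0.001, slopeSE = 0.1, nPoints = 10L,
            degenerate = FALSE)
  down <- new("DeclineFit", slope = -2, intercept = 0, rSquared = 0.8,
              pValue = 0.04, slopeSE = 0.1, nPoints = 10L,
              degenerate = FALSE)
  expect_identical(classifyDecline(up), "not_detected")
  expect_identical(classifyDecline(down), "detected")
  expect_identical(classifyDecline(down, nComparisons = 2), "not_detected")
  # monotone in alpha
  for (a in c(0.01, 0.03, 0.041, 0.2)) {
    det <- classifyDecline(down, alpha = a)
    if (det == "detected")
      for (a2 in c(a, 0.25, 0.5))
        expect_identical(classifyDecline(down, alpha = a2), "detected")
  }
  expect_true(biologicalInterest(down))
  weak <- new("DeclineFit", slope = -2, intercept = 0, rSquared = 0.05,
              pValue = 0.01, slopeSE = 0.1, nPoints = 10L,
              degenerate = FALSE)
  expect_false(biologicalInterest(weak))
})

test_that("coefficient of variation uses the sample SD over the mean", {
  expect_equal(coefficientOfVariation(c(2, 2, 2)), 0)
  expect_equal(coefficientOfVariation(c(1, 3)), sqrt(2) / 2)
  expect_error(coefficientOfVariation(5), "2")
  expect_error(coefficientOfVariation(c(-3, 1)), "mean")
})

test_that("day correlation matrices are symmetric R^2 with missing flags", {
  m <- cbind(day1 = c(1, 2, 3, 4), day2 = 2 * c(1, 2, 3, 4),
             day3 = c(4, 1, 3, 2))
  dc <- dayCorrelationMatrix(m)
  expect_equal(dc["day1", "day2"], 1)
  expect_identical(dc, t(dc))
  expect_equal(diag(dc), c(day1 = 1, day2 = 1, day3 = 1))
  expect_equal(dc["day1", "day3"], oraclePearson(m[, 1], m[, 3])^2)
  # independent totals decorrelate
  set.seed(7)
  big <- cbind(a = rlnorm(1000), b = rlnorm(1000))
  expect_lt(dayCorrelationMatrix(big)["a", "b"], 0.01)
  # fewer than 3 complete pairs -> NA
  m2 <- cbind(d1 = c(1, 2, NA, NA), d2 = c(NA, NA, 1, 2))
  expect_true(is.na(dayCorrelationMatrix(m2)["d1", "d2"]))
})

test_that("within-block bootstrap degenerates and reproduces correctly", {
  t <- as.vector(outer(seq(0, 10740, by = 60), (0:3) * 10800, "+"))
  d <- rep(c(1000, 2000, 1500, 800), each = 180)
  ds <- makeDS(sort(t), d, 60)
  ci <- bootstrapDeclineCI(ds, nBoot = 50, seed = 4L)
  expect_equal(ci@lower, ci@upper)
  expect_equal(ci@lower, ci@pointEstimate)
  set.seed(123)
  ds2 <- makeDS(sort(t), d + rep(runif(180, 0, 500), 4), 60)
  a <- bootstrapDeclineCI(ds2, nBoot = 200, seed = 9L)
  b <- bootstrapDeclineCI(ds2, nBoot = 200, seed = 9L)
  expect_identical(confInt(a), confInt(b))
  expect_lte(a@lower, a@pointEstimate)
  expect_gte(a@upper, a@pointEstimate)
  expect_error(bootstrapDeclineCI(makeDS(c(0, 60), c(1, 2), 60)), "3 blocks")
})

test_that("bootstrap CIs shrink as within-block noise vanishes", {
  width <- vapply(c(400, 100, 10), function(sigma) {
    set.seed(31)
    t <- as.vector(outer(seq(0, 10740, by = 360), (0:15) * 10800, "+"))
    mu <- rep((60 - 7.8 * (0:15) * 0.125) * 1000 / 30, each = 30)
    ds <- makeDS(sort(t), pmax(mu + rnorm(length(mu), 0, sigma), 0), 360)
    ci <- bootstrapDeclineCI(ds, nBoot = 400, seed = 2L)
    ci@upper - ci@lower
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("animal-subset R^2 bootstrap handles exact fits and reseeds", {
  g <- rep(1:8, each = 5)
  x <- rnorm(40)
  ci <- bootstrapR2CI(x, x, g, nBoot = 100, seed = 1L)
  expect_equal(ci@pointEstimate, 1)
  expect_equal(confInt(ci), c(lower = 1, upper = 1))
  y <- x + rnorm(40)
  a <- bootstrapR2CI(x, y, g, nBoot = 100, seed = 3L)
  b <- bootstrapR2CI(x, y, g, nBoot = 100, seed = 3L)
  expect_identical(confInt(a), confInt(b))
  expect_error(bootstrapR2CI(x, y, g, fraction = 1.5), "fraction")
  expect_error(bootstrapR2CI(x, y, rep(1:2, 20)), "5")
})

test_that("protocol fidelity is a squared Pearson correlation over matched periods", {
  tr <- simulateIndividual(testConfig(nDays = 1, seed = 23L), 0)
  gold <- blockTotals(displacementSeries(tr, 60), 10800)
  cont <- scoreProtocol(tr, continuousProtocol())
  expect_equal(protocolFidelity(gold, cont), 1)
  constant <- new("ScoreSeries", individualId = "toy",
                  protocol = singleSnapshotProtocol(10800),
                  t = blockStarts(gold), score = rep(2, length(totals(gold))))
  expect_warning(r0 <- protocolFidelity(gold, constant), "zero-variance")
  expect_equal(r0, 0)
  # direct-formula oracle on random pairings
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    gv <- runif(n, 0, 60)
    sv <- gv * runif(1, 0.2, 1) + rnorm(n, 0, 5)
    bs <- new("BlockSeries", individualId = "toy", blockDuration = 10800,
              blockStart = (seq_len(n) - 1) * 10800, total = gv,
              nContributing = rep(1L, n))
    ss <- new("ScoreSeries", individualId = "toy",
              protocol = singleSnapshotProtocol(10800),
              t = (seq_len(n) - 1) * 10800, score = pmax(sv, 0))
    expect_equal(protocolFidelity(bs, ss),
                 oraclePearson(gv, pmax(sv, 0))^2, tolerance = 1e-12)
  }
})
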