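test_that("the two-mode EM separates a clean mixture deterministically", {
  set.seed(1)
  x <- c(rnorm(2000, 100, 0.5), rnorm(2000, 200, 0.5))
  fit <- fitTwoModeGMM(x)
  expect_equal(fit$means, c(100, 200), tolerance = 0.01)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.01)
  expect_identical(fit$means, fitTwoModeGMM(x)$means)
  expect_error(fitTwoModeGMM(rep(7, 100)), "distinct")
  expect_error(fitTwoModeGMM(rnorm(5000)), "unimodal")
})

test_that("the EM recovers known mixture parameters within 2%", {
  set.seed(12)
  n <- 1e5
  z <- runif(n) < 0.3
  x <- ifelse(z, rnorm(n, 80, 5), rnorm(n, 180, 10))
  fit <- fitTwoModeGMM(x)
  expect_equal(fit$means[1], 80, tolerance = 0.02 * 80)
  expect_equal(fit$means[2], 180, tolerance = 0.02 * 180)
  expect_equal(fit$weights[1], 0.3, tolerance = 0.02)
  expect_equal(sqrt(fit$variances[1]), 5, tolerance = 0.02 * 5)
  expect_equal(sqrt(fit$variances[2]), 10, tolerance = 0.02 * 10)
})

test_that("the EM agrees with an independent mixture fitter", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(3)
  x <- c(rnorm(5000, 24000, 900), rnorm(12000, 33000, 1100))
  mine <- fitTwoModeGMM(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(mine$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(sort(mine$weights), sort(as.numeric(mc$parameters$pro)),
               tolerance = 1e-2)
})

test_that("rendered frames have the stated geometry and noise behaviour", {
  fr <- renderArenaImages(widthPx = 256, heightPx = 256, pixelSize = 1.3,
                          lawnRadius = 130, noiseSd = 0, nFrames = 1,
                          seed = 1)
  px <- imagePixels(fr[[1]])
  expect_identical(sort(unique(as.vector(px))), c(26000, 34000))
  # dark-pixel count equals the analytic disc area within rasterisation error
  rpx <- 130 / 1.3
  expect_equal(sum(px == 26000), pi * rpx^2, tolerance = 0.02)
  fr5 <- renderArenaImages(widthPx = 128, heightPx = 128, lawnRadius = 60,
                           noiseSd = 500, nFrames = 5, seed = 2)
  expect_identical(length(fr5), 5L)
  expect_false(identical(imagePixels(fr5[[1]]), imagePixels(fr5[[2]])))
  expect_error(renderArenaImages(widthPx = 64, heightPx = 64,
                                 lawnRadius = 100), "inside")
})

test_that("lawn segmentation recovers disc areas and is idempotent under OR", {
  fr <- renderArenaImages(widthPx = 256, heightPx = 256, pixelSize = 1.3,
                          lawnRadius = 130, noiseSd = 0, nFrames = 5,
                          seed = 4)
  mask <- segmentLawn(fr)
  trueArea <- pi * 130^2 / 1e6
  expect_equal(lawnArea(mask), trueArea, tolerance = 0.02)
  single <- segmentLawn(fr[1])
  expect_identical(maskPixels(mask), maskPixels(single))
  # noisy frames at SNR ~ 6.7 stay within 5%
  frN <- renderArenaImages(widthPx = 256, heightPx = 256, pixelSize = 1.3,
                           lawnRadius = 130, noiseSd = 1200, nFrames = 5,
                           seed = 5)
  expect_equal(lawnArea(segmentLawn(frN)), trueArea, tolerance = 0.05)
  # the OR-combined mask is a superset of each per-frame mask
  for (k in 1:5) {
    mk <- maskPixels(segmentLawn(frN[k]))
    expect_true(all(maskPixels(segmentLawn(frN))[mk]))
  }
})

test_that("intensity inversion with the upper mode yields the identical mask", {
  fr <- renderArenaImages(widthPx = 128, heightPx = 128, lawnRadius = 60,
                          noiseSd = 800, nFrames = 1, seed = 6)
  px <- imagePixels(fr[[1]])
  fit <- fitTwoModeGMM(as.vector(px))
  post <- function(px, fit, comp) {
    fit$weights[comp] *
      dnorm(px, fit$means[comp], sqrt(fit$variances[comp]))
  }
  lower <- post(px, fit, 1) >= post(px, fit, 2)
  inv <- 65535 - px
  fitInv <- fitTwoModeGMM(as.vector(inv))
  upper <- post(inv, fitInv, 2) >= post(inv, fitInv, 1)
  expect_gte(mean(lower == upper), 1 - 1e-3)
})

test_that("a synthetic arena at the reference optics yields the expected lawn area", {
  fr <- renderArenaImages(nFrames = 2, seed = 8)
  mask <- segmentLawn(fr, nFrames = 2)
  expect_equal(lawnArea(mask), pi * 0.88^2, tolerance = 0.03)
})
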