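#' @include AllClasses.R
NULL

#' Fit a two-component Gaussian mixture to pixel intensities
#'
#' Expectation-maximisation fit of a univariate two-mode Gaussian mixture
#' to raw pixel values (not binned counts).  Initialisation is
#' deterministic — component means start at the 25% and 75% intensity
#' quantiles (a k-means++-style spread seeding with ties broken toward the
#' lower mean) — so repeated fits are identical.  Components are returned
#' sorted by mean, ascending.
#'
#' A fit is declared degenerate (error) when the data are effectively
#' unimodal: fitted means separated by less than one pooled standard
#' deviation, or either weight below 1%.
#'
#' @param intensities Numeric vector with at least 2 distinct values.
#' @param maxIter Maximum EM iterations.
#' @param tol Convergence tolerance on the mean log-likelihood.
#' @return List with `means`, `variances`, `weights` (each length 2,
#'   sorted by mean), `logLik` and `iterations`.
#' @examples
#' x <- c(rnorm(500, 100, 3), rnorm(500, 200, 5))
#' fitTwoModeGMM(x)$means
#' @export
fitTwoModeGMM <- function(intensities, maxIter = 500, tol = 1e-8) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2)
    stop("degenerate fit: fewer than 2 distinct intensity values")
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- sort(q)
  if (mu[1] == mu[2]) mu <- range(x)
  v0 <- max(stats::var(x) / 4, 1e-12)
  va <- c(v0, v0)
  w <- c(0.5, 0.5)
  ll0 <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(va[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(va[2]))
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    g1 <- d1 / tot
    ll <- mean(log(tot))
    if (iter >= maxIter || abs(ll - ll0) < tol) break
    ll0 <- ll
    n1 <- sum(g1)
    n2 <- n - n1
    if (n1 < 1e-9 || n2 < 1e-9) break
    mu[1] <- sum(g1 * x) / n1
    mu[2] <- sum((1 - g1) * x) / n2
    va[1] <- max(sum(g1 * (x - mu[1])^2) / n1, 1e-12)
    va[2] <- max(sum((1 - g1) * (x - mu[2])^2) / n2, 1e-12)
    w <- c(n1, n2) / n
  }
  ord <- order(mu)
  mu <- mu[ord]
  va <- va[ord]
  w <- w[ord]
  pooledSd <- sqrt(w[1] * va[1] + w[2] * va[2])
  if (min(w) < 0.01 || abs(mu[2] - mu[1]) < pooledSd)
    stop(sprintf(
      "degenerate fit: effectively unimodal intensities (separation %.3g, pooled SD %.3g, weights %.3g/%.3g)",
      mu[2] - mu[1], pooledSd, w[1], w[2]))
  list(means = mu, variances = va, weights = w, logLik = ll * n,
       iterations = iter)
}

# posterior lower-mode mask for one frame under a fitted 2-component GMM
.lowerModeMask <- function(pixels, fit) {
  d1 <- fit$weights[1] *
    stats::dnorm(pixels, fit$means[1], sqrt(fit$variances[1]))
  d2 <- fit$weights[2] *
    stats::dnorm(pixels, fit$means[2], sqrt(fit$variances[2]))
  d1 >= d2
}

#' Segment the bacterial lawn from arena frames
#'
#' Per frame, fits [fitTwoModeGMM()] to the pixel intensities, assigns each
#' pixel to its more probable component (posterior rule) and keeps the
#' lower-mean ("visually darker") component's pixels as that frame's lawn
#' mask.  The masks of the first `min(nFrames, length(frames))` frames are
#' combined with a bitwise OR into a robust estimate of the entire lawn
#' region, and the area is calibrated from the pixel size.  Frames whose
#' GMM is degenerate are skipped with a warning; if every frame is
#' degenerate, an error is raised.
#'
#' @param frames List of [ArenaImage-class] objects of identical shape.
#' @param nFrames Number of leading frames to combine (default 5).
#' @return A [LawnMask-class].
#' @examples
#' frames <- renderArenaImages(widthPx = 256, heightPx = 256,
#'                             lawnRadius = 120, pixelSize = 1.3,
#'                             nFrames = 5, seed = 1)
#' lawnArea(segmentLawn(frames))
#' @export
segmentLawn <- function(frames, nFrames = 5) {
  if (length(frames) < 1) stop("at least one frame is required")
  dims <- dim(frames[[1]]@pixels)
  for (f in frames)
    if (!identical(dim(f@pixels), dims))
      stop("frames must share the same shape")
  use <- frames[seq_len(min(nFrames, length(frames)))]
  mask <- NULL
  combined <- 0L
  for (k in seq_along(use)) {
    f <- use[[k]]
    fit <- tryCatch(fitTwoModeGMM(as.vector(f@pixels)),
                    error = function(e) {
                      warning(sprintf("frame %d skipped: %s", k,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(fit)) next
    m <- .lowerModeMask(f@pixels, fit)
    mask <- if (is.null(mask)) m else (mask | m)
    combined <- combined + 1L
  }
  if (is.null(mask))
    stop("all frames produced degenerate mixture fits")
  px <- use[[1]]@pixelSize
  new("LawnMask", mask = mask, pixelSize = px,
      nFramesCombined = combined,
      area = sum(mask) * px^2 / 1e6)
}
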