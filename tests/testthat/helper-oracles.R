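# Independent oracles and toy-data builders shared across the suite.

# closed-form OLS + Wald t-test, independent of stats::lm
oracleOLS <- function(t, y) {
  n <- length(y)
  tb <- mean(t)
  yb <- mean(y)
  sxx <- sum((t - tb)^2)
  b <- sum((t - tb) * (y - yb)) / sxx
  a <- yb - b * tb
  res <- y - a - b * t
  rss <- sum(res^2)
  tss <- sum((y - yb)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  list(slope = b, intercept = a, r2 = 1 - rss / tss,
       p = 2 * stats::pt(-abs(b / se), n - 2), se = se)
}

# direct Pearson formula, independent of stats::cor
oraclePearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# build a Trajectory from explicit coordinates
makeTraj <- function(t, x, y, arenaRadius = NULL, ew = NULL, id = "toy") {
  if (is.null(arenaRadius))
    arenaRadius <- max(sqrt(x^2 + y^2), 1)
  if (is.null(ew))
    ew <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  new("Trajectory", individualId = id, t = t, x = x, y = y,
      arenaRadius = arenaRadius, excludedWindows = ew)
}

# bounded-random-walk toy trajectory (no behavioural structure)
randomToyTraj <- function(n = 600, dt = 1, step = 40, radius = 880,
                          seed = 1, ew = NULL, id = "toy") {
  set.seed(seed)
  x <- numeric(n)
  y <- numeric(n)
  for (i in 2:n) {
    repeat {
      cx <- x[i - 1] + rnorm(1, 0, step)
      cy <- y[i - 1] + rnorm(1, 0, step)
      if (cx^2 + cy^2 <= radius^2) break
    }
    x[i] <- cx
    y[i] <- cy
  }
  makeTraj((0:(n - 1)) * dt, x, y, arenaRadius = radius, ew = ew, id = id)
}

# small, fast generator configuration for unit tests
testConfig <- function(nDays = 1, seed = 5L, ...) {
  generatorConfig(nDays = nDays, seed = seed, ...)
}

# DisplacementSeries built directly (for statistics tests)
makeDS <- function(t, d, interval, excluded = NULL, id = "toy") {
  if (is.null(excluded)) excluded <- rep(FALSE, length(d))
  new("DisplacementSeries", individualId = id, interval = interval,
      t = t, d = d, excluded = excluded)
}
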