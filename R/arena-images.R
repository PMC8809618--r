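#' @include AllClasses.R
NULL

#' Render synthetic brightfield-like arena frames
#'
#' Renders `nFrames` frames sharing one lawn geometry: a uniform bright
#' background with a darker disc where the bacterial lawn sits, plus
#' independent additive Gaussian noise per frame, clamped to the 16-bit
#' range.  Defaults reproduce the package's reference optics (6.5-um sensor
#' pixels at 5x magnification, i.e. 1.3 um/px) and a lawn of roughly
#' 0.88 mm radius (~2.4 mm^2), darker than the background.
#'
#' @param widthPx,heightPx Frame size in pixels.
#' @param pixelSize Length per pixel (um).
#' @param lawnCenter Lawn centre (um, image coordinates); default the image
#'   centre.
#' @param lawnRadius Lawn radius (um); the disc must lie fully inside the
#'   image.
#' @param backgroundLevel,lawnLevel Mean intensities (16-bit range); the
#'   lawn must be darker.
#' @param noiseSd Additive Gaussian noise SD (intensity units); 0 yields
#'   exactly two distinct pixel values.
#' @param nFrames Number of frames (default 5).
#' @param seed Integer seed.
#' @return List of [ArenaImage-class] frames.
#' @examples
#' frames <- renderArenaImages(widthPx = 128, heightPx = 128,
#'                             lawnRadius = 60, nFrames = 2, seed = 1)
#' frames[[1]]
#' @export
renderArenaImages <- function(widthPx = 1408, heightPx = 1408,
                              pixelSize = 1.3,
                              lawnCenter = NULL,
                              lawnRadius = 880,
                              backgroundLevel = 34000,
                              lawnLevel = 26000,
                              noiseSd = 1200,
                              nFrames = 5, seed = 1L) {
  if (nFrames < 1) stop("'nFrames' must be >= 1")
  if (lawnLevel >= backgroundLevel)
    stop("the lawn must be darker than the background")
  w <- widthPx * pixelSize
  h <- heightPx * pixelSize
  if (is.null(lawnCenter)) lawnCenter <- c(w / 2, h / 2)
  if (lawnCenter[1] - lawnRadius < 0 || lawnCenter[1] + lawnRadius > w ||
      lawnCenter[2] - lawnRadius < 0 || lawnCenter[2] + lawnRadius > h)
    stop("lawn disc must lie fully inside the image")
  # pixel-centre coordinates (um)
  cx <- (seq_len(widthPx) - 0.5) * pixelSize
  cy <- (seq_len(heightPx) - 0.5) * pixelSize
  inside <- outer(cy, cx, function(yy, xx)
    (xx - lawnCenter[1])^2 + (yy - lawnCenter[2])^2 <= lawnRadius^2)
  base <- matrix(backgroundLevel, heightPx, widthPx)
  base[inside] <- lawnLevel
  .withSeed(as.integer(seed), {
    lapply(seq_len(nFrames), function(i) {
      px <- base
      if (noiseSd > 0)
        px <- px + matrix(stats::rnorm(length(base), 0, noiseSd),
                          heightPx, widthPx)
      px <- pmin(pmax(px, 0), 65535)
      new("ArenaImage", pixels = px, pixelSize = pixelSize,
          lawnCenter = lawnCenter, lawnRadius = lawnRadius,
          noiseSd = noiseSd)
    })
  })
}

#' Read and write arena frames as 16-bit grayscale TIFF
#'
#' `writeArenaTiff` writes a list of [ArenaImage-class] frames as a
#' single-channel 16-bit TIFF stack; `readArenaTiff` reads one back.
#' Pixel geometry (`pixelSize`) is not stored in the TIFF and must be
#' supplied on reading.
#'
#' @param frames List of [ArenaImage-class] frames.
#' @param path TIFF file path.
#' @param pixelSize Length per pixel (um) to attach on reading.
#' @return `readArenaTiff` returns a list of [ArenaImage-class] frames;
#'   `writeArenaTiff` returns `path` invisibly.
#' @name arenaTiff
NULL

#' @rdname arenaTiff
#' @export
writeArenaTiff <- function(frames, path) {
  imgs <- lapply(frames, function(f) f@pixels / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname arenaTiff
#' @export
readArenaTiff <- function(path, pixelSize = 1.3) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    new("ArenaImage", pixels = m * 65535, pixelSize = pixelSize,
        lawnCenter = c(0, 0), lawnRadius = 0, noiseSd = NA_real_)
  })
}
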