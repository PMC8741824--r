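# The four colour-based greenness algorithms. ExG and NExG produce 8-bit
# index maps that are thresholded downstream; HSV and ExHSV produce binary
# masks directly.

#' Excess-green index map
#'
#' Computes the excess-green index ExG = 2G - R - B per pixel, in a signed
#' intermediate so the arithmetic cannot wrap, then clips to the 8-bit range
#' [0, 255]. Soil and other achromatic pixels score 0; green vegetation
#' scores high.
#'
#' @param frame an RGB frame (\code{H x W x 3} array of 0--255 intensities).
#' @return an \code{H x W} index map with values in [0, 255].
#' @examples
#' f <- rgbFrame(50, 150, 40, width = 4, height = 2)
#' exgMap(f)[1, 1]  # 2*150 - 50 - 40 = 210
#' @seealso [nexgMap()] for the illumination-normalised variant.
#' @export
exgMap <- function(frame) {
  .assertFrame(frame)
  v <- 2 * frame[, , 2] - frame[, , 1] - frame[, , 3]
  pmin(pmax(v, 0), 255)
}

#' Normalised excess-green index map
#'
#' Normalises each channel by the channel sum (r = R/(R+G+B) etc.), computes
#' 2g - r - b, and scales the 0--1 result by 255, clipping to [0, 255].
#' Normalisation reduces sensitivity to overall illumination. Black pixels
#' (R+G+B = 0) yield 0: black is never vegetation.
#'
#' @inheritParams exgMap
#' @return an \code{H x W} index map with values in [0, 255].
#' @examples
#' f <- rgbFrame(0, 255, 0, width = 4, height = 2)
#' nexgMap(f)[1, 1]  # g = 1 -> 2*255 clipped to 255
#' @export
nexgMap <- function(frame) {
  .assertFrame(frame)
  s <- frame[, , 1] + frame[, , 2] + frame[, , 3]
  s0 <- pmax(s, 1)  # zero-sum guard; masked to 0 below
  r <- frame[, , 1] / s0; g <- frame[, , 2] / s0; b <- frame[, , 3] / s0
  out <- ifelse(s == 0, 0, 255 * (2 * g - r - b))
  round(pmin(pmax(out, 0), 255))
}

# RGB frame -> list of H x W byte-scale HSV matrices, hue on the 0-179
# half-circle convention (so the 8-bit bands of ThresholdProfile apply),
# saturation and value on 0-255.
.hsvBytes <- function(frame) {
  d <- dim(frame)
  m <- rbind(
    as.vector(frame[, , 1]),
    as.vector(frame[, , 2]),
    as.vector(frame[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(
    h = matrix(round(hsv[1, ] * 180) %% 180, d[1], d[2]),
    s = matrix(round(hsv[2, ] * 255), d[1], d[2]),
    v = matrix(round(hsv[3, ] * 255), d[1], d[2])
  )
}

#' HSV band-threshold vegetation mask
#'
#' Converts the frame to HSV and marks a pixel as vegetation (255) when all
#' three channels fall inside the profile's bands (inclusive): hue on the
#' 0--179 half-circle scale, saturation and value on 0--255. The output is
#' already binary, so no adaptive-threshold stage follows it in the
#' pipeline. The value band's upper bound deliberately excludes blown-out
#' bright pixels such as specular glare from stubble.
#'
#' @inheritParams exgMap
#' @param profile a [ThresholdProfile-class] supplying the bands.
#' @return an \code{H x W} binary mask holding {0, 255}.
#' @examples
#' f <- rgbFrame(40, 160, 40, width = 4, height = 2)
#' hsvMask(f, presetProfile("day", "hsv"))[1, 1]
#' @export
hsvMask <- function(frame, profile) {
  .assertFrame(frame)
  stopifnot(is(profile, "ThresholdProfile"))
  ch <- .hsvBytes(frame)
  ok <- ch$h >= profile@hueMin & ch$h <= profile@hueMax &
    ch$s >= profile@satMin & ch$s <= profile@satMax &
    ch$v >= profile@valMin & ch$v <= profile@valMax
  matrix(255 * ok, nrow(ok), ncol(ok))
}

#' Combined greenness-index and HSV mask
#'
#' Marks a pixel 255 only when its greenness index lies inside the
#' profile's defined-threshold band \emph{and} the HSV band mask is set at
#' that pixel (intersection). The greenness term is the normalised
#' excess-green index by default; \code{profile@useRawExG} switches it to
#' raw excess green. The result feeds the adaptive-threshold stage like the
#' grayscale index algorithms.
#'
#' @inheritParams hsvMask
#' @return an \code{H x W} binary mask holding {0, 255}.
#' @export
exhsvMask <- function(frame, profile) {
  .assertFrame(frame)
  stopifnot(is(profile, "ThresholdProfile"))
  idx <- if (isTRUE(profile@useRawExG)) exgMap(frame) else nexgMap(frame)
  inBand <- idx >= profile@exgMin & idx <= profile@exgMax
  hm <- hsvMask(frame, profile)
  matrix(255 * (inBand & hm == 255), nrow(idx), ncol(idx))
}
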