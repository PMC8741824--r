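# Frame conventions used throughout the package.
#
# An RGB frame is a plain H x W x 3 array of 8-bit intensities (0-255),
# channels ordered R, G, B, indexed [row = y, col = x] with the origin at
# the top-left. Index maps are H x W matrices in 0-255; binary masks are
# H x W matrices holding exactly {0, 255}. Bounding boxes reported to users
# are 0-based and half-open on the right/bottom. EBImage::Image (width x
# height, values 0-1) is used only at the I/O and filtering boundary.

.assertFrame <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[3] != 3)
    stop("frame must be an H x W x 3 array (channels R, G, B)", call. = FALSE)
  if (dim(frame)[2] < 4 || dim(frame)[1] < 1)
    stop("frame must be at least 4 pixels wide and 1 tall", call. = FALSE)
  rng <- range(frame)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  invisible(frame)
}

.assertMask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 255)))
    stop("mask must be a two-valued {0, 255} matrix", call. = FALSE)
  invisible(mask)
}

#' Build an RGB frame from channel matrices or a constant colour
#'
#' Convenience constructor for the package's frame convention: an
#' \code{H x W x 3} array of 8-bit intensities with channels R, G, B.
#'
#' @param r,g,b equal-sized numeric matrices in [0, 255], or scalars which
#'   are recycled to \code{height} x \code{width}.
#' @param width,height canvas size, required when \code{r} is a scalar.
#' @return an \code{H x W x 3} array.
#' @examples
#' f <- rgbFrame(100, 100, 100, width = 8, height = 6)
#' dim(f)
#' @export
rgbFrame <- function(r, g, b, width = NULL, height = NULL) {
  if (length(r) == 1) {
    if (is.null(width) || is.null(height))
      stop("width and height are required for constant frames")
    r <- matrix(r, height, width)
    g <- matrix(g[1], height, width)
    b <- matrix(b[1], height, width)
  }
  stopifnot(identical(dim(r), dim(g)), identical(dim(r), dim(b)))
  frame <- array(0L, dim = c(nrow(r), ncol(r), 3))
  frame[, , 1] <- r; frame[, , 2] <- g; frame[, , 3] <- b
  .assertFrame(frame)
}

# frame array (H x W x 3, 0-255) -> EBImage Image (W x H, 0-1)
.frameToImage <- function(frame) {
  EBImage::Image(aperm(frame, c(2, 1, 3)) / 255, colormode = "Color")
}

# EBImage Image -> frame array, clipped and rounded back to 8-bit
.imageToFrame <- function(img) {
  d <- dim(img)
  if (length(d) == 2) d <- c(d, 1)
  a <- array(as.numeric(img), dim = d)
  if (d[3] == 1) a <- array(rep(a, 3), dim = c(d[1], d[2], 3))
  a <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  round(pmin(pmax(a * 255, 0), 255))
}

#' Read an image file as an RGB frame
#'
#' Reads PNG/JPEG/TIFF via EBImage and converts to the package's
#' \code{H x W x 3} 8-bit convention (grayscale images are replicated
#' across channels).
#'
#' @param path image file path.
#' @return an RGB frame array.
#' @export
readFrame <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: ", path, call. = FALSE)
  .imageToFrame(EBImage::readImage(path))
}

#' Write an RGB frame to an image file
#'
#' @param frame an RGB frame array.
#' @param path output path; format from extension (png/jpeg/tiff).
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(frame, path) {
  .assertFrame(frame)
  EBImage::writeImage(.frameToImage(frame), path)
  invisible(path)
}
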