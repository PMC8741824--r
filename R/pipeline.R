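# Frame-processing pipeline: resize -> greenness algorithm -> defined
# threshold -> adaptive threshold -> morphological cleaning -> connected
# components -> size filter -> detections.

#' Construct a pipeline configuration
#'
#' @param algorithm one of \code{"exg"}, \code{"nexg"}, \code{"hsv"},
#'   \code{"exhsv"}.
#' @param profile a [ThresholdProfile-class]; defaults to the day preset
#'   for the chosen algorithm.
#' @param resizeTo frame size \code{c(width, height)} processed frames are
#'   resized to; the default 416 x 320 keeps throughput high on embedded
#'   hardware.
#' @param visualise,saveFrames flags forwarded to [runDetect()].
#' @return a [PipelineConfig-class].
#' @examples
#' pipelineConfig("exg")
#' @export
pipelineConfig <- function(algorithm = c("exg", "nexg", "hsv", "exhsv"),
                           profile = NULL,
                           resizeTo = c(416L, 320L),
                           visualise = FALSE, saveFrames = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(profile)) profile <- presetProfile("day", algorithm)
  new("PipelineConfig",
    algorithm = algorithm, profile = profile,
    resizeTo = as.integer(resizeTo),
    visualise = visualise, saveFrames = saveFrames
  )
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:", object@algorithm, "|",
      object@profile@profileName, "|",
      paste(object@resizeTo, collapse = "x"), "\n")
})

#' Resize a frame with bilinear interpolation
#'
#' No-op when the frame already has the target size.
#'
#' @param frame an RGB frame array.
#' @param width,height target size in pixels.
#' @return an RGB frame of the requested size.
#' @export
resizeFrame <- function(frame, width = 416, height = 320) {
  .assertFrame(frame)
  if (width < 1 || height < 1)
    stop("target dimensions must be positive", call. = FALSE)
  d <- dim(frame)
  if (d[1] == height && d[2] == width) return(frame)
  .imageToFrame(EBImage::resize(.frameToImage(frame), w = width, h = height))
}

#' Apply a fixed intensity band to an index map
#'
#' A pixel is kept (255) when \code{lo <= value <= hi}, both bounds
#' inclusive.
#'
#' @param index an \code{H x W} index map.
#' @param lo,hi intensity bounds, \code{lo <= hi}.
#' @return a binary mask holding {0, 255}.
#' @export
definedThreshold <- function(index, lo, hi) {
  if (lo > hi) stop("threshold lower bound exceeds upper bound", call. = FALSE)
  matrix(255 * (index >= lo & index <= hi), nrow(index), ncol(index))
}

# Gaussian kernel matching the common computer-vision default: for an odd
# window of size n, sigma = 0.3 * ((n - 1) / 2 - 1) + 0.8.
.gaussKernel <- function(n) {
  sigma <- 0.3 * ((n - 1) * 0.5 - 1) + 0.8
  x <- seq_len(n) - (n + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Adaptive local-contrast refinement of a defined-threshold mask
#'
#' Computes a Gaussian-weighted local mean of the index map over an odd
#' \code{adaptiveBlockSize} window (replicated borders) and keeps a pixel
#' only when its index exceeds that local mean by more than
#' \code{adaptiveOffset}, intersected with the defined-threshold mask.
#' A uniform map therefore yields an empty mask: with no local contrast,
#' nothing is a detection. The HSV algorithm skips this stage (its mask is
#' already binary); [processFrame()] handles that routing.
#'
#' @param index an \code{H x W} index map.
#' @param defined binary mask from [definedThreshold()], same size.
#' @param profile a [ThresholdProfile-class] supplying
#'   \code{adaptiveBlockSize} and \code{adaptiveOffset}.
#' @return a binary mask holding {0, 255}.
#' @export
adaptiveRefine <- function(index, defined, profile) {
  stopifnot(is(profile, "ThresholdProfile"))
  if (!identical(dim(index), dim(defined)))
    stop("index and defined mask must share dimensions", call. = FALSE)
  n <- profile@adaptiveBlockSize
  if (n %% 2 != 1 || n < 3)
    stop("adaptive block size must be odd and >= 3", call. = FALSE)
  local <- EBImage::filter2(index, .gaussKernel(n), boundary = "replicate")
  keep <- (index > local + profile@adaptiveOffset) & defined == 255
  matrix(255 * keep, nrow(index), ncol(index))
}

#' Morphological noise cleaning
#'
#' Opening (removes sub-kernel speckle) followed by closing (fills
#' sub-kernel gaps), both with a disc-shaped structuring element.
#'
#' @param mask a binary {0, 255} mask.
#' @param kernel structuring-element size in pixels (>= 1); sizes below 3
#'   leave the mask unchanged.
#' @return a binary mask holding {0, 255}.
#' @export
morphClean <- function(mask, kernel = 3) {
  .assertMask(mask)
  if (kernel < 1) stop("kernel must be >= 1", call. = FALSE)
  if (kernel < 3) return(mask)
  brush <- EBImage::makeBrush(as.integer(kernel), shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask / 255, brush), brush)
  matrix(255 * (as.numeric(m) > 0), nrow(mask), ncol(mask))
}

#' Extract detections from a binary mask
#'
#' Fills holes, labels 8-connected foreground components, discards those
#' smaller than \code{minArea}, and returns one detection per surviving
#' component: the axis-aligned bounding box (0-based, half-open), its
#' centre, and the filled pixel area. Detections are ordered by bounding
#' box origin (y, then x) so the output is deterministic.
#'
#' @param mask a binary {0, 255} mask.
#' @param minArea smallest component kept, in pixels.
#' @param frameIndex ordinal recorded in the \code{frame_index} column.
#' @return a data.frame with columns \code{frame_index, x, y, w, h, cx, cy,
#'   area}; zero rows for a blank mask.
#' @export
findDetections <- function(mask, minArea = 10, frameIndex = 0) {
  .assertMask(mask)
  filled <- EBImage::fillHull(mask / 255)
  lab <- .label8(matrix(as.numeric(filled), nrow(mask), ncol(mask)))
  k <- max(lab)
  empty <- data.frame(
    frame_index = integer(), x = integer(), y = integer(),
    w = integer(), h = integer(), cx = numeric(), cy = numeric(),
    area = integer()
  )
  if (k == 0) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  area <- tabulate(labs, nbins = k)
  y0 <- tapply(idx[, 1], labs, min) - 1L
  y1 <- tapply(idx[, 1], labs, max) - 1L
  x0 <- tapply(idx[, 2], labs, min) - 1L
  x1 <- tapply(idx[, 2], labs, max) - 1L
  keep <- area >= minArea
  if (!any(keep)) return(empty)
  out <- data.frame(
    frame_index = as.integer(frameIndex),
    x = as.integer(x0[keep]), y = as.integer(y0[keep]),
    w = as.integer(x1[keep] - x0[keep] + 1L),
    h = as.integer(y1[keep] - y0[keep] + 1L),
    area = as.integer(area[keep])
  )
  out$cx <- out$x + out$w / 2
  out$cy <- out$y + out$h / 2
  out <- out[order(out$y, out$x), c("frame_index", "x", "y", "w", "h",
                                    "cx", "cy", "area")]
  rownames(out) <- NULL
  out
}

#' Run the full detection pipeline on one frame
#'
#' Resizes the frame, applies the configured greenness algorithm, the
#' defined and adaptive thresholds (adaptive is skipped for the pure HSV
#' algorithm, whose mask is already binary), morphological cleaning, and
#' component extraction with the minimum-size filter. Deterministic for a
#' fixed frame and configuration.
#'
#' @param frame an RGB frame array of any size.
#' @param config a [PipelineConfig-class].
#' @param frameIndex ordinal stamped on the detections.
#' @return a detection data.frame as from [findDetections()].
#' @examples
#' cfg <- pipelineConfig("exg")
#' processFrame(rgbFrame(120, 120, 120, width = 64, height = 48), cfg)
#' @export
processFrame <- function(frame, config, frameIndex = 0) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  p <- config@profile
  frame <- resizeFrame(frame, config@resizeTo[1], config@resizeTo[2])
  mask <- switch(config@algorithm,
    exg = {
      idx <- exgMap(frame)
      adaptiveRefine(idx, definedThreshold(idx, p@exgMin, p@exgMax), p)
    },
    nexg = {
      idx <- nexgMap(frame)
      adaptiveRefine(idx, definedThreshold(idx, p@exgMin, p@exgMax), p)
    },
    hsv = hsvMask(frame, p),
    exhsv = {
      idx <- if (isTRUE(p@useRawExG)) exgMap(frame) else nexgMap(frame)
      adaptiveRefine(idx, exhsvMask(frame, p), p)
    }
  )
  mask <- morphClean(mask, p@morphKernel)
  findDetections(mask, p@minObjectArea, frameIndex)
}

#' Draw detection boxes on a frame
#'
#' Marks each detection with a 1-pixel red rectangle, the conventional
#' visualisation of the detection process.
#'
#' @param frame an RGB frame array.
#' @param detections a detection data.frame.
#' @return the annotated frame.
#' @export
annotateFrame <- function(frame, detections) {
  .assertFrame(frame)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  for (i in seq_len(nrow(detections))) {
    x0 <- detections$x[i] + 1L
    y0 <- detections$y[i] + 1L
    x1 <- min(x0 + detections$w[i] - 1L, w)
    y1 <- min(y0 + detections$h[i] - 1L, h)
    frame[y0, x0:x1, 1] <- 255; frame[y0, x0:x1, 2:3] <- 0
    frame[y1, x0:x1, 1] <- 255; frame[y1, x0:x1, 2:3] <- 0
    frame[y0:y1, x0, 1] <- 255; frame[y0:y1, x0, 2:3] <- 0
    frame[y0:y1, x1, 1] <- 255; frame[y0:y1, x1, 2:3] <- 0
  }
  frame
}

#' Write detections to CSV
#'
#' Schema: \code{frame_index,x,y,w,h,cx,cy,area,zone}. The \code{zone}
#' column is filled with \code{NA} when zoning was not applied.
#'
#' @param detections a detection data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDetections <- function(detections, path) {
  cols <- c("frame_index", "x", "y", "w", "h", "cx", "cy", "area", "zone")
  if (is.null(detections$zone)) detections$zone <- NA_integer_
  utils::write.csv(detections[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a detection CSV written by [writeDetections()]
#'
#' @param path CSV path.
#' @return a detection data.frame.
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path,
                               call. = FALSE)
  utils::read.csv(path)
}
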