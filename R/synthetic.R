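# Parametric synthetic fallow scenes with exact ground truth. The renderer
# emulates the conditions the detector faces in the field: green-leaved
# weeds of varying hue, size and blur on red-orange or dark-brown soil,
# with optional pale stubble streaks and blown-out specular highlights.

# run code under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a synthetic scene specification
#'
#' @param width,height canvas size in pixels (default 416 x 320, the
#'   pipeline's working resolution).
#' @param background \code{"red_orange_soil"}, \code{"dark_brown_soil"} or
#'   \code{"tilled"}.
#' @param stubbleDensity fraction in [0, 1] scaling the number of pale
#'   straw streaks.
#' @param specularFraction approximate fraction of the canvas covered by
#'   blown-out specular highlights (value channel saturated at 255).
#' @param weeds data.frame with columns \code{cx, cy, radius, leaves, hue,
#'   sat, val, shape}; hue in degrees, sat/val on 0--255, shape one of
#'   \code{disc}, \code{rosette}, \code{grass_blade}. Centroids are 0-based
#'   pixel coordinates and must lie on the canvas.
#' @param blurSigma Gaussian blur sigma in pixels applied after
#'   compositing (camera optics / motion blur surrogate).
#' @param illuminationGain global multiplier applied after blur.
#' @param seed integer making the render reproducible.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(width = 416, height = 320,
                      background = "red_orange_soil",
                      stubbleDensity = 0, specularFraction = 0,
                      weeds = data.frame(
                        cx = numeric(), cy = numeric(), radius = numeric(),
                        leaves = integer(), hue = numeric(), sat = numeric(),
                        val = numeric(), shape = character()
                      ),
                      blurSigma = 0, illuminationGain = 1, seed = 1L) {
  new("SceneSpec",
    width = as.integer(width), height = as.integer(height),
    background = background, stubbleDensity = stubbleDensity,
    specularFraction = specularFraction, weeds = weeds,
    blurSigma = blurSigma, illuminationGain = illuminationGain,
    seed = as.integer(seed)
  )
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec %dx%d | %s | %d weeds | stubble %.2f, specular %.3f | seed %d\n",
    object@width, object@height, object@background, nrow(object@weeds),
    object@stubbleDensity, object@specularFraction, object@seed
  ))
})

#' @describeIn renderScene rendered frame accessor.
#' @export
setMethod("sceneFrame", "SyntheticScene", function(x) x@frame)

#' @describeIn renderScene ground-truth accessor.
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)

#' @describeIn renderScene seed the scene was rendered with.
#' @export
setMethod("sceneSeed", "SyntheticScene", function(x) x@spec@seed)

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene %dx%d with %d ground-truth weeds (seed %d)\n",
              dim(object@frame)[2], dim(object@frame)[1],
              nrow(object@truth), object@spec@seed))
})

.soilBase <- list(
  red_orange_soil = c(168, 96, 58),
  dark_brown_soil = c(72, 52, 38),
  tilled = c(72, 52, 38)
)

# pixel set of one weed, as (row, col) indices on the canvas; 0-based
# centroid coordinates, 1-based matrix indices
.weedPixels <- function(w, width, height, phase) {
  r <- w$radius
  win <- ceiling(r * if (w$shape == "grass_blade") 4.2 else 1.6) + 2
  xs <- max(0, floor(w$cx - win)):min(width - 1, ceiling(w$cx + win))
  ys <- max(0, floor(w$cy - win)):min(height - 1, ceiling(w$cy + win))
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  dx <- gx - w$cx; dy <- gy - w$cy
  inside <- switch(w$shape,
    disc = dx^2 + dy^2 <= r^2,
    rosette = {
      hit <- dx^2 + dy^2 <= (0.5 * r)^2
      k <- max(3, w$leaves)
      for (a in phase + 2 * pi * seq_len(k) / k) {
        px <- 0.6 * r * cos(a); py <- 0.6 * r * sin(a)
        hit <- hit | ((dx - px)^2 + (dy - py)^2 <= (0.55 * r)^2)
      }
      hit
    },
    grass_blade = {
      along <- dx * cos(phase) + dy * sin(phase)
      perp <- -dx * sin(phase) + dy * cos(phase)
      abs(along) <= 4 * r & abs(perp) <= max(0.6, r / 6)
    }
  )
  cbind(row = gy[inside] + 1L, col = gx[inside] + 1L)
}

#' Render a synthetic field scene
#'
#' Deterministic for a fixed spec: composites the soil background (with
#' per-pixel texture noise, plus tillage row shading for the
#' \code{"tilled"} background), pale straw stubble streaks, near-white
#' specular patches (high value, low saturation, value channel saturated
#' so the HSV value band can reject them), and the weeds in their
#' specified HSV colours; then applies Gaussian blur and the illumination
#' gain. Ground truth records each weed's centroid and painted pixel count
#' before blur (blur makes post-hoc areas ambiguous).
#'
#' @param spec a [SceneSpec-class].
#' @return a [SyntheticScene-class] holding the frame and its ground truth.
#' @examples
#' sc <- renderScene(sceneSpec(width = 64, height = 48, seed = 7))
#' nrow(sceneTruth(sc))
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  W <- spec@width; H <- spec@height
  .withSeed(spec@seed, {
    base <- .soilBase[[spec@background]]
    frame <- array(0, dim = c(H, W, 3))
    for (c in 1:3)
      frame[, , c] <- base[c] + matrix(stats::rnorm(H * W, 0, 6), H, W)
    if (spec@background == "tilled") {
      rows <- 14 * sin(2 * pi * (seq_len(H) - 1) / 18)
      for (c in 1:3) frame[, , c] <- frame[, , c] + rows
    }
    paint <- function(px, col) {
      for (c in 1:3) {
        ch <- frame[, , c]
        ch[px] <- col[c]
        frame[, , c] <<- ch
      }
    }
    # stubble: thin pale straw streaks, reddish hue so the straw stays
    # outside the green hue bands
    nStreak <- round(spec@stubbleDensity * 80)
    for (i in seq_len(nStreak)) {
      x0 <- stats::runif(1, 0, W - 1); y0 <- stats::runif(1, 0, H - 1)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 40, 150)
      wdt <- sample(1:2, 1)
      col <- c(215, 185, 110) + stats::rnorm(3, 0, 6)
      t <- seq(0, len, by = 0.5)
      for (off in seq_len(wdt) - 1) {
        xs <- round(x0 + t * cos(ang) - off * sin(ang))
        ys <- round(y0 + t * sin(ang) + off * cos(ang))
        ok <- xs >= 0 & xs < W & ys >= 0 & ys < H
        if (any(ok)) paint(cbind(ys[ok] + 1L, xs[ok] + 1L), col)
      }
    }
    # specular glare: blown-out near-white patches with a faint green
    # tint; value channel pinned at 255
    if (spec@specularFraction > 0) {
      meanArea <- pi * 4.5^2
      nPatch <- max(1, round(spec@specularFraction * W * H / meanArea))
      for (i in seq_len(nPatch)) {
        cx <- stats::runif(1, 0, W - 1); cy <- stats::runif(1, 0, H - 1)
        r <- stats::runif(1, 3, 6)
        px <- .weedPixels(
          list(cx = cx, cy = cy, radius = r, shape = "disc"), W, H, 0
        )
        if (nrow(px))
          paint(px, c(235 + stats::rnorm(1, 0, 3), 255,
                      215 + stats::rnorm(1, 0, 3)))
      }
    }
    # weeds, and their exact ground truth (pre-blur painted area)
    truth <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                        area = integer(), shape = character())
    for (i in seq_len(nrow(spec@weeds))) {
      w <- spec@weeds[i, ]
      phase <- stats::runif(1, 0, 2 * pi)
      px <- .weedPixels(w, W, H, phase)
      col <- grDevices::col2rgb(
        grDevices::hsv(w$hue / 360, w$sat / 255, w$val / 255)
      )[, 1]
      if (nrow(px)) paint(px, col)
      truth <- rbind(truth, data.frame(
        id = i, cx = w$cx, cy = w$cy, area = nrow(px), shape = w$shape
      ))
    }
    frame <- round(pmin(pmax(frame, 0), 255))
    if (spec@blurSigma > 0)
      frame <- .imageToFrame(
        EBImage::gblur(.frameToImage(frame), sigma = spec@blurSigma)
      )
    if (spec@illuminationGain != 1)
      frame <- round(pmin(pmax(frame * spec@illuminationGain, 0), 255))
    new("SyntheticScene", frame = frame, truth = truth, spec = spec)
  })
}

# place n weed centroids with a minimum pairwise separation, away from the
# canvas border
.placeWeeds <- function(n, width, height, margin, minSep) {
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0
  while (length(cx) < n && tries < 500) {
    tries <- tries + 1
    x <- stats::runif(1, margin, width - 1 - margin)
    y <- stats::runif(1, margin, height - 1 - margin)
    if (!length(cx) || all(sqrt((cx - x)^2 + (cy - y)^2) >= minSep)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  data.frame(cx = cx, cy = cy)
}

.batteryStyles <- c("day_green", "night", "stubble_glare", "grass_thin",
                    "purple_stressed")

# style-specific scene parameters; drawn under the battery RNG stream
.styleSpec <- function(style, width, height, sceneSeed) {
  mk <- function(n, radius, hue, sat, val, shape, leaves = 0L) {
    pos <- .placeWeeds(n, width, height, margin = max(radius) + 12,
                       minSep = 60)
    data.frame(
      cx = pos$cx, cy = pos$cy,
      radius = stats::runif(nrow(pos), radius[1], radius[2]),
      leaves = leaves,
      hue = stats::runif(nrow(pos), hue[1], hue[2]),
      sat = stats::runif(nrow(pos), sat[1], sat[2]),
      val = stats::runif(nrow(pos), val[1], val[2]),
      shape = shape
    )
  }
  green <- c(110, 130); gsat <- c(120, 145); gval <- c(100, 165)
  switch(style,
    day_green = sceneSpec(
      width, height, "red_orange_soil", 0, 0,
      mk(sample(2:4, 1), c(5, 10), green, gsat, gval, "disc"),
      blurSigma = 0.8, seed = sceneSeed
    ),
    night = sceneSpec(
      width, height, "dark_brown_soil", 0, 0,
      mk(sample(1:4, 1), c(5, 10), green, gsat, c(90, 150), "disc"),
      blurSigma = 1.0, illuminationGain = 0.85, seed = sceneSeed
    ),
    stubble_glare = sceneSpec(
      width, height, "red_orange_soil", 0.5,
      stats::runif(1, 0.006, 0.02),
      mk(sample(1:3, 1), c(5, 9), green, gsat, gval, "disc"),
      blurSigma = 0.8, seed = sceneSeed
    ),
    grass_thin = sceneSpec(
      width, height, "red_orange_soil", 0.1, 0,
      mk(sample(2:5, 1), c(4, 7), c(100, 130), c(100, 170), c(90, 150),
         "grass_blade"),
      blurSigma = 1.2, seed = sceneSeed
    ),
    purple_stressed = sceneSpec(
      width, height, "red_orange_soil", 0, 0,
      mk(sample(2:4, 1), c(5, 10), c(280, 320), c(90, 160), c(90, 150),
         "disc"),
      blurSigma = 0.8, seed = sceneSeed
    )
  )
}

#' Generate a battery of synthetic scenes in a named style
#'
#' Styles mirror the field conditions that drive detector behaviour:
#' \describe{
#'   \item{day_green}{strongly green, well-separated broadleaf discs on
#'     red-orange soil, mild blur -- the conditions colour algorithms
#'     detect confidently.}
#'   \item{night}{darker, artificially lit variant on dark brown soil.}
#'   \item{stubble_glare}{heavy pale stubble plus blown-out specular
#'     highlights -- the false-positive regime for raw greenness indices.}
#'   \item{grass_thin}{thin grass blades that blur into the background.}
#'   \item{purple_stressed}{purple-green stressed rosettes whose hue falls
#'     outside the green bands -- the missed-detection regime.}
#' }
#' Reproducible: scene i uses a seed derived from \code{seed} and is
#' recorded in the scene's spec.
#'
#' @param style one of \code{day_green}, \code{night}, \code{stubble_glare},
#'   \code{grass_thin}, \code{purple_stressed}.
#' @param n number of scenes (>= 1).
#' @param seed integer battery seed.
#' @param width,height scene canvas size.
#' @return list of [SyntheticScene-class] objects, length \code{n}.
#' @examples
#' battery <- sceneBattery("day_green", n = 2, seed = 11)
#' sceneTruth(battery[[1]])
#' @export
sceneBattery <- function(style, n, seed = 1L, width = 416, height = 320) {
  if (!style %in% .batteryStyles)
    stop("unknown battery style: ", style, call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    sceneSeed <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
    spec <- .withSeed(sceneSeed,
                      .styleSpec(style, width, height, sceneSeed))
    renderScene(spec)
  })
}

#' Save a synthetic scene as PNG plus JSON ground truth
#'
#' @param scene a [SyntheticScene-class].
#' @param pathPrefix output prefix; writes \code{<prefix>.png} and
#'   \code{<prefix>.json}.
#' @return the two paths, invisibly.
#' @export
writeScene <- function(scene, pathPrefix) {
  stopifnot(is(scene, "SyntheticScene"))
  png <- paste0(pathPrefix, ".png"); js <- paste0(pathPrefix, ".json")
  writeFrame(scene@frame, png)
  jsonlite::write_json(
    list(seed = scene@spec@seed, truth = scene@truth), js,
    digits = NA, auto_unbox = TRUE
  )
  invisible(c(png, js))
}

#' Save a scene battery with a manifest
#'
#' Writes each scene via [writeScene()] plus a \code{manifest.csv} listing
#' file, seed and weed count per scene.
#'
#' @param scenes list of [SyntheticScene-class] from [sceneBattery()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeBattery <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    prefix <- file.path(dir, sprintf("scene_%03d", i))
    writeScene(scenes[[i]], prefix)
    data.frame(file = basename(paste0(prefix, ".png")),
               seed = scenes[[i]]@spec@seed,
               n_weeds = nrow(scenes[[i]]@truth))
  }))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
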