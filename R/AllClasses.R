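#' @import methods
NULL

#' ThresholdProfile: tunable detection parameters
#'
#' Holds every tunable parameter of the colour-based detection pipeline:
#' the defined-threshold band on the greenness index, the HSV channel bands,
#' the minimum detected object size, and the adaptive-threshold and
#' morphology constants. Index and saturation/value bounds are on the 8-bit
#' scale 0--255; hue is on the half-circle 8-bit scale 0--179 (so green,
#' 120 degrees, sits at 60).
#'
#' @slot exgMin,exgMax defined-threshold band on the greenness index, 0--255.
#' @slot hueMin,hueMax hue band, 0--179 (half-circle convention).
#' @slot satMin,satMax saturation band, 0--255.
#' @slot valMin,valMax value (brightness) band, 0--255.
#' @slot minObjectArea smallest object area kept, in pixels.
#' @slot adaptiveBlockSize odd window size of the local adaptive threshold.
#' @slot adaptiveOffset intensity offset a pixel must exceed the local mean by.
#' @slot morphKernel size of the morphological structuring element, pixels.
#' @slot profileName label, e.g. \code{"day-hsv"}.
#' @slot useRawExG use the raw excess-green index (rather than the
#'   normalised one) as the greenness term of the combined algorithm.
#'
#' @seealso [thresholdProfile()], [presetProfile()]
#' @exportClass ThresholdProfile
setClass("ThresholdProfile",
  representation(
    exgMin = "numeric", exgMax = "numeric",
    hueMin = "numeric", hueMax = "numeric",
    satMin = "numeric", satMax = "numeric",
    valMin = "numeric", valMax = "numeric",
    minObjectArea = "numeric",
    adaptiveBlockSize = "numeric",
    adaptiveOffset = "numeric",
    morphKernel = "numeric",
    profileName = "character",
    useRawExG = "logical"
  )
)

setValidity("ThresholdProfile", function(object) {
  msg <- character()
  bands <- list(
    exg = c(object@exgMin, object@exgMax, 255),
    hue = c(object@hueMin, object@hueMax, 179),
    sat = c(object@satMin, object@satMax, 255),
    val = c(object@valMin, object@valMax, 255)
  )
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (b[1] > b[2])
      msg <- c(msg, sprintf("%sMin must be <= %sMax", nm, nm))
    if (b[1] < 0 || b[2] > b[3])
      msg <- c(msg, sprintf("%s band must lie in [0, %d]", nm, b[3]))
  }
  if (object@minObjectArea < 0)
    msg <- c(msg, "minObjectArea must be >= 0")
  if (object@adaptiveBlockSize < 3 || object@adaptiveBlockSize %% 2 != 1)
    msg <- c(msg, "adaptiveBlockSize must be odd and >= 3")
  if (object@morphKernel < 1)
    msg <- c(msg, "morphKernel must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: one frame-processing configuration
#'
#' @slot algorithm one of \code{"exg"}, \code{"nexg"}, \code{"hsv"},
#'   \code{"exhsv"}.
#' @slot profile a [ThresholdProfile-class].
#' @slot resizeTo integer \code{c(width, height)} every frame is resized to
#'   before processing (default 416 x 320).
#' @slot visualise draw detection boxes on processed frames.
#' @slot saveFrames keep processed frames for saving.
#'
#' @seealso [pipelineConfig()], [processFrame()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    algorithm = "character",
    profile = "ThresholdProfile",
    resizeTo = "integer",
    visualise = "logical",
    saveFrames = "logical"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("exg", "nexg", "hsv", "exhsv"))
    msg <- c(msg, "algorithm must be one of exg, nexg, hsv, exhsv")
  if (length(object@resizeTo) != 2 || any(object@resizeTo < 1))
    msg <- c(msg, "resizeTo must be two positive integers (width, height)")
  if (length(msg)) msg else TRUE
})

#' ZoneConfig: lateral actuation-zone geometry and wiring
#'
#' The camera field of view (1 m on the ground by default) is split into
#' \code{nZones} equal lateral strips; a detection whose centroid falls in a
#' strip fires that strip's output channel for \code{activationDuration}
#' milliseconds.
#'
#' @slot nZones number of zones (default 4, i.e. 25 cm strips over 1 m).
#' @slot frameWidth frame width in pixels the centroids are expressed in.
#' @slot fovWidth on-ground field-of-view width in metres.
#' @slot pinMap integer vector; \code{pinMap[i]} is the output channel of
#'   zone \code{i - 1}. Must be a bijection over zones.
#' @slot activationDuration activation length in milliseconds.
#'
#' @seealso [zoneConfig()], [assignZone()]
#' @exportClass ZoneConfig
setClass("ZoneConfig",
  representation(
    nZones = "integer",
    frameWidth = "integer",
    fovWidth = "numeric",
    pinMap = "integer",
    activationDuration = "numeric"
  )
)

setValidity("ZoneConfig", function(object) {
  msg <- character()
  if (object@nZones < 1) msg <- c(msg, "nZones must be >= 1")
  if (object@frameWidth < object@nZones)
    msg <- c(msg, "frameWidth must be >= nZones")
  if (object@fovWidth <= 0) msg <- c(msg, "fovWidth must be positive")
  if (length(object@pinMap) != object@nZones ||
      anyDuplicated(object@pinMap))
    msg <- c(msg, "pinMap must assign one distinct channel per zone")
  if (object@activationDuration <= 0)
    msg <- c(msg, "activationDuration must be positive")
  if (length(msg)) msg else TRUE
})

#' EvalResult: precision/recall of one detection run
#'
#' Precision = TP / (TP + FP); recall = TP / total weeds present. A metric
#' whose denominator is zero is undefined and stored as \code{NA} (shown as
#' \code{n/a}), never silently as zero.
#'
#' @slot truePositives,falsePositives,totalWeeds non-negative counts.
#' @slot precision,recall fractions in [0, 1], or \code{NA} when undefined.
#'
#' @seealso [precisionRecall()], [matchDetections()]
#' @exportClass EvalResult
setClass("EvalResult",
  representation(
    truePositives = "numeric",
    falsePositives = "numeric",
    totalWeeds = "numeric",
    precision = "numeric",
    recall = "numeric"
  )
)

setValidity("EvalResult", function(object) {
  msg <- character()
  if (object@truePositives < 0 || object@falsePositives < 0 ||
      object@totalWeeds < 0)
    msg <- c(msg, "counts must be non-negative")
  if (object@totalWeeds > 0 && object@truePositives > object@totalWeeds)
    msg <- c(msg, "true positives cannot exceed total weeds")
  ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!ok(object@precision) || !ok(object@recall))
    msg <- c(msg, "precision and recall must be NA or in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: parametric description of a synthetic field image
#'
#' Everything needed to render one synthetic fallow scene deterministically:
#' canvas size, soil background, stubble and specular-glare load, the weeds
#' (position, size, colour, shape), optics (blur) and illumination.
#'
#' @slot width,height canvas size in pixels.
#' @slot background one of \code{"red_orange_soil"}, \code{"dark_brown_soil"},
#'   \code{"tilled"}.
#' @slot stubbleDensity fraction in [0, 1] controlling pale straw streaks.
#' @slot specularFraction fraction in [0, 1] of the canvas covered by
#'   blown-out specular highlights.
#' @slot weeds data.frame with columns \code{cx, cy, radius, leaves, hue,
#'   sat, val, shape}; hue in degrees [0, 360), sat/val 0--255, shape one of
#'   \code{"disc"}, \code{"rosette"}, \code{"grass_blade"}.
#' @slot blurSigma Gaussian blur sigma in pixels (0 = none).
#' @slot illuminationGain multiplier applied after compositing.
#' @slot seed integer seed making the render reproducible.
#'
#' @seealso [sceneSpec()], [renderScene()], [sceneBattery()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    width = "integer", height = "integer",
    background = "character",
    stubbleDensity = "numeric",
    specularFraction = "numeric",
    weeds = "data.frame",
    blurSigma = "numeric",
    illuminationGain = "numeric",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@width < 4 || object@height < 1)
    msg <- c(msg, "canvas must be at least 4 pixels wide and 1 tall")
  if (!object@background %in%
      c("red_orange_soil", "dark_brown_soil", "tilled"))
    msg <- c(msg, "unknown background")
  frac <- c(object@stubbleDensity, object@specularFraction)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "stubbleDensity and specularFraction must be in [0, 1]")
  w <- object@weeds
  need <- c("cx", "cy", "radius", "leaves", "hue", "sat", "val", "shape")
  if (!all(need %in% names(w))) {
    msg <- c(msg, paste("weeds must have columns", paste(need, collapse = ", ")))
  } else if (nrow(w)) {
    if (any(w$cx < 0 | w$cx >= object@width |
            w$cy < 0 | w$cy >= object@height))
      msg <- c(msg, "weed centroid off canvas")
    if (any(w$radius < 1)) msg <- c(msg, "weed radius must be >= 1")
    if (!all(w$shape %in% c("disc", "rosette", "grass_blade")))
      msg <- c(msg, "unknown weed shape")
  }
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@illuminationGain <= 0)
    msg <- c(msg, "illuminationGain must be positive")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a rendered frame plus its exact ground truth
#'
#' @slot frame H x W x 3 integer array, 8-bit RGB.
#' @slot truth data.frame with one row per weed: \code{id, cx, cy, area}
#'   (area = painted pixel count before blur) and \code{shape}.
#' @slot spec the [SceneSpec-class] that produced the scene.
#'
#' @seealso [renderScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(frame = "array", truth = "data.frame", spec = "SceneSpec")
)

setValidity("SyntheticScene", function(object) {
  if (nrow(object@truth) != nrow(object@spec@weeds))
    return("ground-truth rows must match the number of weeds in the spec")
  TRUE
})
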