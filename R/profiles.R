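#' Construct a threshold profile
#'
#' @param exgMin,exgMax defined-threshold band on the greenness index (0--255).
#' @param hueMin,hueMax hue band on the 0--179 half-circle scale.
#' @param satMin,satMax saturation band (0--255).
#' @param valMin,valMax value band (0--255).
#' @param minObjectArea smallest object kept, in pixels.
#' @param adaptiveBlockSize odd local-window size of the adaptive threshold.
#' @param adaptiveOffset intensity margin above the local mean.
#' @param morphKernel structuring-element size for morphological cleaning.
#' @param profileName label for logs and file output.
#' @param useRawExG use raw excess green (not the normalised index) as the
#'   greenness term of the combined algorithm.
#' @return a [ThresholdProfile-class].
#' @examples
#' thresholdProfile(exgMin = 13, exgMax = 200, profileName = "custom")
#' @export
thresholdProfile <- function(exgMin = 13, exgMax = 200,
                             hueMin = 30, hueMax = 92,
                             satMin = 4, satMax = 250,
                             valMin = 15, valMax = 250,
                             minObjectArea = 10,
                             adaptiveBlockSize = 31,
                             adaptiveOffset = 2,
                             morphKernel = 3,
                             profileName = "custom",
                             useRawExG = FALSE) {
  new("ThresholdProfile",
    exgMin = exgMin, exgMax = exgMax,
    hueMin = hueMin, hueMax = hueMax,
    satMin = satMin, satMax = satMax,
    valMin = valMin, valMax = valMax,
    minObjectArea = minObjectArea,
    adaptiveBlockSize = adaptiveBlockSize,
    adaptiveOffset = adaptiveOffset,
    morphKernel = morphKernel,
    profileName = profileName,
    useRawExG = useRawExG
  )
}

# Shipped threshold presets. The index band is shared by the excess-green
# and normalised excess-green algorithms; the combined algorithm has its own
# wider HSV bands, and the pure HSV algorithm its own narrower ones. Night
# presets raise the index floor and the value floor to suit artificial
# illumination.
.presets <- list(
  day = list(
    exg   = list(exg = c(13, 200)),
    nexg  = list(exg = c(13, 200)),
    exhsv = list(exg = c(13, 200), hue = c(30, 92),
                 sat = c(4, 250), val = c(15, 250)),
    hsv   = list(hue = c(35, 84), sat = c(10, 220), val = c(50, 200))
  ),
  night = list(
    exg   = list(exg = c(29, 200)),
    nexg  = list(exg = c(29, 200)),
    exhsv = list(exg = c(29, 200), hue = c(30, 92),
                 sat = c(10, 250), val = c(60, 250)),
    hsv   = list(hue = c(45, 80), sat = c(75, 200), val = c(46, 240))
  )
)

#' Shipped day/night threshold presets
#'
#' Returns the tuned day or night threshold profile for one of the four
#' algorithms. All presets keep the pipeline constants (minimum object size
#' 10 px, adaptive block 31, offset 2, morphology kernel 3) and differ only
#' in the colour bands.
#'
#' @param period \code{"day"} or \code{"night"}.
#' @param algorithm \code{"exg"}, \code{"nexg"}, \code{"hsv"} or
#'   \code{"exhsv"}.
#' @return a [ThresholdProfile-class] named \code{"<period>-<algorithm>"}.
#' @examples
#' presetProfile("day", "hsv")
#' @export
presetProfile <- function(period = c("day", "night"),
                          algorithm = c("exg", "nexg", "hsv", "exhsv")) {
  period <- match.arg(period)
  algorithm <- match.arg(algorithm)
  p <- .presets[[period]][[algorithm]]
  args <- list(profileName = paste(period, algorithm, sep = "-"))
  if (!is.null(p$exg)) args <- c(args, exgMin = p$exg[1], exgMax = p$exg[2])
  if (!is.null(p$hue)) {
    args <- c(args,
      hueMin = p$hue[1], hueMax = p$hue[2],
      satMin = p$sat[1], satMax = p$sat[2],
      valMin = p$val[1], valMax = p$val[2]
    )
  }
  do.call(thresholdProfile, args)
}

.profileFields <- c(
  "exgMin", "exgMax", "hueMin", "hueMax", "satMin", "satMax",
  "valMin", "valMax", "minObjectArea", "adaptiveBlockSize",
  "adaptiveOffset", "morphKernel", "profileName", "useRawExG"
)

#' Write a threshold profile to a YAML or JSON file
#'
#' Field names in the file match the slot names, so a written profile
#' round-trips through [readProfile()] unchanged.
#'
#' @param profile a [ThresholdProfile-class].
#' @param path output file; format chosen from the extension
#'   (\code{.yml}/\code{.yaml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ThresholdProfile"))
  x <- lapply(.profileFields, function(f) slot(profile, f))
  names(x) <- .profileFields
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a threshold profile from YAML/JSON, or fetch a preset
#'
#' @param path a file path, or one of the preset names \code{"day"} /
#'   \code{"night"} (combined with \code{algorithm}).
#' @param algorithm algorithm the preset is for; ignored for files.
#' @return a [ThresholdProfile-class].
#' @export
readProfile <- function(path, algorithm = "exg") {
  if (path %in% c("day", "night")) return(presetProfile(path, algorithm))
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(x), .profileFields)
  if (length(unknown))
    stop("unknown profile fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(thresholdProfile, x)
}

#' @describeIn thresholdProfile profile label accessor.
#' @param x a \code{ThresholdProfile}.
#' @export
setMethod("profileName", "ThresholdProfile", function(x) x@profileName)

setMethod("show", "ThresholdProfile", function(object) {
  cat("ThresholdProfile '", object@profileName, "'\n", sep = "")
  cat(sprintf("  index band   : [%g, %g]\n", object@exgMin, object@exgMax))
  cat(sprintf("  hue band     : [%g, %g] (0-179)\n",
              object@hueMin, object@hueMax))
  cat(sprintf("  sat band     : [%g, %g]\n", object@satMin, object@satMax))
  cat(sprintf("  val band     : [%g, %g]\n", object@valMin, object@valMax))
  cat(sprintf("  min area %g px | adaptive %gx%g +%g | morph %g\n",
              object@minObjectArea, object@adaptiveBlockSize,
              object@adaptiveBlockSize, object@adaptiveOffset,
              object@morphKernel))
})
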