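# Run-level front end: stream frames from an image directory, file list or
# synthetic battery through the pipeline and the zone mapper, write the
# requested outputs, and benchmark algorithms.

# resolve an input spec to a list of frames plus optional truth
.frameSource <- function(input, nFrames = 10, seed = 1) {
  if (is.list(input) && length(input) && is(input[[1]], "SyntheticScene")) {
    return(list(frames = lapply(input, sceneFrame),
                truth = lapply(input, sceneTruth)))
  }
  if (is.character(input) && length(input) == 1 &&
      grepl("^synthetic:", input)) {
    style <- sub("^synthetic:", "", input)
    scenes <- sceneBattery(style, n = nFrames, seed = seed)
    return(list(frames = lapply(scenes, sceneFrame),
                truth = lapply(scenes, sceneTruth)))
  }
  paths <- if (length(input) == 1 && dir.exists(input)) {
    sort(list.files(input, pattern = "\\.(png|jpe?g|tiff?)$",
                    ignore.case = TRUE, full.names = TRUE))
  } else {
    input
  }
  if (!length(paths) || !all(file.exists(paths)))
    stop("unreadable input: ", paste(input, collapse = ", "), call. = FALSE)
  list(frames = paths, truth = NULL)
}

.loadFrame <- function(x) if (is.character(x)) readFrame(x) else x

#' Run detection over a frame stream
#'
#' Streams frames through [processFrame()] and the zone mapper, optionally
#' writing a detection CSV, annotated frames and a mock-actuation
#' transition log. Frame timestamps advance by \code{framePeriod}
#' milliseconds. Per-frame failures are logged and skipped, not fatal.
#'
#' @param input a directory of images, a vector of image paths,
#'   \code{"synthetic:<style>"} (see [sceneBattery()]), or a list of
#'   [SyntheticScene-class] objects.
#' @param config a [PipelineConfig-class].
#' @param zones a [ZoneConfig-class]; its \code{frameWidth} should match
#'   \code{config@resizeTo[1]}.
#' @param outDir output directory, created if needed; required when any
#'   output flag is set.
#' @param csv write \code{detections.csv} (schema
#'   \code{frame_index,x,y,w,h,cx,cy,area,zone}).
#' @param saveFrames write annotated \code{frame_####.png} images with red
#'   detection boxes.
#' @param actuationLog write \code{actuation.csv}
#'   (\code{channel,state,t_ms}) from the mock relay backend.
#' @param nFrames,seed frame count and seed for synthetic inputs.
#' @param framePeriod milliseconds between frame timestamps.
#' @return list: \code{frames} processed, \code{detections} (data.frame),
#'   \code{activations}, \code{meanFps} (wall-clock, hardware-dependent),
#'   \code{failures}, and paths of files written.
#' @examples
#' s <- runDetect("synthetic:day_green", pipelineConfig("exg"),
#'                nFrames = 2, seed = 3)
#' s$frames
#' @export
runDetect <- function(input, config = pipelineConfig("exg"),
                      zones = zoneConfig(frameWidth = config@resizeTo[1]),
                      outDir = NULL, csv = !is.null(outDir),
                      saveFrames = FALSE, actuationLog = FALSE,
                      nFrames = 10, seed = 1, framePeriod = 100) {
  src <- .frameSource(input, nFrames = nFrames, seed = seed)
  wantOut <- csv || saveFrames || actuationLog
  if (wantOut) {
    if (is.null(outDir)) stop("outDir required for file outputs",
                              call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  }
  all <- list(); pending <- NULL; failures <- 0L
  written <- character()
  t0 <- Sys.time()
  for (i in seq_along(src$frames)) {
    det <- tryCatch({
      frame <- .loadFrame(src$frames[[i]])
      d <- processFrame(frame, config, frameIndex = i - 1L)
      if (nrow(d)) d$zone <- assignZone(d$cx, zones)
      if (saveFrames) {
        rf <- resizeFrame(frame, config@resizeTo[1], config@resizeTo[2])
        fp <- file.path(outDir, sprintf("frame_%04d.png", i - 1L))
        writeFrame(annotateFrame(rf, d), fp)
        written <- c(written, fp)
      }
      d
    }, error = function(e) {
      message("frame ", i - 1L, " failed: ", conditionMessage(e))
      failures <<- failures + 1L
      NULL
    })
    if (is.null(det)) next
    pending <- scheduleActivations(det, now = (i - 1L) * framePeriod,
                                   config = zones, pending = pending)
    all[[length(all) + 1L]] <- det
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  detections <- if (length(all)) do.call(rbind, all) else
    cbind(findDetections(matrix(0, 4, 4) * 0, 0)[0, ], zone = integer())
  if (csv) {
    fp <- file.path(outDir, "detections.csv")
    writeDetections(detections, fp)
    written <- c(written, fp)
  }
  if (actuationLog) {
    backend <- mockRelayBackend()
    log <- if (!is.null(pending) && nrow(pending))
      driveBackend(pending, backend) else backend$log
    fp <- file.path(outDir, "actuation.csv")
    utils::write.csv(log, fp, row.names = FALSE)
    written <- c(written, fp)
  }
  list(
    frames = length(src$frames), detections = detections,
    activations = if (is.null(pending)) .emptyActivations() else pending,
    meanFps = length(src$frames) / max(elapsed, 1e-9),
    failures = failures, files = written, truth = src$truth
  )
}

#' Evaluate a detection log against ground truth
#'
#' Matches detections to ground truth per frame (see [matchDetections()]);
#' a weed detected in several frames counts once per run (deduplicated by
#' ground-truth id), while every unmatched detection counts as a false
#' positive. Ground truth without a \code{frame} column applies to every
#' frame.
#'
#' @param detections a detection data.frame or CSV path.
#' @param truth a ground-truth data.frame or CSV/JSON path
#'   (\code{id,cx,cy[,frame,...]}).
#' @param tolerance centroid match tolerance, pixels.
#' @param report optional CSV path for a one-row summary.
#' @return an [EvalResult-class].
#' @export
runEvaluate <- function(detections, truth, tolerance = 50, report = NULL) {
  if (is.character(detections)) detections <- readDetections(detections)
  if (is.character(truth)) truth <- readGroundTruth(truth)
  miss <- setdiff(c("cx", "cy"), names(detections))
  if (length(miss))
    stop("detections are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  frames <- if ("frame_index" %in% names(detections) && nrow(detections))
    sort(unique(detections$frame_index)) else 0L
  matched <- integer(); fp <- 0L
  for (f in frames) {
    det <- if ("frame_index" %in% names(detections))
      detections[detections$frame_index == f, , drop = FALSE] else detections
    tru <- if ("frame" %in% names(truth))
      truth[truth$frame == f, , drop = FALSE] else truth
    m <- matchDetections(det, tru, tolerance)
    matched <- union(matched, m$matchedIds)
    fp <- fp + m$fp
  }
  res <- precisionRecall(length(matched), fp, nrow(truth))
  if (!is.null(report)) {
    utils::write.csv(data.frame(
      tp = truePositives(res), fp = falsePositives(res),
      total_weeds = totalWeeds(res),
      precision_pct = round(100 * precision(res), 1),
      recall_pct = round(100 * recall(res), 1)
    ), report, row.names = FALSE)
  }
  res
}

#' Benchmark algorithm frame rates
#'
#' Feeds the identical frame stream to each algorithm and reports the mean
#' wall-clock frames per second. Absolute values are hardware-dependent and
#' are reported, never asserted.
#'
#' @param algorithms character vector of algorithm names.
#' @param frames number of frames (>= 1).
#' @param input frame source as in [runDetect()]; defaults to a synthetic
#'   day battery.
#' @param seed seed for synthetic inputs.
#' @return data.frame with columns \code{algorithm, fps, frames}.
#' @export
runBenchmark <- function(algorithms = c("exg", "nexg", "hsv", "exhsv"),
                         frames = 10, input = "synthetic:day_green",
                         seed = 1) {
  if (frames < 1) stop("frames must be >= 1", call. = FALSE)
  src <- .frameSource(input, nFrames = frames, seed = seed)
  mats <- lapply(src$frames, .loadFrame)
  do.call(rbind, lapply(algorithms, function(alg) {
    cfg <- pipelineConfig(alg)
    t0 <- Sys.time()
    for (i in seq_along(mats)) processFrame(mats[[i]], cfg, i - 1L)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    data.frame(algorithm = alg, fps = length(mats) / max(dt, 1e-9),
               frames = length(mats))
  }))
}
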