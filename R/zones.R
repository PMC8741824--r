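# Lateral actuation zones: the on-ground field of view is split into equal
# strips, each wired to one output channel (relay) that fires for a set
# duration when a weed is detected in the strip.

#' Construct a zone configuration
#'
#' @param nZones number of lateral zones (default 4: four 25 cm strips
#'   across a 1 m field of view).
#' @param frameWidth width in pixels of the frames detections come from.
#' @param fovWidth on-ground field-of-view width, metres.
#' @param pinMap integer channel per zone (defaults to \code{0:(nZones-1)}).
#' @param activationDuration activation length, milliseconds.
#' @return a [ZoneConfig-class].
#' @examples
#' zoneConfig()
#' @export
zoneConfig <- function(nZones = 4, frameWidth = 416, fovWidth = 1.0,
                       pinMap = seq_len(nZones) - 1L,
                       activationDuration = 200) {
  new("ZoneConfig",
    nZones = as.integer(nZones), frameWidth = as.integer(frameWidth),
    fovWidth = fovWidth, pinMap = as.integer(pinMap),
    activationDuration = activationDuration
  )
}

#' @describeIn zoneConfig on-ground width of one zone in metres
#'   (\code{fovWidth / nZones}).
#' @param x a \code{ZoneConfig}.
#' @export
setMethod("zoneWidthGround", "ZoneConfig",
          function(x) x@fovWidth / x@nZones)

setMethod("show", "ZoneConfig", function(object) {
  cat(sprintf(
    "ZoneConfig: %d zones x %.3g m over %d px | %g ms activations\n",
    object@nZones, zoneWidthGround(object), object@frameWidth,
    object@activationDuration
  ))
})

#' Map a detection centroid to its actuation zone
#'
#' Zones are half-open equal-width bins over \code{[0, frameWidth)}:
#' \code{zone = floor(x * nZones / frameWidth)}, clamped to the last zone,
#' so every in-frame x maps to exactly one zone with no gaps or overlaps.
#'
#' @param centroidX centroid x coordinate(s) in pixels, 0-based.
#' @param config a [ZoneConfig-class].
#' @return integer zone index/indices in \code{[0, nZones)}.
#' @examples
#' assignZone(c(0, 300, 415), zoneConfig())
#' @export
assignZone <- function(centroidX, config) {
  stopifnot(is(config, "ZoneConfig"))
  if (any(centroidX < 0 | centroidX >= config@frameWidth))
    stop("centroid x outside frame [0, frameWidth)", call. = FALSE)
  pmin(as.integer(floor(centroidX * config@nZones / config@frameWidth)),
       config@nZones - 1L)
}

.emptyActivations <- function() {
  data.frame(
    zone = integer(), channel = integer(), start_time = numeric(),
    end_time = numeric(), source_frame = integer()
  )
}

#' Schedule zone activations for one frame's detections
#'
#' One activation per distinct zone hit in the frame. A zone already active
#' at \code{now} has its end time extended to \code{now + duration}
#' (retrigger-extends policy) instead of gaining a duplicate, so contiguous
#' weeds produce continuous actuation.
#'
#' @param detections detection data.frame with a \code{cx} column.
#' @param now current time, milliseconds.
#' @param config a [ZoneConfig-class].
#' @param pending activation data.frame from previous calls (or missing).
#' @return updated activation data.frame with columns \code{zone, channel,
#'   start_time, end_time, source_frame}.
#' @export
scheduleActivations <- function(detections, now, config,
                                pending = .emptyActivations()) {
  stopifnot(is(config, "ZoneConfig"))
  if (is.null(pending)) pending <- .emptyActivations()
  if (nrow(detections) == 0) return(pending)
  zones <- sort(unique(assignZone(detections$cx, config)))
  dur <- config@activationDuration
  frameIdx <- if (nrow(detections)) detections$frame_index[1] else NA_integer_
  for (z in zones) {
    active <- which(pending$zone == z & pending$end_time > now)
    if (length(active)) {
      pending$end_time[active] <- now + dur
    } else {
      pending <- rbind(pending, data.frame(
        zone = z, channel = config@pinMap[z + 1L],
        start_time = now, end_time = now + dur,
        source_frame = as.integer(frameIdx)
      ))
    }
  }
  rownames(pending) <- NULL
  pending
}

#' Create a mock relay backend
#'
#' Records every channel transition instead of driving hardware. The
#' returned object is an environment with \code{setChannel(channel, on,
#' time)} and a \code{log} data.frame (\code{channel, state, t_ms}); a
#' hardware backend honours the same \code{setChannel} contract.
#'
#' @return a mock backend environment.
#' @examples
#' be <- mockRelayBackend()
#' be$setChannel(0, TRUE, 0); be$setChannel(0, FALSE, 200)
#' be$log
#' @export
mockRelayBackend <- function() {
  env <- new.env()
  env$log <- data.frame(channel = integer(), state = character(),
                        t_ms = numeric())
  env$setChannel <- function(channel, on, time) {
    env$log <- rbind(env$log, data.frame(
      channel = as.integer(channel),
      state = if (isTRUE(on)) "on" else "off",
      t_ms = time
    ))
    invisible(TRUE)
  }
  env
}

#' Drive a relay backend from an activation schedule
#'
#' Merges overlapping activations per channel (so a retriggered zone emits
#' exactly one on and one off, never glitching) and replays the on/off
#' transitions through the backend in time order. A failing backend raises
#' an actuation error identifying the channel; the detection loop catches
#' it.
#'
#' @param activations activation data.frame from [scheduleActivations()].
#' @param backend an object with \code{setChannel(channel, on, time)};
#'   see [mockRelayBackend()].
#' @return the backend's transition log (for the mock backend), invisibly
#'   for others.
#' @export
driveBackend <- function(activations, backend) {
  if (is.null(backend$setChannel))
    stop("backend must provide setChannel(channel, on, time)", call. = FALSE)
  events <- data.frame(channel = integer(), on = logical(), t = numeric())
  for (ch in unique(activations$channel)) {
    a <- activations[activations$channel == ch, , drop = FALSE]
    a <- a[order(a$start_time), , drop = FALSE]
    # merge intervals that touch or overlap
    s <- a$start_time[1]; e <- a$end_time[1]
    for (i in seq_len(nrow(a))[-1]) {
      if (a$start_time[i] <= e) {
        e <- max(e, a$end_time[i])
      } else {
        events <- rbind(events,
                        data.frame(channel = ch, on = c(TRUE, FALSE),
                                   t = c(s, e)))
        s <- a$start_time[i]; e <- a$end_time[i]
      }
    }
    events <- rbind(events,
                    data.frame(channel = ch, on = c(TRUE, FALSE), t = c(s, e)))
  }
  events <- events[order(events$t, events$channel, !events$on), ,
                   drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ok <- tryCatch(
      backend$setChannel(events$channel[i], events$on[i], events$t[i]),
      error = function(e) {
        stop("actuation error on channel ", events$channel[i], ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  if (!is.null(backend$log)) backend$log else invisible(NULL)
}
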