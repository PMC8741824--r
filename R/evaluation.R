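# Scoring detections against ground truth: greedy centroid matching,
# precision/recall, weed density, and the per-field / per-algorithm
# aggregation of a metric table.

#' Match detections to ground-truth weeds
#'
#' Greedy nearest-centroid matching: candidate pairs within
#' \code{tolerance} pixels are taken closest-first; each ground-truth weed
#' and each detection is used at most once. Detections with no truth inside
#' the tolerance are false positives; several detections on one weed count
#' as one true positive plus false positives for the remainder. Both inputs
#' are canonically sorted first, so the result does not depend on row
#' order; distance ties break on truth id then detection position.
#'
#' @param detections data.frame with centroid columns \code{cx, cy}.
#' @param truth data.frame with columns \code{id, cx, cy} (one row per
#'   weed).
#' @param tolerance maximum centroid distance in pixels for a match.
#' @return list with counts \code{tp} and \code{fp} and the vector
#'   \code{matchedIds} of matched truth ids.
#' @examples
#' det <- data.frame(cx = c(10, 11, 12), cy = c(10, 10, 10))
#' tru <- data.frame(id = 1, cx = 10, cy = 10)
#' matchDetections(det, tru, 50)  # 1 TP, 2 FP
#' @export
matchDetections <- function(detections, truth, tolerance = 50) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(tp = 0L, fp = as.integer(nd), matchedIds = integer()))
  det <- detections[order(detections$cy, detections$cx), , drop = FALSE]
  tru <- truth[order(truth$id), , drop = FALSE]
  dx <- outer(det$cx, tru$cx, "-")
  dy <- outer(det$cy, tru$cy, "-")
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= tolerance, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(dist[cand], cand[, 2], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
  }
  usedDet <- logical(nd); usedTru <- logical(nt)
  matched <- integer()
  for (i in seq_len(nrow(cand))) {
    d <- cand[i, 1]; t <- cand[i, 2]
    if (usedDet[d] || usedTru[t]) next
    usedDet[d] <- TRUE; usedTru[t] <- TRUE
    matched <- c(matched, tru$id[t])
  }
  list(tp = sum(usedDet), fp = as.integer(nd - sum(usedDet)),
       matchedIds = sort(matched))
}

#' Precision and recall from raw counts
#'
#' Precision = TP / (TP + FP); recall = TP / total weeds present. A metric
#' whose denominator is zero is undefined and returned as \code{NA}
#' (printed \code{n/a}), never coerced to zero.
#'
#' @param tp,fp,totalWeeds non-negative counts.
#' @return an [EvalResult-class].
#' @examples
#' precisionRecall(5, 0, 10)
#' @export
precisionRecall <- function(tp, fp, totalWeeds) {
  if (tp < 0 || fp < 0 || totalWeeds < 0)
    stop("counts must be non-negative", call. = FALSE)
  new("EvalResult",
    truePositives = tp, falsePositives = fp, totalWeeds = totalWeeds,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (totalWeeds > 0) tp / totalWeeds else NA_real_
  )
}

#' @describeIn precisionRecall true-positive count accessor.
#' @param x an \code{EvalResult}.
#' @export
setMethod("truePositives", "EvalResult", function(x) x@truePositives)

#' @describeIn precisionRecall false-positive count accessor.
#' @export
setMethod("falsePositives", "EvalResult", function(x) x@falsePositives)

#' @describeIn precisionRecall ground-truth weed count accessor.
#' @export
setMethod("totalWeeds", "EvalResult", function(x) x@totalWeeds)

#' @describeIn precisionRecall precision accessor (\code{NA} if undefined).
#' @export
setMethod("precision", "EvalResult", function(x) x@precision)

#' @describeIn precisionRecall recall accessor (\code{NA} if undefined).
#' @export
setMethod("recall", "EvalResult", function(x) x@recall)

.fmtPct <- function(x) if (is.na(x)) "n/a" else sprintf("%.1f%%", 100 * x)

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: TP %g, FP %g of %g weeds | precision %s, recall %s\n",
    object@truePositives, object@falsePositives, object@totalWeeds,
    .fmtPct(object@precision), .fmtPct(object@recall)
  ))
})

#' Weed density over a transect
#'
#' @param totalWeeds weeds counted on the transect.
#' @param transectLength transect length, metres.
#' @param fovWidth on-ground field-of-view width, metres.
#' @return plants per square metre.
#' @examples
#' weedDensity(155, 50, 1)  # 3.1 plants per m^2
#' @export
weedDensity <- function(totalWeeds, transectLength, fovWidth = 1) {
  if (transectLength <= 0 || fovWidth <= 0)
    stop("transect area must be positive", call. = FALSE)
  if (totalWeeds < 0) stop("weed count must be non-negative", call. = FALSE)
  totalWeeds / (transectLength * fovWidth)
}

#' Bundled field-validation performance table
#'
#' Per-field, per-algorithm precision and recall percentages from the
#' seven-transect field validation of the four colour-based algorithms
#' (five daylight and two artificially lit night transects). One cell
#' (normalised excess green on the second night transect) is missing: the
#' algorithm lost detection entirely there.
#'
#' @return data.frame with columns \code{field, algorithm, precision,
#'   recall} (percent; \code{NA} for the missing cell).
#' @export
fieldPerformance <- function() {
  utils::read.csv(system.file("extdata", "field_performance.csv",
                              package = "spotweed"))
}

#' Bundled field-site summaries
#'
#' Background, lighting, weed density and transect geometry for the seven
#' validation transects.
#'
#' @return a data.frame, one row per field site.
#' @export
fieldSites <- function() {
  utils::read.csv(system.file("extdata", "field_sites.csv",
                              package = "spotweed"))
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Aggregate a per-field, per-algorithm metric table
#'
#' Computes the summary statistics of a metric table laid out like
#' [fieldPerformance()]: overall mean and standard error over all present
#' cells, per-algorithm means/medians, and per-field means. Missing cells
#' are excluded from every statistic, never treated as zero.
#'
#' @param table data.frame with columns \code{field, algorithm, precision,
#'   recall} (percent).
#' @return list with elements \code{overall} (data.frame of mean/sem/n for
#'   each metric), \code{byAlgorithm} and \code{byField} (data.frames with
#'   mean, sem and median columns per metric).
#' @examples
#' agg <- aggregateMetrics(fieldPerformance())
#' agg$overall
#' @export
aggregateMetrics <- function(table) {
  need <- c("field", "algorithm", "precision", "recall")
  if (!all(need %in% names(table)) || nrow(table) == 0)
    stop("metric table must be non-empty with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  stat <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sem = .sem(x), median = stats::median(x),
      n = length(x))
  }
  overall <- rbind(
    precision = stat(table$precision)[c("mean", "sem", "n")],
    recall = stat(table$recall)[c("mean", "sem", "n")]
  )
  byGroup <- function(key) {
    groups <- unique(table[[key]])
    do.call(rbind, lapply(groups, function(g) {
      sub <- table[table[[key]] == g, ]
      p <- stat(sub$precision); r <- stat(sub$recall)
      data.frame(
        group = g,
        mean_precision = p["mean"], sem_precision = p["sem"],
        median_precision = p["median"],
        mean_recall = r["mean"], sem_recall = r["sem"],
        median_recall = r["median"],
        n = p["n"], row.names = NULL
      )
    }))
  }
  byAlg <- byGroup("algorithm"); names(byAlg)[1] <- "algorithm"
  byField <- byGroup("field"); names(byField)[1] <- "field"
  list(overall = as.data.frame(overall), byAlgorithm = byAlg,
       byField = byField)
}

#' Write and read ground truth
#'
#' Ground truth is stored as CSV (\code{id,frame,cx,cy,area[,species]}) or
#' JSON with the same fields.
#'
#' @param truth data.frame with at least \code{id, cx, cy}.
#' @param path output path (\code{.csv} or \code{.json}).
#' @return \code{path} invisibly; \code{readGroundTruth} returns the
#'   data.frame.
#' @export
writeGroundTruth <- function(truth, path) {
  if (anyDuplicated(truth$id))
    stop("ground-truth ids must be unique", call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(truth, path, digits = NA)
  } else {
    utils::write.csv(truth, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path,
                               call. = FALSE)
  truth <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path)
  }
  miss <- setdiff(c("id", "cx", "cy"), names(truth))
  if (length(miss))
    stop("ground truth is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  truth
}
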