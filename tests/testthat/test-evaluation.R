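# Matching, precision/recall, density and table aggregation.

test_that("greedy centroid matching handles the canonical layouts", {
  tru <- data.frame(id = 1, cx = 10, cy = 10)
  none <- matchDetections(data.frame(cx = numeric(), cy = numeric()),
                          tru, 50)
  expect_equal(c(none$tp, none$fp), c(0, 0))
  exact <- matchDetections(data.frame(cx = 10, cy = 10), tru, 50)
  expect_equal(c(exact$tp, exact$fp), c(1, 0))
  # three detections on one weed: 1 TP + 2 FP, agreeing with the
  # exhaustive optimal one-to-one matching
  det3 <- data.frame(cx = c(10, 11, 12), cy = c(10, 10, 10))
  m <- matchDetections(det3, tru, 50)
  expect_equal(c(m$tp, m$fp), c(1, 2))
  expect_equal(m$tp, optimalMatchCount(det3, tru, 50))
  # out-of-tolerance detection is a false positive
  far <- matchDetections(data.frame(cx = 200, cy = 10), tru, 50)
  expect_equal(c(far$tp, far$fp), c(0, 1))
})

test_that("greedy matching agrees with exhaustive matching on separated layouts", {
  set.seed(41)
  for (rep in 1:5) {
    nt <- sample(1:4, 1)
    tru <- data.frame(id = seq_len(nt),
                      cx = stats::runif(nt, 0, 400),
                      cy = stats::runif(nt, 0, 300))
    # detections jittered near a subset of truths, plus spurious ones
    keep <- sample(nt, sample(0:nt, 1))
    det <- data.frame(
      cx = c(tru$cx[keep] + stats::runif(length(keep), -5, 5),
             stats::runif(2, 500, 900)),
      cy = c(tru$cy[keep] + stats::runif(length(keep), -5, 5),
             stats::runif(2, 500, 900))
    )
    m <- matchDetections(det, tru, 20)
    expect_equal(m$tp, optimalMatchCount(det, tru, 20))
    expect_equal(m$fp, nrow(det) - m$tp)
  }
})

test_that("matching is invariant to input row order", {
  set.seed(43)
  tru <- data.frame(id = 1:5, cx = stats::runif(5, 0, 400),
                    cy = stats::runif(5, 0, 300))
  det <- data.frame(cx = c(tru$cx + 3, 50), cy = c(tru$cy, 250))
  a <- matchDetections(det, tru, 25)
  b <- matchDetections(det[sample(nrow(det)), ], tru[sample(5), ], 25)
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fp)
  expect_equal(a$matchedIds, b$matchedIds)
})

test_that("precision and recall follow their definitions, undefined stays NA", {
  r <- precisionRecall(5, 0, 10)
  expect_equal(precision(r), 1.0)
  expect_equal(recall(r), 0.5)
  r <- precisionRecall(0, 7, 10)
  expect_equal(precision(r), 0.0)
  expect_equal(recall(r), 0.0)
  r <- precisionRecall(0, 0, 10)
  expect_true(is.na(precision(r)))  # undefined, not zero
  expect_equal(recall(r), 0.0)
  r <- precisionRecall(3, 1, 0)
  expect_true(is.na(recall(r)))
  expect_error(precisionRecall(-1, 0, 5), "non-negative")
  # algebraic bounds on random counts
  set.seed(47)
  for (rep in 1:10) {
    tot <- sample(1:50, 1); tp <- sample(0:tot, 1); fp <- sample(0:20, 1)
    r <- precisionRecall(tp, fp, tot)
    expect_true(is.na(precision(r)) ||
                  (precision(r) >= 0 && precision(r) <= 1))
    expect_true(recall(r) >= 0 && recall(r) <= 1)
    expect_true(truePositives(r) <= totalWeeds(r))
  }
})

test_that("weed density divides count by transect area", {
  expect_equal(weedDensity(155, 50, 1), 3.1)
  expect_equal(weedDensity(465, 50, 1), 9.3)
  expect_equal(weedDensity(0, 50, 1), 0)
  expect_error(weedDensity(10, 0, 1), "positive")
})

test_that("the bundled field table aggregates to the published-style summaries", {
  tbl <- fieldPerformance()
  expect_equal(nrow(tbl), 28)
  expect_equal(sum(is.na(tbl$precision)), 1)  # one lost transect cell
  agg <- aggregateMetrics(tbl)
  expect_equal(agg$overall["precision", "n"], 27)
  expect_equal(round(agg$overall["precision", "mean"], 1), 78.8)
  expect_equal(round(agg$overall["recall", "mean"], 1), 52.2)
  ba <- agg$byAlgorithm
  expect_equal(ba$median_recall[ba$algorithm == "exg"], 68.1)
  expect_equal(ba$median_precision[ba$algorithm == "hsv"], 96.6)
  bf <- agg$byField
  expect_equal(round(bf$mean_precision[bf$field == "HEN1"], 1), 26.6)
  expect_equal(bf$mean_precision[bf$field == "WAG1"], 95.65)
  # missing cells are excluded, never zero-filled
  expect_equal(ba$n[ba$algorithm == "nexg"], 6)
})

test_that("aggregation of a single cell returns that cell for every statistic", {
  one <- data.frame(field = "A", algorithm = "exg",
                    precision = 42.5, recall = 77.0)
  agg <- aggregateMetrics(one)
  expect_equal(agg$overall["precision", "mean"], 42.5)
  expect_equal(agg$byAlgorithm$median_precision, 42.5)
  expect_equal(agg$byField$mean_recall, 77.0)
  expect_error(aggregateMetrics(one[0, ]), "non-empty")
})

test_that("ground truth round-trips through CSV and JSON", {
  tru <- data.frame(id = 1:3, frame = 0L, cx = c(1.5, 20, 300),
                    cy = c(2, 40, 100), area = c(80L, 120L, 95L))
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    writeGroundTruth(tru, path)
    back <- readGroundTruth(path)
    expect_equal(back$cx, tru$cx)
    expect_equal(back$id, tru$id)
    unlink(path)
  }
  expect_error(writeGroundTruth(data.frame(id = c(1, 1), cx = 0, cy = 0),
                                tempfile()), "unique")
})

test_that("bundled site summaries are consistent with their densities", {
  sites <- fieldSites()
  expect_equal(nrow(sites), 7)
  # density times transect area recovers an integer weed count
  counts <- sites$weed_density_per_m2 * sites$transect_length_m *
    sites$fov_width_m
  expect_equal(counts, round(counts))
  expect_equal(weedDensity(counts[sites$field == "HEN1"],
                           sites$transect_length_m[1], 1),
               sites$weed_density_per_m2[sites$field == "HEN1"])
})
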