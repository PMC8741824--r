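# Greenness indices and colour masks.

test_that("excess green matches hand-evaluated pixels and clips", {
  expect_equal(exgMap(rgbFrame(100, 100, 100, width = 4, height = 2))[1, 1], 0)
  expect_equal(exgMap(rgbFrame(50, 150, 40, width = 4, height = 2))[1, 1], 210)
  # negative raw value clips to zero instead of wrapping
  expect_equal(exgMap(rgbFrame(0, 0, 255, width = 4, height = 2))[1, 1], 0)
  # saturated green clips at 255
  expect_equal(exgMap(rgbFrame(0, 255, 0, width = 4, height = 2))[1, 1], 255)
})

test_that("normalised excess green handles grays, saturation and black", {
  expect_equal(nexgMap(rgbFrame(100, 100, 100, width = 4, height = 2))[1, 1], 0)
  expect_equal(nexgMap(rgbFrame(0, 255, 0, width = 4, height = 2))[1, 1], 255)
  # zero-sum guard: black is never vegetation
  expect_equal(nexgMap(rgbFrame(0, 0, 0, width = 4, height = 2))[1, 1], 0)
})

test_that("achromatic frames give all-zero index maps", {
  for (v in c(0, 77, 255)) {
    f <- rgbFrame(v, v, v, width = 6, height = 5)
    expect_true(all(exgMap(f) == 0))
    expect_true(all(nexgMap(f) == 0))
  }
})

test_that("excess green is invariant to a brightness offset when no clipping engages", {
  set.seed(31)
  # channels in [60, 140] so +/-40 offsets cannot clip the index or channels
  base <- array(sample(60:140, 5 * 5 * 3, replace = TRUE), dim = c(5, 5, 3))
  for (off in c(-40, 15, 40)) {
    expect_equal(exgMap(base + off), exgMap(base))
  }
})

test_that("vectorised index maps equal per-pixel loop evaluation", {
  set.seed(7)
  for (rep in 1:5) {
    f <- randomFrame(5, 5)
    expect_identical(unname(exgMap(f)), loopExg(f))
    expect_identical(unname(nexgMap(f)), loopNexg(f))
  }
})

test_that("HSV mask applies inclusive bands on the half-circle hue scale", {
  day <- presetProfile("day", "hsv")
  # pure green: H = 60 in range, but V = 255 exceeds the value cap, so
  # saturated brights are excluded
  expect_equal(hsvMask(rgbFrame(0, 255, 0, width = 4, height = 2), day)[1, 1], 0)
  # black fails any positive value floor
  expect_equal(hsvMask(rgbFrame(0, 0, 0, width = 4, height = 2), day)[1, 1], 0)
  # mid green sits inside all three wide bands
  wide <- thresholdProfile(hueMin = 30, hueMax = 92, satMin = 10,
                           satMax = 250, valMin = 15, valMax = 250)
  expect_equal(hsvMask(rgbFrame(40, 160, 40, width = 4, height = 2),
                       wide)[1, 1], 255)
})

test_that("HSV mask agrees with a per-pixel byte-scale conversion", {
  set.seed(11)
  prof <- presetProfile("day", "exhsv")
  for (rep in 1:3) {
    f <- randomFrame(5, 5)
    expect_identical(unname(hsvMask(f, prof)), loopHsvMask(f, prof))
  }
})

test_that("combined mask is the intersection of index band and HSV bands", {
  prof <- presetProfile("day", "exhsv")
  # all-gray frame: index 0 < 13 everywhere, conjunction fails
  expect_true(all(exhsvMask(rgbFrame(120, 120, 120, width = 6, height = 4),
                            prof) == 0))
  # pixel in all bands: mid green
  f <- rgbFrame(52, 140, 52, width = 4, height = 2)
  expect_equal(exhsvMask(f, prof)[1, 1], 255)
  # containment: combined mask never exceeds the HSV mask
  set.seed(13)
  for (rep in 1:4) {
    f <- randomFrame(8, 8)
    expect_true(all(exhsvMask(f, prof) <= hsvMask(f, prof)))
  }
})

test_that("the combined algorithm can switch its greenness term to raw excess green", {
  # pixel whose raw ExG is in band but whose normalised index is not:
  # dark pixel scaled up by normalisation
  f <- rgbFrame(10, 30, 10, width = 4, height = 2)  # ExG 40, NExG 204
  pNorm <- thresholdProfile(exgMin = 13, exgMax = 100, valMin = 0,
                            satMin = 0, hueMin = 0, hueMax = 179)
  pRaw <- thresholdProfile(exgMin = 13, exgMax = 100, valMin = 0,
                           satMin = 0, hueMin = 0, hueMax = 179,
                           useRawExG = TRUE)
  expect_equal(exhsvMask(f, pNorm)[1, 1], 0)
  expect_equal(exhsvMask(f, pRaw)[1, 1], 255)
})

test_that("masks are strictly two-valued and inputs are validated", {
  set.seed(17)
  f <- randomFrame(6, 6)
  prof <- presetProfile("day", "hsv")
  expect_true(all(hsvMask(f, prof) %in% c(0, 255)))
  expect_true(all(exhsvMask(f, presetProfile("day", "exhsv")) %in% c(0, 255)))
  expect_error(exgMap(matrix(0, 4, 4)), "3")
  expect_error(exgMap(array(300, dim = c(4, 4, 3))), "255")
})

test_that("preset profiles carry the tuned day and night bands", {
  expect_equal(presetProfile("day", "exg")@exgMin, 13)
  expect_equal(presetProfile("night", "nexg")@exgMin, 29)
  hsvN <- presetProfile("night", "hsv")
  expect_equal(c(hsvN@hueMin, hsvN@hueMax), c(45, 80))
  expect_equal(c(hsvN@satMin, hsvN@satMax), c(75, 200))
  expect_equal(c(hsvN@valMin, hsvN@valMax), c(46, 240))
  expect_equal(presetProfile("day", "exhsv")@satMin, 4)
  expect_error(thresholdProfile(exgMin = 50, exgMax = 10))
  expect_error(thresholdProfile(adaptiveBlockSize = 30))
})

test_that("profiles round-trip through YAML and JSON", {
  p <- thresholdProfile(exgMin = 21, exgMax = 180, profileName = "rt",
                        useRawExG = TRUE)
  for (ext in c(".yml", ".json")) {
    path <- tempfile(fileext = ext)
    writeProfile(p, path)
    q <- readProfile(path)
    for (f in slotNames(p)) expect_equal(slot(q, f), slot(p, f), info = f)
    unlink(path)
  }
  expect_error(readProfile(tempfile(fileext = ".yml")), "not found")
})
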