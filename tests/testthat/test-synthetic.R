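# Synthetic scene generator: determinism, ground truth, style batteries.

test_that("ground truth matches the spec's weed list", {
  none <- renderScene(sceneSpec(width = 64, height = 48, seed = 3))
  expect_equal(nrow(sceneTruth(none)), 0)
  weeds <- data.frame(
    cx = c(40, 120, 200, 280, 330, 90, 170),
    cy = c(40, 80, 120, 160, 220, 250, 40),
    radius = 6, leaves = 5L, hue = 120, sat = 140, val = 140,
    shape = c("disc", "rosette", "grass_blade", "disc", "disc",
              "rosette", "disc")
  )
  sc <- renderScene(sceneSpec(weeds = weeds, seed = 9))
  expect_equal(nrow(sceneTruth(sc)), 7)
  expect_equal(sceneTruth(sc)$id, 1:7)
  expect_true(all(sceneTruth(sc)$area >= 1))
  # disc painted area is the pre-blur pixel count of the disc
  disc <- renderScene(sceneSpec(
    weeds = weeds[1, ], blurSigma = 2, seed = 9
  ))
  expect_equal(sceneTruth(disc)$area, sum(outer(
    (-10:10)^2, (-10:10)^2, "+"
  ) <= 36))
})

test_that("rendering is deterministic per seed and differs across seeds", {
  spec <- sceneSpec(width = 128, height = 96, stubbleDensity = 0.3,
                    specularFraction = 0.01,
                    weeds = data.frame(cx = 60, cy = 50, radius = 7,
                                       leaves = 0L, hue = 115, sat = 140,
                                       val = 150, shape = "disc"),
                    blurSigma = 1, seed = 21)
  a <- renderScene(spec); b <- renderScene(spec)
  expect_identical(sceneFrame(a), sceneFrame(b))
  expect_identical(sceneTruth(a), sceneTruth(b))
  spec2 <- spec; spec2@seed <- 22L
  expect_false(identical(sceneFrame(a), sceneFrame(renderScene(spec2))))
  # rendering does not disturb the caller's RNG stream
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(renderScene(spec)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("off-canvas weeds and malformed specs are rejected", {
  bad <- data.frame(cx = 500, cy = 10, radius = 5, leaves = 0L,
                    hue = 120, sat = 140, val = 140, shape = "disc")
  expect_error(sceneSpec(weeds = bad), "off canvas")
  expect_error(sceneSpec(background = "lunar"), "background")
  expect_error(sceneSpec(stubbleDensity = 2), "0, 1")
  expect_error(sceneBattery("noon_fog", 3), "unknown")
  expect_error(sceneBattery("day_green", 0), ">= 1")
})

test_that("batteries are reproducible and style parameters hold by construction", {
  a <- sceneBattery("day_green", n = 1, seed = 77)
  b <- sceneBattery("day_green", n = 1, seed = 77)
  expect_identical(sceneFrame(a[[1]]), sceneFrame(b[[1]]))
  expect_equal(sceneSeed(a[[1]]), sceneSeed(b[[1]]))

  day <- sceneBattery("day_green", n = 6, seed = 19)
  expect_length(day, 6)
  for (s in day) {
    hues <- s@spec@weeds$hue / 2  # degrees -> half-circle byte scale
    expect_true(all(hues >= 30 & hues <= 92))
    expect_equal(s@spec@specularFraction, 0)
  }
  purple <- sceneBattery("purple_stressed", n = 6, seed = 19)
  for (s in purple) {
    hues <- s@spec@weeds$hue / 2
    expect_true(all(hues < 30 | hues > 92))
  }
  glare <- sceneBattery("stubble_glare", n = 3, seed = 19)
  for (s in glare) expect_true(s@spec@specularFraction > 0)
  grass <- sceneBattery("grass_thin", n = 3, seed = 19)
  for (s in grass) expect_true(all(s@spec@weeds$shape == "grass_blade"))
})

test_that("specular patches are blown out: value 255, low saturation", {
  sc <- renderScene(sceneSpec(width = 128, height = 96,
                              specularFraction = 0.03, seed = 31))
  f <- sceneFrame(sc)
  hit <- f[, , 2] == 255  # green channel pinned in specular patches
  expect_true(any(hit))
  # those pixels fail the day HSV value band but pass the raw greenness floor
  mask <- hsvMask(f, presetProfile("day", "hsv"))
  expect_true(all(mask[hit] == 0))
  expect_true(mean(exgMap(f)[hit] >= 13) > 0.9)
})

test_that("scenes persist as PNG plus JSON truth with a battery manifest", {
  dir <- tempfile("battery")
  scenes <- sceneBattery("day_green", n = 2, seed = 5, width = 96,
                         height = 64)
  manifest <- writeBattery(scenes, dir)
  expect_true(file.exists(manifest))
  mf <- utils::read.csv(manifest)
  expect_equal(nrow(mf), 2)
  expect_true(all(file.exists(file.path(dir, mf$file))))
  # the PNG round-trips to the rendered frame
  back <- readFrame(file.path(dir, mf$file[1]))
  expect_equal(back, sceneFrame(scenes[[1]]))
  truth <- jsonlite::read_json(file.path(dir, "scene_001.json"),
                               simplifyVector = TRUE)$truth
  expect_equal(nrow(truth), nrow(sceneTruth(scenes[[1]])))
  unlink(dir, recursive = TRUE)
})
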