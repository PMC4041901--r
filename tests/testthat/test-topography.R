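# Incremental-threshold maps, layer/wall pattern classification, overlays.

test_that("ladder validation rejects short or non-increasing ladders", {
  expect_error(thresholdLadder(c(990)), "at least 2")
  expect_error(thresholdLadder(c(990, 990)), "strictly increasing")
  expect_error(incrementalMasks(NULL, ladder = c(1200, 990)), "strictly increasing")
  expect_identical(thresholdLadder(), c(990, 1030, 1070, 1110, 1150, 1200))
})

test_that("ladder masks nest after area filtering and extent is monotone", {
  res <- synthesizeSubject(groupPreset("I"), smallGeom(4), seed = 19)
  s <- res$study
  masks <- incrementalMasks(s, c(990, 1030, 1070, 1110), qcMode = "include-all")
  sizes <- vapply(masks, lesionPixelCount, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  for (k in seq_len(length(masks) - 1)) {
    lo <- masks[[k]]; hi <- masks[[k + 1]]
    for (nm in names(hi@masks)) {
      expect_true(all(lo@masks[[nm]][hi@masks[[nm]]]))
    }
  }
  geoms <- lapply(studySlices(s), `[[`, "geometry")
  ext <- vapply(masks, function(m)
    subjectExtent(segmentExtent(m, geoms)), numeric(1))
  expect_true(all(diff(ext) <= 1e-12))
})

test_that("a single moderate lesion appears at 990 ms but not at 1200 ms", {
  p <- zeroNoisePreset("I", meanT1 = 990, deltaT1 = 110,
                       extent = list(median = 20, iqr = c(15, 25)))
  # subject mean 990, lesion at baseline+110; baseline < 990 < lesion < 1200
  res <- synthesizeSubject(p, smallGeom(3), seed = 23)
  masks <- incrementalMasks(res$study, c(990, 1200))
  for (i in seq_len(3)) {
    expect_identical(masks[[1]]@masks[[as.character(i - 1)]],
                     res$truth$trueMasks[[i]])
  }
  expect_identical(lesionPixelCount(masks[[2]]), 0)
})

test_that("uniform normal myocardium yields empty masks at every rung", {
  res <- synthesizeSubject(zeroNoisePreset("control", meanT1 = 946),
                           smallGeom(3), seed = 1)
  masks <- incrementalMasks(res$study)
  expect_true(all(vapply(masks, lesionPixelCount, numeric(1)) == 0))
})

test_that("layer fractions classify transmural bands correctly", {
  g <- makeHeartGeometry(c(64L, 64L), c(32.5, 32.5), 12, 18, c(1, 1), "mid")
  # component entirely subepicardial (depth > 2/3)
  deep <- myoMask(g) & !is.na(transmuralDepth(g)) & transmuralDepth(g) > 2 / 3 &
    segmentLabels(g) == 11L
  les <- filterContiguous(deep, c(1, 1), minArea = 10, slice = 0L)
  pat <- classifyPattern(les, list(g))
  expect_identical(nrow(pat), 1L)
  expect_identical(pat$subepicardial, 1)
  expect_identical(pat$dominantLayer, "subepicardial")
  expect_identical(pat$dominantWall, "inferolateral")
  expect_false(pat$subendocardialOnly)

  # annular sector spanning depths 0.4-1.0: no subendocardial involvement,
  # midwall and subepicardial fractions near their analytic band shares
  band <- myoMask(g) & transmuralDepth(g) >= 0.4 & segmentLabels(g) == 8L
  lesB <- filterContiguous(band, c(1, 1), minArea = 10, slice = 0L)
  patB <- classifyPattern(lesB, list(g))
  expect_lt(patB$subendocardial, 0.02)
  expect_equal(patB$midwall, 0.267 / 0.6, tolerance = 0.25)
  expect_equal(patB$subepicardial, 0.333 / 0.6, tolerance = 0.2)
  expect_equal(patB$midwall + patB$subepicardial + patB$subendocardial, 1)
})

test_that("layer fractions are invariant to rotating the whole study by 90 degrees", {
  p <- zeroNoisePreset("I", meanT1 = 1000, deltaT1 = 150,
                       extent = list(median = 20, iqr = c(15, 25)))
  res <- synthesizeSubject(p, smallGeom(3), seed = 29)
  s <- res$study
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # 90 deg ccw
  sl <- studySlices(s)[[2]]
  g <- sl$geometry
  gR <- new("HeartGeometry", center = g@center, endoRadius = g@endoRadius,
            epiRadius = g@epiRadius, myoMask = rot(g@myoMask),
            segments = rot(g@segments), muscleMask = matrix(FALSE, 64, 64),
            transmural = rot(g@transmural), pixelSpacing = g@pixelSpacing)
  map <- sl$maps$T1
  mapR <- ParametricMap(rot(pixels(map)), pixelSpacing(map), 1L, 8, "T1")
  les <- detectT1Injury(map, g)
  lesR <- detectT1Injury(mapR, gR)
  pat <- classifyPattern(les, list(NULL, g))
  patR <- classifyPattern(lesR, list(NULL, gR))
  expect_identical(nrow(pat), nrow(patR))
  if (nrow(pat)) {
    o <- order(pat$pixels); oR <- order(patR$pixels)
    expect_equal(pat$subendocardial[o], patR$subendocardial[oR], tolerance = 1e-9)
    expect_equal(pat$midwall[o], patR$midwall[oR], tolerance = 1e-9)
    expect_equal(pat$subepicardial[o], patR$subepicardial[oR], tolerance = 1e-9)
  }
})

test_that("cohort lesion menu favors subepicardial/midwall lateral-inferior patterns", {
  co <- synthesizeCohort(c(I = 12), geom = smallGeom(4), masterSeed = 77)
  pats <- list()
  for (k in seq_along(co$studies)) {
    s <- co$studies[[k]]
    geoms <- lapply(studySlices(s), `[[`, "geometry")
    # classify the ground-truth lesions themselves (menu property, not
    # detection performance)
    les <- bindLesionSlices(lapply(seq_along(geoms), function(i)
      filterContiguous(co$truth[[k]]$trueMasks[[i]], c(1.2, 1.2),
                       minArea = 20, slice = i - 1L)))
    pats[[k]] <- classifyPattern(les, geoms)
  }
  pat <- do.call(rbind, pats)
  expect_gt(nrow(pat), 10)
  expect_gt(mean(pat$subepicardial > 0), 0.6)   # subepicardial involvement common
  expect_lt(mean(pat$subendocardialOnly), 0.1)  # ischemic pattern rare
  # laterality holds for the sector centers themselves; full-ring lesions
  # (severe, near-global involvement) carry no wall preference
  centers <- unlist(lapply(co$truth, function(t) t$lesions$centerAngle))
  expect_true(all(centers >= 60 & centers <= 270))
  widths <- unlist(lapply(co$truth, function(t) t$lesions$width))
  narrow <- pat[pat$pixels < 200, ]
  if (nrow(narrow) > 5) {
    lat <- narrow$dominantWall %in% c("anterolateral", "inferolateral", "inferior")
    expect_gt(mean(lat), 0.5)
  }
})

test_that("overlay rendering marks lesions red and the reference contour green", {
  res <- synthesizeSubject(groupPreset("I"), smallGeom(3), seed = 19)
  s <- res$study
  g <- geometryFor(s, 1)
  map <- mapFor(s, 1, "T1")
  d <- withr::local_tempdir()

  # empty lesion: no pure red pixels
  p1 <- file.path(d, "empty.png")
  renderOverlay(map, g, matrix(FALSE, 64, 64), NULL, p1)
  img <- png::readPNG(p1)
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  expect_identical(sum(red), 0L)

  # full-myocardium lesion: red count equals mask size
  p2 <- file.path(d, "full.png")
  renderOverlay(map, g, myoMask(g), NULL, p2)
  img2 <- png::readPNG(p2)
  red2 <- img2[, , 1] == 1 & img2[, , 2] == 0 & img2[, , 3] == 0
  expect_identical(sum(red2), sum(myoMask(g)))

  # reference contour appears in green
  roi <- selectRemoteRoi(s, 1, "T2W")
  p3 <- file.path(d, "roi.png")
  renderOverlay(map, g, matrix(FALSE, 64, 64), roi, p3)
  img3 <- png::readPNG(p3)
  green <- img3[, , 1] == 0 & img3[, , 2] == 1 & img3[, , 3] == 0
  expect_gt(sum(green), 0)

  expect_error(renderOverlay(map, g, matrix(FALSE, 10, 10), NULL,
                             file.path(d, "x.png")), "misaligned")

  # one panel per ladder rung
  masks <- incrementalMasks(s, c(990, 1070, 1150))
  paths <- renderLadderPanels(s, masks, 1, file.path(d, "panels"))
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
})
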