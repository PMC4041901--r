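# Detection criteria, minimum-area filtering, remote-ROI selection,
# subject-level positivity.

test_that("minimum-area filter keeps 40 mm^2 components and drops smaller ones", {
  sp <- c(2, 2)  # STIR-like resolution: 40 mm^2 = 10 pixels
  m <- matrix(FALSE, 32, 32)
  m[5, 3:12] <- TRUE      # 10 pixels = 40 mm^2: retained
  m[20, 3:11] <- TRUE     # 9 pixels = 36 mm^2: removed
  les <- filterContiguous(m, sp, minArea = 40)
  expect_identical(sum(les@masks[[1]]), 10L)
  expect_identical(nrow(components(les)), 1L)
  expect_equal(components(les)$areaMM2, 40)

  empty <- filterContiguous(matrix(FALSE, 20, 20), sp, 40)
  expect_identical(sum(empty@masks[[1]]), 0L)
  expect_identical(nrow(components(empty)), 0L)
  expect_error(filterContiguous(m, sp, minArea = -1), "minArea")
})

test_that("component labeling matches the flood-fill oracle and the filter is an idempotent contraction", {
  set.seed(404)
  for (i in 1:60) {
    m <- matrix(runif(24 * 24) < runif(1, 0.2, 0.55), 24, 24)
    for (conn in c(4, 8)) {
      mine <- labelComponents(m, conn)
      oracle <- floodFillLabel(m, conn)
      expect_identical(componentSets(mine), componentSets(oracle))
    }
    les <- filterContiguous(m, c(1, 1), minArea = 5, connectivity = 8)
    out <- les@masks[[1]]
    expect_true(all(m[out]))                       # contraction
    les2 <- filterContiguous(out, c(1, 1), minArea = 5, connectivity = 8)
    expect_identical(les2@masks[[1]], out)         # idempotence
    # 4-connected components nest inside 8-connected ones
    l4 <- filterContiguous(m, c(1, 1), 5, 4)@masks[[1]]
    l8 <- filterContiguous(m, c(1, 1), 5, 8)@masks[[1]]
    expect_true(all(l8[l4]))
  }
})

test_that("T1 detection thresholds nest and respect modality and qc flags", {
  res <- synthesizeSubject(groupPreset("I"), smallGeom(4), seed = 31)
  s <- res$study
  m990 <- detectStudy(s, "T1", threshold = 990)
  m1200 <- detectStudy(s, "T1", threshold = 1200)
  for (k in names(m1200@masks)) {
    expect_true(all(m990@masks[[k]][m1200@masks[[k]]]))
  }
  expect_error(detectT1Injury(mapFor(s, 0, "T2W"), geometryFor(s, 0)),
               "requires a T1 map")
})

test_that("a uniform normal-range map yields no injury", {
  res <- synthesizeSubject(zeroNoisePreset("control", meanT1 = 946),
                           smallGeom(3), seed = 1)
  les <- detectStudy(res$study, "T1")
  expect_identical(lesionPixelCount(les), 0)
})

test_that("zero-noise lesion recovery is exact (Dice 1) for T1 and LGE", {
  p <- zeroNoisePreset("I", meanT1 = 1000, deltaT1 = 150,
                       extent = list(median = 30, iqr = c(25, 35)))
  res <- synthesizeSubject(p, smallGeom(4), seed = 9)
  lesT1 <- detectStudy(res$study, "T1")
  lesLGE <- suppressWarnings(detectStudy(res$study, "LGE"))
  for (i in seq_len(4)) {
    expect_identical(lesT1@masks[[as.character(i - 1)]],
                     res$truth$trueMasks[[i]])
    expect_identical(lesLGE@masks[[as.character(i - 1)]],
                     res$truth$lgeMasks[[i]])
  }
})

test_that("with default noise, recovery of a sizeable lesion keeps Dice above 0.8", {
  p <- groupPreset("I")
  p$meanT1 <- c(980, 0)
  p$deltaT1 <- 120
  p$extent <- list(median = 25, iqr = c(20, 30))
  res <- synthesizeSubject(p, smallGeom(5), seed = 17)
  les <- detectStudy(res$study, "T1", qcMode = "include-all")
  inter <- 0; a <- 0; b <- 0
  for (i in seq_len(5)) {
    tr <- res$truth$trueMasks[[i]]
    dm <- les@masks[[as.character(i - 1)]]
    inter <- inter + sum(tr & dm); a <- a + sum(tr); b <- b + sum(dm)
  }
  dice <- 2 * inter / (a + b)
  expect_gt(dice, 0.8)
})

test_that("T2 SI ratio arithmetic: identity, constructed value, scale invariance", {
  myo <- matrix(FALSE, 20, 20); myo[5:8, 5:8] <- TRUE
  mus <- matrix(FALSE, 20, 20); mus[15:18, 5:8] <- TRUE
  px <- matrix(0, 20, 20)
  px[myo] <- 200; px[mus] <- 200
  expect_equal(computeT2Ratio(px, myo, mus), 1.0)
  px[myo] <- 312; px[mus] <- 200
  expect_equal(computeT2Ratio(px, myo, mus), 1.56)
  expect_equal(computeT2Ratio(2 * px, myo, mus), 1.56)
  expect_error(computeT2Ratio(px, myo, matrix(FALSE, 20, 20)), "muscle")
})

test_that("T2W edema criterion fires on the 2-SD branch and stays silent on uniform tissue", {
  g <- makeHeartGeometry(c(48L, 48L), c(24.5, 24.5), 10, 15, c(1, 1), "mid",
                         muscleRows = c(42, 47), muscleCols = c(10, 38))
  px <- matrix(50, 48, 48)
  px[myoMask(g)] <- 200
  px[muscleMask(g)] <- 180  # ratio 200/180 = 1.1 < 2
  remote <- new("RemoteROI", slice = 0L, segments = 7L, mean = 200,
                sd = 10, modality = "T2W")
  map <- ParametricMap(px, c(1, 1), 0L, 8, "T2W")
  expect_identical(lesionPixelCount(detectT2Edema(map, g, remote)), 0)

  hot <- myoMask(g) & segmentLabels(g) == 11L
  px2 <- px; px2[hot] <- 225  # >= 200 + 2*10
  map2 <- ParametricMap(px2, c(1, 1), 0L, 8, "T2W")
  les <- detectT2Edema(map2, g, remote)
  expect_identical(les@masks[[1]], hot)
})

test_that("LGE criterion detects enhancement above remote + 2 SD", {
  g <- makeHeartGeometry(c(48L, 48L), c(24.5, 24.5), 10, 15, c(1, 1), "mid",
                         muscleRows = c(42, 47), muscleCols = c(10, 38))
  remote <- new("RemoteROI", slice = 0L, segments = 7L, mean = 10, sd = 5,
                modality = "LGE")
  px <- matrix(5, 48, 48); px[myoMask(g)] <- 10
  hot <- myoMask(g) & segmentLabels(g) == 9L
  px[hot] <- 50
  map <- ParametricMap(px, c(1, 1), 0L, 8, "LGE")
  les <- detectLge(map, g, remote)
  expect_identical(les@masks[[1]], hot)
  # uniform nulled myocardium: nothing
  px0 <- matrix(5, 48, 48); px0[myoMask(g)] <- 10
  expect_identical(
    lesionPixelCount(detectLge(ParametricMap(px0, c(1, 1), 0L, 8, "LGE"), g, remote)),
    0)
})

test_that("remote-ROI selection prefers quiet segments, avoids hot, dark and LGE segments", {
  res <- synthesizeSubject(zeroNoisePreset("control"), smallGeom(3), seed = 2)
  s <- res$study
  roi <- selectRemoteRoi(s, 0, "T2W")
  expect_identical(roi@segments, 1L)  # uniform slice: tie-break to lowest id

  # one elevated segment is never chosen
  sl <- studySlices(s)[[1]]
  px <- pixels(sl$maps$T2W)
  g <- sl$geometry
  hot <- myoMask(g) & segmentLabels(g) == 1L
  px[hot] <- px[hot] * 3
  sMod <- s
  sMod@slices[[1]]$maps$T2W <- ParametricMap(px, pixelSpacing(sl$maps$T2W),
                                             0L, 8, "T2W")
  roi2 <- selectRemoteRoi(sMod, 0, "T2W")
  expect_false(1L %in% roi2@segments)

  # an artifactually dark segment is excluded by the low-signal rule
  px3 <- pixels(sl$maps$T2W)
  dark <- myoMask(g) & segmentLabels(g) == 2L
  px3[dark] <- 0.1
  sMod2 <- s
  sMod2@slices[[1]]$maps$T2W <- ParametricMap(px3, pixelSpacing(sl$maps$T2W),
                                              0L, 8, "T2W")
  roi3 <- selectRemoteRoi(sMod2, 0, "T2W")
  expect_false(2L %in% roi3@segments)

  # LGE-overlapping segments are ineligible
  lge <- myoMask(g) & segmentLabels(g) %in% c(1L, 3L)
  roi4 <- selectRemoteRoi(s, 0, "T2W", lgeMask = lge)
  expect_false(any(c(1L, 3L) %in% roi4@segments))
})

test_that("subject positivity follows the default and contiguous-slice rules", {
  mk <- function(slices) {
    masks <- list(); labs <- list()
    comp <- list()
    for (s in 0:5) {
      m <- matrix(FALSE, 16, 16); l <- matrix(0L, 16, 16)
      if (s %in% slices) { m[4:8, 4:8] <- TRUE; l[4:8, 4:8] <- 1L }
      masks[[as.character(s)]] <- m
      labs[[as.character(s)]] <- l
      if (s %in% slices)
        comp[[length(comp) + 1]] <- data.frame(id = 1L, slice = s,
                                               pixels = 25L, areaMM2 = 25,
                                               centroidRow = 6, centroidCol = 6)
    }
    comp <- if (length(comp)) do.call(rbind, comp) else
      data.frame(id = integer(), slice = integer(), pixels = integer(),
                 areaMM2 = numeric(), centroidRow = numeric(),
                 centroidCol = numeric())
    new("LesionMask", masks = masks, modality = "T1", threshold = "T1>=990ms",
        minArea = 40, components = comp, labels = labs)
  }
  expect_false(subjectPositive(mk(integer()))$positive)
  expect_true(subjectPositive(mk(c(3, 4)), list(confirmSlices = 2))$positive)
  expect_false(subjectPositive(mk(c(3, 5)), list(confirmSlices = 2))$positive)
  expect_true(subjectPositive(mk(c(3, 5)))$positive)
  # confirmation only below the extent gate
  expect_true(subjectPositive(mk(c(3, 5)),
                              list(confirmSlices = 2, applyBelowExtentPct = 10),
                              extentPct = 40)$positive)
  expect_false(subjectPositive(mk(c(3, 5)),
                               list(confirmSlices = 2, applyBelowExtentPct = 10),
                               extentPct = 4)$positive)
  expect_error(subjectPositive(mk(3), list(orthogonalPlanes = TRUE)),
               "unsupported")
})

test_that("qc-excluded segments are removed from the search; include-all restores them", {
  p <- zeroNoisePreset("I", meanT1 = 1000, deltaT1 = 150,
                       extent = list(median = 30, iqr = c(25, 35)))
  res <- synthesizeSubject(p, smallGeom(3), seed = 9)
  s <- res$study
  # exclude every segment that overlaps the lesion, on every slice
  qc <- qcFlags(s)
  for (i in seq_len(3)) {
    tr <- res$truth$trueMasks[[i]]
    if (!any(tr)) next
    segs <- unique(segmentLabels(geometryFor(s, i - 1))[tr])
    qc$included[qc$slice == i - 1 & qc$modality == "T1" &
                  qc$segment %in% segs] <- FALSE
  }
  s@qcFlags <- qc
  expect_identical(lesionPixelCount(detectStudy(s, "T1", qcMode = "exclude")), 0)
  expect_gt(lesionPixelCount(detectStudy(s, "T1", qcMode = "include-all")), 0)
})
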