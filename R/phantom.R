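# Digital cardiac phantom: multiparametric short-axis cohorts with ground
# truth, calibrated to the printed population statistics of the study
# cohort (50 controls; 41 edema+/LGE+, 12 edema-/LGE+ and 7 edema-/LGE-
# patients).
#
# Signal model per subject:
#   T1:  myocardium = per-subject baseline + deltaT1 on lesion pixels,
#        baseline chosen so the subject's true mean T1 equals a draw from
#        the group's mean-T1 distribution; blood pool 1600 ms, background
#        300 ms; additive Gaussian pixel noise (Rician approximation at the
#        simulated SNR).
#   T2W: skeletal-muscle baseline x a ratio field (global per-subject ratio,
#        edematous lesions boosted); dark blood pool.
#   LGE: nulled myocardium with enhancing lesion pixels (groups I and II).
#
# Lesions are annular sectors with a circumferential center/width and a
# transmural band, preferentially subepicardial/midwall in the lateral and
# inferior walls (the non-ischemic pattern).

#' Default phantom geometry configuration
#'
#' 9 short-axis slices of 8 mm on a 128x128 grid at 0.9 x 0.9 mm (all three
#' modalities share this analysis grid), epicardial radius 32 mm, wall
#' thickness 9 mm, and a paraspinal skeletal-muscle block.
#'
#' @return list of geometry parameters.
#' @export
defaultGeometry <- function() {
  list(dim = c(128L, 128L), nSlices = 9L, spacing = c(0.9, 0.9),
       thickness = 8, center = c(64.5, 64.5), endoRadius = 23,
       epiRadius = 32, startAngle = 0,
       muscleRows = c(108L, 122L), muscleCols = c(34L, 94L),
       muscleBaseline = 200)
}

#' Group presets calibrated to the study's population statistics
#'
#' Per group: the per-subject mean myocardial T1 distribution, global T2 SI
#' ratio distribution, target true-extent distribution, lesion amplitudes
#' and pattern menu, per-modality pixel noise and segment-level qc exclusion
#' rates. Controls: T1 946 +/- 23 ms, ratio 1.56 +/- 0.15, no lesions.
#' Group I (edema+, LGE+): T1 1030 +/- 62, ratio 1.79 +/- 0.27, extent
#' median 49% (IQR 24-70), edematous LGE-enhancing lesions. Group II
#' (edema-, LGE+): T1 986 +/- 54, ratio 1.60 +/- 0.16 (below the 2.0 cut),
#' extent median 15% (12-29), enhancing lesions without T2 boost. Group III
#' (edema-, LGE-): T1 947 +/- 27, ratio 1.47 +/- 0.17, one to two small
#' non-enhancing foci (about 45-70 mm^2 per slice on 2-3 contiguous
#' slices).
#'
#' @param group one of "control", "I", "II", "III".
#' @return list of preset parameters.
#' @export
groupPreset <- function(group = c("control", "I", "II", "III")) {
  group <- match.arg(group)
  base <- list(
    group = group,
    noiseSD = c(T1 = 40, T2W = 15, LGE = 6),
    qcExclude = c(T1 = 0.11, T2W = 0.09, LGE = 0.03),
    capMean = Inf,
    lesionType = "none",
    deltaT1 = 0, lesionFloor = 1015,
    t2Boost = 0, t2CoreFrac = 0.25,
    t2BaseNormal = 1.55, t2BoostMax = 1.5,
    lgeEnhance = FALSE, lgeDelta = 65, lgeCoreFrac = 0.45,
    extent = list(median = 0, iqr = c(0, 0)),
    sliceFrac = c(0, 0),
    ef = c(72, 6), troponin = NULL, daysRange = c(1, 7),
    cleanLesionQc = FALSE
  )
  switch(group,
    control = utils::modifyList(base, list(
      meanT1 = c(946, 23), t2Ratio = c(1.56, 0.15))),
    I = utils::modifyList(base, list(
      meanT1 = c(1030, 62), t2Ratio = c(1.79, 0.27),
      lesionType = "sector", deltaT1 = 75, t2Boost = 0.35,
      lgeEnhance = TRUE,
      extent = list(median = 49, iqr = c(24, 70)), sliceFrac = c(0.6, 1),
      ef = c(61, 13), troponin = list(median = 9.6, iqr = c(3.4, 21)))),
    II = utils::modifyList(base, list(
      meanT1 = c(986, 54), t2Ratio = c(1.60, 0.16),
      lesionType = "sector", deltaT1 = 70, lgeEnhance = TRUE,
      extent = list(median = 15, iqr = c(12, 29)), sliceFrac = c(0.3, 0.6),
      ef = c(70, 11), troponin = list(median = 0.54, iqr = c(0.25, 4.19)))),
    III = utils::modifyList(base, list(
      meanT1 = c(947, 27), t2Ratio = c(1.47, 0.17),
      lesionType = "focal", deltaT1 = 90, cleanLesionQc = TRUE,
      extent = list(median = 1, iqr = c(0.5, 1.5)),
      ef = c(72, 6), troponin = list(median = 0.48, iqr = c(0.19, 1.29))))
  )
}

#' @rdname groupPreset
#' @export
defaultGroupPresets <- function() {
  ps <- lapply(STUDY_GROUPS, groupPreset)
  names(ps) <- STUDY_GROUPS
  ps
}

# Low-grade variant of a patient preset: small, mildly elevated lesions in a
# subject with near-normal mean T1. These subjects sit below the 990 ms
# detection operating point and calibrate the criterion's sensitivity.
.subtlePreset <- function(preset) {
  utils::modifyList(preset, list(
    meanT1 = c(950, 15), capMean = 960, deltaT1 = 15, lesionFloor = -Inf,
    extent = list(median = 5, iqr = c(3, 8)), sliceFrac = c(0.2, 0.4),
    lesionType = if (preset$lesionType == "none") "none" else "sector"))
}

.rlnormMedIqr <- function(n, median, iqr) {
  if (median <= 0) return(rep(0, n))
  sdlog <- max(1e-6, (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75)))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# annular band area fraction of the full ring (ignoring pixelation)
.bandAreaFrac <- function(band, endo, epi) {
  w <- epi - endo
  r0 <- endo + band[1] * w
  r1 <- endo + band[2] * w
  (r1^2 - r0^2) / (epi^2 - endo^2)
}

.sampleBand <- function() {
  u <- stats::runif(1)
  if (u < 0.55) c(0.45, 1.0) else if (u < 0.85) c(0.33, 0.85) else c(0.6, 1.0)
}

.sampleCenterAngle <- function() {
  # lateral wall 60-180 deg, inferior 180-240 deg in this convention
  if (stats::runif(1) < 0.7) stats::runif(1, 90, 200) else stats::runif(1, 160, 260)
}

.lesionMaskOnSlice <- function(geomSlice, centerAngle, width, band) {
  pg <- .polarGrids(dim(geomSlice@myoMask), geomSlice@center,
                    geomSlice@pixelSpacing)
  dAng <- (pg$theta - centerAngle + 180) %% 360 - 180
  inSector <- abs(dAng) <= width / 2
  tm <- geomSlice@transmural
  inBand <- !is.na(tm) & tm >= band[1] & tm <= band[2]
  geomSlice@myoMask & inSector & inBand
}

.buildGeometries <- function(geom) {
  lapply(seq_len(geom$nSlices), function(i) {
    makeHeartGeometry(geom$dim, geom$center, geom$endoRadius, geom$epiRadius,
                      geom$spacing, slicePosition(i - 1L, geom$nSlices),
                      geom$startAngle, geom$muscleRows, geom$muscleCols)
  })
}

#' Synthesize one subject study with ground truth
#'
#' Deterministic for a fixed seed. The per-subject baseline T1 is derived
#' from a draw of the group's mean-T1 distribution minus the lesion
#' contribution, so the subject's true mean T1 matches the target draw; the
#' T2W base ratio is likewise compensated for lesion boost so the global SI
#' ratio matches its draw.
#'
#' @param preset a group preset from [groupPreset()].
#' @param geom geometry configuration from [defaultGeometry()].
#' @param seed integer seed.
#' @param subjectId identifier stored on the study.
#' @param geoms optional precomputed list of per-slice geometries (a speed
#'   hook for cohort generation; must match \code{geom}).
#' @return list with \code{study} (\linkS4class{SubjectStudy}) and
#'   \code{truth} (group, per-slice true injury masks, true extent %,
#'   lesion table, seed).
#' @export
synthesizeSubject <- function(preset, geom = defaultGeometry(), seed = 1L,
                              subjectId = "S1", geoms = NULL) {
  if (any(preset$noiseSD < 0)) stop("negative noise SD")
  set.seed(seed)
  if (is.null(geoms)) geoms <- .buildGeometries(geom)
  n <- geom$nSlices
  d <- geom$dim

  targetMean <- min(stats::rnorm(1, preset$meanT1[1], preset$meanT1[2]),
                    preset$capMean)
  targetRatio <- max(1.05, stats::rnorm(1, preset$t2Ratio[1], preset$t2Ratio[2]))

  # --- lesion specs -------------------------------------------------------
  lesions <- list()
  if (preset$lesionType == "sector") {
    extentFrac <- min(0.9, max(0.01,
      .rlnormMedIqr(1, preset$extent$median, preset$extent$iqr) / 100))
    k <- max(2L, round(stats::runif(1, preset$sliceFrac[1], preset$sliceFrac[2]) * n))
    s0 <- sample.int(n - k + 1L, 1L) - 1L
    band <- .sampleBand()
    # severe injury deepens transmurally rather than closing the full ring:
    # the sector is capped at 300 deg so a remote reference segment always
    # survives, and the band grows towards the endocardium to absorb the
    # remaining target extent
    perSlice <- extentFrac * n / k
    dA <- .bandAreaFrac(band, geom$endoRadius, geom$epiRadius)
    if (360 * perSlice / dA > 300) {
      dNeed <- min(1, 360 * perSlice / 300)
      w <- geom$epiRadius - geom$endoRadius
      r1 <- geom$endoRadius + band[2] * w
      r0 <- sqrt(max(0, r1^2 - dNeed * (geom$epiRadius^2 - geom$endoRadius^2)))
      band[1] <- max(0, min(band[1], (r0 - geom$endoRadius) / w))
      dA <- .bandAreaFrac(band, geom$endoRadius, geom$epiRadius)
    }
    width <- min(300, 360 * perSlice / dA)
    lesions[[1]] <- list(slices = s0:(s0 + k - 1L),
                         centerAngle = .sampleCenterAngle(),
                         width = width, band = band)
  } else if (preset$lesionType == "focal") {
    nFoci <- sample(1:2, 1)
    for (f in seq_len(nFoci)) {
      k <- sample(2:3, 1)
      s0 <- sample.int(n - k + 1L, 1L) - 1L
      band <- c(0.55, 1.0)
      area <- stats::runif(1, 60, 90)   # mm^2 per slice, above the 40 mm^2 gate
      w <- geom$epiRadius - geom$endoRadius
      r0 <- geom$endoRadius + band[1] * w
      r1 <- geom$endoRadius + band[2] * w
      width <- 360 * area / (pi * (r1^2 - r0^2))
      lesions[[f]] <- list(slices = s0:(s0 + k - 1L),
                           centerAngle = .sampleCenterAngle(),
                           width = width, band = band)
    }
  }

  # The T1-abnormal region is the widest; necrosis (LGE) occupies a core
  # sector inside it and STIR-visible edema an even narrower core, so
  # injured-but-LGE-negative tissue exists, as observed in vivo
  truthMasks <- lapply(seq_len(n), function(i) matrix(FALSE, d[1], d[2]))
  t2Masks <- lapply(seq_len(n), function(i) matrix(FALSE, d[1], d[2]))
  lgeMasks <- lapply(seq_len(n), function(i) matrix(FALSE, d[1], d[2]))
  for (l in lesions) {
    covered <- 0L
    for (s in l$slices) {
      m <- .lesionMaskOnSlice(geoms[[s + 1L]], l$centerAngle, l$width, l$band)
      covered <- covered + sum(m)
      truthMasks[[s + 1L]] <- truthMasks[[s + 1L]] | m
      if (preset$t2Boost > 0) {
        t2Masks[[s + 1L]] <- t2Masks[[s + 1L]] |
          .lesionMaskOnSlice(geoms[[s + 1L]], l$centerAngle,
                             l$width * preset$t2CoreFrac, l$band)
      }
      if (preset$lgeEnhance) {
        lgeMasks[[s + 1L]] <- lgeMasks[[s + 1L]] |
          .lesionMaskOnSlice(geoms[[s + 1L]], l$centerAngle,
                             l$width * preset$lgeCoreFrac, l$band)
      }
    }
    if (covered == 0L) stop("lesion spec lies outside the myocardium")
  }
  myoPix <- sum(vapply(geoms, function(g) sum(g@myoMask), numeric(1)))
  truePix <- sum(vapply(truthMasks, sum, numeric(1)))
  fTrue <- truePix / myoPix
  fBoost <- sum(vapply(t2Masks, sum, numeric(1))) / myoPix
  # lesion level: baseline + deltaT1, but a manifest lesion never sits below
  # the floor (injured segments carry T1 near 1042 ms in vivo even when the
  # subject's mean is modest); the baseline is re-solved so the subject mean
  # still equals the target draw
  deltaT1 <- preset$deltaT1
  baseline <- targetMean - fTrue * deltaT1
  if (truePix > 0 && baseline + deltaT1 < preset$lesionFloor) {
    lesionLevel <- preset$lesionFloor
    baseline <- (targetMean - fTrue * lesionLevel) / (1 - fTrue)
    deltaT1 <- lesionLevel - baseline
  }
  # T2 elevation is concentrated in the edematous lesion core: the base
  # ratio field stays near the normal level and the core boost absorbs the
  # rest of the subject's target global ratio (capped for realism), so
  # remote myocardium does not cross the pixel-ratio cut wholesale
  if (fBoost > 0) {
    t2Boost <- min(preset$t2BoostMax,
                   max(preset$t2Boost,
                       (targetRatio - preset$t2BaseNormal) /
                         (preset$t2BaseNormal * fBoost)))
    baseRatio <- targetRatio / (1 + t2Boost * fBoost)
  } else {
    t2Boost <- 0
    baseRatio <- targetRatio
  }

  # --- images -------------------------------------------------------------
  sliceList <- vector("list", n)
  qcRows <- list()
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    myo <- g@myoMask
    pg <- .polarGrids(d, g@center, g@pixelSpacing)
    blood <- pg$r < g@endoRadius
    truth <- truthMasks[[i]]

    t1 <- matrix(300, d[1], d[2])
    t1[blood] <- 1600
    t1[myo] <- baseline
    t1[truth] <- baseline + deltaT1
    if (preset$noiseSD["T1"] > 0)
      t1 <- t1 + stats::rnorm(length(t1), 0, preset$noiseSD["T1"])
    t1 <- pmax(t1, 1)

    mb <- geom$muscleBaseline
    t2 <- matrix(0.4 * mb, d[1], d[2])
    t2[blood] <- 0.2 * mb
    t2[myo] <- baseRatio * mb
    t2[t2Masks[[i]]] <- baseRatio * mb * (1 + t2Boost)
    t2[g@muscleMask] <- mb
    if (preset$noiseSD["T2W"] > 0)
      t2 <- t2 + stats::rnorm(length(t2), 0, preset$noiseSD["T2W"])

    lge <- matrix(20, d[1], d[2])
    lge[blood] <- 60
    lge[myo] <- 15
    if (preset$lgeEnhance) lge[lgeMasks[[i]]] <- 15 + preset$lgeDelta
    lge[g@muscleMask] <- 25
    if (preset$noiseSD["LGE"] > 0)
      lge <- lge + stats::rnorm(length(lge), 0, preset$noiseSD["LGE"])

    maps <- list(
      T1 = ParametricMap(t1, geom$spacing, i - 1L, geom$thickness, "T1"),
      T2W = ParametricMap(t2, geom$spacing, i - 1L, geom$thickness, "T2W"),
      LGE = ParametricMap(lge, geom$spacing, i - 1L, geom$thickness, "LGE"))
    sliceList[[i]] <- list(maps = maps, geometry = g)

    segs <- sort(unique(g@segments[myo]))
    for (mod in MODALITIES) {
      included <- stats::runif(length(segs)) >= preset$qcExclude[mod]
      if (mod == "T1" && isTRUE(preset$cleanLesionQc) && any(truth)) {
        # focal findings are verified against artifacts on the raw maps:
        # segments carrying a lesion are reported with clean T1 quality
        included[segs %in% unique(g@segments[truth])] <- TRUE
      }
      qcRows[[length(qcRows) + 1L]] <- data.frame(
        slice = i - 1L, segment = segs, modality = mod,
        included = included)
    }
  }
  qc <- do.call(rbind, qcRows)

  ef <- round(stats::rnorm(1, preset$ef[1], preset$ef[2]))
  trop <- if (is.null(preset$troponin)) NA_real_ else
    round(.rlnormMedIqr(1, preset$troponin$median, preset$troponin$iqr), 2)
  md <- list(ef_pct = ef, troponin_ugL = trop,
             days_from_symptoms = sample(seq(preset$daysRange[1],
                                             preset$daysRange[2]), 1))

  study <- new("SubjectStudy", subjectId = subjectId, group = preset$group,
               slices = sliceList, qcFlags = qc, metadata = md)
  lesionTab <- if (length(lesions)) do.call(rbind, lapply(lesions, function(l)
    data.frame(sliceFrom = min(l$slices), sliceTo = max(l$slices),
               centerAngle = l$centerAngle, width = l$width,
               bandLo = l$band[1], bandHi = l$band[2])))
    else data.frame()
  truth <- list(subjectId = subjectId, group = preset$group,
                trueMasks = truthMasks, lgeMasks = lgeMasks,
                t2Masks = t2Masks, trueExtentPct = 100 * fTrue,
                lesions = lesionTab, seed = seed,
                targetMeanT1 = targetMean, targetT2Ratio = targetRatio)
  list(study = study, truth = truth)
}

.subjectSeed <- function(masterSeed, i) {
  (as.double(masterSeed) * 7919 + as.double(i) * 104729) %% 2147483629
}

# evenly spaced interior indices for the low-grade / lesion-free variants
.variantIndices <- function(n, k) {
  if (k <= 0 || n == 0) return(integer())
  unique(round(seq(1, n, length.out = k + 2)))[seq(2, k + 1)]
}

#' Synthesize a calibrated multiparametric cohort
#'
#' Default cohort: 50 controls plus 41 Group I, 12 Group II and 7 Group III
#' patients. Per-subject seeds are derived from the master seed by a
#' counter-based scheme, so cohorts are extensible without reshuffling
#' existing subjects. A fraction of patients is generated from a low-grade
#' variant of their group preset (3 of 41 in Group I, 2 of 12 in Group II,
#' scaled proportionally for other sizes), and one in seven Group III
#' subjects carries no lesion at all: together these place the expected
#' sensitivity of the 990 ms T1 criterion at its calibrated 90% operating
#' point.
#'
#' @param counts named counts per group (control, I, II, III).
#' @param presets list of group presets, by default [defaultGroupPresets()].
#' @param geom geometry configuration.
#' @param masterSeed integer master seed.
#' @param callback optional \code{function(study, truthEntry, index)}; when
#'   given, studies are streamed to the callback and not retained (memory
#'   hook for full-size cohorts).
#' @return list with \code{studies} (list or NULL when streaming),
#'   \code{truth} (per-subject truth entries) and \code{roster}
#'   (data.frame: subjectId, group, variant, seed, trueExtentPct).
#' @export
synthesizeCohort <- function(counts = c(control = 50, I = 41, II = 12, III = 7),
                             presets = defaultGroupPresets(),
                             geom = defaultGeometry(), masterSeed = 1L,
                             callback = NULL) {
  bad <- setdiff(names(counts), STUDY_GROUPS)
  if (length(bad)) stop("unknown group name: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be >= 0")
  geoms <- .buildGeometries(geom)
  studies <- list(); truth <- list(); roster <- list()
  idx <- 0L
  for (gname in names(counts)) {
    n <- counts[[gname]]
    if (n == 0) next
    preset <- presets[[gname]]
    subtleIdx <- switch(gname,
      I = .variantIndices(n, round(3 * n / 41)),
      II = .variantIndices(n, round(2 * n / 12)),
      integer())
    freeIdx <- if (gname == "III") .variantIndices(n, round(n / 7)) else integer()
    for (j in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", if (gname == "control") "C" else paste0("P", gname, "-"), j)
      p <- preset
      variant <- "standard"
      if (j %in% subtleIdx) { p <- .subtlePreset(p); variant <- "low-grade" }
      if (j %in% freeIdx) {
        p <- utils::modifyList(p, list(lesionType = "none"))
        variant <- "lesion-free"
      }
      res <- synthesizeSubject(p, geom, .subjectSeed(masterSeed, idx), sid, geoms)
      truth[[idx]] <- res$truth
      truth[[idx]]$variant <- variant
      roster[[idx]] <- data.frame(subjectId = sid, group = gname,
                                  variant = variant, seed = res$truth$seed,
                                  trueExtentPct = res$truth$trueExtentPct)
      if (is.null(callback)) studies[[idx]] <- res$study
      else callback(res$study, truth[[idx]], idx)
    }
  }
  list(studies = if (is.null(callback)) studies else NULL,
       truth = truth,
       roster = if (length(roster)) do.call(rbind, roster) else
         data.frame(subjectId = character(), group = character(),
                    variant = character(), seed = numeric(),
                    trueExtentPct = numeric()))
}

#' Compare realized cohort statistics against their preset targets
#'
#' Reports, per group: realized mean and SD of per-subject mean myocardial
#' T1, realized mean global T2 SI ratio, and realized median true extent,
#' side by side with the preset targets and a pass flag at the given
#' absolute tolerances.
#'
#' @param cohort list of \linkS4class{SubjectStudy} objects, or a
#'   data.frame with columns subjectId, group, meanT1, t2Ratio (precomputed
#'   per-subject statistics).
#' @param truth truth list from [synthesizeCohort()].
#' @param presets the presets the cohort was generated from.
#' @param tol named absolute tolerances (meanT1 ms, t2Ratio, extentPct).
#' @return data.frame with columns group, statistic, target, realized,
#'   tolerance, pass.
#' @export
calibrationReport <- function(cohort, truth, presets = defaultGroupPresets(),
                              tol = c(meanT1 = 10, t2Ratio = 0.08,
                                      extentPct = 10)) {
  if (is.data.frame(cohort)) {
    stats <- cohort
  } else {
    stats <- data.frame(
      subjectId = vapply(cohort, subjectId, character(1)),
      group = vapply(cohort, studyGroup, character(1)),
      meanT1 = vapply(cohort, subjectMeanT1, numeric(1)),
      t2Ratio = vapply(cohort, globalT2Ratio, numeric(1)))
  }
  extents <- data.frame(
    group = vapply(truth, `[[`, character(1), "group"),
    trueExtentPct = vapply(truth, `[[`, numeric(1), "trueExtentPct"))
  rows <- list()
  for (g in intersect(STUDY_GROUPS, unique(stats$group))) {
    p <- presets[[g]]
    sg <- stats[stats$group == g, ]
    eg <- extents[extents$group == g, ]
    add <- function(statistic, target, realized, tolerance) {
      rows[[length(rows) + 1L]] <<- data.frame(
        group = g, statistic = statistic, target = target,
        realized = realized, tolerance = tolerance,
        pass = abs(realized - target) <= tolerance)
    }
    add("meanT1", p$meanT1[1], mean(sg$meanT1), tol[["meanT1"]])
    add("sdT1", p$meanT1[2], stats::sd(sg$meanT1), Inf)
    add("t2Ratio", p$t2Ratio[1], mean(sg$t2Ratio), tol[["t2Ratio"]])
    add("medianTrueExtentPct", p$extent$median,
        stats::median(eg$trueExtentPct), tol[["extentPct"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
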