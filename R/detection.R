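# The three tissue-characterization criteria.
#
#  T1:  native T1 above 990 ms (comparator configurable between > and >=,
#       a measure-zero distinction on continuous maps).
#  T2W: pixel SI / slice skeletal-muscle mean >= 2.0, OR pixel SI >= remote
#       mean + 2 SD; the subject-level global ratio uses pooled means.
#  LGE: pixel SI >= remote mean + 2 SD on the nulled-myocardium image.
#
# All criteria search only qc-included segments and keep only contiguous
# areas of at least 40 mm^2.

#' Myocardial search mask restricted to qc-included segments
#'
#' @param geometry a \linkS4class{HeartGeometry}.
#' @param qc the study's qcFlags data.frame (or NULL to include everything).
#' @param slice 0-based slice index.
#' @param modality modality whose qc flags apply.
#' @param qcMode "exclude" honors the flags; "include-all" re-includes every
#'   segment (the artifact-reinclusion sensitivity analysis).
#' @return logical matrix.
#' @export
includedMyoMask <- function(geometry, qc, slice, modality,
                            qcMode = c("exclude", "include-all")) {
  qcMode <- match.arg(qcMode)
  myo <- geometry@myoMask
  if (is.null(qc) || qcMode == "include-all") return(myo)
  rows <- qc[qc$slice == slice & qc$modality == modality & !qc$included, ]
  if (nrow(rows)) myo[geometry@segments %in% rows$segment] <- FALSE
  myo
}

.thresholdDescriptor <- function(modality, comparator, value) {
  switch(modality,
         T1 = sprintf("T1%s%gms", comparator, value),
         T2W = "T2ratio>=2.0|remote+2SD",
         LGE = "LGE>=remote+2SD")
}

#' Detect myocardial injury on a native T1-map slice
#'
#' Pixels at or above the T1 threshold inside the qc-included myocardium,
#' followed by the minimum-contiguous-area filter. The validated threshold
#' is 990 ms for the objective detection of acute myocardial edema.
#'
#' @param map a T1 \linkS4class{ParametricMap}.
#' @param geometry the slice's \linkS4class{HeartGeometry}.
#' @param threshold T1 threshold in ms (default 990).
#' @param minArea minimum contiguous area, mm^2 (default 40).
#' @param connectivity 4 or 8 (default 8).
#' @param comparator ">=" (default) or ">".
#' @param qc,qcMode see [includedMyoMask()].
#' @return A single-slice \linkS4class{LesionMask}.
#' @export
detectT1Injury <- function(map, geometry, threshold = 990, minArea = 40,
                           connectivity = 8, comparator = c(">=", ">"),
                           qc = NULL, qcMode = "exclude") {
  comparator <- match.arg(comparator)
  if (map@modality != "T1")
    stop("detectT1Injury requires a T1 map, got ", map@modality)
  search <- includedMyoMask(geometry, qc, map@sliceIndex, "T1", qcMode)
  cand <- if (comparator == ">=") map@pixels >= threshold else map@pixels > threshold
  filterContiguous(cand & search, map@pixelSpacing, minArea, connectivity,
                   modality = "T1",
                   threshold = .thresholdDescriptor("T1", comparator, threshold),
                   slice = map@sliceIndex)
}

#' Myocardial T2 signal-intensity ratio against skeletal muscle
#'
#' Mean myocardial SI over the given subset divided by the mean
#' skeletal-muscle SI. With multiple slices the subject-level global ratio
#' pools myocardial and muscle pixels across slices before dividing.
#'
#' @param t2Pixels matrix or list of matrices of T2W signal intensity.
#' @param myoMask matrix or list of matrices selecting the myocardial subset.
#' @param muscleMask matrix or list of matrices selecting skeletal muscle.
#' @return The dimensionless SI ratio.
#' @export
computeT2Ratio <- function(t2Pixels, myoMask, muscleMask) {
  if (!is.list(t2Pixels)) {
    t2Pixels <- list(t2Pixels); myoMask <- list(myoMask)
    muscleMask <- list(muscleMask)
  }
  myoVals <- unlist(Map(function(p, m) p[m], t2Pixels, myoMask))
  musVals <- unlist(Map(function(p, m) p[m], t2Pixels, muscleMask))
  if (!length(musVals)) stop("empty skeletal-muscle mask")
  mean(myoVals) / mean(musVals)
}

#' Global T2 SI ratio of a study
#'
#' Pools qc-included myocardial pixels and skeletal-muscle pixels across all
#' slices (the subject-level edema marker, 2.0 cut-off).
#'
#' @param study a \linkS4class{SubjectStudy} with T2W maps.
#' @param qcMode see [includedMyoMask()].
#' @return The global myocardial T2 SI ratio.
#' @export
globalT2Ratio <- function(study, qcMode = "exclude") {
  px <- list(); myo <- list(); mus <- list()
  for (i in seq_along(study@slices)) {
    g <- geometryFor(study, i - 1L)
    px[[i]] <- mapFor(study, i - 1L, "T2W")@pixels
    myo[[i]] <- includedMyoMask(g, study@qcFlags, i - 1L, "T2W", qcMode)
    mus[[i]] <- g@muscleMask
  }
  computeT2Ratio(px, myo, mus)
}

#' Select the remote reference ROI on one slice
#'
#' Algorithmic surrogate for the expert's choice of "least affected"
#' myocardium: among qc-included segments with no overlap with the detected
#' LGE mask, segments with abnormally low signal (mean SI below the slice
#' myocardial median minus twice the robust SD) are excluded, and the
#' segment with the lowest mean SI is chosen; ties break to the lowest
#' segment id.
#'
#' The low-signal exclusion guards against signal dropout on T2W images; it
#' is disabled on LGE images, where nulled (dark) myocardium is the normal
#' reference and low signal is the expected remote appearance.
#'
#' @param study a \linkS4class{SubjectStudy}.
#' @param slice 0-based slice index.
#' @param modality modality whose SI statistics are wanted.
#' @param lgeMask optional logical matrix of detected LGE on this slice.
#' @param qc,qcMode see [includedMyoMask()].
#' @param lowSignalRule apply the abnormally-low-signal exclusion (default:
#'   only for non-LGE modalities).
#' @return A \linkS4class{RemoteROI}.
#' @export
selectRemoteRoi <- function(study, slice, modality = "T2W", lgeMask = NULL,
                            qc = NULL, qcMode = "exclude",
                            lowSignalRule = modality != "LGE") {
  g <- geometryFor(study, slice)
  px <- mapFor(study, slice, modality)@pixels
  search <- includedMyoMask(g, qc, slice, modality, qcMode)
  segIds <- sort(unique(g@segments[search]))
  if (length(segIds)) {
    myoVals <- px[search]
    lowCut <- if (lowSignalRule)
      stats::median(myoVals) - 2 * stats::mad(myoVals) else -Inf
    stats <- lapply(segIds, function(s) {
      m <- search & g@segments == s
      if (!is.null(lgeMask) && any(lgeMask & m)) return(NULL)
      v <- px[m]
      list(id = s, mean = mean(v), sd = stats::sd(v), n = sum(m))
    })
    stats <- Filter(function(x) !is.null(x) && x$mean >= lowCut, stats)
  } else stats <- list()
  if (!length(stats)) {
    cond <- simpleError("no remote reference: no eligible qc-included segment")
    class(cond) <- c("t1topoNoRemote", class(cond))
    stop(cond)
  }
  means <- vapply(stats, `[[`, numeric(1), "mean")
  ids <- vapply(stats, `[[`, integer(1), "id")
  best <- order(means, ids)[1]
  new("RemoteROI", slice = as.integer(slice),
      segments = ids[best], mean = means[best],
      sd = vapply(stats, `[[`, numeric(1), "sd")[best], modality = modality)
}

#' Detect myocardial edema on a dark-blood T2W slice
#'
#' A pixel is a candidate when its SI relative to the slice skeletal-muscle
#' mean reaches 2.0, or when it lies at least 2 SD above the remote-region
#' mean; candidates are then area-filtered. With a NULL remote (no eligible
#' reference segment) only the ratio branch is applied.
#'
#' @param map a T2W \linkS4class{ParametricMap}.
#' @param geometry the slice geometry (supplies the skeletal-muscle mask).
#' @param remote a \linkS4class{RemoteROI} from the same slice, or NULL.
#' @inheritParams detectT1Injury
#' @param sdMult SD multiplier for the remote branch (default 2).
#' @param ratioCut pixel-ratio cut-off (default 2).
#' @return A single-slice \linkS4class{LesionMask}.
#' @export
detectT2Edema <- function(map, geometry, remote = NULL, minArea = 40,
                          connectivity = 8, sdMult = 2, ratioCut = 2,
                          qc = NULL, qcMode = "exclude") {
  if (map@modality != "T2W")
    stop("detectT2Edema requires a T2W map, got ", map@modality)
  search <- includedMyoMask(geometry, qc, map@sliceIndex, "T2W", qcMode)
  if (!any(geometry@muscleMask)) stop("empty skeletal-muscle mask")
  muscleMean <- mean(map@pixels[geometry@muscleMask])
  cand <- map@pixels / muscleMean >= ratioCut
  if (!is.null(remote)) {
    if (remote@slice != map@sliceIndex)
      stop("remote ROI must come from the same slice")
    sd <- remote@sd
    if (sd == 0) {
      if (stats::sd(map@pixels[search]) > 0)
        warning("remote ROI has zero SD; 2-SD branch degenerates to a mean comparison")
      cand <- cand | (map@pixels > remote@mean)
    } else {
      cand <- cand | (map@pixels >= remote@mean + sdMult * sd)
    }
  }
  filterContiguous(cand & search, map@pixelSpacing, minArea, connectivity,
                   modality = "T2W",
                   threshold = .thresholdDescriptor("T2W", NULL, NULL),
                   slice = map@sliceIndex)
}

#' Detect late gadolinium enhancement on one slice
#'
#' Focal LGE is defined as SI at least 2 SD above the mean SI of remote
#' myocardium, followed by the minimum-contiguous-area filter.
#'
#' @param map an LGE \linkS4class{ParametricMap}.
#' @param geometry the slice geometry.
#' @param remote a \linkS4class{RemoteROI} measured on the LGE map.
#' @inheritParams detectT2Edema
#' @return A single-slice \linkS4class{LesionMask}.
#' @export
detectLge <- function(map, geometry, remote, minArea = 40, connectivity = 8,
                      sdMult = 2, qc = NULL, qcMode = "exclude") {
  if (map@modality != "LGE")
    stop("detectLge requires an LGE map, got ", map@modality)
  if (remote@slice != map@sliceIndex)
    stop("remote ROI must come from the same slice")
  search <- includedMyoMask(geometry, qc, map@sliceIndex, "LGE", qcMode)
  if (remote@sd == 0) {
    if (stats::sd(map@pixels[search]) > 0)
      warning("remote ROI has zero SD; 2-SD branch degenerates to a mean comparison")
    cand <- map@pixels > remote@mean
  } else {
    cand <- map@pixels >= remote@mean + sdMult * remote@sd
  }
  filterContiguous(cand & search, map@pixelSpacing, minArea, connectivity,
                   modality = "LGE",
                   threshold = .thresholdDescriptor("LGE", NULL, NULL),
                   slice = map@sliceIndex)
}

#' Run one detection criterion across all slices of a study
#'
#' For T2W and LGE the remote reference ROI is selected per slice; LGE is
#' detected first when T2W is requested so that remote selection can avoid
#' enhancing segments. If no eligible remote segment exists on a slice the
#' T2W criterion falls back to the ratio-only branch (logged via a message).
#'
#' @param study a \linkS4class{SubjectStudy}.
#' @param modality "T1", "T2W" or "LGE".
#' @param threshold T1 threshold in ms (T1 only).
#' @inheritParams detectT1Injury
#' @param sdMult remote-SD multiplier for T2W/LGE.
#' @return A multi-slice \linkS4class{LesionMask}.
#' @export
detectStudy <- function(study, modality = c("T1", "T2W", "LGE"),
                        threshold = 990, minArea = 40, connectivity = 8,
                        comparator = ">=", sdMult = 2, qcMode = "exclude") {
  modality <- match.arg(modality)
  qc <- study@qcFlags
  n <- length(study@slices)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- i - 1L
    g <- geometryFor(study, s)
    if (modality == "T1") {
      out[[i]] <- detectT1Injury(mapFor(study, s, "T1"), g, threshold,
                                 minArea, connectivity, comparator, qc, qcMode)
    } else if (modality == "LGE") {
      remote <- selectRemoteRoi(study, s, "LGE", NULL, qc, qcMode)
      out[[i]] <- detectLge(mapFor(study, s, "LGE"), g, remote, minArea,
                            connectivity, sdMult, qc, qcMode)
    } else {
      lgeRemote <- tryCatch(selectRemoteRoi(study, s, "LGE", NULL, qc, qcMode),
                            t1topoNoRemote = function(e) NULL)
      lgeMask <- if (!is.null(lgeRemote)) {
        detectLge(mapFor(study, s, "LGE"), g, lgeRemote, minArea,
                  connectivity, sdMult, qc, qcMode)@masks[[1]]
      }
      remote <- tryCatch(
        selectRemoteRoi(study, s, "T2W", lgeMask, qc, qcMode),
        t1topoNoRemote = function(e) {
          message(sprintf(
            "slice %d: no remote reference; T2W criterion falls back to the ratio-only branch", s))
          NULL
        })
      out[[i]] <- detectT2Edema(mapFor(study, s, "T2W"), g, remote, minArea,
                                connectivity, sdMult, 2, qc, qcMode)
    }
  }
  bindLesionSlices(out)
}

#' Subject-level positivity of one detection criterion
#'
#' Default rule: positive if any retained component exists on any slice.
#' With \code{confirmSlices = 2} retained components are required on at
#' least two contiguous slices; the confirmation can be restricted to
#' low-extent subjects via \code{applyBelowExtentPct} (confirmation then
#' applies only when the subject's extent is below that percentage), which
#' mirrors the handling of small focal lesions in otherwise negative
#' subjects. Orthogonal-plane confirmation is not supported for short-axis
#' stacks and raises an error if requested.
#'
#' @param lesions a multi-slice \linkS4class{LesionMask} of one subject and
#'   modality.
#' @param rule list: \code{confirmSlices} (0 = default rule, 2 = contiguous
#'   slice confirmation), \code{applyBelowExtentPct} (NULL = always apply),
#'   \code{orthogonalPlanes} (must be FALSE).
#' @param extentPct the subject's measured extent (%), needed when
#'   \code{applyBelowExtentPct} is set.
#' @return list with \code{positive}, \code{ruleApplied},
#'   \code{slicesWithComponents}, \code{nComponents}.
#' @export
subjectPositive <- function(lesions,
                            rule = list(confirmSlices = 0,
                                        applyBelowExtentPct = NULL,
                                        orthogonalPlanes = FALSE),
                            extentPct = NULL) {
  if (!length(lesions@masks)) stop("empty study: lesion mask has no slices")
  if (isTRUE(rule$orthogonalPlanes))
    stop("unsupported: orthogonal-plane confirmation requires long-axis views")
  comp <- lesions@components
  slices <- sort(unique(comp$slice))
  confirm <- !is.null(rule$confirmSlices) && rule$confirmSlices >= 2
  if (confirm && !is.null(rule$applyBelowExtentPct)) {
    if (is.null(extentPct))
      stop("extentPct is required when applyBelowExtentPct is set")
    confirm <- extentPct < rule$applyBelowExtentPct
  }
  if (!confirm) {
    pos <- nrow(comp) > 0
  } else {
    k <- rule$confirmSlices
    pos <- FALSE
    if (length(slices) >= k) {
      runs <- rle(diff(slices) == 1L)
      best <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L else 1L
      pos <- best >= k
    }
  }
  list(positive = pos, ruleApplied = if (confirm) "contiguous-slices" else "any-component",
       slicesWithComponents = slices, nComponents = nrow(comp))
}
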