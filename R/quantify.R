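# Extent of injury and Table-1-style cohort summaries.
#
# The extent of injury for a subject is the percentage of abnormal
# myocardium determined for each (slice, segment) and then averaged,
# unweighted, over the subject's qc-included segments. "Mean myocardial T1"
# is a pixel-level mean over all qc-included myocardial pixels (a mean of
# segment means is available via segmentMeans = TRUE).

#' Per-(slice, segment) extent of abnormal myocardium
#'
#' For each included (slice, segment) pair: 100 x |lesion within segment| /
#' |segment|. Excluded segments are reported with included = FALSE and
#' contribute to no aggregate.
#'
#' @param lesion a multi-slice \linkS4class{LesionMask}.
#' @param geoms list of per-slice \linkS4class{HeartGeometry} objects
#'   (most conveniently from \code{studySlices(study)}).
#' @param qc qcFlags data.frame, or NULL for all-included.
#' @param qcMode "exclude" or "include-all".
#' @return data.frame: slice, segment, modality, pctAbnormal, included.
#' @export
segmentExtent <- function(lesion, geoms, qc = NULL, qcMode = "exclude") {
  mod <- lesion@modality
  rows <- list()
  for (sName in names(lesion@masks)) {
    s <- as.integer(sName)
    g <- geoms[[s + 1L]]
    m <- lesion@masks[[sName]]
    segs <- sort(unique(g@segments[g@myoMask]))
    for (seg in segs) {
      segMask <- g@segments == seg
      npix <- sum(segMask)
      if (npix == 0L) stop("segment ", seg, " has zero pixels (geometry bug)")
      inc <- TRUE
      if (!is.null(qc) && qcMode == "exclude") {
        r <- qc[qc$slice == s & qc$segment == seg & qc$modality == mod, ]
        if (nrow(r)) inc <- all(r$included)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        slice = s, segment = seg, modality = mod,
        pctAbnormal = 100 * sum(m & segMask) / npix, included = inc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject extent of injury
#'
#' Unweighted mean of the included segment percentages. With every segment
#' excluded the extent is missing (NA) with a warning.
#'
#' @param rows data.frame from [segmentExtent()].
#' @return extent in percent, or NA.
#' @export
subjectExtent <- function(rows) {
  inc <- rows[rows$included, ]
  if (!nrow(inc)) {
    warning("all segments excluded; subject extent is missing")
    return(NA_real_)
  }
  mean(inc$pctAbnormal)
}

#' Mean myocardial T1 of a subject
#'
#' Pixel-level mean native T1 over all qc-included myocardial pixels across
#' slices (ms). Set \code{segmentMeans = TRUE} for the alternative reading
#' (mean of per-segment means).
#'
#' @param study a \linkS4class{SubjectStudy} with T1 maps.
#' @param qcMode "exclude" or "include-all".
#' @param segmentMeans average per-segment means instead of pooling pixels.
#' @return mean T1 in ms.
#' @export
subjectMeanT1 <- function(study, qcMode = "exclude", segmentMeans = FALSE) {
  vals <- list(); segvals <- list()
  for (i in seq_along(study@slices)) {
    s <- i - 1L
    g <- geometryFor(study, s)
    px <- mapFor(study, s, "T1")@pixels
    inc <- includedMyoMask(g, study@qcFlags, s, "T1", qcMode)
    if (!segmentMeans) {
      vals[[i]] <- px[inc]
    } else {
      for (seg in sort(unique(g@segments[inc]))) {
        segvals[[length(segvals) + 1L]] <- mean(px[inc & g@segments == seg])
      }
    }
  }
  if (segmentMeans) {
    if (!length(segvals)) stop("no included myocardial segments")
    return(mean(unlist(segvals)))
  }
  v <- unlist(vals)
  if (!length(v)) stop("no included myocardial pixels")
  mean(v)
}

#' Size-weighted cross-group mean
#'
#' The all-patients column of a per-group summary: subgroup means weighted
#' by subgroup sizes. Used for internal-consistency checks of printed
#' cohort tables.
#'
#' @param means subgroup means.
#' @param sizes subgroup sizes.
#' @return weighted mean.
#' @export
weightedGroupMean <- function(means, sizes) {
  stopifnot(length(means) == length(sizes))
  sum(means * sizes) / sum(sizes)
}

#' Group-wise cohort summary
#'
#' For each group: mean +/- SD for mean-valued quantities and median (IQR)
#' for extent-like quantities, plus the size-weighted cross-group mean over
#' the patient groups for every mean-valued quantity.
#'
#' @param df per-subject data.frame with a \code{group} column.
#' @param meanCols columns summarized as mean +/- SD.
#' @param medianCols columns summarized as median (IQR).
#' @return list: \code{byGroup} (data.frame), \code{patientWeightedMeans}
#'   (named vector over groups I-III), \code{groupSizes}.
#' @export
cohortSummary <- function(df, meanCols = character(),
                          medianCols = character()) {
  groups <- intersect(STUDY_GROUPS, unique(df$group))
  empty <- setdiff(unique(df$group), groups)
  if (length(empty)) warning("omitting unknown groups: ",
                             paste(empty, collapse = ", "))
  rows <- list()
  for (g in groups) {
    sub <- df[df$group == g, , drop = FALSE]
    if (!nrow(sub)) { warning("empty group ", g, " omitted"); next }
    for (cl in meanCols) {
      x <- sub[[cl]][!is.na(sub[[cl]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, statistic = cl, kind = "mean", n = length(x),
        center = mean(x), spreadLo = if (length(x) > 1) stats::sd(x) else 0,
        spreadHi = NA_real_)
    }
    for (cl in medianCols) {
      x <- sub[[cl]][!is.na(sub[[cl]])]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, statistic = cl, kind = "median", n = length(x),
        center = q[2], spreadLo = q[1], spreadHi = q[3])
    }
  }
  byGroup <- do.call(rbind, rows)
  rownames(byGroup) <- NULL
  patientGroups <- intersect(c("I", "II", "III"), groups)
  wm <- vapply(meanCols, function(cl) {
    ms <- vapply(patientGroups, function(g)
      mean(df[[cl]][df$group == g], na.rm = TRUE), numeric(1))
    ns <- vapply(patientGroups, function(g)
      sum(df$group == g & !is.na(df[[cl]])), numeric(1))
    if (sum(ns) == 0) NA_real_ else weightedGroupMean(ms, ns)
  }, numeric(1))
  sizes <- vapply(groups, function(g) sum(df$group == g), numeric(1))
  list(byGroup = byGroup, patientWeightedMeans = wm, groupSizes = sizes)
}
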