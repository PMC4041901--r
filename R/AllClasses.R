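#' @import methods
NULL

MODALITIES <- c("T1", "T2W", "LGE")

#' ParametricMap: one co-registered short-axis slice of a parametric map
#'
#' Holds a single 2D slice of a quantitative cardiac map: a native T1-map
#' (values in ms) or a signal-intensity image (arbitrary units) from
#' dark-blood T2-weighted (T2W) or late gadolinium enhancement (LGE) imaging.
#' All modalities of a slice share one analysis grid (the phantom generates
#' them co-registered; resampling of real data is out of scope).
#'
#' @slot pixels numeric matrix of finite values; ms for T1, a.u. otherwise.
#' @slot pixelSpacing numeric length-2, (row mm, column mm), both > 0.
#' @slot sliceIndex integer, 0 = most basal slice.
#' @slot sliceThickness slice thickness in mm.
#' @slot modality one of "T1", "T2W", "LGE".
#' @exportClass ParametricMap
setClass("ParametricMap",
  representation(
    pixels = "matrix",
    pixelSpacing = "numeric",
    sliceIndex = "integer",
    sliceThickness = "numeric",
    modality = "character"
  )
)

setValidity("ParametricMap", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixels must be a finite numeric matrix")
  if (any(dim(object@pixels) < 16L))
    msg <- c(msg, "pixel grid must be at least 16x16")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (row mm, col mm)")
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    msg <- c(msg, "modality must be one of T1, T2W, LGE")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a positive scalar (mm)")
  if (object@sliceIndex < 0L) msg <- c(msg, "sliceIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ParametricMap constructor
#'
#' @param pixels numeric matrix.
#' @param pixelSpacing (row mm, col mm).
#' @param sliceIndex 0-based slice index, 0 = most basal.
#' @param sliceThickness mm.
#' @param modality "T1", "T2W" or "LGE".
#' @return A \linkS4class{ParametricMap}.
#' @export
ParametricMap <- function(pixels, pixelSpacing, sliceIndex = 0L,
                          sliceThickness = 8, modality = "T1") {
  new("ParametricMap", pixels = pixels,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceIndex = as.integer(sliceIndex),
      sliceThickness = as.numeric(sliceThickness),
      modality = modality)
}

#' HeartGeometry: per-slice left-ventricular ring geometry and masks
#'
#' Describes the myocardial ring on one short-axis slice: the binary
#' myocardial mask, AHA segment labels (codes 1-16), a skeletal-muscle
#' reference mask (disjoint from the myocardium), and a transmural coordinate
#' field in [0, 1] (0 at the endocardial border, 1 at the epicardial border,
#' NA outside the myocardium).
#'
#' @slot center (row, col) pixel coordinates of the ring center.
#' @slot endoRadius endocardial radius in mm.
#' @slot epiRadius epicardial radius in mm (> endoRadius).
#' @slot myoMask logical matrix, TRUE inside the myocardium.
#' @slot segments integer matrix; AHA codes 1-16 inside the mask, 0 outside.
#' @slot muscleMask logical matrix, skeletal-muscle reference region.
#' @slot transmural numeric matrix in [0,1] on the mask, NA elsewhere.
#' @slot pixelSpacing (row mm, col mm) of the shared analysis grid.
#' @exportClass HeartGeometry
setClass("HeartGeometry",
  representation(
    center = "numeric",
    endoRadius = "numeric",
    epiRadius = "numeric",
    myoMask = "matrix",
    segments = "matrix",
    muscleMask = "matrix",
    transmural = "matrix",
    pixelSpacing = "numeric"
  )
)

setValidity("HeartGeometry", function(object) {
  msg <- character()
  if (object@endoRadius >= object@epiRadius)
    msg <- c(msg, "endoRadius must be < epiRadius")
  d <- dim(object@myoMask)
  if (!identical(d, dim(object@segments)) ||
      !identical(d, dim(object@muscleMask)) ||
      !identical(d, dim(object@transmural)))
    msg <- c(msg, "all geometry grids must share one shape")
  inmask <- object@myoMask
  if (any(object@segments[inmask] < 1L | object@segments[inmask] > 16L))
    msg <- c(msg, "segment labels inside the mask must be in 1..16")
  if (any(object@segments[!inmask] != 0L))
    msg <- c(msg, "segment labels outside the mask must be 0")
  if (any(object@muscleMask & inmask))
    msg <- c(msg, "skeletal-muscle mask must be disjoint from the myocardium")
  tm <- object@transmural[inmask]
  if (any(!is.finite(tm)) || any(tm < 0 | tm > 1))
    msg <- c(msg, "transmural coordinate must lie in [0,1] on the mask")
  if (any(is.finite(object@transmural[!inmask])))
    msg <- c(msg, "transmural coordinate must be NA outside the mask")
  if (length(msg)) msg else TRUE
})

#' SubjectStudy: one subject's co-registered multiparametric short-axis stack
#'
#' An ordered stack of short-axis slices, each carrying one
#' \linkS4class{ParametricMap} per modality on a shared grid plus its
#' \linkS4class{HeartGeometry}, together with per-(slice, segment, modality)
#' quality-control inclusion flags and subject metadata.
#'
#' @slot subjectId character identifier.
#' @slot group one of "control", "I", "II", "III" (patient subgroups by
#'   conventional edema/LGE status).
#' @slot slices list; each element is a list with components \code{maps}
#'   (named list T1/T2W/LGE of ParametricMap) and \code{geometry}.
#' @slot qcFlags data.frame with columns slice (0-based), segment, modality,
#'   included (logical); exactly one row per triple.
#' @slot metadata list (troponin ug/L, EF %, days from symptoms, ...).
#' @exportClass SubjectStudy
setClass("SubjectStudy",
  representation(
    subjectId = "character",
    group = "character",
    slices = "list",
    qcFlags = "data.frame",
    metadata = "list"
  )
)

STUDY_GROUPS <- c("control", "I", "II", "III")

setValidity("SubjectStudy", function(object) {
  msg <- character()
  if (!object@group %in% STUDY_GROUPS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(STUDY_GROUPS, collapse = ", ")))
  for (i in seq_along(object@slices)) {
    sl <- object@slices[[i]]
    if (!all(c("maps", "geometry") %in% names(sl))) {
      msg <- c(msg, sprintf("slice %d lacks maps/geometry", i)); next
    }
    d <- dim(sl$geometry@myoMask)
    for (m in names(sl$maps)) {
      if (!identical(dim(sl$maps[[m]]@pixels), d))
        msg <- c(msg, sprintf("slice %d: %s grid does not match geometry", i, m))
    }
    t1 <- sl$maps[["T1"]]
    if (!is.null(t1) && any(t1@pixels[sl$geometry@myoMask] <= 0))
      msg <- c(msg, sprintf("slice %d: non-positive T1 inside myocardium", i))
  }
  qc <- object@qcFlags
  need <- c("slice", "segment", "modality", "included")
  if (!all(need %in% names(qc))) {
    msg <- c(msg, "qcFlags must have slice, segment, modality, included")
  } else if (anyDuplicated(qc[, c("slice", "segment", "modality")])) {
    msg <- c(msg, "qcFlags must have exactly one row per (slice,segment,modality)")
  }
  if (length(msg)) msg else TRUE
})

#' LesionMask: thresholded, area-filtered binary injury map
#'
#' Per-slice binary masks of pixels exceeding a tissue-characterization
#' threshold, after removal of connected components smaller than the minimum
#' contiguous area, together with an inventory of the retained components.
#'
#' @slot masks list of logical matrices, one per slice (named by 0-based index).
#' @slot modality modality the criterion was applied to.
#' @slot threshold human-readable threshold descriptor, e.g. "T1>=990ms".
#' @slot minArea minimum contiguous area in mm^2.
#' @slot components data.frame: id, slice, pixels, areaMM2, centroidRow,
#'   centroidCol for each retained component.
#' @slot labels list of integer matrices mirroring \code{masks}, with each
#'   retained component's pixels carrying its component id.
#' @exportClass LesionMask
setClass("LesionMask",
  representation(
    masks = "list",
    modality = "character",
    threshold = "character",
    minArea = "numeric",
    components = "data.frame",
    labels = "list"
  )
)

setValidity("LesionMask", function(object) {
  msg <- character()
  if (object@minArea < 0) msg <- c(msg, "minArea must be >= 0")
  npix <- sum(vapply(object@masks, sum, numeric(1)))
  if (nrow(object@components) &&
      !isTRUE(all.equal(sum(object@components$pixels), npix)))
    msg <- c(msg, "component pixel counts must sum to total mask size")
  if (!nrow(object@components) && npix > 0)
    msg <- c(msg, "non-empty mask with empty component inventory")
  if (length(msg)) msg else TRUE
})

#' RemoteROI: reference region used by 2-SD detection criteria
#'
#' Algorithmically chosen stand-in for the expert's "least affected" remote
#' region: a qc-included segment free of LGE and of abnormally low signal,
#' with the lowest mean relative signal intensity on its slice.
#'
#' @slot slice 0-based slice index.
#' @slot segments AHA segment id(s) forming the remote region.
#' @slot mean mean signal intensity over the region.
#' @slot sd standard deviation of signal intensity over the region.
#' @slot modality modality the statistics were measured on.
#' @exportClass RemoteROI
setClass("RemoteROI",
  representation(
    slice = "integer",
    segments = "integer",
    mean = "numeric",
    sd = "numeric",
    modality = "character"
  )
)

setMethod("show", "ParametricMap", function(object) {
  cat(sprintf("ParametricMap [%s] %dx%d, spacing %.2fx%.2f mm, slice %d\n",
              object@modality, nrow(object@pixels), ncol(object@pixels),
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceIndex))
  px <- object@pixels
  cat(sprintf("  range %.1f .. %.1f %s\n", min(px), max(px),
              if (object@modality == "T1") "ms" else "a.u."))
})

setMethod("show", "SubjectStudy", function(object) {
  cat(sprintf("SubjectStudy '%s' (group %s): %d slices, modalities %s\n",
              object@subjectId, object@group, length(object@slices),
              paste(names(object@slices[[1]]$maps), collapse = "/")))
  cat(sprintf("  qc: %d/%d (slice,segment,modality) triples included\n",
              sum(object@qcFlags$included), nrow(object@qcFlags)))
})

setMethod("show", "LesionMask", function(object) {
  cat(sprintf("LesionMask [%s] %s, min area %.0f mm^2: %d component(s), %d pixel(s)\n",
              object@modality, object@threshold, object@minArea,
              nrow(object@components),
              sum(vapply(object@masks, sum, numeric(1)))))
})

setMethod("show", "RemoteROI", function(object) {
  cat(sprintf("RemoteROI [%s] slice %d, segment(s) %s: mean %.2f, sd %.2f\n",
              object@modality, object@slice,
              paste(object@segments, collapse = ","), object@mean, object@sd))
})
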