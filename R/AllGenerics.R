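#' Accessors for t1topo classes
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object a t1topo S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ParametricMap", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setMethod("modality", "ParametricMap", function(object) object@modality)
#' @rdname accessors
#' @export
setMethod("modality", "LesionMask", function(object) object@modality)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ParametricMap", function(object) object@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "HeartGeometry", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("myoMask", function(object) standardGeneric("myoMask"))
#' @rdname accessors
#' @export
setMethod("myoMask", "HeartGeometry", function(object) object@myoMask)

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setMethod("segmentLabels", "HeartGeometry", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("muscleMask", function(object) standardGeneric("muscleMask"))
#' @rdname accessors
#' @export
setMethod("muscleMask", "HeartGeometry", function(object) object@muscleMask)

#' @rdname accessors
#' @export
setGeneric("transmuralDepth", function(object) standardGeneric("transmuralDepth"))
#' @rdname accessors
#' @export
setMethod("transmuralDepth", "HeartGeometry", function(object) object@transmural)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectStudy", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("studyGroup", function(object) standardGeneric("studyGroup"))
#' @rdname accessors
#' @export
setMethod("studyGroup", "SubjectStudy", function(object) object@group)

#' @rdname accessors
#' @export
setGeneric("studySlices", function(object) standardGeneric("studySlices"))
#' @rdname accessors
#' @export
setMethod("studySlices", "SubjectStudy", function(object) object@slices)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setMethod("qcFlags", "SubjectStudy", function(object) object@qcFlags)

#' @rdname accessors
#' @export
setGeneric("studyMetadata", function(object) standardGeneric("studyMetadata"))
#' @rdname accessors
#' @export
setMethod("studyMetadata", "SubjectStudy", function(object) object@metadata)

#' @rdname accessors
#' @export
setGeneric("lesionSlices", function(object) standardGeneric("lesionSlices"))
#' @rdname accessors
#' @export
setMethod("lesionSlices", "LesionMask", function(object) object@masks)

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setMethod("components", "LesionMask", function(object) object@components)

#' Number of lesion pixels in a LesionMask
#' @param object a \linkS4class{LesionMask}.
#' @return integer pixel count over all slices.
#' @export
setGeneric("lesionPixelCount", function(object) standardGeneric("lesionPixelCount"))
#' @rdname lesionPixelCount
#' @export
setMethod("lesionPixelCount", "LesionMask",
          function(object) sum(vapply(object@masks, sum, numeric(1))))

# map accessor on studies: mapFor(study, slice, "T1")
#' Extract one modality map from one slice of a study
#' @param study a \linkS4class{SubjectStudy}.
#' @param slice 0-based slice index.
#' @param mod modality name.
#' @return A \linkS4class{ParametricMap}.
#' @export
mapFor <- function(study, slice, mod) {
  sl <- study@slices[[slice + 1L]]
  m <- sl$maps[[mod]]
  if (is.null(m)) stop("modality ", mod, " absent from slice ", slice)
  m
}

#' Geometry of one slice of a study
#' @inheritParams mapFor
#' @return A \linkS4class{HeartGeometry}.
#' @export
geometryFor <- function(study, slice) study@slices[[slice + 1L]]$geometry
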