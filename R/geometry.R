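# Ring geometry, AHA segmentation and transmural coordinates.
#
# Conventions: row-major 0-based pixel thinking is avoided in R; all matrices
# are 1-based but slice indices are 0-based (0 = most basal) to match the
# on-disk sidecar. The circumferential angle is measured in degrees from the
# anterior direction (decreasing row), increasing towards the image right
# (anterior -> lateral -> inferior -> septum), so the septum sits on the
# image left as on a standard short-axis view.

WALL_NAMES <- c("anterior", "anteroseptal", "inferoseptal",
                "inferior", "inferolateral", "anterolateral")

# AHA codes ordered by increasing angle from the anterior sector.
AHA_RING_ORDER <- list(
  basal  = c(1L, 6L, 5L, 4L, 3L, 2L),
  mid    = c(7L, 12L, 11L, 10L, 9L, 8L),
  apical = c(13L, 16L, 15L, 14L)
)

SEGMENT_WALL <- c(
  "1" = "anterior", "2" = "anteroseptal", "3" = "inferoseptal",
  "4" = "inferior", "5" = "inferolateral", "6" = "anterolateral",
  "7" = "anterior", "8" = "anteroseptal", "9" = "inferoseptal",
  "10" = "inferior", "11" = "inferolateral", "12" = "anterolateral",
  "13" = "anterior", "14" = "inferoseptal", "15" = "inferior",
  "16" = "anterolateral"
)

MUSCLE_LABEL <- 100L

.polarGrids <- function(dim, center, pixelSpacing) {
  drow <- (seq_len(dim[1]) - center[1]) * pixelSpacing[1]
  dcol <- (seq_len(dim[2]) - center[2]) * pixelSpacing[2]
  dr <- matrix(drow, dim[1], dim[2])
  dc <- matrix(dcol, dim[1], dim[2], byrow = TRUE)
  r <- sqrt(dr^2 + dc^2)
  theta <- (atan2(dc, -dr) * 180 / pi) %% 360
  list(r = r, theta = theta)
}

#' Build an AHA segment label grid for one short-axis slice
#'
#' Divides the myocardial ring into equiangular sectors following the AHA
#' 16-segment convention: 6 segments on basal and mid-ventricular slices,
#' 4 on apical slices (the apical-cap segment 17 is not represented in a
#' short-axis stack). Segment 1 (basal anterior) starts at \code{startAngle}
#' degrees from the anterior direction.
#'
#' @param dim grid dimensions (rows, cols).
#' @param center ring center (row, col) in pixel coordinates.
#' @param endoRadius,epiRadius endo- and epicardial radii in mm.
#' @param pixelSpacing (row mm, col mm).
#' @param position slice position class: "basal", "mid" or "apical".
#' @param startAngle rotation of the first sector boundary, degrees.
#' @return Integer matrix of AHA codes (1-16) inside the ring, 0 outside.
#' @export
buildAhaSegments <- function(dim, center, endoRadius, epiRadius, pixelSpacing,
                             position = c("basal", "mid", "apical"),
                             startAngle = 0) {
  position <- match.arg(position)
  if (endoRadius >= epiRadius)
    stop("degenerate ring: endoRadius must be < epiRadius")
  pg <- .polarGrids(dim, center, pixelSpacing)
  ring <- pg$r >= endoRadius & pg$r <= epiRadius
  order <- AHA_RING_ORDER[[position]]
  width <- 360 / length(order)
  sector <- floor(((pg$theta - startAngle) %% 360) / width) + 1L
  labels <- matrix(0L, dim[1], dim[2])
  labels[ring] <- order[sector[ring]]
  labels
}

#' Construct per-slice heart geometry
#'
#' Builds the myocardial ring mask, AHA segment labels, transmural coordinate
#' field (0 at the endocardial border, 1 at the epicardial border) and a
#' rectangular paraspinal skeletal-muscle reference block.
#'
#' @inheritParams buildAhaSegments
#' @param muscleRows,muscleCols row/column index ranges (length-2) of the
#'   skeletal-muscle block; NULL for no muscle region.
#' @return A \linkS4class{HeartGeometry}.
#' @export
makeHeartGeometry <- function(dim, center, endoRadius, epiRadius, pixelSpacing,
                              position = "basal", startAngle = 0,
                              muscleRows = NULL, muscleCols = NULL) {
  segments <- buildAhaSegments(dim, center, endoRadius, epiRadius,
                               pixelSpacing, position, startAngle)
  myo <- segments > 0L
  pg <- .polarGrids(dim, center, pixelSpacing)
  tm <- matrix(NA_real_, dim[1], dim[2])
  tm[myo] <- pmin(1, pmax(0, (pg$r[myo] - endoRadius) / (epiRadius - endoRadius)))
  muscle <- matrix(FALSE, dim[1], dim[2])
  if (!is.null(muscleRows) && !is.null(muscleCols)) {
    rr <- seq(max(1L, muscleRows[1]), min(dim[1], muscleRows[2]))
    cc <- seq(max(1L, muscleCols[1]), min(dim[2], muscleCols[2]))
    muscle[rr, cc] <- TRUE
    if (any(muscle & myo))
      stop("skeletal-muscle block overlaps the myocardial ring")
  }
  new("HeartGeometry", center = as.numeric(center),
      endoRadius = as.numeric(endoRadius), epiRadius = as.numeric(epiRadius),
      myoMask = myo, segments = segments, muscleMask = muscle,
      transmural = tm, pixelSpacing = as.numeric(pixelSpacing))
}

#' Slice position class from slice index
#'
#' Splits a base-to-apex stack into thirds: the first third of slices is
#' basal, the middle third mid-ventricular, the last third apical.
#'
#' @param sliceIndex 0-based slice index (0 = most basal).
#' @param nSlices total number of slices.
#' @return "basal", "mid" or "apical".
#' @export
slicePosition <- function(sliceIndex, nSlices) {
  third <- floor(3 * sliceIndex / nSlices)
  c("basal", "mid", "apical")[pmin(third, 2) + 1L]
}

#' Map AHA segment codes to wall names
#'
#' Basal/mid codes map to the six standard wall names; apical codes map to
#' the nearest basal/mid wall (14 "apical septal" to inferoseptal, 16
#' "apical lateral" to anterolateral).
#'
#' @param segments integer vector of AHA codes (1-16).
#' @return character vector of wall names.
#' @export
segmentWall <- function(segments) {
  unname(SEGMENT_WALL[as.character(segments)])
}
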