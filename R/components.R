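# Connected-component labeling and the minimum-contiguous-area filter.
#
# Labeling is a vectorized iterative minimum-label propagation restricted to
# the mask's bounding box: every foreground pixel starts with its own label
# and repeatedly adopts the smallest label among its (4- or 8-) neighbors
# until a fixed point. Components are then renumbered in raster order of
# their first pixel, which makes ids deterministic.

.shiftPad <- function(m, dr, dc, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  rs <- seq(max(1, 1 + dr), min(nr, nr + dr))
  cs <- seq(max(1, 1 + dc), min(nc, nc + dc))
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal).
#' @return Integer matrix: 0 background, components numbered 1..k in raster
#'   order of their first (column-major) pixel.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  rr <- range(row(mask)[idx]); cc <- range(col(mask)[idx])
  sub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cur <- matrix(Inf, nrow(sub), ncol(sub))
  cur[sub] <- which(sub)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    nxt <- cur
    for (o in offs) nxt <- pmin(nxt, .shiftPad(cur, o[1], o[2]))
    nxt[!sub] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  labs <- cur[sub]
  first <- sort(unique(labs))
  sublab <- matrix(0L, nrow(sub), ncol(sub))
  sublab[sub] <- match(labs, first)
  lab[rr[1]:rr[2], cc[1]:cc[2]] <- sublab
  lab
}

.componentInventory <- function(labels, pixelSpacing, slice) {
  k <- max(labels)
  if (k == 0L)
    return(data.frame(id = integer(), slice = integer(), pixels = integer(),
                      areaMM2 = numeric(), centroidRow = numeric(),
                      centroidCol = numeric()))
  pxArea <- pixelSpacing[1] * pixelSpacing[2]
  idx <- which(labels > 0L)
  lv <- labels[idx]
  counts <- tabulate(lv, nbins = k)
  data.frame(
    id = seq_len(k), slice = slice, pixels = counts,
    areaMM2 = counts * pxArea,
    centroidRow = as.numeric(tapply(row(labels)[idx], lv, mean)),
    centroidCol = as.numeric(tapply(col(labels)[idx], lv, mean))
  )
}

#' Minimum-contiguous-area filter for a candidate lesion mask
#'
#' Retains exactly those connected components whose physical area
#' (pixel count x pixel area) reaches \code{minArea}; everything else is
#' removed. The operation never adds pixels and is idempotent. The default
#' 40 mm^2 corresponds to 10 adjacent pixels at 2.0 x 2.0 mm STIR resolution
#' and suppresses isolated noise pixels as positive findings.
#'
#' @param mask logical matrix of candidate pixels (one slice).
#' @param pixelSpacing (row mm, col mm).
#' @param minArea minimum contiguous area in mm^2 (default 40).
#' @param connectivity 4 or 8 (default 8).
#' @param modality,threshold,slice descriptors stored on the result.
#' @return A \linkS4class{LesionMask} with one slice.
#' @export
filterContiguous <- function(mask, pixelSpacing, minArea = 40,
                             connectivity = 8, modality = "T1",
                             threshold = "", slice = 0L) {
  if (minArea < 0) stop("minArea must be >= 0")
  labels <- labelComponents(mask, connectivity)
  pxArea <- pixelSpacing[1] * pixelSpacing[2]
  counts <- if (max(labels) > 0) tabulate(labels[labels > 0L]) else integer()
  keep <- which(counts * pxArea >= minArea)
  newlab <- matrix(0L, nrow(mask), ncol(mask))
  out <- mask & FALSE
  if (length(keep)) {
    m <- labels %in% keep
    out[m] <- TRUE
    newlab[m] <- match(labels[m], keep)
  }
  comp <- .componentInventory(newlab, pixelSpacing, slice)
  masks <- list(out); labs <- list(newlab)
  names(masks) <- names(labs) <- as.character(slice)
  new("LesionMask", masks = masks, modality = modality,
      threshold = threshold, minArea = minArea, components = comp,
      labels = labs)
}

#' Combine per-slice LesionMasks into one multi-slice LesionMask
#'
#' @param lesions list of single-slice \linkS4class{LesionMask} objects.
#' @return A \linkS4class{LesionMask} spanning all slices.
#' @export
bindLesionSlices <- function(lesions) {
  stopifnot(length(lesions) > 0)
  masks <- list(); labs <- list(); comp <- list()
  for (l in lesions) {
    masks <- c(masks, l@masks)
    labs <- c(labs, l@labels)
    comp[[length(comp) + 1L]] <- l@components
  }
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  new("LesionMask", masks = masks, modality = lesions[[1]]@modality,
      threshold = lesions[[1]]@threshold, minArea = lesions[[1]]@minArea,
      components = comp, labels = labs)
}
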