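# Incremental-threshold topographic maps and lesion pattern classification.
#
# The ladder starts at the validated 990 ms detection threshold; higher
# rungs are presentation thresholds that localize the most elevated T1
# within the injured myocardium (the non-ischemic pattern: subepicardial /
# midwall, lateral and inferior walls). Layer terciles of transmural depth
# define subendocardial [0, 1/3), midwall [1/3, 2/3) and subepicardial
# [2/3, 1] involvement.

DEFAULT_LADDER <- c(990, 1030, 1070, 1110, 1150, 1200)

#' Validate an incremental T1 threshold ladder
#'
#' @param thresholds strictly increasing numeric vector of T1 thresholds
#'   (ms), at least two entries, first 990 by convention.
#' @return the validated ladder.
#' @export
thresholdLadder <- function(thresholds = DEFAULT_LADDER) {
  if (length(thresholds) < 2) stop("ladder needs at least 2 thresholds")
  if (any(diff(thresholds) <= 0)) stop("ladder must be strictly increasing")
  thresholds
}

#' Incremental-threshold lesion masks for one subject
#'
#' Applies the T1 detection criterion at every rung of the ladder. Masks
#' are nested: each higher-threshold mask is contained in the lower one
#' (area filtering preserves nesting because any retained component at a
#' higher rung lies inside a component of at least equal area at the rung
#' below).
#'
#' @param study a \linkS4class{SubjectStudy}.
#' @param ladder from [thresholdLadder()].
#' @inheritParams detectStudy
#' @return named list of multi-slice \linkS4class{LesionMask}, one per rung.
#' @export
incrementalMasks <- function(study, ladder = thresholdLadder(), minArea = 40,
                             connectivity = 8, comparator = ">=",
                             qcMode = "exclude") {
  ladder <- thresholdLadder(ladder)
  out <- lapply(ladder, function(t)
    detectStudy(study, "T1", threshold = t, minArea = minArea,
                connectivity = connectivity, comparator = comparator,
                qcMode = qcMode))
  names(out) <- as.character(ladder)
  out
}

LAYER_NAMES <- c("subendocardial", "midwall", "subepicardial")

#' Classify the layer and wall pattern of lesion components
#'
#' Per retained component: the fractions of component pixels with
#' transmural depth in [0, 1/3), [1/3, 2/3) and [2/3, 1] (subendocardial,
#' midwall, subepicardial), the involved walls with pixel counts, the
#' dominant layer (tie towards the more epicardial layer) and dominant
#' wall. A component whose subendocardial fraction is 1 is flagged as
#' subendocardial-only (ischemic-pattern suspicion).
#'
#' @param lesion a \linkS4class{LesionMask}.
#' @param geoms list of per-slice \linkS4class{HeartGeometry}.
#' @return data.frame, one row per component: slice, id, pixels, the three
#'   layer fractions, dominantLayer, dominantWall, subendocardialOnly, and
#'   one \code{wall.*} count column per wall name.
#' @export
classifyPattern <- function(lesion, geoms) {
  comp <- lesion@components
  if (!nrow(comp)) {
    return(data.frame(slice = integer(), id = integer(), pixels = integer(),
                      subendocardial = numeric(), midwall = numeric(),
                      subepicardial = numeric(), dominantLayer = character(),
                      dominantWall = character(),
                      subendocardialOnly = logical()))
  }
  rows <- list()
  for (r in seq_len(nrow(comp))) {
    s <- comp$slice[r]; id <- comp$id[r]
    lab <- lesion@labels[[as.character(s)]]
    g <- geoms[[s + 1L]]
    idx <- which(lab == id)
    if (!length(idx)) stop("empty component ", id, " on slice ", s)
    tm <- g@transmural[idx]
    fr <- c(mean(tm < 1 / 3), mean(tm >= 1 / 3 & tm < 2 / 3), mean(tm >= 2 / 3))
    walls <- segmentWall(g@segments[idx])
    wcount <- vapply(WALL_NAMES, function(w) sum(walls == w), numeric(1))
    dom <- LAYER_NAMES[max(which(fr == max(fr)))]  # tie -> more epicardial
    row <- data.frame(slice = s, id = id, pixels = length(idx),
                      subendocardial = fr[1], midwall = fr[2],
                      subepicardial = fr[3], dominantLayer = dom,
                      dominantWall = WALL_NAMES[which.max(wcount)],
                      subendocardialOnly = fr[1] == 1)
    for (w in WALL_NAMES) row[[paste0("wall.", w)]] <- wcount[[w]]
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a lesion overlay panel to PNG
#'
#' Grayscale base image with the lesion mask in red and the reference-ROI
#' contour in green; byte-deterministic for fixed inputs.
#'
#' @param map a \linkS4class{ParametricMap} (the base image).
#' @param geometry the slice geometry.
#' @param lesionMask logical matrix of lesion pixels on this slice.
#' @param refRoi optional \linkS4class{RemoteROI}; its segment contour is
#'   drawn in green.
#' @param path output PNG path.
#' @param window grayscale display window (low, high); defaults to the
#'   image range.
#' @return \code{path}, invisibly.
#' @export
renderOverlay <- function(map, geometry, lesionMask, refRoi = NULL, path,
                          window = NULL) {
  px <- map@pixels
  if (!identical(dim(px), dim(lesionMask)) ||
      !identical(dim(px), dim(geometry@myoMask)))
    stop("misaligned shapes between map, lesion mask and geometry")
  if (is.null(window)) window <- range(px)
  gray <- pmin(1, pmax(0, (px - window[1]) / max(window[2] - window[1], 1e-12)))
  rgb <- array(gray, dim = c(dim(px), 3))
  red <- lesionMask
  rgb[, , 1][red] <- 1; rgb[, , 2][red] <- 0; rgb[, , 3][red] <- 0
  if (!is.null(refRoi)) {
    seg <- matrix(FALSE, nrow(px), ncol(px))
    seg[geometry@segments %in% refRoi@segments] <- TRUE
    interior <- seg &
      .shiftPad(seg, 1, 0, FALSE) & .shiftPad(seg, -1, 0, FALSE) &
      .shiftPad(seg, 0, 1, FALSE) & .shiftPad(seg, 0, -1, FALSE)
    contour <- seg & !interior
    rgb[, , 1][contour] <- 0; rgb[, , 2][contour] <- 1; rgb[, , 3][contour] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Render one panel per ladder rung for a subject slice
#'
#' @param study a \linkS4class{SubjectStudy}.
#' @param masks ladder masks from [incrementalMasks()].
#' @param slice 0-based slice index to render.
#' @param dir output directory.
#' @param window grayscale window passed to [renderOverlay()].
#' @return character vector of written file paths.
#' @export
renderLadderPanels <- function(study, masks, slice, dir, window = c(600, 1400)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- mapFor(study, slice, "T1")
  g <- geometryFor(study, slice)
  paths <- character()
  for (t in names(masks)) {
    p <- file.path(dir, sprintf("%s_slice%02d_T1_%sms.png",
                                study@subjectId, slice, t))
    renderOverlay(map, g, masks[[t]]@masks[[as.character(slice)]],
                  refRoi = NULL, path = p, window = window)
    paths <- c(paths, p)
  }
  paths
}
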