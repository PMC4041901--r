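# Study I/O: one NIfTI volume per modality (slices stacked on the third
# axis), one NIfTI label volume (AHA codes 1-16, skeletal muscle 100,
# background 0), and a JSON sidecar carrying spacings, group, metadata, qc
# flags and ring geometry. The sidecar is the source of truth for group
# labels and qc flags; the image headers are the source for pixel spacing.

SIDECAR_SCHEMA <- "1.0"

.sidecarPath <- function(path) file.path(path, "study.json")

.writeNiftiVolume <- function(arr, spacing, thickness, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing[1], spacing[2], thickness)
  RNifti::writeNifti(img, path)
}

#' Write a SubjectStudy to a self-contained directory
#'
#' Writes \code{T1.nii.gz}, \code{T2W.nii.gz}, \code{LGE.nii.gz} (as
#' available), a \code{labels.nii.gz} volume (AHA segment codes 1-16,
#' skeletal muscle 100) and a versioned JSON sidecar \code{study.json}.
#' Writing, reading back and writing again is byte-stable for the sidecar.
#'
#' @param study a valid \linkS4class{SubjectStudy}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @seealso [readStudy()]
#' @export
writeStudy <- function(study, path) {
  validObject(study)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create study directory: ", path)
  slices <- study@slices
  n <- length(slices)
  g1 <- slices[[1]]$geometry
  d <- dim(g1@myoMask)
  spacing <- g1@pixelSpacing
  thickness <- slices[[1]]$maps[[1]]@sliceThickness
  mods <- names(slices[[1]]$maps)
  for (m in mods) {
    arr <- array(0, dim = c(d, n))
    for (i in seq_len(n)) arr[, , i] <- slices[[i]]$maps[[m]]@pixels
    .writeNiftiVolume(arr, spacing, thickness, file.path(path, paste0(m, ".nii.gz")))
  }
  lab <- array(0L, dim = c(d, n))
  for (i in seq_len(n)) {
    g <- slices[[i]]$geometry
    sl <- g@segments
    sl[g@muscleMask] <- MUSCLE_LABEL
    lab[, , i] <- sl
  }
  .writeNiftiVolume(lab, spacing, thickness, file.path(path, "labels.nii.gz"))

  qc <- study@qcFlags
  qc <- qc[order(qc$slice, qc$segment, qc$modality), , drop = FALSE]
  rownames(qc) <- NULL
  sidecar <- list(
    schema_version = SIDECAR_SCHEMA,
    subject_id = study@subjectId,
    group = study@group,
    modalities = as.list(mods),
    pixel_spacing = as.numeric(spacing),
    slice_thickness = as.numeric(thickness),
    n_slices = n,
    geometry = lapply(seq_len(n), function(i) {
      g <- slices[[i]]$geometry
      list(slice = i - 1L, center = as.numeric(g@center),
           endo_radius_mm = g@endoRadius, epi_radius_mm = g@epiRadius)
    }),
    qc_flags = qc,
    metadata = study@metadata
  )
  json <- jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, .sidecarPath(path))
  invisible(path)
}

#' Read a SubjectStudy from a directory written by writeStudy
#'
#' Reconstructs the study from the NIfTI volumes and sidecar. Pixel-spacing
#' disagreements between the sidecar and the NIfTI headers are reconciled in
#' favor of the image header, with a warning. The label volume must contain
#' only the codes 0 (background), 1-16 (AHA segments) and 100 (skeletal
#' muscle).
#'
#' @param path directory written by [writeStudy()].
#' @return A \linkS4class{SubjectStudy}.
#' @export
readStudy <- function(path) {
  sj <- .sidecarPath(path)
  if (!file.exists(sj)) stop("missing sidecar: ", sj)
  sc <- jsonlite::fromJSON(readLines(sj), simplifyVector = TRUE)
  mods <- unlist(sc$modalities)
  vols <- list()
  spacing <- as.numeric(sc$pixel_spacing)
  thickness <- as.numeric(sc$slice_thickness)
  for (m in mods) {
    f <- file.path(path, paste0(m, ".nii.gz"))
    if (!file.exists(f)) stop("missing modality file: ", f)
    img <- RNifti::readNifti(f)
    hd <- RNifti::pixdim(img)
    if (any(abs(hd[1:2] - spacing) > 1e-6)) {
      warning(sprintf(
        "pixel spacing mismatch for %s: sidecar %.4gx%.4g, header %.4gx%.4g; using header",
        m, spacing[1], spacing[2], hd[1], hd[2]))
      spacing <- hd[1:2]
    }
    if (length(hd) >= 3 && abs(hd[3] - thickness) > 1e-6) {
      warning(sprintf("slice thickness mismatch for %s: using header %.4g", m, hd[3]))
      thickness <- hd[3]
    }
    vols[[m]] <- unclass(img)
  }
  labf <- file.path(path, "labels.nii.gz")
  if (!file.exists(labf)) stop("missing label volume: ", labf)
  lab <- round(unclass(RNifti::readNifti(labf)))
  codes <- sort(unique(as.integer(lab)))
  bad <- setdiff(codes, c(0L, 1:16, MUSCLE_LABEL))
  if (length(bad))
    stop("label volume contains invalid codes: ", paste(bad, collapse = ", "))

  n <- sc$n_slices
  geo <- sc$geometry
  geoSlice <- function(i) {
    if (is.data.frame(geo)) {
      cn <- geo$center
      list(center = if (is.matrix(cn)) cn[i, ] else unlist(cn[[i]]),
           endo = geo$endo_radius_mm[i], epi = geo$epi_radius_mm[i])
    } else {
      list(center = unlist(geo[[i]]$center),
           endo = geo[[i]]$endo_radius_mm, epi = geo[[i]]$epi_radius_mm)
    }
  }
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    labi <- matrix(as.integer(lab[, , i]), dim(lab)[1], dim(lab)[2])
    segs <- labi
    segs[segs == MUSCLE_LABEL] <- 0L
    myo <- segs > 0L
    muscle <- labi == MUSCLE_LABEL
    gs <- geoSlice(i)
    center <- as.numeric(gs$center)
    endo <- gs$endo
    epi <- gs$epi
    pg <- .polarGrids(dim(labi), center, spacing)
    tm <- matrix(NA_real_, nrow(labi), ncol(labi))
    tm[myo] <- pmin(1, pmax(0, (pg$r[myo] - endo) / (epi - endo)))
    gobj <- new("HeartGeometry", center = center, endoRadius = endo,
                epiRadius = epi, myoMask = myo, segments = segs,
                muscleMask = muscle, transmural = tm, pixelSpacing = spacing)
    maps <- list()
    for (m in mods) {
      maps[[m]] <- ParametricMap(
        matrix(as.numeric(vols[[m]][, , i]), nrow(labi), ncol(labi)),
        pixelSpacing = spacing, sliceIndex = i - 1L,
        sliceThickness = thickness, modality = m)
    }
    slices[[i]] <- list(maps = maps, geometry = gobj)
  }
  qc <- as.data.frame(sc$qc_flags)
  qc$slice <- as.integer(qc$slice)
  qc$segment <- as.integer(qc$segment)
  qc$included <- as.logical(qc$included)
  md <- sc$metadata
  new("SubjectStudy", subjectId = sc$subject_id, group = sc$group,
      slices = slices, qcFlags = qc,
      metadata = if (is.null(md)) list() else as.list(md))
}
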