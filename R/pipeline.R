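# End-to-end orchestration: phantom -> detection -> quantification ->
# diagnostics, with a run manifest that makes the run reproducible
# (config + master seed are complete).

#' Default pipeline configuration
#'
#' Houses the analysis constants: the 990 ms T1 threshold, the 2.0 T2 SI
#' ratio cut, the 2-SD remote criteria, the 40 mm^2 minimum contiguous
#' area, 8-connectivity, the incremental ladder, and the two-contiguous-
#' slice confirmation applied to low-extent subjects.
#'
#' @param seed master seed.
#' @param counts cohort composition.
#' @param outDir optional output directory; NULL = in-memory only.
#' @return config list.
#' @export
defaultRunConfig <- function(seed = 1L,
                             counts = c(control = 50, I = 41, II = 12, III = 7),
                             outDir = NULL) {
  list(
    counts = counts,
    geom = defaultGeometry(),
    seed = seed,
    t1Threshold = 990,
    t1Comparator = ">=",
    t2RatioCut = 2.0,
    sdMult = 2.0,
    minArea = 40,
    connectivity = 8,
    ladder = DEFAULT_LADDER,
    confirm = list(slices = 2, belowExtentPct = 10),
    qcMode = "exclude",
    lgeEvaluableControlFrac = 35 / 50,
    outDir = outDir,
    writeImages = FALSE,
    renderPanels = FALSE
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [readRunConfig()] returns the config list merged over defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  if (is.null(cfg)) return(base)
  out <- utils::modifyList(base, cfg)
  out$counts <- unlist(out$counts)
  out
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
writeRunConfig <- function(config, path) {
  config$counts <- as.list(config$counts)  # YAML drops names of atomic vectors
  yaml::write_yaml(config, path)
  invisible(path)
}

# Analyse one subject: detection on all three modalities, extents, subject
# mean T1 and global T2 ratio, criterion decisions.
.analyzeSubject <- function(study, cfg) {
  geoms <- lapply(study@slices, `[[`, "geometry")
  qc <- study@qcFlags
  res <- list(subjectId = study@subjectId, group = study@group)
  res$meanT1 <- subjectMeanT1(study, cfg$qcMode)
  res$t2Ratio <- globalT2Ratio(study, cfg$qcMode)

  lesT1 <- detectStudy(study, "T1", threshold = cfg$t1Threshold,
                       minArea = cfg$minArea, connectivity = cfg$connectivity,
                       comparator = cfg$t1Comparator, qcMode = cfg$qcMode)
  lesT2 <- suppressMessages(
    detectStudy(study, "T2W", minArea = cfg$minArea,
                connectivity = cfg$connectivity, sdMult = cfg$sdMult,
                qcMode = cfg$qcMode))
  lesLGE <- detectStudy(study, "LGE", minArea = cfg$minArea,
                        connectivity = cfg$connectivity, sdMult = cfg$sdMult,
                        qcMode = cfg$qcMode)

  ext <- list()
  for (les in list(lesT1, lesT2, lesLGE)) {
    rows <- segmentExtent(les, geoms, qc, cfg$qcMode)
    rows$subjectId <- study@subjectId
    ext[[les@modality]] <- rows
  }
  res$extentT1 <- subjectExtent(ext$T1)
  res$extentT2W <- subjectExtent(ext$T2W)
  res$extentLGE <- subjectExtent(ext$LGE)

  rule <- list(confirmSlices = cfg$confirm$slices,
               applyBelowExtentPct = cfg$confirm$belowExtentPct,
               orthogonalPlanes = FALSE)
  res$posT1 <- subjectPositive(lesT1, rule, extentPct = res$extentT1)$positive
  t2Regional <- subjectPositive(lesT2)$positive
  res$posT2 <- (res$t2Ratio >= cfg$t2RatioCut) || t2Regional
  res$posLGE <- subjectPositive(lesLGE)$positive

  md <- study@metadata
  res$ef <- if (!is.null(md$ef_pct)) md$ef_pct else NA_real_
  res$troponin <- if (!is.null(md$troponin_ugL)) md$troponin_ugL else NA_real_
  list(row = as.data.frame(res), extent = do.call(rbind, ext),
       lesions = list(T1 = lesT1, T2W = lesT2, LGE = lesLGE))
}

.table2Combinations <- function(d) {
  list(
    "T1-mapping" = d$T1,
    "Dark-blood T2" = d$T2,
    "LGE" = d$LGE,
    "Dark-blood T2 and LGE (2 of 2)" = combineCriteria(list(d$T2, d$LGE), 2),
    "Dark-blood T2 or LGE (Any 1 of 2)" = combineCriteria(list(d$T2, d$LGE), 1),
    "T1-mapping and LGE (2 of 2)" = combineCriteria(list(d$T1, d$LGE), 2),
    "T1-mapping or LGE (Any 1 of 2)" = combineCriteria(list(d$T1, d$LGE), 1),
    "T1, T2 or LGE (Any 1 of 3)" = combineCriteria(list(d$T1, d$T2, d$LGE), 1),
    "T1, T2 or LGE (Any 2 of 3)" = combineCriteria(list(d$T1, d$T2, d$LGE), 2),
    "T1, T2 and LGE (3 of 3)" = combineCriteria(list(d$T1, d$T2, d$LGE), 3),
    "T1-mapping and Dark-blood T2 (2 of 2)" = combineCriteria(list(d$T1, d$T2), 2),
    "T1-mapping or Dark-blood T2 (Any 1 of 2)" = combineCriteria(list(d$T1, d$T2), 1)
  )
}

.summaryRow <- function(name, s) {
  data.frame(criterion = name,
             TP = s$counts["TP"], FP = s$counts["FP"],
             TN = s$counts["TN"], FN = s$counts["FN"],
             sensitivity = s$display["sensitivity"],
             specificity = s$display["specificity"],
             accuracy = s$display["accuracy"],
             ppv = s$display["ppv"], npv = s$display["npv"],
             row.names = NULL)
}

#' Evaluate the native T1 criterion alone on a synthetic cohort
#'
#' Streams the configured cohort through T1 detection (threshold, minimum
#' contiguous area, connectivity) and subject-level positivity with the
#' two-contiguous-slice confirmation for low-extent subjects, and reports
#' patient-level sensitivity and control-level specificity.
#'
#' @param counts cohort composition.
#' @param geom geometry configuration.
#' @param masterSeed integer master seed.
#' @param threshold T1 threshold in ms.
#' @param minArea minimum contiguous area in mm^2.
#' @param connectivity 4 or 8.
#' @param comparator ">=" or ">".
#' @param confirm confirmation rule (slices, belowExtentPct).
#' @param qcMode "exclude" or "include-all".
#' @return list: \code{perSubject} (subjectId, group, variant, extentPct,
#'   positive), \code{sensitivityPct}, \code{specificityPct}.
#' @export
evaluateT1Criterion <- function(counts = c(control = 50, I = 41, II = 12, III = 7),
                                geom = defaultGeometry(), masterSeed = 1L,
                                threshold = 990, minArea = 40,
                                connectivity = 8, comparator = ">=",
                                confirm = list(slices = 2, belowExtentPct = 10),
                                qcMode = "exclude") {
  rows <- list()
  rule <- list(confirmSlices = confirm$slices,
               applyBelowExtentPct = confirm$belowExtentPct,
               orthogonalPlanes = FALSE)
  cb <- function(study, truthEntry, idx) {
    les <- detectStudy(study, "T1", threshold = threshold, minArea = minArea,
                       connectivity = connectivity, comparator = comparator,
                       qcMode = qcMode)
    geoms <- lapply(study@slices, `[[`, "geometry")
    ext <- subjectExtent(segmentExtent(les, geoms, study@qcFlags, qcMode))
    pos <- subjectPositive(les, rule, extentPct = ext)$positive
    rows[[idx]] <<- data.frame(subjectId = study@subjectId,
                               group = study@group,
                               variant = truthEntry$variant,
                               extentPct = ext, positive = pos)
  }
  synthesizeCohort(counts, geom = geom, masterSeed = masterSeed, callback = cb)
  perSubject <- do.call(rbind, rows)
  pat <- perSubject$group != "control"
  list(perSubject = perSubject,
       sensitivityPct = if (any(pat)) 100 * mean(perSubject$positive[pat]) else NA_real_,
       specificityPct = if (any(!pat)) 100 * mean(!perSubject$positive[!pat]) else NA_real_)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the configured cohort, runs all three detection criteria per
#' subject, quantifies extents, evaluates single and combined diagnostic
#' criteria, ROC/AUC with DeLong comparisons, McNemar and Cochran's Q, and
#' the generator calibration report. Deterministic for a fixed config.
#'
#' @param config from [defaultRunConfig()] or [readRunConfig()].
#' @return invisibly, a bundle list: perSubject, extent, table2, summaries,
#'   roc, tests, calibration, table1, roster, manifest.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- config
  rows <- list(); extents <- list()
  panelPaths <- character()
  outDir <- cfg$outDir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  firstPatientDone <- FALSE

  cb <- function(study, truthEntry, index) {
    a <- .analyzeSubject(study, cfg)
    rows[[index]] <<- a$row
    extents[[index]] <<- a$extent
    if (!is.null(outDir)) {
      if (isTRUE(cfg$writeImages))
        writeStudy(study, file.path(outDir, "studies", study@subjectId))
      if (isTRUE(cfg$renderPanels) && !firstPatientDone &&
          study@group != "control") {
        firstPatientDone <<- TRUE
        masks <- incrementalMasks(study, cfg$ladder, cfg$minArea,
                                  cfg$connectivity, cfg$t1Comparator,
                                  cfg$qcMode)
        mid <- floor(length(study@slices) / 2)
        panelPaths <<- renderLadderPanels(study, masks, mid,
                                          file.path(outDir, "panels"))
      }
    }
  }
  gen <- synthesizeCohort(cfg$counts, geom = cfg$geom,
                          masterSeed = cfg$seed, callback = cb)
  perSubject <- do.call(rbind, rows)
  extent <- do.call(rbind, extents)
  rownames(extent) <- NULL

  # LGE evaluable subset in controls (contrast not given to every volunteer)
  isControl <- perSubject$group == "control"
  nEval <- round(cfg$lgeEvaluableControlFrac * sum(isControl))
  if (sum(isControl) > nEval) {
    set.seed(.subjectSeed(cfg$seed, 999983))
    drop <- sample(which(isControl), sum(isControl) - nEval)
    perSubject$posLGE[drop] <- NA
    perSubject$extentLGE[drop] <- NA
  }

  truthPos <- perSubject$group != "control"
  d <- list(T1 = perSubject$posT1, T2 = perSubject$posT2,
            LGE = perSubject$posLGE)
  combos <- suppressMessages(.table2Combinations(d))
  summaries <- lapply(combos, summarizeCriterion, truth = truthPos)
  table2 <- do.call(rbind, Map(.summaryRow, names(summaries), summaries))
  rownames(table2) <- NULL

  roc <- NULL; tests <- NULL
  if (any(truthPos) && any(!truthPos)) {
    scores <- list(T1 = perSubject$meanT1, T2 = perSubject$t2Ratio,
                   LGE = perSubject$extentLGE)
    lgeOk <- !is.na(scores$LGE)
    roc <- list(
      aucT1 = rocAuc(scores$T1, truthPos),
      aucT2 = rocAuc(scores$T2, truthPos),
      aucLGE = rocAuc(scores$LGE[lgeOk], truthPos[lgeOk]),
      delongT1vsT2 = delongCompare(scores$T1, scores$T2, truthPos),
      delongT1vsLGE = delongCompare(scores$T1[lgeOk], scores$LGE[lgeOk],
                                    truthPos[lgeOk]))
    pat <- truthPos
    tests <- list(
      mcnemarT1vsT2 = mcnemarTest(d$T1[pat], d$T2[pat]),
      mcnemarT1vsLGE = mcnemarTest(d$T1[pat], d$LGE[pat]),
      cochranQ = cochranQ(data.frame(T1 = d$T1, T2 = d$T2, LGE = d$LGE)))
  } else {
    warning("degenerate cohort (one class empty); diagnostics limited")
  }

  stats <- data.frame(subjectId = perSubject$subjectId,
                      group = perSubject$group,
                      meanT1 = perSubject$meanT1,
                      t2Ratio = perSubject$t2Ratio)
  calibration <- calibrationReport(stats, gen$truth)
  table1 <- cohortSummary(perSubject,
                          meanCols = c("meanT1", "t2Ratio", "ef"),
                          medianCols = c("extentT1", "extentT2W", "extentLGE"))

  manifest <- list(
    package = "t1topo",
    version = as.character(utils::packageVersion("t1topo")),
    configHash = rlang::hash(cfg),
    seed = cfg$seed,
    nSubjects = nrow(perSubject),
    rVersion = paste(R.version$major, R.version$minor, sep = "."))

  bundle <- list(perSubject = perSubject, extent = extent, table2 = table2,
                 summaries = summaries, roc = roc, tests = tests,
                 calibration = calibration, table1 = table1,
                 roster = gen$roster, manifest = manifest,
                 panels = panelPaths)
  if (!is.null(outDir)) {
    utils::write.csv(perSubject, file.path(outDir, "per_subject.csv"),
                     row.names = FALSE)
    utils::write.csv(extent, file.path(outDir, "extent.csv"), row.names = FALSE)
    utils::write.csv(table2, file.path(outDir, "table2.csv"), row.names = FALSE)
    utils::write.csv(calibration, file.path(outDir, "calibration_report.csv"),
                     row.names = FALSE)
    utils::write.csv(table1$byGroup, file.path(outDir, "table1_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(gen$roster, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bundle)
}
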