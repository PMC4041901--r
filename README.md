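# t1topo — contrast-free tissue characterization of acute myocarditis on native T1-maps

`t1topo` implements a quantitative, threshold-based analysis of acute
myocarditis on cardiovascular MR (CMR) parametric maps, for imaging
scientists and CMR methodologists who want a reproducible, fully scripted
version of the workflow — including a calibrated digital cardiac phantom to
exercise it end to end, since clinical DICOM data of this kind are not
redistributable.

## The analysis

Acute myocarditis produces myocardial edema and necrosis in a
characteristic **non-ischemic pattern**: subepicardial or midwall lesions,
most often in the lateral and inferior walls, sparing the subendocardium.
Conventional CMR shows this with T2-weighted (T2W) imaging and late
gadolinium enhancement (LGE); native T1-mapping shows it **without contrast
agents**. The package implements the three quantitative criteria:

| criterion | rule |
|---|---|
| native T1 | pixel T1 ≥ 990 ms inside the myocardium |
| dark-blood T2W | pixel SI / skeletal-muscle mean ≥ 2.0, **or** SI ≥ remote mean + 2 SD |
| LGE | SI ≥ remote-myocardium mean + 2 SD |

with, in every case, a **minimum contiguous area of 40 mm²** (connected
components below that are discarded as noise; 8-connectivity by default),
segment-level quality-control exclusion, and an algorithmic remote-ROI
surrogate for the expert's "least affected myocardium" choice. On top of
the criteria sit:

* **extent of injury** — % abnormal pixels per AHA segment, averaged per
  subject;
* **incremental-threshold topographic maps** — a ladder of T1 thresholds
  (990, 1030, …, 1200 ms) that localizes the most elevated T1 inside the
  injured region and classifies each lesion's transmural layer
  (subendocardial / midwall / subepicardial terciles) and wall;
* **subject-level positivity** — any retained component, with an optional
  two-contiguous-slice confirmation for low-extent subjects (small focal
  lesions);
* **diagnostic evaluation** — sensitivity/specificity/accuracy/PPV/NPV for
  single criteria and any-k-of-n combinations, rank-based ROC AUC with the
  DeLong test for correlated AUCs, McNemar and Cochran's Q;
* **a digital phantom** — multiparametric short-axis cohorts (co-registered
  T1/T2W/LGE + masks + AHA labels + ground truth) calibrated to published
  population statistics: controls 946 ± 23 ms, patient subgroups up to
  1030 ± 62 ms, global T2 SI ratios 1.47–1.79, group sizes 50/41/12/7.

## Worked example

```r
library(t1topo)

res   <- synthesizeSubject(groupPreset("I"), seed = 3, subjectId = "PI-003")
study <- res$study
study
#> SubjectStudy 'PI-003' (group I): 9 slices, modalities T1/T2W/LGE
#>   qc: 139/144 (slice,segment,modality) triples included

lesions <- detectStudy(study, "T1", threshold = 990, minArea = 40)
lesions
#> LesionMask [T1] T1>=990ms, min area 40 mm^2: 8 component(s), 5520 pixel(s)

geoms <- lapply(studySlices(study), function(s) s$geometry)
ext   <- subjectExtent(segmentExtent(lesions, geoms, qcFlags(study)))
sprintf("mean myocardial T1: %.0f ms | global T2 SI ratio: %.2f | extent: %.1f%%",
        subjectMeanT1(study), globalT2Ratio(study), ext)
#> "mean myocardial T1: 971 ms | global T2 SI ratio: 1.72 | extent: 34.7%"

subjectPositive(lesions, list(confirmSlices = 2, applyBelowExtentPct = 10),
                extentPct = ext)$positive
#> TRUE

vapply(incrementalMasks(study, c(990, 1070, 1150)), lesionPixelCount, numeric(1))
#>  990 1070 1150
#> 5520    0    0

classifyPattern(lesions, geoms)[1:2, c("slice", "pixels", "midwall",
                                       "subepicardial", "dominantLayer",
                                       "dominantWall")]
#>   slice pixels   midwall subepicardial dominantLayer  dominantWall
#> 1     2   1015 0.3763547     0.2561576       midwall inferolateral
#> 2     3    591 0.3959391     0.2639594       midwall inferolateral
```

Reading: this synthetic edema+/LGE+ patient has a mildly elevated mean T1
(971 ms) but a clearly abnormal regional extent — 34.7% of the myocardium
exceeds 990 ms in contiguous areas ≥ 40 mm², in a midwall, inferolateral
(non-ischemic) pattern. The higher ladder rungs are empty: the elevation is
moderate, as in low-grade disease. The full pipeline
(`runPipeline(defaultRunConfig())`) scales this to a whole cohort and emits
extent tables, Table-1-style cohort summaries, Table-2-style diagnostic
performance for all criterion combinations, calibration reports, overlay
panels and a reproducibility manifest.

A thin CLI covers the two common entry points:

```sh
Rscript inst/scripts/t1topo.R generate --out cohort/ --seed 1
Rscript inst/scripts/t1topo.R run --config run.yaml --out results/
```

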