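---
title: "Methods: threshold-based myocarditis tissue characterization and the calibrated phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based myocarditis tissue characterization and the calibrated phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1topo)
```

## The detection model

Acute myocardial inflammation raises free tissue water, which prolongs the
native (pre-contrast) T1 relaxation time. Because normal myocardial T1 has a
tight range on a given platform (here modeled as 946 ± 23 ms across
subjects), a fixed absolute threshold separates injured from normal tissue:
a pixel is abnormal when its T1 reaches **990 ms**. The comparator is
configurable between `>` and `>=` — the distinction has measure zero on
continuous maps but both readings appear in practice; `>=` is the default.

The two comparator criteria follow the same thresholding template on
signal-intensity images, where no absolute scale exists:

* **T2W edema**: a pixel is abnormal when its SI is at least **2.0 times**
  the slice's skeletal-muscle mean, or at least **2.0 SD** above the mean of
  a remote myocardial reference region. The subject-level "global SI ratio"
  (pooled myocardial mean over pooled muscle mean) with the same 2.0 cut is
  the global-edema marker.
* **LGE**: a pixel is abnormal when its SI is at least **2.0 SD** above the
  remote-myocardium mean on the nulled-myocardium image.

All three criteria then pass a **minimum contiguous-area filter**: only
connected components of at least **40 mm²** survive (about 50 pixels at the
0.9 × 0.9 mm analysis grid; equivalently 10 adjacent pixels at 2 × 2 mm STIR
resolution). This suppresses isolated noise excursions — with Gaussian pixel
noise, supra-threshold pixels are plentiful but spatially scattered, and the
area gate removes them. Connectivity is 8-connected in-plane by default
(4-connected available); components are never merged across slices, because
the area rule is an in-plane rule.

### Remote-ROI surrogate

Expert readers choose a "least affected" reference region. The algorithmic
surrogate is: among qc-included segments with zero overlap with the detected
LGE mask, discard segments whose mean SI falls below the slice myocardial
median minus twice the robust SD (signal dropout), then take the segment
with the lowest mean SI; ties break to the lowest segment id. The low-signal
exclusion is **disabled on LGE images**: there, nulled (dark) myocardium is
the normal reference and low signal is the expected remote appearance —
applying the rule would push the reference into enhancing tissue on heavily
enhanced slices. If no eligible segment exists, the T2W criterion falls back
to its ratio-only branch (logged); with a zero-SD remote the 2-SD branch
degenerates to a strict mean comparison, with a warning.

### Subject-level positivity

Default: a subject is positive when any retained component exists. For
low-extent subjects (extent below 10% by default) a confirmation rule
requires components on at least two contiguous slices, mirroring how small
focal findings are confirmed in practice. Orthogonal-plane confirmation
requires long-axis views and deliberately raises an error in this
short-axis-only implementation.

## Quantification conventions

* **Extent of injury**: 100 × |lesion ∩ segment| / |segment| per
  (slice, segment), averaged **unweighted** over the subject's qc-included
  segments. Excluded segments enter no aggregate.
* **Mean myocardial T1**: pixel-level mean over all qc-included myocardial
  pixels (a mean of per-segment means is available via `segmentMeans = TRUE`;
  the pixel mean is the default as the plainest reading of "mean myocardial
  T1").
* **AHA model**: 16 segments (6 basal, 6 mid, 4 apical), equiangular from a
  configurable anterior insertion angle; the apical cap (segment 17) is not
  represented in a short-axis stack. Slice thirds define basal/mid/apical.
* **Transmural layers**: terciles of the transmural coordinate (0 at
  endocardium, 1 at epicardium) define subendocardial [0, 1/3), midwall
  [1/3, 2/3) and subepicardial [2/3, 1]; a dominant-layer tie resolves to
  the more epicardial layer. "Lateral" summaries aggregate anterolateral +
  inferolateral.
* **Incremental ladder**: 990, 1030, 1070, 1110, 1150, 1200 ms. The first
  rung is the validated detection threshold and 1200 ms the illustrative
  high rung; the intermediate steps are evenly spaced presentation
  thresholds, not validated cut-offs. Ladder masks nest, and extent is
  non-increasing along the ladder.

## Diagnostic evaluation

2×2 counts and sensitivity/specificity/accuracy/PPV/NPV are computed on the
evaluable subset per criterion (LGE is evaluable in 35 of 50 controls by
default, reflecting contrast not being given to every volunteer;
configurable). Display values round half-up to integers; unrounded values
are retained and used in all tests. Combinations are any-k-of-n over the
constituent decisions; subjects with a non-evaluable constituent are dropped
from that combination. AUC uses the rank (Mann–Whitney) formulation with
ties counting one half; paired AUCs are compared with the DeLong
placement-value variance and a two-sided normal p. McNemar uses the exact
doubled-binomial tail below 25 discordant pairs and the continuity-corrected
chi-square above; Cochran's Q uses the standard statistic with k − 1 df
(reducing to McNemar's uncorrected chi-square at k = 2). ROC score
variables are mean myocardial T1, the global T2 SI ratio, and LGE extent —
a documented, configurable choice.

## The phantom: what it emulates

Each subject is a 9-slice, 128 × 128, 0.9 × 0.9 × 8 mm short-axis stack
(all three modalities co-registered on one grid) with a circular
left-ventricular ring (epicardial radius 32 mm, wall 9 mm), a paraspinal
skeletal-muscle block, AHA labels, and per-(slice, segment, modality) qc
flags sampled at the reported rejection rates (T1 11%, T2W 9%, LGE 3%).

Per-subject draws calibrate to the published population statistics:

| group | mean T1 (ms) | global T2 ratio | extent target | lesions |
|---|---|---|---|---|
| control | 946 ± 23 | 1.56 ± 0.15 | — | none |
| I (edema+, LGE+) | 1030 ± 62 | 1.79 ± 0.27 | median 49% (24–70) | sector, edematous, enhancing |
| II (edema−, LGE+) | 986 ± 54 | 1.60 ± 0.16 | median 15% (12–29) | sector, enhancing, no T2 boost |
| III (edema−, LGE−) | 947 ± 27 | 1.47 ± 0.17 | 1–2 foci, 60–90 mm²/slice | focal, non-enhancing |

Lesions are annular sectors with a circumferential center (drawn from a
menu favoring the lateral and inferior walls), an angular width solved from
the target extent, and a transmural band drawn from subepicardial/midwall
presets — the non-ischemic pattern. The modality structure is nested: the
T1-abnormal sector strictly contains an LGE "necrosis" core (45% of the
sector width) which contains a narrower STIR-visible edema core (25%). This
reproduces two in-vivo observations: injured-but-LGE-negative tissue shows
elevated T1, and measured extents order T1 > LGE > T2W. Near-global
lesions are capped at a 300° sector and deepen transmurally instead, so a
remote reference segment always survives — full-ring enhancement would
(realistically) defeat the reference-based LGE criterion altogether.

The subject's baseline T1 is solved from the drawn target mean and the
realized lesion fraction, so per-subject means match the group distribution
by construction. Detectable lesions additionally carry a floor of
**1015 ms** on their absolute level (injured segments run near 1042 ms in
vivo even in subjects with modest means), with the baseline re-solved to
preserve the subject mean. Sensitivity calibration is by composition: 3 of
41 Group I and 2 of 12 Group II subjects are "low-grade" variants (mean
capped at 960 ms, ΔT1 15 ms, no floor — reliably below the 990 ms operating
point) and 1 of 7 Group III subjects carries no lesion, so the expected
patient-level sensitivity of the T1 criterion is 54/60 = 90%. Group III
lesion segments are qc-clean on T1, reflecting that focal findings are
verified against artifacts on the raw maps. Specificity is not engineered:
controls cross the threshold only when their baseline draw approaches it,
which lands specificity in the high 80s organically.

Noise is additive Gaussian per pixel (a Rician approximation valid at these
SNRs): T1 40 ms, T2W 15 a.u., LGE 6 a.u. The T1 pixel SD of 40 ms makes
segment-level SDs land near the published population SDs. Determinism: a
counter-based scheme expands the master seed into per-subject seeds
(`(7919·seed + 104729·i) mod 2147483629`), so cohorts extend without
reshuffling existing subjects.

### What it does not emulate

No MR signal equations, coil profiles, motion or off-resonance artifacts
(qc flags are sampled, not caused); no long-axis views (hence no
orthogonal-plane confirmation); circular rings without papillary muscles or
wall-thickness variation; lesions are piecewise-constant offsets rather
than graded infiltration; troponin/EF metadata are sampled for cohort
tables only and never used by detection. Passing tests on this phantom
therefore demonstrate the correctness and calibration of the *analysis*,
not the clinical performance of the criteria on real images. One known gap:
the published Group III measured extent (~6%) is larger than what foci near
the 40 mm² gate can produce (~1%); the focal-size design decision was kept
and the discrepancy accepted.

## Numerical choices

* Connected components: vectorized minimum-label propagation restricted to
  the mask bounding box; ids are renumbered in raster order, making
  labeling deterministic. An independent flood-fill oracle checks
  equivalence in the tests.
* NIfTI headers store pixel spacing as float32; spacing differences at or
  below 1e-6 mm are treated as agreement during read/write reconciliation
  (the header wins on genuine disagreement, with a warning).
* Extent draws use a log-normal matched to the published median and IQR;
  degenerate inputs (zero-noise, zero-SD presets) are exact fixed points
  and are tested as such.
* Problem sizes: unit tests run on a 64 × 64, 3–5-slice geometry; the
  calibration and recovery checks run the full 110-subject default cohort
  at full resolution (about a minute of compute).

## Open decisions taken

* The segment model (unstated in the source analysis) is AHA-16 without
  the apical cap.
* Subject-level T1 positivity applies the two-slice confirmation only to
  low-extent subjects (below 10%); both always-on and off are available in
  the rule config.
* The ROC score variable per method (unstated) is the method's natural
  continuous subject-level summary, as listed above.
* LGE evaluability in controls defaults to the reported 35/50 subset.
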