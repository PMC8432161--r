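---
title: "Methods: surface-based lesion detection and sEEG planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based lesion detection and sEEG planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionplan)
```

# The model and its assumptions

`lesionplan` treats focal cortical dysplasia detection as per-vertex
classification on a cortical surface mesh. The assumptions, in order of
consequence:

* **Vertex correspondence.** All subjects' features live on a bilaterally
  symmetric template where vertex *i* of the left hemisphere is
  homologous to vertex *i* of the right. On real data this correspondence
  comes from spherical registration (out of scope here; a per-vertex
  index table is accepted as input); on synthetic data the meshes are
  built vertex-paired, so the correspondence is the identity.
  Classification runs on template vertices — one of the open design
  points; running on subject vertices mapped back would only permute
  rows.
* **Lesions are focal and unilateral.** The training sampler takes its
  healthy examples from the hemisphere contralateral to each patient's
  mask and refuses bilateral masks; the asymmetry channels assume a
  roughly symmetric healthy brain.
* **Lesions are larger than the smoothing kernels.** The 10/20 mm FWHM
  kernels stabilize per-vertex estimates; clinical lesion areas (median
  1185 mm², MAD 789 mm²) are an order of magnitude larger, so smoothing
  attenuates noise more than signal.
* **Control features are locally Gaussian enough** for per-vertex
  z-scores against the control mean/sd to be interpretable.

## Processing chain

smooth → within-subject z → between-subject z → asymmetry, in that fixed
order. Within-subject z-scoring pools both hemispheres of a subject and
uses the population (1/n) standard deviation; between-subject statistics
pool both hemispheres of every control (two samples per template vertex
per control, sample sd). The design matrix has 22 columns: the 11
feature channels in `FEATURE_CHANNELS` order, then their 11 asymmetry
counterparts. Whether sulcal depth and mean curvature should also be
z-scored is ambiguous in the source method's description; the default
z-scores every channel, and `preprocess_features(zscore_all = FALSE)`
restricts normalization to the channels conventionally described as
normalized.

## Classifier

One hidden layer of logistic units, logistic output, cross-entropy loss,
full-batch Adam (step 0.05), iteration cap 500, inputs standardized
internally, all randomness (initial weights, training-set sampling)
derived from an explicit seed. The hidden size equals the smallest
number of principal components of the control feature matrix explaining
strictly more than 99% of variance, capped at the matrix rank — an
architecture choice that avoids searching (and overfitting)
alternatives. The exact optimizer of the original MATLAB toolbox is not
reproducible from its description, so reproducibility here is defined by
the seed, not by matching any historical weights. Scores are
probabilities in [0, 1] (the open question of probabilities vs logits is
resolved to probabilities). A single global Youden threshold is fitted
on pooled training vertices, not per structure.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| smoothing FWHM (thickness, contrast, FLAIR) | 10 | mm | per-vertex stability; lesion scale >> kernel |
| smoothing FWHM (intrinsic curvature) | 20 | mm | folding abnormality stable across adjacent gyri |
| PCA variance threshold (hidden size) | 0.99 | — | fixes architecture from the control cohort |
| Youden threshold grid | 0.01 steps in (0, 1) | score | "a range of values", made concrete |
| minimum cluster area | 50 | mm² | smaller suprathreshold islands are noise |
| colocalization threshold | 10 (strict `<`) | mm | sEEG sampling radius vs electrode-collision risk |
| planning top-k | 3 | clusters | only the strongest candidates justify electrodes |
| power: cohorts | 1000 | simulations | Monte-Carlo confidence estimate |
| power: target, confidence | 10, 0.90 | — | prospective-study design point |
| contribution probability | concordant focal / all patients | — | the estimator is not pinned by the source; it is a config field, defaulting to the cohort's concordant fraction |

# The synthetic world

The generator emulates exactly what the classifier consumes, not cortical
geometry:

* **Meshes** are mirror-symmetric deformed icospheres (subdivision 4 by
  default: 2562 vertices/hemisphere, radius 50 mm, surface area
  ~33,000 mm² — roughly a third of a real hemisphere). There is no
  folding, so sulcal depth, curvature and intrinsic curvature are
  generated as smooth spatial fields rather than recomputed from
  geometry: the classifier consumes channels, and folding realism is out
  of scope.
* **Controls**: channel = smooth mean field (identical across subjects,
  mirror-symmetric across hemispheres) + i.i.d. Gaussian vertex noise of
  the channel's stated sd, independent per hemisphere.
* **Lesions**: a patch around a random center vertex, area drawn from a
  lognormal with median 1185 mm² scaled by (mesh area / 90,000 mm²
  reference hemisphere) and log-sd 1.15 (calibrating the median absolute
  deviation to the clinical 789/1185 ratio), truncated below at a
  300 mm²-equivalent and above at 20% of the hemisphere. Channel offsets
  are `effect × control sd` with a flat top to 90% of the radius and a
  cosine roll-off to the rim; the default effect magnitude is 3 sd on
  thickness (+), gray-white contrast (−, blurred junction), all six
  FLAIR depths (+) and intrinsic curvature (+). Patch membership uses
  straight-line distance, which on these near-spherical meshes matches
  the true geodesic to <1% at lesion radii, whereas shortest-edge-path
  distances overestimate by up to ~15% and would shrink the patch area
  well outside its nominal π r².
* **Electrodes**: straight trajectories entering radially, deepest
  contact at the target, 8 contacts at 3.5 mm; contacts within 10 mm of
  the lesion patch are labelled SOZ, within 20 mm irritative, the rest
  uninvolved. One electrode per patient targets the lesion center; the
  others target random same-hemisphere vertices.

What a green synthetic test establishes: that the implementation of each
stage is correct and that the pipeline recovers planted lesions of the
stated effect size and extent with the stated specificity. What it does
**not** establish: clinical sensitivity/specificity. Real cortical
features are spatially autocorrelated, non-Gaussian, and confounded by
age and scanner; real lesions are subtler than 3 sd and live in folded
geometry. The clinical headline numbers (74% sensitivity on 34
MRI-positive patients, 100% specificity on 20 controls) are therefore
not reproducible at desk scale and are replaced by the property-based
acceptance criteria in `tests/testthat/test-acceptance.R`.

# Numerical choices

* **Geodesic distances** are Dijkstra shortest paths with Euclidean edge
  weights on the mesh edge graph *augmented with the cross-chords of
  every two-ring neighbourhood*. Pure edge-path distances overestimate
  true geodesics by up to ~15% in directions between edge orientations;
  measured against an exact-geodesic oracle on a planar grid, the
  impulse-response RMS error is ~10.7% with plain edges and ~1% with the
  augmentation, which is what lets the smoothing oracle test hold at 5%.
* **Kernel normalization.** The truncated (3σ) Gaussian kernel is
  Sinkhorn-balanced against the vertex-area measure, yielding an
  operator that preserves constants exactly *and* conserves the
  area-weighted sum of any overlay to machine precision; plain row
  normalization would only conserve mass approximately. σ = FWHM /
  (2√(2 ln 2)).
* **Vertex areas**: one third of incident triangle areas, so they sum
  exactly to the mesh area; degenerate triangles contribute nothing and
  warn. Intrinsic curvature is the angle deficit over vertex area
  (border vertices use a π deficit), so closed meshes satisfy
  Gauss–Bonnet exactly.
* **sd floor**: between-subject z-scoring floors the per-vertex control
  sd at 1e-6 of the channel's global sd; a within-subject sd below the
  floor yields zeros with a warning.
* **Youden convention**: a vertex with score ≥ t is called lesional when
  scanning thresholds; ties in J break toward the *highest* threshold
  (favoring specificity). Cluster extraction uses strictly score > t —
  with continuous scores the disagreement at exactly t has measure zero.
* **Cluster tie-breaks**: equal mean predictions rank by larger area,
  then left before right, then lowest vertex id — total and
  permutation-invariant.
* **Colocalization** is strict (`< 10 mm`), the stricter of the two
  phrasings in the source material; distances are vertex-to-point (no
  point-to-triangle projection: vertex spacing is far below the 10 mm
  threshold), measured on the mid-thickness surface when white and gray
  are both available.
* **Percentages** round half away from zero (13/21 → 62%, 7/8 → 88%;
  the occasionally quoted 86% for 7/8 is an arithmetic slip and is not
  reproduced). A direct tally of the packaged table gives 11/16
  seizure-free focal surgical patients, not the printed 10/16; the
  computed value is reported.
* **Monte-Carlo power search** draws fresh seeded binomial cohorts per
  candidate size and returns the first size whose success fraction
  reaches the confidence level. At p = 13/34 the exact tail at n = 34 is
  0.893 — within one Monte-Carlo standard error (±0.009 at 1000 cohorts)
  of 0.90 — so seeded runs legitimately return 34–36; the exact tail
  path (`method = "exact"`) is deterministic at 35 and serves as the
  oracle.

# Known limitations

* Spherical registration, cortical reconstruction and contact
  localization are inputs, not computed; their errors are not modelled.
* The synthetic generator draws vertex noise i.i.d.; real control
  cohorts have spatially correlated residuals, so synthetic specificity
  at a given threshold is optimistic.
* Mesial temporal structures are not represented: the classifier is
  cortical, and patients with mesial temporal seizure onset are
  `not-applicable` for concordance by construction.
* The network is intentionally shallow; ensembles and graph
  convolutional variants are out of scope.
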