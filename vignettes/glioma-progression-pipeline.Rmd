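---
title: "Multifocal glioma as a natural progression contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifocal glioma as a natural progression contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaconn)
```

## The design this package implements

A multifocal glioma patient carries two spatially distinct lesions of one
clonal origin. Treating the larger lesion as the later progression stage
turns a single resting-state scan into a paired design: every functional
metric can be compared larger-vs-smaller within patient. Two safeguards
address the obvious confound that the two lesions sit in different places:

1. **Mirror controls.** Each tumor mask reflected across the midsagittal
   plane provides a location-matched reference region in (radiologically)
   healthy cortex. Every analysis is run twice — on the raw lesion values
   and on lesion-minus-control differences — and a finding counts as
   positive only when *both* versions beat the Bonferroni family
   threshold (the *dual criterion*).
2. **Mixed-model adjustment.** Dual-positive metrics are refit with
   `value ~ group + volume + tSNR + n_networks + (1 | subject)` so that
   lesion volume, data quality and the number of resting-state networks a
   lesion straddles cannot masquerade as a group effect.

The statistical families are defined per results section: 3 activity
metrics × 2 approaches (m = 6), 3 connectivity summaries × 2 (m = 6), and
4 topology metrics × 2 (m = 8). At α = 0.05 the first two families give
the threshold 0.05/6 = 0.00833, reported to three decimals as 0.008.

## The synthetic cohort generator

No public dataset exists for this design, so the package ships a
generator whose defaults encode the study conditions it emulates: 24
subjects, TR 1.6 s, 500 volumes, a midline-symmetric parcellation
(default 400 parcels, 7 bilateral network labels), and paired spheroidal
lesions whose volume means keep the 78.6 : 24.9 larger-to-smaller ratio
of the clinical cohort (volumes live in voxels; only the ratio and the
coefficients of variation, 33.7/78.6 and 15.3/24.9, carry over, with the
larger mean set to 3% of brain voxels).

Latent signals are band-limited Gaussian processes drawn in the frequency
domain (all power inside 0.01–0.1 Hz by construction — chosen so ALFF and
fALFF have a known band structure). Each parcel's signal is

  x_j = a·c + b·g_net(j) + sqrt(1 − a² − b²)·e_j,

a shared cortical factor `c`, a within-network factor, and a
parcel-specific remainder. Each tumor's latent signal couples to the
shared factor with strength κ:

  t_i = κ_i·c + sqrt(1 − κ_i²)·u_i,

so the expected tumor–parcel correlation is κ_i·a, monotone in κ, and the
default gap (κ_larger = 0.6, κ_smaller = 0.2) is the ground-truth effect
the pipeline should recover. Voxels inherit their parcel's (or tumor's)
latent signal plus a 100-unit baseline, a small common WM/CSF leakage
term (so nuisance regression has something real to remove), and AR(1)
noise (ρ = 0.3, unit SD). Lesions are placed off-midline in one
hemisphere with bounded retries; their exact x-mirrors are the controls.
One master seed hashes into per-subject seeds, so cohorts are
bit-reproducible and subjects are order-independent.

**Choice of loadings.** The defaults a² = 0.09 and b² = 0.15 were fixed
by a Monte-Carlo calibration of the generator before the validation
experiments were frozen. The binding constraint is the graph stage: at
sparsity 0.15 the edge cutoff falls where the parcel-pair weight
distribution and the tumor-parcel weights overlap. If within-network
correlations are made much stronger than cross-network ones (e.g.
a² = 0.2, b² = 0.25), within-network pairs alone saturate the edge
budget, the tumor node cannot win edges even at κ = 0.6, and no
topological group difference can exist — a degenerate regime in which
sensitivity criteria are unmeetable by construction. The frozen values
give within-network r ≈ 0.24 against cross-network r ≈ 0.09 and leave
the cutoff in the bulk of the distribution, where the tumor node's edge
count responds to κ.

**What the generator does not emulate.** No hemodynamic response, no
scanner drift or spike artifacts, no multi-site effects, spheroidal
rather than irregular lesions, and spatially independent parcel
signals. Passing tests therefore certify the *pipeline logic* — metric
definitions, exclusion handling, statistical gating — not robustness to
real-scanner noise. One consequence of the independent-parcel choice is
worth knowing: the mean series of a *larger* cortical region is a purer
copy of the shared factor (idiosyncratic parts average out), so
mirror-control FC and degree grow with region size. The
control-subtracted comparison alone is thus anti-conservative under the
null — precisely why the dual criterion demands the raw comparison too,
which keeps the familywise false-positive rate of a 3-metric family at
or below α/2.

## Preprocessing and metric definitions

* **Order:** trim (5 volumes) → nuisance regression (intercept + 6
  motion + WM + CSF, least squares, pseudoinverse on rank deficiency) →
  5 mm FWHM Gaussian smoothing → ideal FFT band-pass (0.01–0.1 Hz,
  DC removed). ALFF/fALFF are computed on the *unfiltered* (but
  regressed and smoothed) stage — band-passing first would force
  fALFF → 1 — while ReHo uses the band-passed run. The pipeline fixes
  this order once; it is exposed stepwise for sensitivity analyses.
* **FD** uses the Power formulation with a 50 mm rotation radius;
  **DVARS** is the unstandardized RMS frame derivative (the exclusion
  threshold of 20 presumes native units); exclusion requires breaching
  *both* thresholds (the conjunctive reading; `rule = "or"` is
  available, and one-sided breaches warn).
* **ALFF** sums one-sided periodogram power over band bins
  (2|X_k|²/T²), so a sinusoid of amplitude A contributes its variance
  A²/2; a raw periodogram (no Welch averaging) keeps the estimator
  deterministic and oracle-checkable. **fALFF** divides by 0–0.25 Hz
  power with the DC bin excluded; 0.25 Hz is kept even though Nyquist at
  TR 1.6 s is 0.3125 Hz. **ReHo** is Kendall's W with average ranks on
  ties and no tie correction; edge voxels use their in-mask neighbor
  subset (K < 27) rather than zero padding; K < 2 yields `NA`.
* **All SDs** use the sample (n − 1) denominator; z-scoring of metric
  maps is within the brain mask.

## Connectivity and graphs

Tumor masks are subtracted from the parcellation before parcel series
are formed; a control seed additionally excludes its own voxels
(symmetric treatment — the tumor and control code path is identical).
Fisher z caps |r| at 1 − 1e-15 to stay finite; two-sided p-values come
from t = r√((T−2)/(1−r²)). Bonferroni parcel selection divides α by the
*usable* parcel count by default (parcels emptied by exclusion carry
`NA` sentinels and are never selected); a fixed denominator (e.g. 400)
is available. Centroid distances are world-mm via the affine.

Graphs are built per seed over P parcels + 1 lesion node: the
K = round(s·N(N−1)/2) largest *signed* z weights become unweighted
edges (strong positive coupling first; absolute ranking is a config
option — negative-edge handling is genuinely underdetermined), ties
broken by lexicographic pair order. The sweep examines s = 0.15–0.40 in
0.05 steps, validating levels by no-isolates and small-world σ > 1.1;
σ compares clustering and path length to degree-preserving rewirings
(10 swap attempts per edge, 10 references, seeded). Statistics are
reported at s = 0.15 with the sweep retained for stability checks.
Closeness uses the Wasserman–Faust component-scaled form so
disconnected graphs stay well-defined; σ falls back to the largest
component with a warning.

## Statistical workflow details

Shapiro–Wilk at 0.05 on pair differences gates paired t vs Wilcoxon.
The Wilcoxon branch uses the normal approximation with continuity and
tie corrections for n ≥ 10 and the exact distribution below; its effect
size is r = |Z|/√n with n the pair count. All-zero differences return
the degenerate no-effect result (p = 1); a nonzero constant difference
is an error. The LMM is REML with Wald z tests (no df correction);
singular fits are flagged and refit by ML; covariates are standardized
before fitting (the group coefficient is unaffected).

## The progression-gene filter

The microscale module consumes any staged DE table with two log2FC
columns (mid-vs-early, end-vs-mid). Benjamini–Hochberg runs per
transition; the filter keeps genes with log2FC ≥ 0.25 *and* q < 0.05 in
both transitions. Although the threshold is stated on |log2FC|, the
selection targets progressively *up*regulated genes, so the default
demands positive fold changes (`signed = FALSE` restores the literal
absolute-value reading). The packaged 42-gene table prints fold changes
only; its q columns are 0.01 placeholders so the worked example
isolates the fold-change logic — they are not measured values.

## Validation experiments and problem sizes

Two Monte-Carlo experiments ship as package functions:

```r
fc_null_calibration(n_replicates = 200)  # kappa-equal null, FPR <= alpha
coupling_recovery(n_replicates = 50)     # 0.4 kappa gap, recovery rates
```

Both default to 24-subject cohorts on a 40-parcel atlas over small grids
(14×14×10 and 16×16×10) with the full 500-volume runs — cohort sizes
chosen so hundreds of replicates complete on a single CPU while keeping
every downstream code path identical to a full-size analysis. The null
experiment sets both couplings to zero: with equal nonzero coupling the
larger lesion's lower ROI-averaging noise genuinely raises its measured
FC (an attenuation artifact that is a real volume confound, not a code
false positive — it is exactly what the LMM's volume covariate absorbs).

## Known limitations

* The mirror-control size artifact above means control-subtracted
  analyses should never be interpreted alone; the package only reports
  them inside the dual criterion.
* Graph metrics are binary-graph definitions; weighted variants are out
  of scope.
* The Bonferroni denominator for parcel selection (usable vs. full
  count) and the negative-edge policy are exposed as configuration
  because the underlying convention is not uniquely determined; defaults
  follow the conservative choice (usable count, signed ranking).
* The simulator's spatial independence between parcels understates
  spatial autocorrelation in real BOLD; absolute FC and degree levels
  should not be compared to patient data, only contrasts within the
  simulated design.
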