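---
title: "Methods: multi-parameter quantification of flow-chamber thrombus formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-parameter quantification of flow-chamber thrombus formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombomap)
```

## The assay and its parameters

Whole anticoagulated blood is perfused over protein microspots in a
parallel-plate flow chamber (wall shear rate 1000 or 1700 s⁻¹):
collagen-I (*M1*, engaging GPIb/GPVI/α2β1), rhodocytin + laminin + VWF-binding
peptide (*M2*, CLEC2 and α6β1), and laminin + VWF-BP (*M3*, α6β1). After
perfusion, thrombi are imaged in brightfield and in up to three fluorescence
channels (annexin A5 for phosphatidylserine exposure, anti-CD62P for granule
secretion, JON/A for activated integrin αIIbβ3).

Eight parameters summarize each image set: platelet surface area coverage
*P1* and aggregate coverage *P2* (%SAC, brightfield), visual thrombus
morphology *P3* (0–5), multilayer *P4* (0–3) and contraction *P5* (0–3)
scores assigned against standard images, and the three activation %SACs
*P6–P8*. `thrombomap` computes *P1*, *P2* and *P6–P8* from pixels and
ingests *P3–P5* from a scores table (it does not attempt to automate visual
scoring). Values from three images per experiment are averaged; strains
enter the comparison only with n ≥ 3 animals (modified) or n ≥ 4
(wild-type dataset).

## Image quantification

**Background correction.** Uneven illumination is removed with a
frequency-domain Gaussian high-pass,
$$H(f) = 1 - \exp(-f^2 N^2 / 2),$$
with $f$ the radial spatial frequency (cycles/pixel) and $N$ the
large-structure scale (60 px brightfield, 65 px fluorescence). This
parametrization makes the filter's contract concrete: a background sinusoid
of period $3N$ or longer survives with under 10 % of its amplitude, while a
compact object a few pixels wide keeps over 70 % of its peak contrast. We
deliberately anchor the Gaussian width to this behaviour (spatial sigma
$N/2\pi$) rather than to $N/2$, which would leave a third of a period-200
background wave in place — the filter is supposed to flatten background, and
this is the width at which it demonstrably does. Small-structure
suppression is available (`bandpass_small_px`) but off by default: the fine
structure *is* the platelet signal. The zero-frequency term is restored by
re-offsetting the output to the input mean, and intensities are clipped to
the bit-depth range only at operator boundaries; all intermediate arithmetic
is floating point.

**Morphology.** Striping from enhanced-contrast CCD acquisition is
suppressed by a grayscale closing with a diamond (radius 4 px), a closing
with a disc (2 px), and a dilation with a small disc (1 px). Radii are
configurable; the defaults bridge 1–2 px stripes at 60×/63× magnification
and must satisfy large > medium > small ≥ 1. The operators are delegated to
EBImage after verifying bit-identical agreement with a brute-force sliding
min/max oracle, including the footprint-restricted border convention; the
test suite keeps that oracle comparison in place.

**Thresholding and the coverage re-measurement.** With `threshold = "auto"`
the threshold is Otsu's criterion on the processed image, and the resolved
value is always recorded — manual thresholds were the original workflow's
main reproducibility hazard, so every resolved threshold and scaling anchor
is logged in the outputs. Two numerical guards matter:

* *Minimum-contrast guard.* Otsu on a featureless image splits the noise in
  half. When the two class means are separated by less than 5 % of the
  dynamic range, the image is declared background-only and the mask is
  empty.
* *Coverage re-measurement.* Closings and dilations are extensive: they
  bridge narrow gaps between adjacent platelets and add a one-radius halo,
  which at realistic monolayer densities inflates %SAC by several points.
  The cleaned image is therefore used for *detection* only; the mask is
  re-measured against the bandpass-corrected intensities with the detected
  threshold shifted by the morphology-induced background lift (median raise
  of background pixels) and refined to the flattest point of the
  coverage-vs-threshold curve — the intensity gap between background and
  platelet classes, where the estimate is insensitive to the exact cut. In
  the packaged benchmark this keeps recovery within ±1 %SAC point even at
  the largest artifact amplitudes the generator produces, where direct
  thresholding of the uncorrected image errs by an order of magnitude more.

**Aggregates (P2).** The original workflow never states how aggregates are
separated from adhered single platelets in brightfield, so the rule here is
our own, stated openly: a connected foreground component is an aggregate
when (i) its area is at least `min_area_px` (default 80 px, larger than any
single spread platelet at this magnification) and (ii) at least 30 % of its
pixels pass a second, more stringent intensity threshold capturing
multilayered material — by default a second Otsu split computed within the
platelet foreground, subject to the same minimum-contrast guard. An
explicit stringent threshold laxer than the primary one is a configuration
error. By construction P2 ≤ P1.

**Brightfield polarity.** Depending on contrast enhancement platelets may
be brighter or darker than background; `polarity` is `auto` (the minority
class of the Otsu split), `bright_objects`, or `dark_objects`. The
morphology sequence as published is meaningful for bright structures; for
dark-object material the same chain is applied on the inverted axis.

## Comparative statistics

**Scaling.** Per (surface, parameter) column, strain means are scaled by
$10 \, x / \max(x)$: the observed maximum maps to 10 and the lower anchor
is fixed at zero because every published parameter range starts at 0.
Anchors are computed jointly across all wild-type and modified strains of a
run, are saved with the outputs, and can be supplied to scale new data
consistently. Scaling is idempotent given the same anchors; an all-zero
column warns and scales to zero.

**Subtraction heatmap and relevance filter.** Each modified strain is
paired to the wild-type sharing its database id; the scaled wild-type mean
is subtracted. A difference is *relevant* when |Δ| exceeds the composite
SD, for which the published description ("composite mean ± SD") admits more
than one reading. We define it as the root-mean-square of the two group SDs
on the scaled axis, `sqrt((sd_mod² + sd_wt²)/2)` — symmetric in the groups
and equal to either SD when they agree — and expose `composite = "max"` as
the conservative alternative. SDs are scaled *after* scaling the means
(with the same anchors), i.e. the filter operates entirely on the 0–10
axis. Irrelevant cells are reported as unchanged (zero in the filtered
matrix) and excluded from effect sums. Under the generator's study
conditions (replicate SD 1 scaled unit, n = 4/group) this rule flags a null
cell about 16–21 % of the time and a |Δ| ≥ 3 effect with correct sign over
99 % of the time; both rates are recomputed by `scripts/acceptance.R`.

**Correlation.** Kendall's tau-b with the standard tie terms is implemented
directly; p-values use the tie-corrected variance of C − D, or the exact
null distribution (via `stats::cor.test`) for n ≤ 10 without ties. The
implementation is validated against exhaustive pair enumeration and against
`stats::cor`. All-tied inputs return an explicit undefined marker rather
than a number. The published correlation range for the original 60-strain
cohort is not reproducible without the undeposited per-strain raw data; the
machinery is validated by oracle properties instead.

**Rankings, clustering, concordance.** Rows order by ascending filtered
ΣP2–5 (thrombus signature) or P1 delta, ties broken alphabetically for
determinism; `rank_by = "none"` returns the leaf order of complete-linkage
hierarchical clustering on Euclidean distances (missing cells
pairwise-excluded), our choice where the original analysis names only "R".
For in vitro / in vivo concordance each strain is classified by the sign of
its filtered ΣP1–5 at the chosen surface and cross-tabulated against the
categorical thrombosis and bleeding labels of the packaged strain table;
"n.d." is tabulated separately. P-values are reported raw, without
multiple-testing correction, matching the original analysis.

## Network analysis

The module consumes a pre-exported STRING-style TSV (`node1`, `node2`,
`combined_score`; integer 0–1000 and float 0–1 dialects auto-detected);
live database queries and shell-interactor expansion are out of scope, as
is pathway enrichment (those results depend on the external annotation
database version). Edges below the confidence cutoff (default 0.40,
"medium") are dropped; duplicates collapse to the highest confidence.

MCODE is implemented in full: vertices are weighted by the core number of
their closed neighborhood times the density of that highest k-core
(vertices under the degree cutoff 2 score zero); complexes grow from the
highest-weighted unvisited seed, admitting neighbors whose weight is at
least `seed_weight × (1 − node_score_cutoff)` up to `max_depth`;
post-processing applies fluff, then the haircut (2-core), then discards
complexes without a `k_core`-core. Cluster score is density × node count,
and every returned cluster's score and core membership are re-derived
independently in the tests. Tie-breaks are lexicographic on vertex names
throughout, so the output is deterministic and invariant under relabeling.

One default departs from the classic parameter sheet: **fluff is on**
(density threshold 0.1), applied before the haircut. With fluff off, a
dense module's boundary members — vertices whose neighborhood weight falls
just below the seed-relative cutoff — are permanently lost to their
complex; on planted two-block benchmarks this halves recovery (≈52 % vs
≈99 % of seeds recovering ≥7/8 of both blocks). Fluff re-admits those
members, and running the haircut afterwards removes any fluffed-in vertex
that attaches by a single edge, so purity is preserved. Blocks bridged by
several confident cross edges can still merge into one complex; that is
inherent to seed-relative expansion, and the merged complex still contains
both blocks' members.

## What the generators emulate — and what they do not

`generate_brightfield()` renders bright platelet discs (radius 2–4 px,
contrast +0.22 of dynamic range over a 0.35 background) and multi-intensity
aggregate blobs (+0.40/+0.50, radius ~14 px), then applies exactly the
artifacts the pipeline targets: periodic vertical striping (default
amplitude 10 % of range, period 7 px), a linear illumination gradient
(default 15 % peak-to-peak), and additive Gaussian noise (default SD 2 %).
Truth masks are exact by construction. `generate_fluorescence()` stains an
exact pixel quota of the platelet mask in contiguous patches.
`generate_strain_table()` draws replicate values from truncated normals on
the 0–10 scaled axis (converted to each parameter's published raw range),
with between-dataset baseline CVs of 24 % (P1–P2) and 11 % (P3–P5),
matching the consistency bands reported for wild-type cohorts, and
replicate SD 1 scaled unit at n = 4 per group. Planted effects are defined
on the generator's own axis (range maximum = 10) and returned with the
anchors that reproduce that axis.

These generators exercise the pipeline's failure modes, not biology: no
flow or adhesion physics, no platelet shape variation or focus drift, discs
instead of spread platelets, stationary Gaussian noise instead of
photon/readout statistics, and sinusoidal striping instead of scan-line
artifacts. Passing the ground-truth benchmarks therefore demonstrates that
the operators do what they claim under the documented artifact model — not
that the pipeline is validated on real micrographs.

## Numerical choices and degenerate inputs

* Intermediate images are floating point; clipping/rounding happens only at
  operator outputs. Coordinates are row-major, origin top-left.
* Image dimensions must be ≥ 8 (≥ 64 recommended; the bandpass additionally
  requires the filter scale to fit inside the image).
* Visual scores are validated in 0.5-step increments against their ranges
  at ingestion; P2 > P1 is rejected.
* Sample SD (n − 1) is used throughout; the original text does not state
  the estimator.
* A parameter present in only a subset of an experiment's images is
  averaged over the available images with a warning — partial fluorescence
  panels are common — and stays missing only when absent everywhere.
* The thrombus signature is undefined (NA), never zero, when any of scaled
  P2–P5 is missing. ΣP2–5 is the canonical sum (0–40); the /4 normalized
  mean is an attribute.
* Truncated-normal draws use inverse-CDF sampling, so all generators are
  bit-reproducible under a seed.
* Wild-type CV with a zero mean, all-tied correlation inputs, and all-zero
  scaling columns return explicit markers (NA + warning) rather than
  numbers.

## Problem sizes in the packaged checks

The test suite and `scripts/acceptance.R` run at sizes chosen to
characterize the estimators tightly while staying quick on one CPU: 50
synthetic 256×256 images for %SAC recovery (artifacts at the documented
amplitude limits, content randomized), 500 simulated strain tables (4
wild-type datasets, 8 modified strains, n = 4/group) for effect-detection
rates, 100 planted-partition graphs (two 8-node blocks, p_in 0.9, p_out
0.05) for MCODE recovery, and exhaustive oracles at n ≤ 8 (pair counting)
and 64×64 (sliding min/max). The full suite completes in about a minute;
the acceptance script in about half a minute.

## Known limitations

* The aggregate (P2) definition is an operational choice; other labs'
  manual gating may differ systematically.
* Relevance filtering inherits the published rule's character: it is a
  per-cell SD band, not a hypothesis test, and its false-flag rate (~16 %
  per cell under normal noise) is a property, not a bug.
* Scaling to the observed maximum makes deltas depend on the cohort
  composition; supplying fixed anchors is the remedy when comparing across
  runs.
* MCODE's seed-relative expansion can merge modules linked by confident
  cross edges (see above).
* Visual scores P3–P5 and their inter-observer variability are taken as
  given; no agreement statistics are computed.
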