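---
title: "neuroquant: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroquant: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

This vignette records the scientific conventions the package implements and
the choices made where more than one reasonable convention existed. Nothing
here asserts an empirical result that the test suite does not itself
compute.

## 1. The fluorescence index

For a single-channel image with integer intensities, the channel index is

$$\mathrm{index} = \sum_b \mathrm{count}(b)\, b^2,$$

the sum over histogram bins $b$ (one bin per integer intensity level, 256
or 65,536) of bin count times squared brightness. This is identically the
per-pixel sum of squared intensities; squaring up-weights bright stained
structures relative to dim background, so the index responds to marker
abundance rather than to field area. The per-field statistic is the ratio
of the marker-channel index to the DAPI nuclei-channel index, which
normalizes for cell density and exposure common to both channels of a
field.

Conventions, and why:

* **Raw intensities, exact integer arithmetic.** The index operates on
  stored intensity values with no rescaling to $[0,1]$; both channels of a
  pair must share a bit depth so the ratio is scale-consistent. Histogram
  counts are integers and bin values at most $65{,}535^2$, so a double
  accumulator is exact (everything stays far below $2^{53}$); the test
  suite asserts *exact* equality with a per-pixel oracle at both bit
  depths.
* **Saturation.** Saturated pixels are included in the index (excluding
  them would bias bright fields downward), but a saturation fraction above
  1% attaches a quality flag, since a clipped histogram understates true
  brightness.
* **No background subtraction.** The secondary-antibody-only negative
  control *is* the background treatment: detection is the one-sided Welch
  test of stained ratios exceeding matched control ratios. One-sided is
  appropriate because specific staining can only add signal; condition
  contrasts (e.g. passage 5 vs 25) use the two-sided test because a marker
  can move either way.
* **Replicate structure.** Technical replicates are averaged within
  biological replicate before any group test, so the test's *n* counts
  biological units and pseudo-replication is avoided.
* **Color images are refused.** Channel identity is semantic (red/green =
  marker, blue = DAPI); an implicit grayscale conversion would silently mix
  channels, so callers must extract a named channel.
* **Degenerate comparisons.** Two groups that are both constant and equal
  yield $t = 0$, $p = 1$ rather than an error; blank control fields make
  this case real.

The Welch statistic, Satterthwaite degrees of freedom and $p$-values are
delegated to `stats::t.test()`; the suite cross-checks them against the
textbook formulas coded independently.

## 2. Image simulator: what it emulates, what it does not

`simulate_image_pair()` renders a stated world, not a tuned one:

* Nuclei are isotropic Gaussian blobs (default $\sigma = 5$ px, peak 3,000
  intensity units) at centers rejected closer than $2\sigma$ — the
  simplest morphology that gives the index a cell-count signal while
  approximating non-overlapping nuclei.
* Marker-positive cells (a `positive_fraction` of all cells, rounded)
  reuse nucleus centers with a $2\times$ larger footprint, approximating
  cytoplasmic staining; `control = TRUE` zeroes the marker amplitude,
  modelling staining without the primary antibody.
* The camera model is standard: optional Poisson shot noise on the
  noiseless signal, additive Gaussian read noise (default sd 20), then
  clipping and quantization to bit depth.
* Defaults — 16-bit, 512×512, 150 cells, background 200 — are stated
  choices for a plausible widefield acquisition, not values inferred from
  any particular instrument.

Not emulated: realistic optics (PSF, illumination falloff), autofluorescence
structure, focal drift, or segmentation-level ground truth beyond center
labels. A green ordering test (mean ratio increasing in the planted
positive fraction) therefore establishes that the index responds
monotonically to marker abundance under this noise model — not that it is
robust to uneven illumination, which real use should control upstream.

Seeding: every generator is a pure function of its parameters and seed; a
fixture set derives per-field child seeds from one root seed by a fixed
counter scheme, so any single field can be regenerated independently.

## 3. qPCR: −ΔΔCt and reference stability

With perfect amplification efficiency (2.00 per cycle; the package applies
no standard-curve correction), one threshold cycle equals one doubling of
template. Technical replicates are averaged to one Ct per (gene, sample);
then per sample $\Delta C_t = C_t^{target} - \overline{C_t^{refs}}$ using
the arithmetic mean of reference Ct values — equivalent to the geometric
mean of the linear quantities $2^{-C_t}$, the geNorm normalization-factor
convention; then $\Delta\Delta C_t$ subtracts the calibrator-group mean,
and results are reported as $-\Delta\Delta C_t$ plus fold change
$2^{-\Delta\Delta C_t}$. Both the technical-replicate SD (the error-bar
convention) and the biological-replicate SD are kept.

The stability measure for a candidate reference $j$ is
$M_j = \mathrm{mean}_{k \neq j}\; \mathrm{sd}_s\!\left(\log_2 \frac{Q_{j,s}}{Q_{k,s}}\right)$
over samples $s$, with $Q = 2^{-C_t}$ — so the implementation computes it
directly on Ct differences, and the suite checks it against an independent
evaluation on linear quantities. $M$ is invariant to candidate order and
to any per-sample global Ct shift (a loading effect hits all genes of a
sample equally and cancels in every pairwise ratio); both invariances are
tested. The full geNorm procedure's iterative elimination and
$V(n/n{+}1)$ cutoff are out of scope — the ranking alone is what reference
selection needs.

Group comparisons are two-sided Welch tests on per-sample
$-\Delta\Delta C_t$ values, starred at 0.05/0.01/0.001 with no
multiple-testing correction across genes — mirroring common per-gene
reporting practice, and a documented limitation of that practice.

The Ct simulator plants effects as cycle shifts
($C_t = \mathrm{base} - \mathrm{log2FC} + \mathrm{shift}_s + w_{g,s} + \varepsilon$),
with optional per-sample global shifts (which the estimator must cancel),
a per-gene "stability wobble" $w$ with gene-specific sd (how unstable
housekeeping candidates are expressed), and replicate noise
$\varepsilon$ (default sd 0.2 cycles, a typical SYBR assay). The
planted-stability check uses six conventional neuronal housekeeping
candidates with two planted stable (wobble sd 0.05) and four unstable
(sd 0.5), 2 groups × 5 biological × 2 technical replicates — sizes fixed
once from plausible bench practice before any test was run.

## 4. Single-cell QC

The four filter parameters are fixed by the stated rules and their
inequalities are strict exactly where the wording is strict:

| rule | threshold | boundary |
|---|---|---|
| gene detected in cells | ≥ 3 | 3 kept, 2 removed |
| features per cell | ≥ 300 | 300 kept |
| UMI per cell | < 15,000 | 15,000 removed |
| mitochondrial percent | < 10 | 10.0 removed |

Two conventions were genuinely open and are documented (and switchable via
`qc_thresholds()` only in magnitude, not in semantics):

* **Stage-1 joint evaluation.** Gene and cell-feature rules are evaluated
  together on the raw matrix in one pass — the creation-time semantics of
  loading a matrix with those parameters — rather than iterating until a
  fixed point. Re-evaluation after gene removal could drop a cell below
  300 features; single-pass is the documented contract and the report's
  arithmetic (before − removed = after, per rule) is what the tests
  assert.
* **Raw-matrix metrics for stage 2.** UMI totals and mitochondrial
  percentages are computed on the raw matrix, not post-gene-filter,
  because the filters are described as sequential selections on the loaded
  data.

Removed cells are attributed to the *first* rule that rejects them, in the
order features → UMI → mito, so the report's per-rule counts are disjoint.
The mitochondrial predicate is a case-insensitive `MT-` name prefix (the
human convention), overridable by an explicit gene list. An all-zero cell
has percent-mito 0 by convention and fails the feature rule regardless.
Matrices are genes × cells; the MatrixMarket reader auto-detects a
transposed file from the id-file lengths and says so.

The matrix simulator plants each violation so that exactly one rule fails
per planted cell (low-feature cells get 100 genes; high-UMI cells are
inflated uniformly past 15,000; high-mito cells get ~15% mitochondrial
load while staying under the UMI cap), rare genes are placed in exactly
two cells, and a repair pass guarantees every non-planted gene is detected
in at least three cells — so ground-truth labels are exact, not
probabilistic.

Phase summaries flag G1 dominance strictly above 80% (a cluster at exactly
80% is not flagged), reflecting the interpretation of G1-dominant clusters
as terminally differentiating populations. Composition ratios are plain
cell-count ratios through a caller-supplied cluster → lineage map, because
any such map is an annotation judgement, not something this package should
hard-code.

## 5. Growth

Per passage, $M = \log_2(N_{grown}/N_{seeded})$; the cumulative curve is
the running sum. A zero harvest yields $-\infty$ with a `crashed` flag
rather than an error (cultures do crash), negative $M$ is allowed, no
smoothing is applied, and passage-number gaps warn without invalidating
the sum. The simulator's defaults — 800,000 cells seeded per passage, mean
2.3 doublings per passage over 25 passages — describe a healthy NSC line
whose cumulative doublings over a long series land in the
several-tens range.

## 6. Numerical and I/O notes

* Index arithmetic is exact (integer-valued doubles); no tolerance is
  needed or used in the oracle-equality tests.
* TIFF support is deliberately minimal: uncompressed, single-sample
  grayscale, 8/16-bit, both byte orders on read. Anything else errors
  rather than guessing, because silent conversion would change the index.
* All generators restore the caller's RNG state; CLI runs write a
  provenance record (resolved config, seed, versions) and are
  byte-reproducible given the seed — asserted end-to-end in the suite.
* Acceptance-style checks that needed a size the statement left open were
  fixed once before running: Welch power uses $n = 5$ per group for the
  3-pooled-SD shift; the null-size check uses 1,000 seeds; random-image
  oracle checks use 500 images with sides 16–64 px (image size does not
  enter the identity being tested).

## 7. Known limitations

* The index is a field-level statistic; it does not segment cells, so it
  cannot distinguish "more positive cells" from "brighter positive cells".
* No multiple-testing correction across markers or genes, by convention of
  the reporting style it reproduces.
* The single-cell module consumes externally produced cluster, phase and
  lineage annotations; it does not compute them, and the validity of its
  summaries is bounded by the validity of that upstream annotation.
* Simulated data are idealized in the specific ways §2 lists; green tests
  establish correctness of the computations under the stated world, not
  robustness to every artifact of real acquisitions.
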