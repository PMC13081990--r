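---
title: "Methods: transcript-to-cell assignment for sequential smFISH in whole-mount C. elegans"
author: "wormfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-to-cell assignment for sequential smFISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormfish)
```

# Overview

Sequential single-molecule FISH (smFISH) images an animal over many
hybridization rounds: each round, fluorescent readout probes bind the
overhangs of gene-specific primary probes, two readout channels are imaged
alongside a DAPI nuclear channel, and the readouts are stripped before the
next round. Each mRNA appears as a diffraction-limited spot. `wormfish`
implements the computational side of such an experiment for whole-mount
*C. elegans*: probe panel design, image preprocessing, drift registration,
spot detection, colocalization QC, probabilistic transcript-to-nucleus
assignment, and cell-by-gene quantification — plus a synthetic-data
generator that renders complete, ground-truthed experiments so every stage
is testable without external data.

The centerpiece is the assignment model. Whole-mount worms lack reliable
membrane stains, so cells are represented by their segmented nuclei, and
cytoplasmic transcripts must be attributed to nearby nuclei
probabilistically.

# The assignment model

The pipeline consumes a 3D nuclear label mask from any segmenter. For every
nucleus and every z-slice where it appears, the mask cross-section is
summarized by an ellipse:

* **center** — the pixel centroid;
* **orientation** — the first principal component of the pixel
  coordinates;
* **semi-axes** `(a, b)` — the mask extents (max minus min of the
  projected pixel-center coordinates, floored at 1 px) along the first and
  second principal axes. Because the model doubles the mask to delimit the
  perinuclear zone — an ellipse twice the size of the mask — the doubled
  ellipse's semi-axis equals the mask's full extent. Each semi-axis is
  capped at 15 px (`max_semi_axis`), the ceiling on how far a transcript
  may sit from a nucleus and still be considered.

A detected transcript at `(z, y, x)` is then routed per slice
(`round(z)`):

1. **Hard assignment** — if its voxel lies inside a nuclear mask, it
   belongs to that nucleus with probability 1.
2. **Soft assignment** — otherwise, every nucleus whose doubled ellipse
   contains the point is eligible, and responsibilities follow a 2-D
   Gaussian mixture: component `i` has mean at the nucleus center,
   covariance `R_i diag(a_i^2, b_i^2) R_i^T` (the semi-axes act as
   standard deviations), and mixture weight `w_i = sqrt(a_i * b_i)`. The
   responsibility of nucleus `i` is
   `w_i * phi_i(p) / sum_j w_j * phi_j(p)`, probabilities summing to 1.
3. **Unassigned** — transcripts outside every ellipse are left
   unassigned; mRNAs in neuronal projections are deliberately not handled.

The `sqrt(a*b)` weight deserves a comment: with equal weights, a mixture of
full normal densities penalizes large nuclei, whose density is spread
thinner; weighting by the geometric mean of the semi-axes (the square root
of the covariance determinant's fourth root squared, i.e. proportional to
the component's linear scale) cancels that bias. The package keeps the
per-component normalizing constants — they matter precisely because
covariances differ between nuclei — and computes responsibilities in log
space so ellipse-margin spots do not underflow.

Per-(nucleus, gene) responsibilities summed over all spots and slices give
the cell-by-gene matrix of soft counts; fractional entries are expected.

Degenerate mask cross-sections (fewer than 3 pixels) fall back to an
isotropic ellipse with radius `2 * max(1, sqrt(area/pi))` capped at the
same ceiling, preventing singular covariances. Extents are floored at 1 px
so single-pixel-wide slices remain well-posed.

# Image processing

All image operations run per z-plane in `(y, x)`: voxels are strongly
anisotropic (1000 nm axially vs 103 nm laterally by default), so an
isotropic 3D sigma would be ill-defined.

* **Background correction** — a wide Gaussian blur (`sigma = 3` px)
  estimates local background, which is subtracted; negatives clip to zero.
* **Gamma adjustment** — intensities are normalized to the 99.9th
  percentile (robust to hot pixels; the ceiling choice is ours), raised to
  `gamma = 1.6`, and rescaled. This is a contrast enhancement for display
  and inspection. It is **not** part of the detection input: percentile
  clipping saturates the brightest noise voxels to spot-level amplitudes,
  which is harmless to the eye but ruinous to a detector. Detection
  operates on background-corrected, low-pass-filtered images only.
* **Low-pass filter** — truncated Gaussian, `sigma = 1` px, kernel 3 px.
* **Registration** — each round's DAPI stack is max-projected and aligned
  to round 0 by phase correlation at integer-pixel resolution. The
  returned offset is the measured drift `d` of the moving image, i.e.
  `register_round(shift(I, d), I) = d`; correction applies the negated
  offset. Shifts zero-fill rather than wrap so no content crosses borders.

# Spot detection and decomposition

Detection is Laplacian-of-Gaussian filtering with per-axis sigma
`spot_radius_nm / voxel_size_nm / sqrt(3)` (the standard radius-to-sigma
conversion; defaults give sigma of about 0.61 slices axially and 1.68 px
laterally), followed by local-maximum extraction over a box neighborhood of
`round(spot_radius_nm / voxel_size_nm)` voxels, thresholded on the filtered
response. The threshold is a manual, per-experiment parameter — the
pipeline refuses to invent one. Candidates within the suppression box of an
earlier (lexicographically smaller) candidate are discarded, and a margin
of one suppression box at the y/x borders is excluded, where the
replicate-padded filter response is unreliable; z borders are kept because
axial truncation of real spots there is expected.

Clustered transcripts merge under non-maximum suppression, so detection
alone undercounts dense nuclei. `decompose_dense` rebuilds counts: bright
connected regions (above half the median detected intensity) whose net
integrated signal exceeds twice a single-molecule reference are re-estimated
to hold `round(integral / reference)` molecules, with the extra molecules
placed at the region's unclaimed LoG maxima first and its brightest
remaining voxels after that. Two definitions required care:

* integrals are taken over the region's bounding box padded by the
  detection separation, minus the image-median baseline — supra-threshold
  sums are superadditive for merged peaks (a pair integrates to well over
  twice a single) and would systematically over-split;
* the single-molecule reference is the **lower quartile** of the
  integrals of regions holding one isolated detection. A merged pair
  detected as one spot passes the isolation test, so the reference sample
  is contaminated upward only; the lower quartile resists exactly that
  one-sided contamination where the median does not.

Colocalization QC follows the two-channel control-gene design: two probe
sets on one transcript read out in different channels. For every channel-1
dot the Euclidean nearest neighbor in channel 2 (z in slice units) is
found; efficiency is the fraction within a 2 px radius, matching
non-exclusively.

# Probe design

Primary probes tile each target's coding sequence with 35-nt windows
separated by 2-nt gaps, keep windows with GC in [0.40, 0.65] (inclusive —
the conventional reading of a percent range), and drop windows sharing any
exact contiguous 17-mer (either orientation) with another transcript.
Cross-hybridization between probe sets is screened the same way; on a
conflict the probe from the gene currently holding more probes is removed
(ties broken lexicographically), iterating until clean. Genes retaining
fewer than 24 probes are excluded. Probes are emitted as reverse
complements of their windows, carrying two 3' copies of the gene's
readout-complement overhang.

The screens use exact k-mer sharing via a hash index rather than a seeded
alignment: an ungapped exact match of at least k nt is the deterministic,
reproducible core of a "hit of k nucleotides or longer" criterion, needs no
external binary, and makes containment equivalent to the stated length
rule. Tolerating mismatches inside the window would only loosen the screen.
Readout sequences are rejection-sampled 15-mers with GC in [0.40, 0.60],
discarded on any contiguous 10-nt transcriptome match (either orientation)
or clash with a previously accepted readout, capped at 10^6 draws per
accepted sequence.

# The synthetic generator

`simulate_experiment` emulates the statistical structure the pipeline
assumes, with defaults mirroring the acquisition scales above: a 9×160×160
volume at (1000, 103, 103) nm voxels, 20 non-overlapping ellipsoidal nuclei
(in-plane semi-axes 4–7 and 3–5 px, z half-extent 1.2–2.2 slices, random
orientation), 10 genes over 5 rounds × 2 readout channels, per-cell
per-gene Poisson counts around log-normal means (meanlog `log(3)`, sdlog
0.4 — a few transcripts per cell per gene, typical of moderately expressed
neuronal genes), spot amplitude 1 against Gaussian noise SD 0.2 (SNR 5),
and a cumulative per-round drift of (1, −2) px. Each transcript falls
inside its nucleus's mask with probability 0.4, else is drawn from the
truncated 2-D Gaussian of that nucleus's doubled fitted ellipse at a random
slice — exactly the assignment model's generative assumption, so
parameter-recovery tests are well-posed. A `perinuclear_mode = "uniform"`
switch provides a model-mismatch variant for robustness checks. Counts are
Poisson because the source experiments state no count model; this is the
minimal explicit choice.

What the generator does **not** emulate: optically realistic PSFs,
autofluorescence, cuticle scattering, segmentation errors (the mask given
to assignment is the true mask), or chromatic aberration. Passing tests
therefore demonstrate correctness of the algorithms under the model's own
assumptions, not robustness to every artifact of real worm imaging.

# Numerical choices and problem sizes

* Responsibilities: log-space softmax; oracle agreement to better than
  1e-9 relative error is verified against a dense covariance-matrix
  evaluation.
* Conservation: soft counts plus unassigned spots reproduce the per-gene
  input exactly (to floating-point summation error, < 1e-9).
* Registration is integer-pixel only; no subpixel upsampling is claimed
  or implemented.
* Detection ties are broken in lexicographic (z, y, x) order.
* Test and acceptance runs use the default simulation (20 nuclei, 10
  genes, ~600 spots, 5 rounds) and 100-shift registration sweeps; a full
  pipeline run takes a few seconds on one CPU.

# Known limitations

* End-to-end per-cell count recovery at SNR 5 lands at roughly 10–16%
  RMSE across simulation seeds, dominated by detection of merged
  transcripts inside dense nuclei; z-truncation of spots near the axial
  borders makes single-molecule integrals variable by up to a factor of
  two, which limits how precisely the decomposition ratio can count.
  Assignment itself, measured on ground-truth positions, recovers per-cell
  totals to ~1% RMSE.
* Registration under SNR-5 noise is occasionally off by one pixel on
  drifted rounds; the phase-correlation peak is exact only in the
  noise-free case.
* The 15-px cap is applied to each semi-axis (the natural reading of a
  radial ceiling); the cap is exposed as a parameter.
* Coordinates are 1-based `(z, y, x)` with pixel centers at integers,
  the array-indexing convention of this language; CSV artifacts follow the
  same convention.
* HDF5 containers are not read or written; stacks move as multi-page
  TIFF (32-bit float, values in [0, 1]) and tables as CSV/MatrixMarket.
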