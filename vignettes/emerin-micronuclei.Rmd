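---
title: "Quantifying Emerin-rich micronuclei: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Emerin-rich micronuclei: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdmn)
```

## The biological quantity

Micronuclei (MN) are small chromatin-containing bodies, physically separate
from the main nucleus, that arise from lagging chromosomes or the breakage
of cytokinetic chromatin bridges. In prostate cancer cells a subpopulation
of MN accumulates the nuclear-membrane protein Emerin well above the
nuclear-envelope (NE) staining level — typically around twice it — while
carrying less DNA (a reduced DAPI signal). These *Emerin-rich* MN behave as
a sink that depletes ("pauperizes") Emerin from the NE, and their per-field
frequency, expressed as **Emerin-rich MN per nucleus**, is the scalar this
package is built around. A companion transcriptomic readout, the mean log2
expression of nine genes (*CXCR4, APOE, SPARC, VIM, GSN, ANXA2P2, SFRP1,
COL18A1, FN1*), summarizes the expression program of Emerin-pauperized
tumors and is stratified at its upper quartile for survival analysis.

## The imaging procedure and its assumptions

All image stages consume plain 2-D intensity matrices (one per channel)
with a pixel size in µm/px, and assume:

* fluorescence is linear and background roughly uniform per field (no
  flat-field model is applied);
* the DAPI channel delineates nuclei as bright filled regions; the Emerin
  channel shows an NE rim around each nucleus plus compact extranuclear
  particles;
* one field contains many cells (field workflow), or a single cell crop
  (the ratio and morphometric operations).

The workflow chain is:

1. `segment_nuclei()` — Otsu threshold on DAPI (8-bit floor 25), hole
   filling, objects under 20 µm² removed. The area gate is what separates
   nuclei from micronuclei (MN top out at 12 µm²).
2. `ne_reference()` — per nucleus, the mean Emerin over a ring built as
   *dilation minus erosion* of the nucleus mask by `ring_width_um`
   (default 0.9 µm on each side). Rings truncated by the image border are
   flagged rather than silently used.
3. `detect_mn()` — Otsu threshold on Emerin (floor 25), nucleus pixels
   removed, 8-connected labelling, size gate 0.2–12 µm². Particles touching
   a nucleus (8-adjacency) are excluded: a candidate that overlapped a
   nucleus even by one pixel leaves a remainder adjacent to it, and the
   outer half of the NE rim always survives pixel removal as a halo that
   must not be counted.
4. `classify_mn()` — each candidate is assigned to the nucleus with the
   nearest border within `d_max_um` (default 15 µm); its mean Emerin is
   divided by that nucleus's NE reference, and the MN is *rich* when the
   ratio is at least `rich_ratio` (default 1.2), otherwise *ne_level*.
   Candidates with no nucleus in range are dropped and counted, never
   guessed.
5. `summarize_field()`, `stratify()`, `classify_phenotype()` — per-field
   counts, the quartile class against the cohort cutoffs
   (0.07538 / 0.1280 / 0.1861 rich MN per nucleus), and the
   normal/pauperized call (pauperized when more than 85 % of tumor cells
   are Emerin-negative/low **or** rich MN/nuclei reaches the 75th-percentile
   cutoff).

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `pixel_size_um` | 0.3 | µm/px | typical 20× widefield sampling |
| threshold floor | 25 | 8-bit level | guard against dim backgrounds (see below) |
| nucleus `min_area_um2` | 20 | µm² | above the MN window, below any nucleus |
| MN size gate | 0.2–12 | µm² | the biological MN size window |
| `ring_width_um` | 0.9 | µm | NE rim half-width at this resolution |
| `rich_ratio` | 1.2 | — | rich MN sit near 2× NE; 1.2 leaves noise margin |
| `d_max_um` | 15 | µm | an MN farther than a cell radius is unassignable |
| `cyto_annulus_um` | 3 | µm | cytoplasmic band beyond the NE ring |
| coherency `window_sigma_um` | 2 | µm | structure-tensor averaging scale |

### The threshold floor

The source workflow invokes ImageJ auto-thresholds annotated with a value
(e.g. "Otsu, value 25"; "Otsu, value 100" for nuclei in the MTOC stage).
The annotation's exact meaning is not recoverable; we interpret it as a
**minimum threshold on the 8-bit scale applied after the named method**, a
common macro idiom protecting against fields where the method would split
the background noise. The floor is configurable everywhere and the resolved
thresholds are echoed into the run report. Consistent with this reading,
images whose values already lie in [0, 255] are binned natively (the
threshold and floor are then absolute 8-bit levels, as in ImageJ);
wider-range images are min–max rescaled to 256 bins first.

### Numerical conventions

* **Otsu** maximizes between-class variance over the 255 split points;
  plateau ties (clean two-value images) resolve to the plateau midpoint, so
  the threshold falls between the populations rather than on the lower one.
* **Yen** maximizes the maximum-correlation criterion; splits that leave a
  class empty are ineligible.
* **Intermodes** smooths the 256-bin histogram (running mean, window 3)
  until exactly two local maxima remain (end bins may carry a mode) and
  takes their midpoint; 10 000 iterations without bimodality is an error.
* Constant images raise a classed `DegenerateImage` error from
  thresholding. Downstream stages that can meaningfully absorb it do so:
  `focal_adhesion_sizes()` reports zero adhesions (mean area `NA`, never 0),
  `mtoc_nucleus_distance()` reports a missing record.
* Labelling is 8-connected by default (the Analyze-Particles convention);
  4-connectivity is available.
* Perimeter is the Euclidean length of the traced 8-connected boundary
  chain; circularity 4πA/P² is capped at 1 (tiny rasterized objects can
  exceed it). Solidity uses the convex hull of the pixel corner points, so
  convex shapes score 1 up to rasterization error (a disk of radius 20 px
  measures ≈ 0.96).
* Coordinates are pixel-centred, origin top-left, `x` = column, `y` = row.
* Quartile stratification uses half-open intervals with the **upper-class
  tie rule**: a value exactly at a cutoff joins the class above it.

### 2-D operationalizations

Two measures in the source workflow are intrinsically 3-D and are
deliberately flattened here: "centrosome positioned above the nucleus"
becomes *centrosome centroid inside the nucleus footprint ⇒ negative
distance*, and the spheroid "main cell body" is the largest connected
component of the body mask. Both are documented conventions, not facts
about the optics.

## The transcriptomic arm

`ncounter_normalize()` reproduces the nCounter-style scheme: per-sample
background = mean + 2 SD of negative-control counts (counts below it are
floored to it), then two sequential multiplicative scalings — positive
controls first, housekeeping genes (default *CNOT4, HDAC3, DDX50, CC2D1B*)
second, each sample scaled by cohort-mean / sample-mean. Whether the
original software applied the two steps jointly or sequentially is not
documented; sequential is this package's choice and the housekeeping means
are therefore computed on positive-control-scaled data.

`pauperization_score()` takes the mean over the nine genes of
`log2(count + 1)`. The pseudocount is a package choice (the score
definition says only "log2 counts"); it is configurable to 0 for strictly
positive matrices. The high/low split is **strictly above** the cohort's
third quartile, computed with the linear-interpolation (type-7) quantile.
Under this rule the high group has exactly ⌊n/4⌋ members when n mod 4 is
0 or 1 (and may have one more otherwise) — the tie rule, not a bug.

`differential_expression()` is a per-gene two-sided Mann–Whitney test
(exact for small tie-free groups, as R's `wilcox.test` decides) with
median-based log2 fold change, offset by half a count.

`survival_association()` computes Kaplan–Meier curves and the Cox hazard
ratio with Wald 95 % CI via the survival package, while the log-rank
statistic is implemented directly from its observed − expected / variance
form and cross-checked against `survival::survdiff` in the test suite. A
group with zero events yields a missing HR with a warning rather than a
divergent estimate.

## What the synthetic data emulate — and what they do not

`generate_field()` paints elliptical nuclei (semi-axes drawn from 4–7 µm,
DAPI 150, nucleoplasmic Emerin 20) with an NE rim (full width 1.8 µm,
Emerin 100 — the reference level), plus circular MN of 1–6 µm²: *rich* MN
at 2× the NE Emerin and 0.5× the nuclear DAPI, *ne_level* MN at 1× / 1×,
on a background of 10 with additive Gaussian noise (SD 5), clipped at zero.
Objects are placed by rejection sampling (≤ 1000 attempts each, classed
error naming the failing object), never overlapping, with 2 px clearance,
and each MN within 12 µm of a nuclear boundary — micronuclei live in the
cytoplasm of their parent cell. Fields are reproducible bit-for-bit from
the seed.

The phantoms deliberately omit: point-spread blur, uneven illumination,
autofluorescence, touching/overlapping nuclei, tissue context (stroma,
out-of-focus layers), and 3-D structure. Passing the concordance benchmark
therefore demonstrates that the *algorithmic chain* is correct and robust
to additive noise — not that it would survive the full variability of
clinical tissue, where region selection and pathologist verification were
part of the original protocol (here replaced by an optional
region-of-interest mask).

`generate_cohort()` draws per-gene log2 baselines uniformly on [4, 10] with
unit-SD Gaussian sample noise, shifts the nine signature genes by
`effect_log2` (default 1) in a `frac_pauperized` (default 0.25) subset, and
simulates exponential survival with hazard ratio `true_hr` (default 1.75,
baseline hazard log 2 / 60 months). Censoring is administrative — uniform
on (0, b), with b solved numerically so the expected censored fraction
equals `censor_frac` (default 0.3). The exponential model is the simplest
in which a target hazard ratio is exactly defined; the cohort makes no
attempt at realistic gene–gene correlation, batch structure, or
non-proportional hazards. Note that splitting on the *estimated* score
quartile (rather than the true labels) attenuates the recovered HR
slightly, as boundary samples are exchanged between groups.

## Problem sizes used by the checks

The test suite validates thresholds against exhaustive-search oracles on
100 random 8-bit histograms, MTOC distances against brute-force border
scans on 50 random scenes, and particle counts against an independent
flood-fill. Detection concordance is measured on 50 default phantom fields
(400 planted MN); hazard-ratio recovery on 50 cohorts of n = 500 (CI
coverage) and 20 cohorts of n = 2000 (bias of log HR < 0.05). These sizes
give stable pass/fail behaviour at interactive runtimes.

## Known limitations

* Thresholding operates on 256-bin histograms; images with meaningful
  structure below 1/256 of their dynamic range will quantize.
* The NE ring is morphological, not model-fit; on very irregular nuclei the
  ring mixes in cytoplasm and the NE reference drops accordingly.
* MN-to-nucleus assignment is nearest-border, which can misattribute an MN
  lying between two adjacent cells.
* The tissue-mode Emerin-negativity fraction (`frac_low_cells`) is an input
  here — scoring per-cell staining intensity from immunohistochemistry is
  out of scope.
* The published cohort cutoffs and the 9-gene signature are fixed
  configuration constants; this package validates the machinery on
  synthetic data and does not re-derive them.
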