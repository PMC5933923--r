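---
title: "Methods: spike-normalized coverage, nuclear zoning, FRAP and colocalization"
author: "perinuc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-normalized coverage, nuclear zoning, FRAP and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perinuc)
```

`perinuc` implements four measurement procedures used to study how
fission-yeast chromatin is positioned and maintained at the nuclear
envelope (NE), together with generators that produce synthetic inputs
with the statistical structure each procedure assumes. This vignette
explains the models, the tunable parameters, the numerical choices,
and what the synthetic data do and do not capture.

## Spike-in ChIP-seq normalization

### The model

Comparing H3K9me2 ChIP-seq signal *between* strains requires a scale
that survives differences in library size, IP efficiency and sample
handling. The spike-in design mixes every sample culture at a 1:4
ratio with a fixed reference ("spike") strain whose only distinguishing
feature is an ectopic `ade6+` gene embedded in pericentric
heterochromatin; the sample strains carry `ade6+` only at its
endogenous, euchromatic locus. After ChIP against H3K9me2, reads over
the ectopic locus come (almost) exclusively from the spike strain, so
their excess over the local euchromatic background is a constant
reference. Each track is rescaled by

$$S = \frac{c}{m_\mathrm{spike} - m_\mathrm{ref}},\qquad c = 10,$$

where $m_\mathrm{spike}$ and $m_\mathrm{ref}$ are the median per-base
depths over the spike locus and the neighbouring euchromatic reference
interval. No input-chromatin normalization is applied. Because $S$
is inversely proportional to overall depth, multiplying a raw track by
any constant leaves the normalized track unchanged — the property
that makes independently sequenced isolates comparable
(`normalizeTrack`, tested to 1e-9 relative tolerance).

Two interval subtleties are handled explicitly:

- **Coordinates.** Bedgraph files are 0-based half-open (the format's
  definition); interval strings such as `"chrIII:1316291-1318035"` are
  read as 1-based inclusive, the convention in which the reference
  intervals are stated, and converted on input.
- **The reference interval encloses the spike interval** in the
  published coordinates (reference chrIII:1304000–1380000 vs spike
  chrIII:1316291–1318035). We compute $m_\mathrm{ref}$ over the
  interval as given — the median is robust to the ~2.3% of enclosed
  spike bases — but expose `excludeSpike = TRUE` to drop them, since
  the overlap appears unintentional. The toy-genome defaults in this
  package use `excludeSpike = TRUE`.

`spikeScaleFactor` refuses to return a factor when
$m_\mathrm{spike} \le m_\mathrm{ref}$: absent spike enrichment is an
error, never a silent fallback.

### Ribbon profiles

Replicate isolates of one genotype are summarized per sliding window
(default 250 bp) for ribbon line-plots: per isolate, the window's
per-base normalized depths are reduced to one number; across isolates,
the median is the line and min/max the ribbon. Two open choices are
parameterized:

- **Step.** A "sliding" window implies overlap but no step is
  canonical; the default is 25 bp (smooth ribbons at modest cost), and
  `step = window` gives non-overlapping windows.
- **Per-isolate summary.** The within-window statistic per isolate is
  the mean by default (an unbiased depth summary at window scale);
  `isolateSummary = "median"` is offered. The across-isolate
  statistics are always median/min/max.

### The coverage simulator

`simulateChipCoverage` draws per-base counts with expectation
`baseline × multiplier(domain class)`, plus — over the spike locus
only — `baseline × spike multiplier × spikeMixFraction`. The spike
strain's share of reads is assumed proportional to its share of the
culture (1:4 mix → `spikeMixFraction = 0.2`); the read share of a
volume mix is not observable from the design, so proportionality is a
modeling choice, stated here once. Counts are negative binomial with
variance $\mu + \phi\mu^2$, reducing to Poisson at $\phi = 0$; no
noise model is canonical for ChIP counts at this scale, and NB
overdispersion ($\phi = 0.1$ by default) is the field's usual choice.
Default multipliers (subtelomere 8, pericentromere 10, *mat* 8,
euchromatin 1, spike 10 over baseline 10 reads/bp) give the order of
enrichment seen for H3K9me2 domains. The `toyGenome()` layout —
three 60 kb chromosomes with subtelomeres, pericentromeres, a *mat*
locus and one spike locus — totals 180 kb so that empirical means are
tight (>1e5 bases) while a six-track simulation runs in seconds.

What this emulates: domain-level enrichment, library-size variation
(`depthScale`), count overdispersion, and the spike reference. What it
does not: mappability structure, repeat-induced multi-mapping pileups,
fragment-length autocorrelation, or GC bias. Passing tests therefore
demonstrate the correctness of the normalization and ribbon
arithmetic under the stated statistical model, not robustness to every
artifact of real libraries. Read trimming (`trimReads`, 3 bases off
the 5' end, 50 → 47 bp) and alignment-to-coverage conversion
(`computeCoverage`) are provided so the pipeline can also ingest
BED-like alignments; alignment itself is out of scope.

## The nuclear zoning assay

The nucleus is modelled as an ideal sphere (the zoning is volumetric;
ellipsoidal nuclei are a non-goal). Three concentric equal-volume
shells partition it; Zone I, the outermost, begins at
$r_1 = R(2/3)^{1/3}$ and Zone II at $r_2 = R(1/3)^{1/3}$, so a
uniformly random position falls in each zone with probability exactly
1/3. At the typical nuclear radius $R = 1.74\,\mu m$ the Zone-I shell
is $R(1 - (2/3)^{1/3}) \approx 0.22\,\mu m$ thick.

Numerical conventions, chosen once:

- **Boundary ties** go to the more peripheral zone (a radial
  coordinate of exactly $r_1$ is Zone I) — conservative toward
  peripheral scoring and consistent across the package.
- **Segmentation jitter**: loci measured up to 2% of $R$ outside the
  sphere are clamped to the surface; farther out is an error, since
  that indicates mis-segmentation rather than jitter.
- **Cell-cycle staging** uses nucleate count: interphase binucleate
  cells are early/mid S phase (fission yeast begins S phase before
  cytokinesis completes), mononucleate cells late S/G2; other counts
  are rejected as unclassifiable rather than guessed.

`testZone1Enrichment` tests each (strain, stage) group's Zone-I
fraction against the 1/3 expectation. The test the assay was reported
with is a two-tailed Student's t-test, but its exact units (per cell
or per replicate) are not specified with only two replicates; the
default here is a one-sample t-test on the per-cell Zone-I indicators
pooled across replicates, with the exact binomial test offered as the
recommended alternative (`method = "binomial"`) — with 0/1 data and a
fixed null the binomial test is the exact version of the same
question. Neither is claimed to reproduce any published p-value. When
all indicators are identical the t-test is undefined (zero variance)
and the binomial test is substituted with a message. The two-sided
binomial p-value uses the minimum-likelihood convention of
`stats::binom.test`; for example 30/30 cells in Zone I against 1/3
gives $p = (1/3)^{30}$ — no other outcome is as unlikely, so nothing
is added to the sum.

`simulateNuclei` draws loci uniformly in the sphere, or with
probability `peripheralBias` uniformly within the Zone-I shell
(radial coordinate $R(2/3 + U/3)^{1/3}$), giving an expected Zone-I
fraction of $p + (1-p)/3$; `peripheralBias = 0.7` therefore produces
the ~80% peripheral occupancy typical of a tethered telomere, which
is the regime the power checks use (100 cells give p < 0.001 in
essentially all samples). Stage labels are generated directly —
staging from images is a separate concern exposed via
`classifyStage`.

## FRAP quantitation

Normalization follows the ROI bookkeeping of the bleaching protocol:
the summed ROI intensity minus an equal-size background region beside
the nucleus, divided by the pre-bleach ROI signal so the pre-bleach
level is 1.0. Whether the pre-bleach denominator is itself
background-subtracted is ambiguous in that description; the default
subtracts (keeping the recovery on a 0–1 scale and making the two
measurements symmetric), and `mode = "literal"` divides by the raw
pre-bleach sum instead.

Averaged traces are fitted to the one-phase association
$Y(t) = Y_0 + (P - Y_0)(1 - e^{-kt})$ by bounded Levenberg–Marquardt
least squares ($k \in [10^{-6}, 10^3]\,s^{-1}$), with deterministic
initialization: $\hat P$ from the last-quartile mean, $\hat Y_0$ from
the first point, and $k$ from a log-linear regression of
$\log\bigl((\hat P - Y)/(\hat P - \hat Y_0)\bigr)$ on $t$ — no random
restarts, so fits are reproducible without a seed. The mobile
fraction is reported as the plateau $P$; the half-life is
$\ln 2 / k$ (the identity $T_{1/2}\,k = \ln 2$ is enforced in the
class validity). A flat series is flagged immobile ($P = Y_0$) with
$R^2$ reported as not applicable, and a rate estimate at its bound
triggers a warning rather than a silent result. No correction for
photobleaching during acquisition is applied. Double-exponential and
reaction–diffusion models are non-goals.

The published fitted values this machinery corresponds to (half-lives
of ~5 s for a mobile inner-NE protein and ~23 s / ~11 s for a
lamin-like protein under different genetic backgrounds; mobile
fractions 72–100%; $R^2 \approx 0.96$–0.97) were measured on raw image
series that are not distributable, so the package's accuracy claims
are parameter-recovery claims: with Gaussian noise of sd 0.05 on 12
averaged traces of 60 timepoints at 2 s, the recovered half-life is
within 10% of truth in ≥90% of simulations (tested over 50 seeds).
The noiseless fit recovers parameters to ~1e-6 relative.

## Dot detection and colocalization

`detectDots` implements constant-threshold detection: supra-threshold
pixels are grouped into 8-connected components, components smaller
than `minSize` (default 2 px) are discarded, and centroids are
intensity-weighted. A constant threshold mirrors the automated
scoring it reproduces; the original script's threshold value is not
recorded, so the value is a required argument rather than a default.

`estimateNuclearBoundary` exploits diffuse nucleoplasmic background
to approximate the nuclear edge: Gaussian smoothing (sigma = PSF
sigma), a threshold minimizing intra-class variance (Otsu's split —
deterministic and parameter-free), largest connected component, and a
least-squares (Kasa) circle fit to the component rim. Degenerate
inputs fail loudly: flat images, masks without bimodal separation,
and masks touching the image border. Multiple nuclei keep the largest
mask and set a flag.

Colocalization pairs dots across channels one-to-one, greedily by
ascending distance with a hard cutoff — equivalent to iterated
mutual-nearest-neighbour matching, symmetric in channel order. The
default cutoff is 0.25 µm, chosen below the ~300 nm lateral resolution
of conventional wide-field imaging; the cutoff used in the original
analysis is unknown, so ours is declared a substitute, not a
reproduction. `distanceToEdge` then scores paired dots against the
fitted boundary with the same geometry (and clamping rules) as the
zoning assay. `pearsonColoc` is the plain Pearson correlation over
masked pixel intensities, validated in tests against a direct two-pass
covariance computation at 1e-12.

Analysis is 2D on single z-planes, matching single-plane scoring of
the dot assay; the zoning assay itself is 3D. The image simulator
renders isotropic Gaussian spots, an optional NE ring with Gaussian
radial profile, and Gaussian background noise — sufficient for
detection/matching correctness, but not a model of real optics (no
anisotropic PSF, shot noise, or out-of-focus light).

## Pipeline and reproducibility

`runPipeline` is a uniform front end over the stages (`simulate_chip`,
`simulate_nuclei`, `simulate_frap`, `chip_normalize`, `ribbon`,
`zoning`, `frap_fit`, `coloc`) driven by a YAML/JSON config with
explicit seeds; each run writes its artifacts plus a
`provenance.json` recording stage, parameters, seed and package
version. All generators take explicit seeds, restore the caller's RNG
state, and are bit-reproducible; identical config + seed yields
byte-identical outputs. This package is a library first: the R
functions are the interface, and the pipeline front end exists for
scripted, provenance-tracked runs.

## Problem sizes and limitations

The test suite and examples use desk-scale problem sizes chosen to
keep Monte-Carlo error well below the tolerances being asserted: a
180 kb toy genome with 3 isolates per genotype, 1e5-point uniform
sphere samples (binomial s.e. ≈ 0.15 percentage points on the 33%
expectation), 50-seed FRAP recovery sweeps, and 40-seed zoning power
sweeps at n = 100 cells. Known limitations: no read-level (FASTQ)
simulation; no peak calling; no 3D image segmentation; the binomial
and t-test options bracket, but do not reproduce, the original
under-specified replicate test; and all simulators model the
statistical skeleton of their assays, not instrument-specific
artifacts.
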