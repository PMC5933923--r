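# perinuc

Quantitative assays for chromatin organization at the nuclear envelope
(NE) of fission yeast. Studies of locus tethering to the NE combine four
very different measurements, and `perinuc` implements the complete
quantitative pipeline for each, plus synthetic-data generators that
emulate the statistical structure of the raw inputs so every stage can
be exercised and tested without microscopes or sequencers:

1. **Spike-in normalized ChIP-seq coverage.** Each sample culture is
   mixed 1:4 with a fixed *spike* strain carrying an ectopic `ade6+`
   gene inside pericentric heterochromatin; because the spike reads are
   a constant reference, per-base H3K9me2 coverage can be rescaled by

   *S* = *c* / (*m*<sub>spike</sub> − *m*<sub>ref</sub>),

   where *m*<sub>spike</sub> is the median per-base depth over the
   spike locus, *m*<sub>ref</sub> the median over neighbouring
   euchromatin, and *c* = 10 — with no normalization to input
   chromatin. Replicate isolates are then summarized in sliding windows
   (250 bp) as a ribbon: median line with min–max range across
   isolates.
2. **The nuclear zoning assay.** A locus position inside a spherical
   nucleus of radius *R* is classified into three concentric
   equal-volume zones; Zone I, the periphery, is the shell with radial
   coordinate ≥ *R*·(2/3)<sup>1/3</sup> (thickness ≈ 0.22 µm at
   *R* = 1.74 µm). A uniformly random position lands in Zone I with
   probability exactly 1/3 (≈ 33%), and Zone-I enrichment is tested per
   strain, cell-cycle stage (binucleate = early/mid S, mononucleate =
   late S/G2) and replicate against that expectation.
3. **FRAP recovery kinetics.** Background-subtracted, pre-bleach
   normalized recoveries are fitted to the one-phase association
   *Y*(*t*) = *Y*₀ + (*P* − *Y*₀)(1 − e<sup>−*kt*</sup>), reporting the
   half-life ln 2/*k*, the mobile fraction (plateau *P*) and *R*².
4. **Dot detection and colocalization.** Constant-threshold connected-
   component spot detection with intensity-weighted centroids, greedy
   one-to-one mutual-nearest-neighbour pairing across channels,
   nuclear-boundary estimation from nucleoplasmic background with
   distance-to-edge scoring, and pixelwise Pearson colocalization.

## Worked example

```r
library(perinuc)

## spiked ChIP coverage for 3 wild-type-like isolates on a toy genome
gs  <- toyGenome()
cfg <- SpikeNormConfig("toy_III:45001-46750", "toy_III:40001-55000",
                       constant = 10, excludeSpike = TRUE)
wt  <- simulateChipCoverage(gs, enrichmentModel(), nIsolates = 3,
                            seed = 101, depthScale = c(1, 1.4, 0.8))
spikeScaleFactor(wt[[1]], cfg, verbose = TRUE)
#> m_spike = 29, m_ref = 10, S = 0.526316

rp <- ribbonProfile(normalizeTracks(wt, cfg), "toy_I:27001-33000",
                    window = 250, step = 250)
head(as.data.frame(ribbonWindows(rp)), 3)
#>   seqnames start   end width strand   median      min      max
#> 1    toy_I 27001 27250   250      * 51.92421 51.44889 54.10400
#> 2    toy_I 27251 27500   250      * 53.51789 50.65926 53.70400
#> 3    toy_I 27501 27750   250      * 53.25867 51.44593 54.34737
```

The scale factor rescales each isolate so its spike locus reads the
same excess (*c* = 10) over flanking euchromatin; after normalization
the three isolates — simulated with library sizes differing by up to
75% — agree window by window (median ≈ 52 with a narrow min–max
ribbon over this pericentric region).

```r
## zoning assay: 200 cells with 80% peripheral Zone-I occupancy
obs <- simulateNuclei(200, peripheralBias = 0.7, stageMix = 0.5,
                      seed = 11)
testZone1Enrichment(obs, method = "ttest")
#>   strain       stage   n n_by_replicate zone1 fraction expected  p_value
#> 1     wt early_mid_S 103            103    84    0.816    0.333  2.0e-22
#> 2     wt   late_S_G2  97             97    82    0.845    0.333  1.1e-24

## FRAP: recover a 5 s half-life, 72% mobile fraction from noisy traces
trs <- simulateFrap(trueK = log(2) / 5, truePlateau = 0.72,
                    trueY0 = 0.25, noiseSd = 0.04, seed = 21)
fitRecovery(averageTraces(trs))
#> FrapFit: k = 0.1441 1/s, half-life = 4.81 s, Y0 = 0.234,
#>          mobile fraction (plateau) = 72.3%, R^2 = 0.9843, n = 60
```

Both cell-cycle stages show ~82% Zone-I occupancy against the 33%
random expectation (p ≪ 0.001), and the averaged FRAP fit recovers the
simulated half-life within 4% with *R*² ≈ 0.98.

A uniform front end, `runPipeline()`, runs any stage from a YAML/JSON
config and writes artifacts plus a `provenance.json` (stage,
parameters, seed, package version) so runs are exactly reproducible.

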