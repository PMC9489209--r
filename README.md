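# chromobility

Chromatin locus mobility from live-cell single-particle tracking.

## What it is for

In yeast (and beyond), a DNA double-strand break increases the mobility
of chromatin genome-wide. The standard way to measure this is to tag a
locus fluorescently (e.g. a TetO array bound by TetR-GFP), film it in 2D
at short exposure (100 ms frames, 108 nm pixels, 3-minute movies), track
the spot, and compute the time-averaged mean squared displacement

    MSD(t) = D * t^alpha

over lags up to 10 s. Undamaged interphase chromatin is subdiffusive
with alpha ~ 0.6; damage raises both the amplitude and the exponent.
Conditions are summarized by the population MSD at a 10 s lag (e.g.
0.049 um^2 for undamaged cells vs 0.088 / 0.064 um^2 for
damage-searching vs repaired cells) and compared by Wilcoxon rank-sum
tests on per-cell values.

`chromobility` is a Bioconductor-style R package implementing this
entire chain:

* **Synthetic data** — exact fractional-Brownian-motion trajectories
  (Davies–Harte), nuclear confinement, stage drift, measurement-noise
  overlay, calibrated presets for the study conditions, and rendering
  into realistic TIFF movies with ground truth attached.
* **Tracking** — difference-of-Gaussians spot detection, sub-pixel
  Gaussian localization, greedy nearest-neighbour linking with gap
  closing, SNR/length quality control.
* **Drift correction** — robust (median-based) field-wide drift
  estimation and removal.
* **MSD analysis** — per-trajectory MSD over non-overlapping intervals,
  unweighted population averaging, log–log power-law fits, MSD at a
  lag, fold changes.
* **Population statistics** — rank-sum tests with the paper-style
  significance codes, box-plot summaries, and a mixed-population
  resampling analysis.
* **IO and orchestration** — TSV trajectory interchange format,
  16-bit TIFF movies with JSON sidecars, an end-to-end `runPipeline()`
  with provenance (config hash, seed, stage log), and a thin CLI
  (`inst/scripts/chromobility-cli.R`).

## Worked example

Simulate a 50/50 mixture of damaged and undamaged cells at the study's
acquisition settings and run the full pipeline:

```r
library(chromobility)

cfg <- simulationConfig(hurst = 0.3, amplitude = 0.0123593, nFrames = 1800L,
                        nCells = 200L, seed = 11L,
                        mixtureFractions = c(`damaged-white` = 0.5,
                                             `undamaged-baseline` = 0.5))
rep <- runPipeline(cfg, pipelineConfig(log_level = "quiet"))
rep
#> MobilityReport (config 1e2b67bc )
#>   damaged-white: n=100, alpha=0.690, D=0.01793, MSD@10s=0.08823 um^2 (population)
#>   undamaged-baseline: n=100, alpha=0.603, D=0.01237, MSD@10s=0.05117 um^2 (population)
#> wilcoxon_rank_sum: damaged-white (n=100) vs undamaged-baseline (n=100)
#>   U = 9389, p = 7.955e-27  ***
```

Reading the output: each condition's population MSD curve was fitted
with `MSD ~ D t^alpha` over 0.1–10 s — the undamaged cells recover
alpha ≈ 0.6 and MSD@10s ≈ 0.049 um^2, the damaged preset its elevated
0.088 um^2 — and the per-cell MSD@10s distributions differ by a
rank-sum test at p < 0.0001 (`***`).

The building blocks compose freely, e.g. render movies and re-track
them to include realistic localization error:

```r
pop <- simulatePopulation(presetConfig("undamaged-baseline", nCells = 6L, seed = 1L))
mv  <- renderMovie(pop, spotPeak = 50, backgroundMean = 100,
                   imageShape = c(80L, 80L))          # SNR ~ 5
tracks <- qcFilter(trackMovie(mv))$kept
fitPowerLaw(populationMSD(trajectoryMSD(tracks, maxLag = 10)))
```

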