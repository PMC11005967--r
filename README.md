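# overlapdose

Overlap-based prediction of organ-at-risk dose-volume metrics in prostate
radiotherapy, on a fully synthetic phantom test bed.

## The problem

When planning prostate IMRT/VMAT, the achievable rectum and bladder sparing
is strongly constrained by geometry. The conventional geometric predictor is
the overlapped fraction of the organ at risk (OAR),

    COPP = V_OV / V_OAR

(`V_OV` = overlap volume of OAR and planning target volume, `V_OAR` = OAR
volume). COPP cannot distinguish target sizes: two anatomies with the same
overlap fraction but different PTV volumes get identical predictions. The
volume-ratio-weighted parameter

    POPP = (V_OV / V_OAR) × (V_PTV / V_OAR)

breaks that degeneracy. `overlapdose` provides everything needed to study
which parameter predicts which dose level better:

* **Voxel geometry** — analytic structure rasterization, exact Euclidean
  distance transforms (Rcpp), anisotropic margin expansion (analytic
  Minkowski margins for primitive-backed masks), volume/overlap measures.
* **Phantom families** — a prostate/rectum/bladder surrogate phantom
  calibrated to printed benchmark volumes, plus two experimental designs: six
  cases crossing two PTV sizes with three fixed rectum-overlap levels, and
  the 81-case factorial of rectum/bladder expansions and shifts.
* **Dose emulator** — seeded conformal dose as a sigmoid of signed distance
  to the PTV with IMRT/VMAT falloff presets, smooth multiplicative noise,
  and renormalization to ≥ 95% PTV coverage at 75.6 Gy.
* **Plan metrics** — cumulative DVH with exact order-statistic queries
  (V_xGy, D_2/D_50/D_98), mean dose, conformity number, homogeneity index,
  COPP/POPP.
* **Statistics** — per-level Pearson correlation sweep (V_20Gy–V_75Gy, 1-Gy
  steps), Williams/Steiger comparison of the two dependent correlations
  (with a paired-t-window variant), significant-range extraction, and the
  threshold dose *Dth* where the two parameters are equally informative.

## Worked example

The defining arithmetic, on the benchmark volumes (rectum 49.9 cc, PTV
162.7 cc, overlap 3.3 cc):

```r
library(overlapdose)
overlap_params(3.3, 49.9, 162.7)
#> <overlap_features> V_OV 3.30 / V_OAR 49.90 / V_PTV 162.70 cc | COPP 0.0661 | POPP 0.2156
```

A full cohort run — 81 geometry cases, IMRT-like emulated dose, metric
extraction and the correlation sweep:

```r
ex <- run_experiment(experiment_config(simulation = "simulation2",
                                       modality = "imrt", seed = 1))
ex
#> <overlap_experiment> simulation2 / IMRT | 81 cases | 25 meet dose goals
#>   threshold dose: rectum 54.8 Gy, bladder 44.9 Gy

ex$summary[ex$summary$oar == "rectum", ]
#>      oar metric mean   sd r_copp r_popp
#> 1 rectum  dmean 45.4 3.04  0.957  0.963
#> 2 rectum    v70 15.2 4.09  0.932  0.868
#> 3 rectum    v60 29.3 5.26  0.965  0.954
#> 4 rectum   v375 58.4 6.31  0.925  0.977
```

Reading the table: across the 81 cases the rectum received a mean dose of
45.4 ± 3.0 Gy; the near-prescription metric V_70Gy correlates better with
COPP (R = 0.932 vs 0.868) because the high-dose region essentially *is* the
overlap, while the intermediate metric V_37.5Gy correlates better with POPP
(R = 0.977 vs 0.925) because intermediate dose scales with the
target-to-organ volume relationship. The two correlation curves cross at
the threshold dose — 54.8 Gy for the rectum here — below which POPP is the
better predictor and above which COPP is. `plot_sweep(ex$sweeps$rectum)`
draws the sweep and per-level p-values; `plot_regression(ex$results,
"v375_rectum", "popp_rectum")` gives the scatter with its least-squares
line.

A thin command-line wrapper over the same functions ships in
`inst/scripts/run_phantom_study.R`:

```sh
Rscript inst/scripts/run_phantom_study.R --simulation 2 --modality vmat \
    --seed 1 --outdir results/vmat
```

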