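# acidrop

Single-cell extracellular acidification analysis for droplet microwell
arrays.

Glycolytic cells acidify their surroundings by exporting lactate and
protons. When single cells are compartmentalized in ~140 pL water-in-oil
droplets together with a cell-impermeant dual-emission ratiometric pH probe,
and tens of thousands of droplets are immobilized in a 2-D microwell array,
time-lapse fluorescence microscopy turns extracellular pH into a
per-cell metabolic phenotype. `acidrop` is for the people running such
assays: it takes the multi-channel image stacks (two cell-label channels and
the probe's 600/667 nm emission channels) and produces per-droplet pH
trajectories, occupancy classes, raw-ΔpH statistics and QC reports — plus a
ground-truthed synthetic scene generator so the whole pipeline is testable
without a microscope.

## The model in brief

**Encapsulation** follows Poisson statistics: at cell concentration $c$ and
droplet volume $V$, the cell count per droplet is Poisson with mean
$\lambda = cV$; empty, single and multiple occupancy have probabilities
$e^{-\lambda}$, $\lambda e^{-\lambda}$ and the remainder.

**pH sensing** uses the probe's acid-form (600 nm) and base-form (667 nm)
emissions. With endpoint ratios $R_A$, $R_B$ and normalization factor $N$
(the base/acid intensity ratio at 667 nm), the measured ratio
$R = F_{600}/F_{667}$ inverts to

$$\mathrm{pH} = \mathrm{p}K_a - \log_{10}\!\left(\frac{R - R_B}{R_A - R}\,N\right)$$

**The pipeline**: feature-point cell detection and Brownian track linking in
the label channels (radius 10, percentile 0.6, link range 4,
displacement 5); droplet segmentation from the 667 nm channel with grid
indexing; occupancy from tracks whose median position lies in the central
60% of the droplet area, reconciled across both label channels; per-droplet
raw ΔpH = pH(first frame) − pH(last frame); class-conditional ΔpH QC
windows; encapsulation/error rates and two-tailed Student's t-tests between
groups.

## Worked example

A two-position synthetic run at the design occupancy (λ = 1.716, 1:1 mix of
hyperglycolytic and untreated emulsions):

```r
library(acidrop)

poisson_design(1.2e7, 143)
#> $lambda    1.716
#> $p_empty   0.180
#> $p_single  0.309
#> $p_multi   0.512

droplet_volume(60)
#> 113.1  # pL

cfg <- run_config(
  seed = 42, out_dir = "demo",
  synth = synth_params(seed = 42),
  acquisition = acquisition_config(grid_rows = 5, grid_cols = 5,
                                   n_positions = 2),
  qc = qc_thresholds(single_min = 0.05, single_max = 0.6, empty_max = 0.05))
res <- run_pipeline(cfg)
#> ... position 1: 25 droplets, 51 tracks, 10 single / 0 empty / 15 multi
#> ... position 2: 25 droplets, 53 tracks, 4 single / 6 empty / 15 multi
#> ... QC: 48 kept of 50 droplets; pooled encapsulation efficiency 24.0%

res$group_stats[, c("group_a", "group_b", "n_a", "n_b",
                    "mean_a", "mean_b", "p", "symbol")]
#>     group_a   group_b n_a n_b mean_a mean_b        p symbol
#> 1 HG single UT single   7   5  0.205  0.059  1.9e-04    ***
#> 2  HG multi  UT multi  12  18  0.361  0.144  4.3e-08    ***
#> 3 HG single  HG multi   7  12  0.205  0.361  1.5e-03     **
#> 4 UT single  UT multi   5  18  0.059  0.144  5.6e-03     **
#> 5 HG single     empty   7   6  0.205  0.021  7.0e-06    ***
#> 6 UT single     empty   5   6  0.059  0.021  2.6e-08    ***
```

Reading the output: hyperglycolytic single-cell droplets acidify their
droplet by ~0.2 pH units over the run versus ~0.06 for untreated cells — a
*** difference — while empty droplets only drift (~0.02); multi-cell
droplets drop faster than singles, as expected from additive per-cell
acid export. `run_pipeline()` writes `tracks.csv`, `droplets.csv`,
`ph_traces.csv`, `droplet_summary.csv`, `group_stats.csv`, `qc_report.json`
and a provenance record to `out_dir`, all joinable on
(position, row, col). The QC windows here are scaled to this experiment's
ΔpH range; `qc_thresholds()` defaults hold the windows used for
glucose-rich runs (single: 0.28–1.02, empty: ≤ 0.37).

A thin command-line wrapper with subcommands `simulate`, `sort`, `track`,
`index`, `quantify`, `qc`, `report`, `run` is installed at
`system.file("cli", "acidrop.R", package = "acidrop")`.

See `vignettes/droplet-ph-methods.Rmd` for the full model description,
parameter choices and limitations.

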