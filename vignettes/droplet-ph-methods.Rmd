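---
title: "Methods: single-cell extracellular acidification in droplet microwell arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell extracellular acidification in droplet microwell arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement

Glycolytic cells export lactate and protons, acidifying their surroundings.
When a single cell is sealed in a ~140 pL water-in-oil droplet together with a
cell-impermeant ratiometric pH probe, the droplet's extracellular pH becomes a
per-cell metabolic readout. Thousands of such droplets are immobilized in a
two-dimensional microwell array (13 x 13 wells per imaging window) and imaged
every 5 minutes for 3 hours in four channels: two cell-label channels (GREEN
for the hyperglycolytic population, UV for the untreated population) and the
probe's two emission bands at 600 nm and 667 nm.

`acidrop` implements the full analysis: cell detection and tracking in the
label channels, droplet segmentation and grid indexing, occupancy
classification with cross-channel reconciliation, conversion of the
600/667 nm intensity ratio into pH trajectories, raw-&Delta;pH quality
control, and group statistics. A ground-truthed synthetic scene generator
reproduces the statistical structure of the experiment so that every stage is
testable without microscope data.

# The ratiometric pH model

The probe is a weak acid whose acid form emits at 600 nm and base form at
667 nm. With endpoint ratios $R_A$ (fully acid) and $R_B$ (fully basic) and
the base/acid intensity ratio at 667 nm as normalization factor $N$, the
standard dual-emission equation inverts the measured ratio
$R = F_{600}/F_{667}$:

$$\mathrm{pH} = \mathrm{p}K_a - \log_{10}\!\left(\frac{R - R_B}{R_A - R}\, N\right)$$

The forward model used by the renderer decomposes emission into the two
protonation forms weighted by the Henderson–Hasselbalch acid fraction; the
two directions are exact inverses (the test suite checks the round trip to
1e-9 across pH 5.0–6.5).

The default constants (`pKa = 6.4`, `R_A = 4.0`, `R_B = 0.2`,
`norm_factor = 4.0`) are *synthetic-model defaults*, not measured probe
constants: they were chosen once so that $R$(pH) is close to linear across
the probe's working range 5.0–6.5, as the real probe behaves, with a pKa at
the literature value for this probe family. Real probe data requires fitting
the endpoints (or using `fit_linear_calibration()` on a buffer titration;
`LINEAR` and `RATIOMETRIC` modes agree within 0.05 pH on 5.5–6.5 with the
defaults). Because the conversion uses only the *ratio*, any global gain
common to both channels cancels.

# What the generator emulates — and what it does not

`render_dataset()` draws, per droplet:

* **occupancy** from Poisson($\lambda$), default $\lambda = 1.716$, the
  design value for 1.2e7 cells/mL in 143 pL droplets;
* **emulsion** HG with probability 0.5 (the 1:1 volume mix of the two
  stained emulsions), independent of occupancy;
* **per-cell acidification** from a lognormal with CV 0.4. The parameter
  `dph_mean_hg_single = 0.17` is the mean *total* 3-h drop of a single-cell
  HG droplet; the per-cell contribution is therefore
  `0.17 - dph_empty`, and an $n$-cell droplet drops by the sum of its cells'
  contributions plus the empty-droplet drift (`dph_empty = 0.17/8 ≈ 0.021`).
  The untreated single-cell mean is `0.17/2.6 ≈ 0.065`. The CV of 0.4
  reproduces a ±0.06–0.07 spread around the HG single-cell mean;
* **trajectory**: pH decreases linearly in time from `ph0 = 6.4`; leaving
  the probe's working range is flagged, never silently clipped;
* **pixels**: droplets are uniform disks in the probe channels with
  intensities from the forward calibration; cells are Gaussian spots
  (σ = 3 px) visible only in their emulsion's label channel, bleaching with
  a 90-min half-life; Gaussian readout noise (σ = 500 counts of the 16-bit
  range) on every channel.

Two generator choices matter for realism and are worth stating explicitly:

* **Cells settle near the droplet centre.** A cell sediments to the bottom
  of its spherical droplet, which projects near the 2-D centre in an
  inverted-microscope image. Initial positions are drawn with SD
  0.3 R around the centre; Brownian steps (RMS 2 px/frame) are reflected at
  0.95 R. Without central settling, the central-60%-area assignment rule
  would discard roughly a third of true cells.
* **Excluded volume.** Co-encapsulated cells keep at least one cell
  diameter (12 px) between centres, both at placement and during the walk.
  Real cells cannot interpenetrate; in the rendered images this keeps two
  cells from merging under the detector's radius-10 merge rule.

Not modelled: optics beyond Gaussian spots (no PSF, no rim artifacts in the
label channels), droplet drift or loss from wells, probe leakage between
droplets, and any sub-linear saturation of acidification in crowded
droplets (the model is additive by construction). Passing tests on this
generator therefore demonstrate the correctness of the *pipeline*, not the
biology of any particular cell line; in particular the empirically observed
multi-cell mean drop of real experiments can be sub-additive, which this
generator does not reproduce.

# Tracking

Detection follows the classic intensity-moment feature-point scheme:
band-pass restoration (unit-width Gaussian minus a boxcar background over
the kernel radius, both separable), candidate selection in the upper 0.6th
intensity percentile of the restored frame, local-maximum test within the
kernel radius, merge of detections closer than the radius keeping the
brighter, and iterative intensity-weighted centroid refinement. Moments
`m0`/`m2` are computed on above-threshold intensities normalized to the
frame maximum — thresholding keeps background noise at large disc radii out
of `m2`, and per-frame normalization makes moments comparable across frames
under photobleaching.

Linking minimizes squared displacement plus squared moment differences via
an exact optimal bipartite assignment per frame pair (dummy rows/columns at
cost $L^2$ allow track death and birth), with `displacement = 5` px per
frame step and gap closing across up to `link = 4` frames (the displacement
budget scales with gap length). Defaults are the plugin-style parameters
`radius = 10, percentile = 0.6, cutoff = 0, link = 4, displacement = 5`,
Brownian dynamics. The `percentile` is interpreted as a percentile (the
plugin's default semantics); an absolute-threshold mode is available since
the alternative reading cannot be ruled out.

# Droplet indexing and occupancy

The droplet mask is built from the first 667 nm frame (droplets are
immobilized in their wells; per-frame re-masking is available behind a
flag): Otsu threshold, hole filling, removal of components below 25% of the
expected droplet area, connected-component labelling. Centroids are sorted
into grid rows by y (clusters split at gaps larger than half the row
pitch), then into columns by x; border-touching droplets are flagged and
excluded from downstream statistics.

A track is assigned to a droplet when its *median* position lies within the
central 60% of the droplet area, i.e. within $\sqrt{0.6}\,R \approx 0.775 R$
of the centre — the area reading of "central 60%"; a radius-fraction
reading is available as a config option. The median is robust to
single-frame dropouts. Tracks in the outer annulus are discarded as
potential rim artifacts; tracks spanning fewer than 5 frames are ignored
(per-frame percentile thresholding admits transient noise maxima when few
cells are present; real cells persist, noise does not).

Occupancy per channel is the **maximum number of temporally co-existing
assigned tracks**: two real cells co-exist in every frame, whereas the
fragments of one interrupted trajectory never overlap in time, so
concurrency counts cells correctly even when a track is split. Class and
emulsion then follow from cross-channel reconciliation: 0 cells EMPTY,
1 cell SINGLE with the emulsion of its channel (GREEN→HG, UV→UT by
default), 2+ MULTI with the majority channel and a mixed flag.

# QC windows and statistics

The raw drop $\Delta\mathrm{pH} = \mathrm{pH}_i - \mathrm{pH}_f$ (first
minus last defined frame) feeds class-conditional QC windows: image-derived
single-cell droplets are kept in $[0.28, 1.02]$, reclassified as
debris/empty below and as multi-cell above; image-derived empty droplets
are kept up to $0.37$ and flagged as hidden cells above. The two windows
overlap on $[0.28, 0.37]$; they are applied *conditionally on the
image-derived class*, which resolves the overlap — each droplet sees
exactly one window. These thresholds are per-experiment configuration: they
were derived for a glucose-rich run whose &Delta;pH scale is several times
larger than the two-population experiment's (~0.2); pipelines on the
default synthetic scene use windows appropriate to that scale.

Encapsulation efficiency is kept single-cell droplets over all droplets;
per-class error rates are reclassified-or-flagged over evaluated
candidates. Group comparisons use the two-tailed pooled-variance Student's
t-test with the standard legend (ns, *, **, ***). Crosstalk analysis
samples 3 droplets per population (seeded), forms the positive/negative
mean-intensity ratio per wavelength over time, and calls the emulsion
stable when the ratio drifts less than 10% from its initial value.

# Numerical and scale choices

* Pixel calibration is a free choice (not fixed by the 10x optics): 1 µm/px
  puts a 60 µm droplet at 60 px in a 1014 px window of 13 wells.
* Frames are rendered in counts of a 16-bit range with a 5% background
  level and written as 16-bit TIFF; quantization contributes ~2e-5 pH to a
  droplet mean, negligible against every tolerance used. A 32-bit float
  TIFF mode exists for validation work; the exact forward/inverse identity
  (1e-6) is checked on in-memory frames.
* All randomness flows from one top-level seed through fixed per-position
  derivations; identical seed and parameters give byte-identical stacks,
  truth tables and stage outputs.
* Degenerate inputs are flagged rather than guessed at: ratios at the
  calibration endpoints are "saturated", traces leaving the working range
  "out of range", missing denominators "missing"; assignment ties in the
  linker are broken deterministically by the solver's column order.
* Desk-scale problem sizes: unit tests run 4x4 to 5x5 grids over 40-60 min
  simulated time; the acceptance checks run full 13x13 single-position
  scenes over the full 37-frame cadence, which keeps an end-to-end run in
  the low minutes on one core.

# Known limitations

* The generator's linear-in-time pH decay realizes each droplet's total
  drop over whatever observation window is configured; it does not model
  rate saturation or buffer capacity.
* Occupancy concurrency counting can, in principle, merge two real cells if
  one is detectable only early and the other only late in the run; with
  persistent labels this is rare.
* The grid indexer anchors row/column indices at the smallest cluster
  centre; a window missing its entire first row or column would shift
  indices by one.
* Error-rate accounting reuses the configured QC windows for all positions;
  no per-position threshold re-derivation is attempted.
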