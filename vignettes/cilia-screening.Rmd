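---
title: "Screening for primary-cilium disassembly: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for primary-cilium disassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliascreen)
```

## The assay

Most quiescent mammalian cells carry a single primary cilium that is
resorbed when the cell re-enters the cycle; serum growth factors trigger
this disassembly within a few hours in starved hTERT-RPE1 cells. A
live-cell high-content screen for compounds that either *induce* ciliary
disassembly or *block* serum-induced disassembly images each well of a
96-well plate twice with an automated microscope: a baseline run (IR1)
after starvation, and a post-perturbation run (IR2) a few hours after
serum and/or compound addition. Because the stage returns to the same
coordinates, the two runs give paired fields of the same cells. Each
field has two channels: W1 (Hoechst-stained nuclei, the per-cell
denominator) and W2 (a fluorescent reporter targeted to the ciliary
membrane).

`ciliascreen` implements the full analysis of such a screen — detection,
per-site and per-well metrics, baseline normalization, paired-field
quality control, and ranked hit calling — together with a plate
simulator that renders synthetic fields with exact ground truth, so that
every stage can be validated quantitatively without a microscope.

## Detection model

**Nuclei (W1).** Pixels above `nuclei_threshold` are labeled as
8-connected components. Components larger than the single-nucleus area
maximum are split by a watershed on the distance map (touching nuclei),
then components outside the `[nucleus_min_area_um2, nucleus_max_area_um2]`
band are discarded. A field in which ≥99% of W1 pixels exceed the
threshold is flagged unusable (saturation) rather than silently counted.

**Cilium objects, TF mode.** The screen's primary detector mirrors
dot/vesicle-counting analysis: W2 components above
`cilia_intensity_threshold` whose *longest axis* lies in
`[min_size_um, max_size_um]` are retained. Published settings for the
three reporter lines put the minimum at 1–2 µm and the maximum at
8–11 µm; the defaults (1.5 and 10 µm) sit inside those ranges. We
interpret "size" as the maximum Feret diameter because cilia are
elongated organelles of roughly 2–6 µm length and ~0.5 µm width: an
*area* reading of an 8–11 µm bound would be inconsistent with such
objects, while the longest axis matches both bounds naturally. An
equivalent-diameter reading remains selectable
(`tf_params(size_measure = "equivalent_diameter")`). The Feret measure
is computed as the maximum pairwise distance between pixel centers on
the component's convex hull plus one pixel of finite extent, so a single
pixel has Feret = 1 px.

**Cilium signal, MWS mode.** The alternative stained-area scoring
retains W2 objects passing a minimum intensity (settings 78–150 on the
conventional 8-bit scale; `intensity_8bit()` maps these onto the 16-bit
data), a size band (1–1.8 µm minimum, 5–10 µm maximum in published
settings), and a minimum stained area (settings 1.5–3). It reports total
positive stained area, mean stain area per object, and `pct_positive_w2`
— the percentage of cells owning at least one retained object. The unit
of the minimum stained area is not fixed by convention; we default to
µm² (`stained_area_unit = "px2"` is available). Object-to-cell ownership
is likewise not fixed by any published rule; we assign each object to
the nucleus whose territory contains its centroid, with territories
taken as the nearest-nucleus (Voronoi) partition — the practical
equivalent of watershed expansion from nucleus seeds, and exactly that
partition when nuclei are compact and similar in size.

Two further conventions are deliberate: thresholds are *fixed global
settings* (the screening workflow is settings-driven; a per-field Otsu
mode exists but is off by default), and objects touching the field
border are *retained* if their visible extent passes the filters —
excluding them would bias counts low at field edges by several percent.

## Metrics and normalization

Per field ("site data") we compute nuclei count, vesicle (cilium-object)
count, **vesicle count per cell** — the screen's primary ciliation
metric, cilium number normalized to nuclei number — total vesicle area,
vesicle area per cell, and the MWS scores when enabled. Fields with no
nuclei or flagged channels are unusable; their ratios are absent. Per
well ("summary data") we aggregate usable sites; the mean is the default
summary statistic and sums are kept alongside (`*_sum` columns).

The first screening step normalizes every well's IR2 summary to the mean
IR1 summary of the starved-vehicle control wells (maximal ciliation):

$$
\mathrm{score}(w) \;=\;
\frac{\overline{\mathrm{vcpc}}^{\,\mathrm{IR2}}_{w}}
     {\operatorname{mean}_{c\,\in\,\mathrm{vehicle}}
      \overline{\mathrm{vcpc}}^{\,\mathrm{IR1}}_{c}}
$$

A score of 1 means ciliation unchanged; 25% serum typically yields
0.4–0.8 in this epifluorescence format (a 20–60% apparent change — the
dynamic range is compressed relative to confocal scoring). The printed
convention divides by the controls' *baseline* run; because this leaves
any between-run drift of the controls uncorrected, a
`denominator = "control_ir2"` switch is provided, with the printed
convention as the default.

The second step reviews paired sites: per site, the IR2/IR1 ratios of
total vesicle area and of nuclei count. The manual practice of
eyeballing the nine image pairs of each primary-hit well is replaced
here by a reproducible robust rule: a pair is flagged `cell_loss` when
its nuclei ratio falls below 0.5, and `poor_quality` when its area ratio
lies outside median ± 3.5·MAD of the well's sites or when a partner
field is missing or unusable. Flagged pairs are excluded and scores
recomputed (`score_after_qc`). Exclusion typically tightens replicate
agreement, which is the point of the step. Both cutoffs are
configurable; no published numeric criterion exists for them, so the
defaults are this package's own.

## Hit calling

Each screen is configured for **one** direction — `induce_disassembly`
(hits score below vehicle) or `block_disassembly` (hits score above the
serum control); the two classes are never called in one run. Compound
wells are compared to the reference wells by a classic two-sample
pooled-variance t-test, one-sided in the declared direction, at the
replicate-well level (duplicate wells are the experimental unit;
site-level testing would be pseudo-replication). Compounds are ranked by
directional effect size, then p-value. The hit call uses the raw
p ≤ α (default 0.05); Benjamini–Hochberg adjusted p-values are reported
alongside for screens with many compounds. Compounds with fewer than two
scored wells are reported as "insufficient data", never silently
dropped. Meaningful hits in this assay often start as ~10% score
differences, which duplicate wells across two runs resolve reliably (see
the acceptance tests).

## The simulator

`generate_field()` renders what the detector sees:

* **Nuclei** — 2-D Gaussian blobs (~10 µm apparent diameter, amplitude
  10000 on a 16-bit scale over an 800-count offset), placed by rejection
  sampling with a 10.5 µm minimum center distance. Overlap is a confound
  the real assay avoids by seeding-density control (robust ciliation
  needs 15,000–20,000 cells per well, and too-dense wells lose
  ciliation), so we emulate the controlled regime rather than modeling
  clump segmentation.
* **Cilia** — anti-aliased thick segments (Gaussian cross-profile,
  0.5 µm nominal width, amplitude 40000) anchored just outside the
  nucleus; lengths are truncated-normal (mean 4, sd 1.2, range 2–6 µm).
  A cell is ciliated with probability `ciliation_fraction` (default
  0.85: starvation gives >80% ciliation in these models).
* **Background vesicles** — Gaussian spots whose per-cell rate, size and
  brightness define the three reporter profiles: `arl13b_low_bg`
  (0.05/cell, dim), `smo_moderate_bg` (0.5/cell, moderate),
  `mchr1_high_bg` (3/cell, large and bright, plus a serum-driven
  intensity boost applied only in this profile). The rates are ordered
  by construction and tested. No quantitative cilium-to-background
  intensity data are published for these lines; the absolute intensities
  are invented, chosen once so that the published analysis settings
  (threshold 78 on the 8-bit convention, 1–11 µm band) operate in a
  working regime for the clean reporter and visibly fail for the
  high-background one.
* **Noise** — Gaussian read noise (sd 150–250 by profile) plus a
  Poisson-like shot term (variance proportional to signal), quantized to
  16 bits.

`generate_site_pair()` renders IR1 and IR2 from one layout; the
perturbation flips ciliated flags for a `disassembly_fraction` subset
(latent per-cell uniforms couple the subsets, so a larger fraction loses
a superset of cilia — monotonicity is exact at fixed seed) and shrinks
surviving cilia. The serum default is a 0.4 disassembly fraction, the
middle of the observed 20–60% dynamic range. Two corruption modes
support QC testing: `cell_loss` removes 60% of IR2 cells and, because
the mechanical disturbance that detaches cells also shears cilia,
deciliates half of the survivors; `haze` adds a broad bright
low-frequency background to IR2's W2. Identical seeds give bit-identical
pixels and ground truth everywhere.

What the simulator does **not** model: 3-D structure and z-stacks, a
real optical PSF (Gaussian profiles stand in), cell migration between
runs, focus drift, illumination gradients, or mitotic figures. Passing
tests therefore demonstrate that the *analysis chain* is correct and
well-calibrated under controlled imaging physics — not that the specific
default thresholds transfer to any particular microscope, which always
requires the settings-titration step the workflow prescribes.

## Numerical choices and degenerate inputs

* 8-connected components; pixel size default 0.325 µm/px at 1024×1024
  (20× objective class; tests and examples use 512 or 256 px fields for
  speed, which only reduces cells per field).
* Feret = hull max pairwise center distance + 1 px; a 1-px object has
  Feret 1 px.
* Saturation = ≥99% of a channel above threshold → field unusable.
* Zero-nuclei fields: per-cell ratios absent, field unusable; wells with
  zero usable sites are excluded with a message; a zero or undefined
  control baseline aborts the screen as invalid.
* Area ratios with a zero IR1 denominator: 1 when IR2 is also 0,
  infinite (and flagged) otherwise.
* The MAD in the QC rule uses the usual 1.4826 consistency constant; a
  zero MAD (identical ratios) flags any deviating site.

## Problem sizes used in validation

The acceptance tests run, per criterion: 50 planted fields plus rendered
reporter fields (oracle equality, exact); 15 planted bars across three
pixel sizes (size band); 100 simulated wells × 9 sites at 512 px
(ciliation recovery); 3 disassembly levels × 50 seeds at 256 px (effect
recovery); two 20-well plates with 5% corrupted sites (QC); and, at the
metric level — the simulator's ground truth converted directly to site
metrics via `truth_site_metrics()` — 200 single-compound null plates
plus 50 full 20-compound null plates for type-I error, and 130 screens
for hit recoverability. The type-I check is split deliberately: on a
full screening plate every compound shares the vehicle reference group,
so hit calls are correlated and only a cluster-robust interval is a
valid yardstick there, while the single-compound plates give genuinely
independent Bernoulli trials for the binomial interval. Statistical calibration depends
on the sampling distribution of the metrics, not on re-detecting pixels,
so the metric-level route is the package's deliberate choice for those
two purely statistical checks; rendering fidelity is covered by the
other criteria.

## Worked example

```{r, eval = FALSE}
library(ciliascreen)

design <- design_screen_96(mode = "induce_disassembly", seed = 1)
plate  <- generate_plate(design, sim_profile("arl13b_low_bg"),
                         dim = c(512, 512), dir = "images")
sites  <- analyze_plate(plate)
screen <- run_screen(sites, design, mode = "induce_disassembly")

tidy(screen)     # ranked compound table
glance(screen)   # one-row summary
autoplot(screen) # plate heat map of post-QC scores
```

The same pipeline is available from the shell via the thin CLI at
`inst/cli/ciliascreen.R` (`simulate`, `analyze`, `run` subcommands over
a YAML `run_config()`).

## Known limitations

* Cilium *length* is only proxied by the longest-axis measure; true
  morphometry needs confocal imaging and is out of scope.
* The t-test with duplicate wells has low power per compound; the screen
  is a ranking instrument, and the ~10% planted-effect recoverability
  test reflects that usage.
* The MCHR1-like profile demonstrates the failure mode of
  threshold-based counting under heavy vesicular background; no settings
  shipped here rescue it, matching practice (that line is used for
  confocal validation, not automated screening).
* Dose–response fitting and Z′-factor assay statistics are deliberately
  not included.
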