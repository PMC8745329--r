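---
title: "Multiparameter analysis of thrombus formation under flow: models and methods"
author: "thrombusflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparameter analysis of thrombus formation under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombusflow)
```

## The assay and what this package computes

Whole blood perfused over collagen microspots in a parallel-plate flow
chamber forms platelet thrombi whose growth, contraction, procoagulant
activity and fibrin deposition can be followed by four-channel microscopy:
brightfield (thrombus structure), DiOC6 (adhered platelets), AF568-annexin
A5 (phosphatidylserine-exposing platelets) and AF647-fibrin(ogen) (fibrin
formation). Co-coating the collagen with tissue factor (TF) triggers the
extrinsic coagulation pathway and accelerates thrombin and fibrin
formation. A three-way inlet lets the perfusate switch from untreated to
inhibitor-treated blood at a chosen moment, separating the *early*
(0–2 min) from the *late* (2–10 min) contribution of each platelet or
coagulation pathway.

Each microspot and time point is summarised by seven parameters:

| Parameter | Channel | Meaning | Unit |
|---|---|---|---|
| P1 | DiOC6 | platelet adhesion | % SAC |
| P2 | brightfield | thrombus coverage | % SAC |
| P3 | brightfield | thrombus morphology | score 0–5 |
| P4 | brightfield | thrombus contraction | score 0–3 |
| P5 | brightfield | thrombus multilayering | score 0–3 |
| P6 | AF568-annexin A5 | PS exposure | % SAC |
| P7 | AF647-fibrin | fibrin deposition | % SAC |

SAC is surface-area coverage: the percentage of field-of-view pixels
covered by the channel's binary mask.

`thrombusflow` implements the full computational chain — a seeded simulator
of thrombus kinetics with switchable interventions, a renderer that turns
kinetic states into realistic four-channel 8-bit image stacks with ground
truth, the segmentation chain, parameter extraction, and the heatmap
statistics — so the whole pipeline can be validated end to end against
known ground truth.

## Flow arithmetic

The wall-shear rate of laminar flow between parallel plates is
$\gamma_w = 6Q/(wh^2)$. With the default chamber (height 50 µm, width
3.0 mm) a flow of 75 µL/min gives the arterial operating point of
1000 s⁻¹:

```{r}
wall_shear_rate(flow_geometry(flow_ul_min = 75))
```

Blood mixes in-line with recalcification medium (63 mM CaCl2, 32 mM MgCl2)
at 10:1, so final concentrations are stock × 1/11:

```{r}
final_concentration(mixing_spec(), "CaCl2")
```

## The kinetic model

What is known about these kinetics at the assay level are curve shapes and
directional effects, not rate constants, so the simulator uses the
simplest model that reproduces them: seeded logistic growth per process,

$$\frac{dC}{dt} = f \, r \,(C + c_0)\left(1 - \frac{C}{K}\right),$$

for platelet adhesion, thrombus (aggregate) coverage, PS exposure (driven
by the adhered-platelet pool) and fibrin coverage, plus relaxation
equations for the continuous contraction and multilayering levels (0–3).
Fibrin formation starts after an onset delay: about 4 min on collagen/TF,
beyond the 10-min observation window on collagen alone. Surface-specific
rates make collagen/TF faster than collagen for every thrombus-related
process (the stimulating role of TF).

An intervention preset multiplies the process rates by factors $f \in
[0,1]$ from the switch time onward (`intervention_presets()` prints the
table). Two mechanistic rules encode thrombin's role:

* **Extrinsic initiation commits early.** TF/FVIIa-driven initiation is
  complete within the first two minutes, so the FVIIa inhibitor preset is
  flagged `initiation_only`: present from 0 min it abolishes fibrin
  formation entirely; introduced at 2 min it changes nothing.
* **Thrombin consolidates thrombi on TF surfaces.** The integrin
  αIIbβ3-antagonist preset (tirofiban) zeroes new aggregation and adds a
  detachment term (0.3/min) on established thrombi. On collagen alone the
  detachment acts for as long as the inhibitor flows — established thrombi
  are dismantled retroactively. On collagen/TF the detachment only acts
  within the initial two-minute window; after thrombin commits, pre-formed
  thrombi stay intact and only further build-up is blocked.

Biological variability is multiplicative log-normal noise on the process
rates at two levels: donor factors (σ = 0.15, shared by all runs of one
donor, which makes the design paired) and run factors (σ = 0.10, per flow
run, which is what replicate averaging suppresses). Published figures
report means ± SD only, so these σ are plausible settings, not estimates;
they give visible but non-dominant spread.

```{r}
cfg <- flow_run_config("collagen_TF", "vehicle", seed = 7)
simulate_kinetics(cfg, noise = "none")
```

## The renderer

`render_images()` turns each kinetic state into the four 8-bit channels.
The native acquisition geometry is 1360 × 1024 px at 0.108 µm/px
(`render_config(full_size = TRUE)`); the default raster is quarter scale
(340 × 256), since SAC and all downstream statistics are scale-free, and
area cut points scale with the squared pixel ratio. Platelets are small
discs; thrombi are clustered aggregates whose radius grows with the
multilayering level and whose satellite raggedness falls with the
contraction level; contracted aggregates get dark cores in brightfield and
multilayered ones bright cores in DiOC6. Fibrin renders as high-intensity
fiber segments anchored on thrombi over a dim fibrinogen haze, so the
fibrin/fibrinogen threshold discrimination is genuinely exercised. Every
channel receives Gaussian read noise (σ = 6) and a low-frequency
illumination gradient (amplitude 20) that the FFT background filter must
remove. Shapes are stamped until the mask reaches the state's coverage, so
stored masks match the true coverages to well under one percentage point.

What the renderer does *not* emulate: optical blur and diffraction,
shot-noise statistics, focal drift, chamber debris, or the continuous
texture of real platelet carpets. Passing the recovery tests therefore
shows the chain is correct on well-posed images, not that it is robust to
every real-world artefact — threshold resetting against QC overlays exists
precisely because real data need per-experiment tuning.

## The segmentation chain

Per channel: (1) brightfield is inverted (thrombi are dark on bright);
(2) `fft_background_filter()` attenuates spatial frequencies below the
cutoff with a smooth high-pass mask $H(f) = 1 - e^{-(f/c)^4}$, after
mirror-padding the image to avoid wrap-around ringing; (3) the directional
opening `morphological_clean()` (horizontal then vertical line elements,
default 3 px) removes speckle; (4) `threshold_channel()` binarizes;
(5) components under `min_object_area` (4 px²) are dropped. The AF647
channel instead uses `fibrin_discriminate()`: a fixed high threshold
(default 120) that keeps strongly labelled fibrin fibers and rejects the
low-intensity fibrinogen haze, followed by the same cleanup.

Two numerical choices deserve explanation:

* **Cutoff 1.5 cycles/image for all channels.** The illumination field
  varies over at most ~1 cycle; the smallest structures worth keeping
  (platelets, aggregates) live at ≥ 3 cycles. The steep quartic mask edge
  separates the two. Higher cutoffs hollow out large aggregates: an object
  spanning a fraction $s$ of the field has most of its spectral energy
  below $1/s$ cycles, so a 60 %-coverage carpet is destroyed by any cutoff
  much above 1–2 cycles.
* **Fixed threshold (8) as default rather than Otsu.** After the
  high-pass, the background is clipped to exactly zero; a threshold just
  above the residual noise floor then binarizes correctly at any coverage.
  Otsu's method is implemented and exact (it matches an exhaustive
  256-level search), but when foreground spans most of the field the
  filtered foreground smears over a wide range and Otsu splits it rather
  than separating it from the empty background. The fixed default also
  mirrors how the semi-automated scripts this chain models are actually
  operated: thresholds are per-channel settings, verified against QC
  overlays (`overlay_qc()`) and reset when the overlay looks wrong.
  Ordering is grayscale-morphology-then-threshold by default;
  `morphology_on = "binary"` gives the other order, and tests check the
  two agree to within 2 % SAC.

## Ordinal scores P3–P5

In the laboratory these are visual scores; the package provides automated
proxies with explicit rules, which track the simulator's ground truth
(Spearman ≥ 0.9) but make no claim to replicate human judgment:

* **P3 morphology (0–5)** classifies connected components by area —
  single platelet < 200 px², small aggregate < 2 000 px², medium
  < 10 000 px², big ≥ 10 000 px² at full resolution — and returns the
  highest class present; 0/1/2 are decided by component count and SAC
  ("widespread" = ≥ 50 single-size components and SAC ≥ 5 %).
* **P4 contraction (0–3)** combines compactness with darkening. Compactness
  is *fill solidity*: mask area divided by the area of its closed,
  hole-filled envelope. (Convex-hull solidity, the textbook measure, stops
  working once aggregates merge at high coverage — a fully contracted
  50 %-coverage field scores ~0.79 on hull solidity simply because the
  union of thrombi is not convex.) Darkening is the fraction of mask
  pixels with brightfield intensity below 70. Bins: ≥ 0.90/0.50 → 3,
  ≥ 0.80/0.30 → 2, ≥ 0.70/0.10 → 1.
* **P5 multilayering (0–3)** bins the fraction of thrombus pixels whose
  DiOC6 intensity exceeds 180 (stacked platelets render brighter):
  ≥ 0.5 → 3, ≥ 0.25 → 2, ≥ 0.08 → 1.

## Statistics

The statistics stage follows the assay's reporting conventions exactly:

1. `average_replicates()` — one parameter set per donor and condition
   (arithmetic mean over duplicate/triplicate runs).
2. `scale_records()` — univariate scaling of each parameter onto 0–10
   across *all* conditions, surfaces and time points of the experiment set
   (so heatmap panels are comparable; `scope = "surface"` scales per
   surface instead). Scaling before subtraction keeps the paired design
   well defined, and since the map is affine per parameter it leaves
   t-statistics unchanged.
3. `paired_t_test()` — two-sided paired Student's t-test per cell across
   donors, $t = \bar d / (s_d/\sqrt n)$, $df = n-1$. Sidedness is not
   specified in the assay's convention; two-sided is the conservative
   choice. No multiple-testing correction is applied by default (each cell
   is reported at its raw p, as the assay does); `p_adjust = "BH"` is
   available.
4. `subtraction_heatmap()` — scaled treated minus scaled reference per
   cell; with the relevance filter, cells with p ≥ 0.05 are set to zero
   (visually "no relevant change") rather than dropped, and the unfiltered
   deltas are always kept in the CSV.

The reference condition must be chosen explicitly (`reference_preset`,
optionally `reference_surface`), because published analyses subtract
against the vehicle on the same surface in some figures and against a
fixed reference surface in others.

Degenerate cells: a constant parameter series scales to all zeros with a
warning; zero-variance paired differences give p = 1 when the mean
difference is zero and p = 0 (with a warning) otherwise.

Under the simulator's null (two vehicle arms per donor differing only in
run noise), the paired test holds its nominal size on growth-phase cells
(2–6 min): the p < 0.05 fraction is ≈ 0.034 over 2 000 cohorts. On
late, saturated cells the test becomes conservative (fraction ≈ 0.02):
near carrying capacity the log-normal rate noise is squashed into
heavy-tailed differences. This is a property of the saturating simulator,
worth remembering when interpreting late-time p-values.

## Problem sizes and determinism

The default test and demonstration scale is quarter-resolution rasters,
2–3 donors with duplicate runs, and five time points — the pipeline's
statistics are scale-free, and these sizes keep a full synthetic study in
the minutes range on one CPU. Full-resolution rendering
(`full_size = TRUE`) is available for realistic image sizes. All
randomness derives from one integer seed per run; donor-level factors
depend only on (seed, donor), run-level factors on the full run identity.
Re-running any stage with the same configuration reproduces its CSV
outputs byte-identically.

## Known limitations

* The kinetic model is phenomenological; rate constants are set to
  reproduce directional behaviour, not fitted to data (published curves
  are not tabulated).
* P3–P5 proxies are rule-based stand-ins for visual scores; their absolute
  values should not be compared against human scoring without calibration.
* The brightfield thrombus mask and the DiOC6 platelet mask are treated as
  independent channels; the package does not attempt to reconcile P1
  versus P2 when thrombi are translucent.
* Segmentation defaults are tuned on the package's own renderer; real
  microscopy will need per-experiment threshold verification via the QC
  overlays.
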