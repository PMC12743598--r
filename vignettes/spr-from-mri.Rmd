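---
title: "Estimating proton stopping-power ratios from hydrogen-concentration MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating proton stopping-power ratios from hydrogen-concentration MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrispr)
```

## The model

Proton range prediction needs the tissue–water linear stopping-power ratio
(SPR) per voxel. The package's central observation is geometric: over the
adult reference tissues, plotting SPR at 100 MeV against the tissue–water
hydrogen-concentration ratio

$$H = \frac{w_H/100 \cdot \rho_\mathrm{tissue}}{w_H/100 \cdot \rho_\mathrm{water}}$$

produces one tight line for soft and bone tissues together. Soft tissues
cluster near $H \approx 1$; bone tissues extend the line downward in $H$
and upward in SPR because hydroxyapatite (Ca, P) displaces water — the
bone-mineral fraction is strongly anti-correlated with the hydrogen
fraction (`bone_mineral_correlation()` gives about $-0.99$ over the bone
media), which is precisely why a hydrogen measurement predicts bone SPR so
well. The calibration is an ordinary least-squares fit

$$\widehat{SPR} = a\,H + b$$

over soft + bone media (`spr_calibration()`), with two dedicated side
models:

* **Lung.** The inflated lung sits far off the joint line because air
  dilutes both $H$ and SPR by the same density factor. Air, inflated and
  compressed lung therefore define their own almost-proportional line
  (`build_lung_model()`), fitted unconstrained — the data come so close to
  the origin that forcing a zero intercept would buy nothing and hide fit
  quality. Density-scaled variants of the inflated lung (±2, ±10, ±20 %)
  are an *evaluation* set, not fit points: the three base media define the
  line, and the variants' RMS relative difference (about 0.05–0.1 %)
  quantifies how well the density-scaling assumption holds.
* **Adipose.** Adipose is the largest soft-tissue outlier of the joint
  line (about +8 % at 100 MeV). Across the reference adipose grades, SPR
  falls linearly with lipid weight fraction (`build_adipose_lipid_model()`),
  so voxels with a lipid fraction above a threshold (default 50 %, inside
  the reported 59.6–81.2 % adipose range) are routed to the lipid line
  when a lipid map is available (`route_and_predict()`).

Model quality is expressed the way a measurement-uncertainty budget needs
it: signed percent differences $\delta_i = 100\,(\widehat{SPR}_i -
SPR_i)/SPR_i$, summarised by their RMS (Type A, `type_a_rms()`) or by a
rectangular distribution over their observed range (Type B,
`type_b_rectangular()`), composed by root sum square with
Welch–Satterthwaite effective degrees of freedom (`build_budget()`).

## Reference data and the water reference

The packaged composition table (`icru46_compositions()`) was transcribed
from the standard compendia (ICRU 46 / Woodard & White). Two choices
matter numerically:

* **Water hydrogen fraction, tissue side.** The compendia print water's
  hydrogen weight fraction as 11.2 % (three significant figures), and only
  that value reproduces the published three-decimal $H$ column for all 34
  media (11.19 % fails for liver, skin and cartilage by one unit in the
  last digit). `water_reference("icru46")` therefore uses 11.2 % with unit
  density on the tissue side, while the phantom chemistry uses the
  molar-mass value $2 \cdot 1.008 / 18.015 = 11.19\,\%$
  (`water_reference("molar")`) because there every quantity flows from the
  same molar arithmetic.
* **Congested lung.** One row could not be transcribed from a primary
  source; it was reconstructed (density 1.04 g cm⁻³, $w_H$ 10.5 %) to be
  consistent with the published hydrogen ratio and SPR of that tissue, and
  is flagged in the data documentation.

The alternative-composition table (`alt_compositions()`) is a
representative subset — three Woodard & White adipose grades with lipid
fractions, grade-1/3 soft-tissue variants, ICRP 110 media including air
and compressed lung, and Hough et al. bone samples. Rows that are
reconstructions rather than verbatim transcriptions carry
`note == "reconstructed"`. The subset exercises the composition-variability
machinery; it is deliberately not claimed to reproduce any particular
published Type B value, which depends on the full 105-sample set.

## Stopping-power computation

`spr_bethe()` uses the first-order Bethe formula with Bragg-additivity
mean excitation energies,

$$\ln I = \frac{\sum_i w_i Z_i/A_i \, \ln I_i}{\sum_i w_i Z_i/A_i},$$

elemental $I$-values from the ICRU 37/49 convention, $m_e c^2 =
0.511$ MeV, $m_p c^2 = 938.272$ MeV, and molar masses at four significant
figures. Two deliberate simplifications:

* **No shell, Barkas or density-effect corrections.** In the tissue-to-
  water *ratio* at therapeutic energies these corrections cancel to well
  below the percent scale of the budget.
* **The water denominator uses the same Bragg-additivity rule as the
  numerator** (giving $I_w \approx 69$ eV) rather than a fixed 75 eV.
  This makes water-vs-water exactly 1 at every energy by construction and
  lets the first-order bias cancel consistently; with this convention the
  computed 100 MeV SPR matches the published column within 0.56 % for all
  34 media (a fixed 75 eV denominator would shift all ratios by about
  1.5 %). Users who want a different $I$-value set can supply their own
  element table.

SPR is stable in energy: over 70–230 MeV every medium stays within 0.5 %
of its 100 MeV value, and the fit/composition uncertainties drift by less
than 0.06 % (`energy_sweep()`), comfortably inside the 0.14 % envelope the
budget assigns to energy sensitivity.

## Group assignment and reported statistics

The published group-wise statistics do not state explicitly where water
and cartilage were pooled. The package's default — water with the soft
tissues, cartilage with the skeletal ones, matching the reference table's
layout — reproduces the soft-tissue RMS exactly (2.51 %) and the bone RMS
to one rounding unit (0.93 vs 0.94 %). `assign_groups()` makes the
assignment explicit and reversible. Because the packaged reference table
prints $H$ and SPR at three decimals while the original statistics used
full-precision values, each per-tissue $\delta$ carries up to ~0.15 % of
input-rounding slack; that envelope is the tolerance used wherever the
published RMS values are asserted (it is also why the soft-without-adipose
RMS computes to 1.76 % against a published 1.70 %). Percentages are
rounded to two decimals only at the reporting layer; all internal values
keep full precision.

## Phantom chemistry

The dilution phantom replaces part of the light water with D₂O, which is
invisible at the hydrogen resonance, so the hydrogen ratio of a solution
is tunable from 1 down to 0. Constants: $M_H = 1.008$, $M_{H_2O} =
18.015$, $M_{D_2O} = 20.028$ g mol⁻¹; default component densities
$\rho_{H_2O} = 0.998$, $\rho_{D_2O} = 1.105$ g cm⁻³ at room temperature,
all overridable. The ideal-mixture density is the mass-weighted harmonic
mean; real D₂O–H₂O solutions deviate from it (partial molar volume
effect), so a measured density always overrides the ideal estimate, and
`partial_molar_deviation()` quantifies the discrepancy. `design_solution()`
inverse-solves the chain for a target hydrogen ratio; round-trips recover
targets in 0.30–1.00 to far better than the 0.005 design tolerance, and
reconstructing the published ten-solution table from its printed weight
fractions reproduces the printed hydrogen ratios at two decimals.

## Image analysis

SNR follows NEMA Method 4: mean voxel value of a 12 mm solution ROI
divided by the mean of four 3 mm background ROI means, repeated over five
slices and averaged. Numerical conventions, chosen where the protocol is
silent:

* **Voxel membership**: a voxel belongs to an ROI when its *centre* lies
  strictly inside the circle; centres sit at `origin + (index − 1) ·
  spacing`. The rule is deterministic and resolution-stable, and the
  synthetic renderer uses the same rule (no partial-volume supersampling),
  so analysis and generation are exactly consistent.
* **Background geometry**: container wall thickness defaults to 1 mm; the
  four background ROIs sit at 90° intervals with centres at
  $19 + 1 + 3 + 3 = 26$ mm from the container centre, putting the near ROI
  edge 3 mm outside the outer wall. All radii are configurable.
* **Raw background mean**: no Rayleigh correction factor is applied to the
  background mean — the ratio is used exactly as the method defines it.
* Images are exchanged as a plain-text gridded format (one CSV per slice
  plus a YAML sidecar with spacing and origin; `write_image_series()` /
  `read_image_series()`). FSE vs GRE is metadata only; no pulse-sequence
  physics is modelled.

## The synthetic phantom: what it does and does not show

`phantom_layout()` packs up to 12 containers (inner radius 19 mm, 240 mm
field of view, 256² matrix) on a hexagonal grid with a 50 mm pitch — wide
enough that every background ROI ring stays clear of neighbouring
containers. `render_phantom_series()` programs each container's noiseless
intensity as `gain × h_ratio` and applies Rician noise (Gaussian on two
quadrature channels, magnitude taken). Defaults `gain = 163`, `noise = 1`
put the programmed SNR at roughly 39–131 over hydrogen ratios 0.30–1.00,
the range of the reference FSE measurements. The analytic Rician mean
(`truth_snr()`, via scaled Bessel functions so high SNR does not overflow)
is the independent oracle: measured five-slice SNR agrees with it within
three standard errors, and the SNR-vs-$H$ fit recovers $R^2 \ge 0.99$.
Noiseless renders replace the zero background by a small intensity floor
(`floor_eps`) so the pipeline stays defined and exactly reproduces the
programmed ratio.

An optional linear shading field (relative gradient across the field of
view) emulates receive-chain non-uniformity *at the image level*; it is
the mechanism by which phantom repositioning produces non-zero positional
deltas, and it makes the positional RMS grow monotonically with the
injected displacement. It is a knob for testing the positional machinery,
not a coil model. The generator deliberately omits k-space effects, coil
sensitivity maps, bias fields and susceptibility distortion, so passing
its tests demonstrates the correctness of the analysis chain — ROI
statistics, Method-4 arithmetic, averaging, calibration, uncertainty
propagation — but says nothing about sequence-dependent artefacts in real
scanner data (the GRE sequence's distortion sensitivity, for instance, is
outside its reach).

## Budget conventions

The budget rows mirror the standard five-component layout: regression fit
(Type A), composition variability (Type B), energy sensitivity (a recorded
drift with no degrees of freedom, excluded from $\nu_{eff}$), positional
SNR (Type A) and voxel-level SNR (Type A). The degrees-of-freedom registry
(`default_dof()`) assigns $\nu = 5$ to the lung fit (six density-scaled
samples), a conservative $\nu = 10$ to lung composition variability,
$\nu = 19$ to the positional comparison (20 pooled deltas) and $\nu = 149$
to the voxel-level statistic (150 slice/solution combinations). How the
positional SNR uncertainty propagates into SPR units is not prescribed by
the method definition; the budget therefore accepts those components as
inputs rather than asserting a propagation rule. With the published
component values the composites are 6.89 % (soft), 2.99 % (bone; the
published 3.00 reflects unrounded internals) and 1.92 % (lung), with
$\nu_{eff} \approx 128.8$ for lung; a ±2 % mass-density what-if
(`density_sensitivity()`) raises soft to 8.42 % and bone to 4.43 %.

## Problem sizes and limitations

The test suite and the acceptance script run entirely at the scale of the
real analysis: 34 reference media, a 20-row alternative-composition
subset, ten phantom solutions, and synthetic series of five 256² slices
with up to ten containers — a few seconds in total; the synthetic
pipeline needs no down-scaling. Known limitations:

* the calibration is only as good as the reference compendia; the
  alternative-composition subset spans, but does not exhaust, reported
  inter-individual variability;
* soft-tissue SPR is intrinsically harder: water/lipid trade-offs barely
  move $H$ while they do move SPR, which is what the 2.51 % soft RMS and
  the adipose route reflect;
* mass-density uncertainty of the reference tables is handled only as a
  what-if, since no systematic estimate of it exists;
* lipid-map workflows (chemical-shift-encoded MRI) are out of scope: the
  adipose route assumes a lipid fraction is supplied.
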