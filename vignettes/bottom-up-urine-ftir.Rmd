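---
title: "Bottom-up simulation of urine ATR-FTIR spectra: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up simulation of urine ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uirsim)
```

## The mixture model

`uirsim` treats the mid-infrared absorbance spectrum of liquid urine as a
linear combination of the spectra of its dissolved components. Every
component standard is an *aqueous* solution measured at a high standard
concentration $s_i$ (mg/L), so its spectrum $b_{i,j}$ already contains a
water contribution. For a sample with component concentrations $c_i$ the
simulated absorbance at wavenumber $j$ is

$$A_j \;=\; \sum_{i=1}^{n}\Big[\tfrac{c_i}{s_i}\, b_{i,j}
  + \big(1 - \tfrac{c_i}{s_i}\big) w_j\Big] \;+\; \varepsilon_j,
  \qquad \varepsilon_j \sim \mathcal N(0, \sigma_j),$$

where $w_j$ is the water spectrum and $\sigma_j$ the per-wavenumber
instrument noise. The assumptions are those of any linear mixing model:
absorbances add, band shapes do not depend on concentration, and
solute–solute or solute–water interactions are neglected. This is a good
approximation for dilute liquid samples measured directly (no drying), and
it is exactly the regime the package targets.

**Two water conventions.** As written, the sum carries one water term per
component, so an all-zero blank equals $n\,w_j$. This is harmless in
practice — baseline correction and SNV remove constant offsets before any
model sees the data — but it is not physical. Both conventions are
implemented in `simulate_spectrum()`: `"verbatim"` (the default, the formula
above) and `"single_water"`,
$A_j = \sum_i \frac{c_i}{s_i}(b_{i,j} - w_j) + w_j + \varepsilon_j$, which
keeps exactly one water contribution. Because downstream preprocessing
eliminates the difference between the two for all results in this package,
the choice is documented rather than consequential; tests assert the
closed-form limits of both.

Concentrations above the standard ($c_i > s_i$) extrapolate the linear
model outside the measured range; the simulator warns but proceeds, since
moderate extrapolation is exactly what a high preconcentration factor
produces.

## The synthetic component library

The packaged library stands in for measured single-component standards. It
covers the 13 calibration components of an artificial-urine recipe
(urea, creatinine, albumin, glucose, two sulfate salts, a phosphate salt,
citrate, ammonium chloride, bicarbonate, and three IR-silent chloride
salts). Each absorbing component is a sum of Gaussian bands; band *centers*
follow the accepted positions of the dominant urine bands (urea at 1626,
1599 and 1466 cm⁻¹, sulfate near 1100 cm⁻¹, phosphate near 1080 cm⁻¹, the
protein amide I/II bands at 1652 and 1548 cm⁻¹), while band widths and
heights are fixture choices calibrated to typical single-bounce diamond-ATR
absorptivities (e.g. tens of milli-AU for protein amide bands at 15 g/L).
The urea doublet widths (FWHM 22 and 20 cm⁻¹) were chosen so the two bands
remain resolved as distinct local maxima on the 2 cm⁻¹ grid, as they are in
measured urine spectra. CaCl₂, KCl and NaCl absorb nothing in this range;
their standards equal the water spectrum, with an optional hook
(`salt_water_perturbation`) for users who want salt-induced reshaping of the
water bands.

Standard concentrations $s_i$ are set to roughly ten times the midpoint of
each component's physiological reference range, mirroring the bench practice
of measuring standards at 10–20× physiological levels to maximize
signal-to-noise. The water spectrum is itself a fixture: broad O–H
stretching and bending bands near 3400 and 1640 cm⁻¹ plus a libration
shoulder. All of these tables ship as editable CSVs under `inst/extdata/`
(`components.csv`, `bands.csv`).

The calibration ranges widen each literature reference range by the same
rule throughout the table — lower bound = reference minimum / 1.5, upper
bound = reference maximum × 1.2. The MgSO₄·7H₂O upper bound is stored as
2181.83 mg/L (= 1818.19 × 1.2) by that rule; a commonly transcribed value
for this bound drops a digit (218.83), which would invert the range and is
rejected by the `component_range` validator.

**Axis convention.** Spectra live on a uniform, strictly ascending
wavenumber grid; the default is 450–4000 cm⁻¹ at 2 cm⁻¹ point spacing (the
usual storage grid for a 4 cm⁻¹ nominal instrument resolution). Files with
descending axes are accepted and normalized on read, with the reversal
recorded in metadata.

## Noise

Noise is additive, Gaussian and independent per wavenumber — the model one
obtains by estimating the standard deviation of repeated blank acquisitions
at each wavenumber (`estimate_noise_model()`, which is exactly that sample
standard deviation). For grids over scan counts, `parametric_noise_model()`
synthesizes the noise library: $\sigma(\text{scans}) =
\sigma_1/\sqrt{\text{scans}}$, optionally shaped by a wavenumber profile.
The absolute 1-scan levels are fixture parameters, not reproductions of any
measured instrument: 1×10⁻³ AU for the portable single-reflection
instrument (`spectrum_two`) and 8×10⁻⁴ AU for the benchtop
(`spectrum_3`), flat across wavenumber — typical magnitudes for this class
of FT-IR hardware. No 1/f or correlated structure is modelled.

## Concentration designs

Calibration sets use a 49-run, seven-level multilevel design whose columns
are cyclic rotations of a single 49-entry base sequence over coded levels
−3…+3 (each level appearing exactly 7 times per column). The exact
generating sequence for such designs is a free choice; the packaged
sequence was found once by a deterministic offline search (simulated
annealing plus steepest-descent swaps) minimizing the maximum absolute
circular autocorrelation over the 12 lags a 13-factor design uses. The
frozen optimum reaches max |r| = 3/196 ≈ 0.0153 between any two columns —
near- rather than exactly orthogonal — and construction fails loudly if the
invariant (max |r| ≤ 0.05, exact level counts) is ever violated.
`orthogonality_report()` exposes the check, and the base sequence is
recorded in the design object.

Coded levels map affinely onto each component's calibration range
(`levels_to_concentrations()`): level −3 hits the range minimum, +3 the
maximum, with equal spacing between — the natural reading of a "calibration
range" bracketing a reference range.

Population-like sets are sampled from a multivariate normal
(`sample_concentrations()`) with user-specified means, SDs and correlation
matrix; negative draws are truncated to zero (the count is recorded). The
packaged correlations among urea, creatinine, sulfate and phosphate — all
of which co-vary with urine concentration — are **placeholders** (0.5–0.65,
verified positive-definite) that quantitative users must override with
measured values.

## Pretreatment

`apply_pretreatment()` models ultrafiltration through a 10 kDa membrane:
protein-class components are multiplied by a per-sample realized
preconcentration factor, while low-molecular-weight metabolites and salts
equilibrate across the membrane and are unaffected by concentration itself;
only cleaning steps (re-dilution and re-centrifugation) touch them,
multiplying each by 0.05 per step (0.0025 after two steps). The realized
factor is drawn per sample — not per batch — from
$\mathcal N(\mu = \text{nominal}, \sigma = 0.15\,\mu)$, reflecting the
irreproducibility of the final retentate volume; the 15 % default CV is the
empirical figure for this device class. Draws are floored at 1 % of nominal
(a Normal tail guard the physical process cannot reach; events are
counted). One factor applies to all protein components of a sample, since
there is a single retentate volume.

Two reproducibility contracts matter for grid comparisons, and both are
enforced by sample-indexed random streams derived from the master seed:
conditions sharing an instrument and scan count receive *identical* noise
realizations, and all conditions share the preconcentration-error
quantiles. Grid differences between conditions are therefore systematic,
never Monte Carlo artifacts, and every dataset stores its realized factors
for exact replay.

## Preprocessing

The fixed chain is: weighted least-squares baseline → SNV → Savitzky–Golay
first derivative → mean centering. The first three are per-spectrum and
split-independent; centering is the only fitted step and is refit inside
every cross-validation fold (it lives inside the PLS fit).

- **WLSB** iteratively fits a polynomial by weighted least squares,
  down-weighting points above the current baseline (weight 0.001 versus 1
  below). The published descriptions of this step omit its parameters;
  defaults are polynomial order 2, asymmetry weight 0.001, at most 100
  iterations, stopping when the weight pattern or the baseline itself
  stabilizes. Non-convergence warns and returns the last iterate rather
  than failing a whole batch.
- **SNV** centers and scales each spectrum to unit SD; it errors on
  constant spectra (no meaningful normalization exists).
- The **derivative** uses a 7-point, order-2 Savitzky–Golay filter
  (endpoints handled by the within-window polynomial fit) and divides by
  the axis spacing so results are per cm⁻¹ and grid-invariant.
- **Region selection** is inclusive, with off-grid bounds snapping outward;
  preprocessing is applied to the full stored range first and the region cut
  afterwards, so derivative edge effects never sit at region boundaries.
  The packaged regions are 1000–1680 cm⁻¹ (creatinine), 1380–1680 cm⁻¹
  (albumin) and 950–1770 cm⁻¹ (albuminuria classification).

## Chemometrics

PLS is NIPALS PLS1 — deterministic, the chemometrics convention — with the
regression vector $\beta = W(P'W)^{-1}q$ and X/y mean-centering stored in
the model. PLS-DA regresses a 0/1 dummy (albuminuric = 1) and thresholds at
0.5; reported "probabilities" are clipped dummy predictions, and AUROC (the
Mann–Whitney concordance, ties counted ½) is the threshold-free headline
metric.

Cross-validation is 10-fold venetian blinds (sample $i$ → fold
$i \bmod k$). Two LV-selection rules are provided. `select_lv_min()` takes
the global RMSECV minimum (ties toward fewer LVs) and drives the
optimization grid. `select_lv_incremental()` grows the model while the next
LV improves RMSECV by more than 10 %, with an exception below 5 LVs. That
exception is ambiguous as stated in the sources this design follows: it
could mean forced exploration (any improvement is accepted while the model
is small) or a minimum model size. The default implements forced
exploration up to 5 LVs — the reading under which a sequence like RMSECV =
(10, 5, 4.8, 4.7, 4.65, 4.6) stops at 5 LVs — and the other reading is
available via `floor_mode = "min_lv"`.

MC2CV (`mc2cv()`) repeats random 70/30 train/test splits 100 times, with
inner venetian-blinds CV on the training rows selecting the LV count per
split. The train/test ratio is not published for the workflow this mirrors;
30 % test is the package default and is configurable. The split sequence is
a pure function of (seed, number of rows), so simulated and reference
datasets of equal size are evaluated on identical splits. Classification
splits that isolate a single class are redrawn from a derived sub-seed (at
most 100 attempts, counted in the result).

Diagnostics: VIP scores use the standard weight/explained-variance formula
(mean squared VIP ≡ 1); `orthogonalized_loadings()` rotates the loading
basis so the first vector is the projection of $\beta$ onto the loading
span with the remainder Gram–Schmidt-orthogonalized (spans are preserved);
`integrated_vector()` cumulatively sums derivative-scale vectors to restore
band-shaped traces for visual comparison.

## What the generator does and does not emulate

The synthetic library reproduces the *structure* of the problem — band
overlap between analytes and interferents, water dominance, noise floors
that scale with scan count, stochastic preconcentration, and the
20-fold-per-step dilution of small molecules — so passing tests demonstrate
that the algorithms behave correctly under realistic covariance and noise
geometry. They do not demonstrate agreement with any particular instrument:
real standards have non-Gaussian band shapes, temperature-sensitive water
bands, membrane contaminants (e.g. glycerol bands at 1200–1000 cm⁻¹ and a
carbonyl near 1735 cm⁻¹), atmospheric residuals and nonlinear
solute–water interactions, none of which are modelled. Users with measured
standards should load them via `load_spectra_csv()` and build a library
from those spectra; every downstream function is agnostic to where the
library came from.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run the 49-run design on the
full 450–4000 cm⁻¹ grid (1776 points) for end-to-end checks, and small
synthetic matrices for algorithmic oracles; the whole suite completes in
well under a minute on a single CPU. Statistical checks use fixed seeds
with bands derived from the relevant sampling distributions (e.g. the χ
distribution of a standard deviation across 25 replicates). Property
tolerances are stated per test: exact identities at 1e-8–1e-12, sampling
recoveries at the width of their Monte Carlo error. Correlation-recovery
checks use n = 10⁵ draws; the preconcentration RSD check uses n = 10⁴.

## Known limitations

- Linear mixing only; no nonlinear effects, band shifts, or drying physics.
- Independent Gaussian noise; no correlated or multiplicative noise.
- The component library is synthetic; absolute RMSECV values depend on its
  band heights and the assumed noise levels, so only *relative* comparisons
  across conditions (the purpose of the grid) are meaningful without a
  measured library.
- The design generator covers exactly the 49-run, seven-level,
  ≤13-factor case; it is not a general factorial/D-optimal constructor.
- The placeholder concentration correlations must be overridden for any
  population-level quantitative claim.
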