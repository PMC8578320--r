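---
title: "Methods: PEG-precipitation solubility assays with pegsolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PEG-precipitation solubility assays with pegsolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegsolve)
```

## The assay and its model

Polyethylene glycol (PEG) is an inert crowding agent: its excluded-volume
effect drives proteins out of solution as its concentration rises. Titrating
PEG against a fixed protein concentration, incubating, pelleting the
precipitate and quantifying the soluble protein left in the supernatant
yields a decreasing sigmoidal curve of soluble concentration against PEG %
w/v. `pegsolve` fits

$$ y = \frac{a - b}{1 + e^{\,s (x - \mathrm{PEG}_{1/2})}} + b $$

where $a$ and $b$ are the upper and lower plateaus, $s > 0$ the slope, and
$\mathrm{PEG}_{1/2}$ the inflection — the PEG concentration at which half
the protein remains soluble. $\mathrm{PEG}_{1/2}$ ranks proteins and buffer
conditions by *relative* solubility; it is not a thermodynamic solubility.
The same parameterization fits increasing curves (turbidity against PEG)
with $a < b$, so both readouts share one code path.

Key assumptions: the precipitation transition is monotone and logistic in
shape; the plateaus are genuinely sampled (concentrations well below and
well above the transition); replicate wells at a concentration are
exchangeable; and the A280/A340 optics are linear in concentration over the
measured range.

## Planning parameters

`design_config()` holds the titration parameters. Defaults describe a
screening-scale run:

* `final_well_volume` = 10 µL, `final_protein_conc` = 1 mg/mL from a
  `protein_stock_conc` = 3 mg/mL stock, so each sample well takes
  10/3 µL of protein and the PEG + buffer budget is 20/3 µL.
* `peg_stock_concs` = 15, 30, 50 % w/v. For each target the *lowest* stock
  that fits the budget at or above the 0.33 µL minimum transfer volume is
  chosen: lower stocks need larger volumes, and larger volumes pipette more
  accurately in viscous PEG solutions. A target is infeasible when no stock
  satisfies both constraints (the error names the target).
* `peg_targets` defaults to twelve concentrations, 0–30% in steps of 3 plus
  the exact ceiling 33⅓% — the maximum achievable with a 50% stock once the
  protein volume is committed: `max(stock) × (V − v_protein)/V`. Ten to
  twelve points across a wide range suffice to locate the half-point; the
  top target uses the entire non-protein budget so its buffer volume is
  exactly zero (any nonzero volume must be pipettable, i.e. ≥ 0.33 µL).
* Blanks are the same PEG + buffer recipe with the protein volume replaced
  by buffer, one per concentration by default. Wells are assigned row-major,
  replicates adjacent, blanks after them; the layout CSV records the
  mapping.
* The supernatant transfer takes 3 µL twice from each well (6 of 10 µL,
  leaving 2 µL headroom for evaporation), doubling technical replicates:
  four measurement wells per concentration. The measurement well is
  prefilled with 10 µL buffer, so the supernatant is diluted by
  (10 + 6)/6 = 16/6 — `quant_config()`'s default `dilution_factor`, which
  users must set to their actual prefill.

## Spectral processing and quality control

Spectra (220–700 nm) are smoothed with a Savitzky–Golay filter before any
blanking, window 11 points and polynomial order 3 by default (both
exposed); edges use mirror padding. These defaults track the curvature of a
protein absorbance band at 1 nm sampling while suppressing shot noise; the
filter is linear, so it rescales all wells identically and cannot move the
fitted inflection.

Outlier flagging uses two spectral summaries per well: the absorbance at
310 nm and the mean absorbance over 350–400 nm (inclusive endpoints). A
well is flagged when the first is more than 4 standard deviations, or the
second more than 7, from reference statistics; values exactly at a
threshold are accepted. Bubbles and particulates scatter broadly across
this region, which protein absorbance and PEG baseline do not explain.
Reference statistics should be compiled from several runs on the user's own
instrument (`compile_reference_stats()`, `run_qc_ref()`); standard
deviations use the sample (n−1) convention for small-n robustness. The
package ships `reference_stats_default()`, compiled at run time from an
ensemble of eight simulated clean plates: it characterizes the simulator,
not any real plate reader, and exists so that simulated pipelines and tests
are self-contained. **Recompile against your own plates before trusting
flags on real data.**

Quantification follows the blanked-absorbance definitions: soluble
concentration is

$$ c = \frac{A_{280} - A_{340}}{\varepsilon\, \ell} \times \text{dilution}, $$

with the A340 subtraction removing residual scattering that survives blank
subtraction (implemented as a plain subtraction; a wavelength-extrapolated
scattering model would need assumptions the data do not constrain).
Negative corrected absorbances clamp to zero — precipitation cannot exceed
the loaded protein — with a warning. Turbidity is the blanked A500.
Blanks are matched by PEG concentration by default; a single shared blank
is supported (PEG barely absorbs at 280 nm) but mis-cancels
wavelength-dependent PEG scattering, so matched blanks are the default.

## Fitting, normalization, and uncertainty

`fit_solubility()` runs the full estimator:

1. **Initial fit.** Levenberg–Marquardt least squares (via
   `minpack.lm::nls.lm`, slope bounded positive, ftol = ptol = 1e−10, at
   most 2000 function evaluations). Starting values come from the data
   (plateaus from the curve ends, inflection at the point nearest the
   mid-level, slope from the 10–90% span). If that start fails, a coarse
   grid over (s, PEG½) — with the plateaus solved in closed form, since the
   model is linear in the logistic term — supplies a second start; a
   Nelder–Mead polish is the last resort, and a fit that still fails is
   returned with `converged = FALSE`. Flat data (total drop below 3× the
   median point SD) raise "no transition detected" rather than returning a
   meaningless inflection.
2. **Plateau normalization.** The curve is rescaled to
   $y' = (y - b)/(a - b)$ and refitted with the plateaus fixed at 1 and 0.
   The reported PEG½ and slope come from this refit, which makes estimates
   comparable across proteins measured in different units.
3. **Bootstrap confidence intervals** (default 500 cycles, 95% level,
   seeded). Replicate wells are case-resampled within each concentration
   and the point means recomputed; deviations are inflated by
   $\sqrt{n/(n-1)}$, the standard correction for the downward bias of the
   resample-mean variance at small per-point $n$. Each cycle refits the
   *full* four-parameter sigmoid so plateau uncertainty propagates. With no
   replicates the fallback resamples fit residuals. The default interval is
   the point estimate ± a Student-t quantile (df = points − 4) times the
   bootstrap standard error, on the log scale for the slope. We chose this
   over raw percentile intervals after measuring calibration on simulated
   assays (four wells per point, 3% concentration noise): percentile
   intervals covered the true PEG½ only ~78–90% of the time depending on
   the resampling details, while the bootstrap-SE t-interval covers ~94%.
   `interval = "percentile"` restores the classical construction for
   comparison with other implementations. Cycles whose refit fails are
   dropped; more than 20% failures triggers a warning.

Derived quantities: the **onset** of precipitation is where the tangent at
the inflection meets the upper plateau; on this parameterization the
tangent slope is $-s(a-b)/4$, giving $\text{onset} = \mathrm{PEG}_{1/2} -
2/s$. The **apparent absolute solubility** extrapolates
$\ln c$ against PEG% over the transition region (points whose fitted value
lies between 20% and 80% of the drop — a configurable window) to 0% PEG.
With typical designs the 20–80% window spans $2\ln 4/s$ percent PEG, so a
slope near 1 leaves fewer than three grid points inside it and the
extrapolation is undefined (reported as `NA`); when defined it is extremely
sensitive to small errors in the transition points (a 10% perturbation of
one point can move it by tens of percent), which is why it is labelled
*apparent* and never used for ranking.

## The plate simulator

`simulate_assay()` generates measurement-plate spectra with known truth so
every stage is testable without an instrument. Per sample well at PEG
concentration $x$:

* true soluble concentration $c(x) = c_0 / (1 + e^{s(x - \mathrm{PEG}_{1/2})})$,
  scaled by $1/(1-\text{evaporation frac})$ and by per-well multiplicative
  noise (`conc_cv`, default 3%, emulating pipetting and transfer
  variability);
* a Gaussian protein band at 280 nm (width 15 nm, truncated at 3σ so the
  340 nm correction point carries no protein signal) scaled to
  $\varepsilon \ell c$ in the measurement well;
* a Rayleigh-like PEG baseline $\propto x \lambda^{-4}$ (identical in the
  matching blank, so blanking removes it);
* particulate scattering proportional to the precipitated amount with a
  gentle $\lambda^{-1}$ dependence — large aggregates scatter almost
  achromatically — which drives the turbidity readout and, being affine in
  $c(x)$, cannot bias the fitted inflection;
* additive i.i.d. Gaussian noise (default 2 mAU) and, with probability
  `bubble_rate`, a broad scattering bump centered at 340 nm that the QC
  rules must catch.

The defaults are the package's statement of realistic screening conditions
and are not adjusted per analysis. Because the generator and the fit share
the sigmoid family, a noiseless simulation must invert exactly (to
optimizer tolerance) through the entire pipeline — parse, smooth, QC,
blank, quantify, fit — and the tests assert this at 1e−3 % w/v. What
passing these tests does **not** show: robustness to spectral shapes the
simulator omits (lamp drift, condensation, wavelength miscalibration,
PEG–protein interaction effects), to non-logistic transitions, or to real
instrument noise spectra. The simulated-clean-plate reference statistics in
particular say nothing about any real reader's well-to-well spread.

## Problem sizes used in validation

The statistical test suite uses: 100 simulated assays (truth PEG½ ∈ [8, 20]
% w/v, slope ∈ [0.5, 3], 3% concentration noise) for parameter recovery,
asserting a median absolute PEG½ error ≤ 0.3 % w/v; 200 simulated curves
with 200 bootstrap cycles each for interval calibration, asserting coverage
in [0.90, 0.99]; and ten plates at 20% bubble rate for QC discrimination
(sensitivity ≥ 0.9, false-positive rate ≤ 0.05). These sizes give stable
pass/fail behaviour at interactive runtimes; larger ensembles tighten the
Monte-Carlo error but do not change the conclusions.

## Known limitations

* PEG½ is a relative ranking tool; absolute solubility claims require
  different experiments.
* The bootstrap treats the four technical replicates per concentration
  (two source replicates × two transfers) as exchangeable wells; transfer
  pairs from one source well share pre-transfer history, so the interval
  mildly understates source-level variability in designs with few source
  replicates.
* Path length in low-volume microplates is geometry-dependent;
  `path_length_from_volume()` helps, but accurate concentrations need the
  user's own calibration.
* The BMG-proprietary export layouts are not parsed byte-for-byte; the two
  documented CSV dialects (long and wide) are the interchange formats, and
  a converter is the natural extension point.
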