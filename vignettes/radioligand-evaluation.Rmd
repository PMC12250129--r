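---
title: "Quantitative evaluation of therapeutic radioligands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative evaluation of therapeutic radioligands: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlig)
```

`radlig` implements the full quantitative chain used to evaluate a
beta-emitting, receptor-targeted radiopharmaceutical preclinically — the
workflow typified by Lu-177-labelled PSMA ligands in prostate-cancer
models: radiochemical quality control, receptor binding, biodistribution,
mouse-to-human dosimetric extrapolation, and survival efficacy. This
vignette describes the models each stage assumes, the tunable parameters,
the numerical choices, and what the synthetic-data generators do and do
not emulate.

## Decay arithmetic and units

All times are hours internally; configuration accepts half-lives in days
with an explicit unit tag because biodistribution timepoints are naturally
in hours while physical half-lives are quoted in days. Activities are MBq;
molar activity appears in GBq/µmol only at the reporting boundary. The
default nuclide is Lu-177 (T~1/2~ = 6.73 d, so λ~phys~ = ln 2 / 161.52 h),
with a mean beta energy of 0.1335 MeV and gamma lines at 208 keV (11%) and
113 keV (6%). The beta mean energy is an external standard constant
shipped in the editable `inst/extdata/nuclides.csv`; figures near 0.5 MeV
sometimes quoted for this nuclide describe the beta spectrum endpoint, not
its mean, and the constants file is authoritative. Decay correction is
exact: `decay_factor(t) = 2^(-t/T1/2)`, and back-correction divides by it,
so correct-then-decay is an identity to machine precision. Note that the
molar-activity operation implements its definition; a nominal 1 GBq on
50 nmol gives 20 GBq/µmol regardless of what any particular synthesis
assayed.

## Radiochemical purity and serum stability

Purity is peak-window integration of a one-dimensional count profile
(iTLC strip position or HPLC retention time). Windows are *explicit
inputs*, not auto-detected — there is no robust universal peak-finding
rule for two-peak radiochromatograms, and the iTLC convention with an
EDTA mobile phase is fixed and well known: labelled product at the
origin, free radiometal (as Lu-EDTA) at the solvent front. All windows
are half-open `[lo, hi)` so that a partition of the axis sums to exactly
100%. A labelling-acceptance flag is attached at the conventional 90%
threshold. Serum-stability records pivot to a temperature-by-time table;
missing cells stay missing — imputation would silently fabricate QC data.

## Binding assays

Saturation data are analysed as classical one-site binding: specific
binding `B(c) = Bmax·c/(Kd + c)` after pointwise subtraction of
nonspecific binding, with negative specific values floored at zero with a
warning (flooring preserves the design points for audit; exclusion would
silently change the design). Competition data are fitted as one-site
displacement on the log-concentration axis,
`B(c) = Bottom + (Top − Bottom)/(1 + c/IC50)`, with Top and Bottom free
and the Hill slope fixed at 1, the classical analysis for a single
binding site. `Ki = IC50 / (1 + [radioligand]/Kd)` (Cheng-Prusoff)
converts the assay-dependent IC50 into an assay-independent inhibition
constant; it guarantees `Ki ≤ IC50`, with equality in the zero-radioligand
limit.

All nonlinear fits use bounded Levenberg–Marquardt least squares
(`minpack.lm`) restarted from a deterministic log-spaced grid over the
plausible parameter decades (5 × 5 for saturation), keeping the smallest
residual sum of squares and breaking ties towards the smaller Kd (or
IC50). This makes fits reproducible bit-for-bit without a global
optimiser. A competition fit whose fitted IC50 falls outside the
concentration range, or whose curve is flat, is an error rather than a
number: the transition must be bracketed by data for IC50 to mean
anything.

## Biodistribution

A gamma-counter worksheet carries per-organ counts, sample masses and
counting timestamps plus calibration standards (aliquots of a known
fraction of the injected activity). Percent injected activity per gram is

\[
\%IA/g \;=\; \frac{100 \cdot \text{cpm}_{organ}/DF(t_{organ})}
{\text{cpm}_{std}/(DF(t_{std})\cdot f_{std})} \Big/ m_{organ},
\]

with both numerator and denominator decay-referenced to the injection
time. The reported %IA/g therefore reflects *biological* distribution
only — the standard %ID/g convention — and makes tumor-to-normal ratios
time-consistent; the dosimetry stage re-applies physical decay where
disintegration counts are needed. Each organ count is matched to the
nearest-in-time standard (configurable gap tolerance, default 24 h).
Group summaries are mean ± sample SD (n − 1) over animals per
organ-timepoint cell; a single animal reports no SD rather than zero.

## Dosimetry

Mouse %IA/g is extrapolated to a reference 70-kg adult by relative
organ-mass scaling:
`(%IA/organ)_human = (%IA/g)_animal × (kg TB)_animal × (g_organ/kg TB)_human`,
using a mouse total-body mass of 0.025 kg by default (typical adult
mouse, configurable). Because the %IA/g table is decay-corrected, the
extrapolated curve is multiplied by `decay_factor(t)` before fitting —
this seam is what makes the subsequent integral count *physical
disintegrations* rather than biological occupancy.

Whole-organ curves are fitted with mono- or bi-exponential models whose
rates are bounded below by λ~phys~ (nothing disappears slower than
physical decay), again with deterministic multi-start. In `auto` mode the
order is chosen by corrected AIC with ties to the simpler model; AICc is
undefined (treated as +∞) when `n − k − 1 ≤ 0`, so a standard 4-timepoint
study is fitted mono-exponentially unless a bi-exponential is forced. A
non-convergent fit falls back to trapezoid integration of the samples
plus an analytic physical-decay tail — conservative and reproducible.

Residence times are `τ = Σ c_i/r_i` (coefficients as fractions of the
injected activity), bounded in total by `T1/2/ln 2 ≈ 233 h` for Lu-177 —
every disintegration happens somewhere, at most once — and the remainder
of body closes that balance by subtraction, clamped at zero. Organ doses
are the MIRD sum `D(target) = Σ_source τ_source · S(target ← source)`.
The S-matrix is an input file; the package ships a toy fixture and a
transparent builder whose self-dose term is
`S_self = 0.5767·E_β(MeV)/m(kg)` mGy/(MBq·h) (3.6 × 10⁹ decays per
MBq·h, electrons absorbed locally) plus optional photon cross-dose via
user-supplied absorbed fractions. Reproducing phantom Monte-Carlo
S-values is explicitly out of scope; the engine's contract is the MIRD
arithmetic. Effective dose is the ICRP-60 tissue-weighted sum (shipped as
an editable constants file), with the remainder tissue receiving the
mass-weighted mean dose of unweighted organs; a weighted tissue missing
from a dose report takes the remainder dose, which preserves the
uniform-dose identity `E = D`.

## Survival efficacy

Humane-endpoint eventing converts body-weight series into event days at
≥ 20% loss from the inoculation-day baseline (inclusive boundary);
endpoint animals are *events*, not censored — the endpoint is terminal by
design — while animals alive at study end are censored. The survivor
function is the Kaplan–Meier product-limit estimator with the
death-before-censoring tie convention. The median is defined as the
smallest time at which S(t) ≤ 0.5 (equal to the conventional KM median
whenever S crosses 0.5 strictly), and lifespan increase is
`100·(median_treated − median_control)/median_control`. Two-group
comparisons use the Mantel–Cox log-rank test with tie-corrected
hypergeometric variances. Percent results are conventionally read to one
decimal; published figures of this kind are often truncated rather than
rounded, so comparisons should allow a 0.1-point tolerance.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes from forward
models that are written independently of the analysis code, so
generator → pipeline round trips are genuine tests. The biodistribution
preset stores decay-corrected %IA/g anchors per organ with log-linear
interpolation (activity declines are quasi-exponential) and log-linear
extrapolation of the terminal slope. Tumor and kidney anchors are
published means; the 1 h tumor value and all blood and muscle values are
back-derived from published tumor-to-normal ratios, and the liver,
spleen and lung curves are nominal low-uptake fixtures — internally
consistent, but not measurements. Worksheet counts follow
`%IA/g·m·A₀·calibration·2^(−t/T½)` with one 1%-aliquot standard per
counting session (calibration 10⁴ CPM/MBq, 3 animals per timepoint at 1,
4, 24 and 48 h, 37 MBq injections). Survival draws are Weibull with
shape k = 6 — chosen once for realistic spread; medians, which the
efficacy statistics use, are shape-robust — scale `median/(ln 2)^{1/k}`,
rounded up to whole days, for arms of n = 6, 8 and 9 at medians 26, 34
and 40 days.

What the generators do **not** emulate: inter-animal biological
variability beyond counting noise, organ-mass variation, detector dead
time and background, partial-volume effects, dissection losses, or any
imaging modality. A passing zero-noise round trip demonstrates that the
pipeline exactly inverts its forward model — calibration, decay and
normalisation — not that it is robust to everything real data does;
robustness is probed separately with Poisson and Gaussian-CV noise at
the counting stage.

## Numerical choices and degenerate inputs

Explicitly declared behaviours: half-open windows everywhere; zero total
counts, flat competition curves, unbracketed transitions, missing
standards and weights not summing to one are *errors*, not numbers;
all-zero time-activity curves yield zero-coefficient fits and τ = 0;
organ-sum residence times exceeding the whole-body value clamp the
remainder at zero with a warning; empty biodistribution cells are
absent, never zero. All simulation entry points take a single seed, and
every stochastic output is a deterministic function of (preset, seed).

## Problem sizes

The bundled demonstration and test runs use the study-scale designs
described above (8-point saturation assays, 10-point competition assays,
12-animal biodistribution, 23-subject survival) plus modest simulation
studies (tens of replicates for noise-robustness checks, 10⁵ draws for
the Weibull median check); the full suite runs in well under a minute on
one CPU.

## Known limitations

Tumor (non-phantom) dosimetry, decay-chain daughters, Cox regression,
multi-arm simultaneous survival tests, receptor-number calibration to
sites/cell and kinetic (on/off-rate) binding models are out of scope.
The shipped S-matrix builder is a transparent first-order model: it is
suitable for exercising and testing the MIRD arithmetic and for
sensitivity work, not for regulatory dose estimates, which require
phantom-specific S-value tables supplied through the CSV interface.
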