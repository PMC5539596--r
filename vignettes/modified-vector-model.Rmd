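---
title: "The modified vector model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified vector model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odormvm)
```

## The model and its assumptions

The vector model treats the perceived intensities of a mixture's components
as vectors separated by an angle $\alpha$; the mixture's intensity is the
norm of their sum. For two components,

$$\mathrm{OI}_{ab}^2 = \mathrm{OI}_a^2 + \mathrm{OI}_b^2 +
  2\cos\alpha\,\mathrm{OI}_a\,\mathrm{OI}_b,$$

with $\cos\alpha \in [-1, 1]$ the interaction coefficient: $+1$ is perfect
additivity, $0$ orthogonality, negative values odor counteraction. The
*modified* vector model adds two empirical regularities that hold within an
odorant family (same functional group, similar molecular structure and odor
type):

1. **One psychophysical law.** Single odorants follow
   $\mathrm{OI} = k \ln(\mathrm{OAV}) + b$ with shared $(k, b)$, where
   $\mathrm{OAV} = C / C_{\mathrm{Thr}}$ is the odor activity value. This
   makes every component intensity computable from instrumental
   concentration measurements.
2. **One interaction coefficient.** Equal-intensity binary mixtures fall on
   a line $\mathrm{OI}_{mix} = s\,\mathrm{OI}_{sum}$ through the origin.
   Substituting that line into the equal-intensity inversion of the binary
   vector sum gives $\cos\alpha = 2s^2 - 1$, one constant per family.

Together, three scalars $(k, b, s)$ map any within-family composition to a
mixture OI. The model is *not* claimed across families: odorants differing
in functional group (e.g. adding an acrylate or vinyl ester to the ester
set) break both regularities, and the package deliberately refuses
compositions containing non-members rather than extrapolating.

The $n$-component form shares the family coefficient across all pairs:

$$\mathrm{OI}_{mix}^2 = \sum_i \mathrm{OI}_i^2 +
  2\cos\alpha \sum_{i<j} \mathrm{OI}_i\,\mathrm{OI}_j .$$

For $n \le 3$ this is exactly the classical binary/ternary model; beyond
that it is the natural generalization under the one-coefficient assumption.

## Parameters and their meaning

| Parameter | Units | Aldehyde preset | Ester preset |
|---|---|---|---|
| $k$ | OI per ln(OAV) | 5.6 | 1.4 |
| $b$ | OI | −5.6 | −2.7 |
| $s$ | — | 0.62 | 0.79 |
| $\cos\alpha = 2s^2-1$ | — | −0.2312 | 0.2482 |

Thresholds (mg/m³) come from the shipped registry's panel-measured column;
reported literature thresholds for the same compounds span an order of
magnitude, so the registry is user-replaceable (`read_registry_csv()`), and
all OAVs inherit whatever threshold source the user supplies.

Two design points deserve emphasis:

- **The slope is primary, $\cos\alpha$ is algebra.** Model files and presets
  store $s$ and derive $\cos\alpha = 2s^2 - 1$ at load time. Carrying both
  printed constants independently invites inconsistency — published roundings
  of this very model disagree with their own printed slopes (0.62 implies
  −0.2312; 0.79 implies +0.2482, a *positive* coefficient). `odormvm` always
  derives the coefficient from the slope and never hard-codes a rounded one.
- **Sub-threshold clamping.** The law yields negative OI for
  $\mathrm{OAV} < e^{-b/k}$; `oi_single()` clamps to 0 on the grounds that
  sub-threshold stimuli are imperceptible. The clamp lives in prediction
  only — calibration fits the unclamped line, and zero-OI panel records
  (censored ratings) are excluded from the law fit by default, with the
  exclusion count messaged.

## Calibration

`fit_psychophysical_law()` pools all of a family's single-odorant records
into one ordinary least-squares fit of OI on ln(OAV) (per-odorant fits are
returned as a pooling diagnostic, not used). `fit_mixture_slope()` fits
$\mathrm{OI}_{mix}$ on $\mathrm{OI}_{sum}$ through the origin,
$s = \sum xy / \sum x^2$: the printed family relations carry no intercept,
and zero summed intensity must map to zero mixture intensity. A
free-intercept variant (`intercept = TRUE`) exists for sensitivity analysis
only. Mixtures with unequal component intensities are accepted by the fit —
the equal-intensity protocol is how $\cos\alpha$ is *derived*, not a
precondition of the regression.

## The referencing scale

OIRS levels are aqueous n-butanol standards in a geometric progression of
two: the 12-point scale runs 10, 20, 40, … ppm, the 8-point scale 12, 24,
48, … ppm. `oirs_concentration()` follows the geometric rule exactly; note
that published 8-point tables sometimes print 1550 ppm at level 8 where the
rule gives $12 \cdot 2^7 = 1536$ — the package sides with the rule.
`nearest_oirs_level()` models assessors reporting at a finite resolution
(half-levels by default); exact ties round up.

## Synthetic data

The panel generators exist so every stage is testable without measured
data. They emulate:

- true single-odorant intensities on an even ln(OAV) grid through the
  configured law (default: 6 samples per odorant over the perceivable
  window $[-b/k,\ -b/k + 2.5]$, so the aldehyde default spans ln(OAV) 1.0
  to 3.5);
- true mixture intensities from the vector sum at $\cos\alpha = 2s^2-1$
  (default: 5 equal-intensity samples per pair on an OI grid over levels 1
  to 12);
- assessor behavior as additive Gaussian noise on the OI scale
  (sd 0.5 by default — the commonly accepted scatter of panel ratings —
  truncated at 0), quantized to half-levels, averaged over an 8-assessor
  panel. Whether real panels report integer, half-level or continuous
  values varies; the resolution is configurable and 0 means continuous.

The sensor generator produces strictly linear, additive responses:
$x_j = \mathrm{baseline}_j + \sum_i S_{ji} C_i + \varepsilon$. The
selectivity pattern of the default 7-sensor array follows the qualitative
characterization of the metal-oxide devices it names (which sensors respond
to which aldehyde, and that MP502 favors n-butyraldehyde over
propionaldehyde), but the baseline and sensitivity magnitudes are synthetic
round numbers: no measured device constants are claimed. The default
sampling plan is 8 samples per single odorant, 25 per binary pair and 50
for the ternary mixture. What this simulation deliberately omits —
saturation, drift, humidity and temperature effects, response/recovery
dynamics, sensor-level mixture interactions — is exactly what makes real
e-nose data hard, so passing tests demonstrate the correctness of the
pipeline's logic, not field performance.

All generators are pure functions of (config, seed); the mixture generator
offsets the seed by one so singles and mixtures from one config are
independent streams.

## The concentration estimator

The e-nose pipeline estimates constituent concentrations from array signals
with a fully connected feedforward network: logistic-sigmoid hidden layers,
identity output, defaulting to the selected architecture of five hidden
layers of twenty neurons (input width = sensors, output width = odorants).
Both signals and concentrations are min–max normalized per column over the
training database only (sensors and odorants live on incommensurate scales,
so a single global MIN/MAX would be meaningless); prediction renormalizes
inputs, denormalizes outputs, and clamps negative concentrations to 0.
Out-of-training-range inputs intentionally map outside $[0,1]$ — no
clipping, so extrapolation is visible rather than silently saturated.

Training minimizes mean squared error with analytic backpropagation
gradients under L-BFGS-B, a quasi-Newton method, with three seeded random
restarts (Glorot-style uniform initialization) keeping the lowest-loss fit.
The contract is accuracy and seeded determinism, not optimizer identity:
on the noiseless linear database the default network's training ARE is a
fraction of a percent, within the 5-percentage-point band of the exact
linear least-squares solution, and identical seeds reproduce identical
weights. The ARE metric itself — $100 \cdot \mathrm{mean}(|p - r|/r)$ —
excludes pairs with zero reference concentration (relative error is
undefined there) and messages the exclusion count.

## Numerical choices and degenerate inputs

- Natural logarithms throughout the law.
- The mixture radicand is clamped at 0 (with a warning) if the quadratic
  form goes negative — reachable only near $\cos\alpha = -1$ with several
  components, and read as complete counteraction.
- Law fits require two distinct abscissae; slope fits require a positive
  $\mathrm{OI}_{sum}$; normalization requires non-constant columns; each
  failure is a named error, not a silent NaN.
- A single-sample training database trains with an artificially widened
  normalization window and an explicit "underdetermined" warning.
- CSV outputs fix OI at 4 decimals and concentrations at 6 significant
  digits so repeated runs diff cleanly.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at the study's own scale: 18 single-odorant records and 15 binary-mixture
records per panel, 200 seeded replicates for the noisy-recovery check, and
a 149-sample noiseless sensor database (3×8 singles, 3×25 binaries, 50
ternaries) for estimator training. These sizes were chosen to mirror the
calibration campaign the model is built for; the whole suite runs in well
under a minute of CPU apart from network training, which takes a few
seconds per fit.

## Known limitations

- One coefficient per family by construction; pairwise-distinct
  $\cos\alpha$ and cross-family mixtures are out of scope.
- Thresholds are inputs, not estimands: the package neither re-estimates
  them from panel data nor predicts them from structure.
- The linear sensor model cannot represent real device nonlinearity; a
  trained estimator is only as good as the (signal, concentration) database
  behind it.
- Panel noise is modeled as independent Gaussian per assessor; real panels
  show correlated, assessor-specific biases that a mixed model would
  capture and this package does not attempt.
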