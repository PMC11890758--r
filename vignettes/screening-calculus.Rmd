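---
title: "The screening calculus: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The screening calculus: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscreen)
```

This vignette is the package's own account of the quantitative models it
implements, the assumptions behind them, and the choices made where the
underlying experimental protocols leave the numerics open.

## The BRET saturation model

A live-cell BRET assay titrates a Venus-tagged acceptor against an
Nluc-tagged donor. The raw readout per well is the 535/460 nm intensity
ratio; subtracting the donor-only control ratio gives net BRET, the specific
interaction signal. Net BRET saturates hyperbolically in the acceptor/donor
expression ratio $X$ (Venus fluorescence over donor luminescence):

$$Y = \frac{BRET_{max} \cdot X}{BRET_{50} + X}$$

$BRET_{max}$ (unitless, typically 0.05–0.5 for genuine interactions in this
format) is the plateau — how much of the donor population can be driven into
the complex — and $BRET_{50}$ (same units as $X$, typically 0.3–5) is the
acceptor/donor ratio at half-saturation, an inverse-affinity proxy. A true
interaction saturates; bystander (collisional) signal rises roughly linearly
and stays low over the titrated range, which is why empty-vector controls are
carried as full titration series rather than single points.

**Exclusion rule.** Negative $X$ or $Y$ values are artifacts of background
subtraction and are flagged `excluded` before fitting; they never enter a
fit, but the raw values are kept. A fit requires at least 3 usable points at
2 or more distinct $X$ values.

**Fitting.** `fit_saturation()` minimizes the residual sum of squares by
variable projection: conditional on $BRET_{50}$, the optimal $BRET_{max}$ is
a nonnegative closed-form amplitude, so the problem reduces to a 1-D search
on $\log BRET_{50}$, solved with Brent's method over
$[10^{-4} x_{max}, 10^{4} x_{max}]$ at tolerance $10^{-10}$. This is
deterministic, needs no starting values, and recovers noiseless parameters
to well below $10^{-6}$ relative error. Degenerate inputs are explicit: an
all-zero curve returns $BRET_{max} = 0$ with $BRET_{50}$ unidentifiable
(`converged = FALSE`), and a search that pins against its bracket is also
reported unconverged rather than trusted.

## AUC scoring and hit calling

The per-curve summary statistic is the area under the *fitted* curve, which
integrates amplitude and shape. It has the closed form

$$\mathrm{AUC}(x_{max}) = BRET_{max}\left(x_{max} - BRET_{50}
\log\frac{BRET_{50} + x_{max}}{BRET_{50}}\right),$$

exact and noise-robust compared with a trapezoid over raw points. Tests
verify it against adaptive quadrature to $10^{-8}$ over 1000 random
parameter triples.

Two choices here were genuinely open:

* **Common integration bound.** No fixed $X$ range is inherent to the assay;
  integrating each condition over its own range would confound expression
  range with affinity. All AUCs entering one comparison use
  $x_{max} = \min$ over the compared curves of each curve's largest usable
  $X$.
* **Replicate unit.** Each of the (default four) replicate series is fitted
  independently, giving four AUCs per condition. Fold-of-change uses
  replicate means; the significance test uses the replicate AUCs.

The score for a candidate pair is
$\mathrm{FOC} = \overline{\mathrm{AUC}}_{PPI} /
\max(\overline{\mathrm{AUC}}_{ctrl1}, \overline{\mathrm{AUC}}_{ctrl2})$
— the *larger* of the two empty-vector controls, a conservative denominator —
with significance from an unpaired, two-tailed, equal-variance Student's
t-test of the pair AUC replicates against the *pooled* control AUC
replicates (4 vs 8 by default), unadjusted. Pooling the two control series
into one reference sample is one reading of a two-control design; testing
against each control separately and combining would be the alternative, and
the pooled form was chosen because the controls estimate the same null
quantity. Hits satisfy FOC $\geq$ 4.0 **and** $p \leq 0.001$, both
inclusive. If neither control has a positive mean AUC the ratio has no
meaningful sign and the pair is flagged non-callable instead.

Degenerate significance: if both AUC samples are exactly constant the t
statistic is undefined; equal means are reported as $p = 1$ and unequal
constant means as $p = 0$, the limiting values.

## The immune co-culture screen

Compounds are screened in two parallel arms — cancer cells alone and cancer
cells plus activated PBMCs. Each arm is normalized per plate to percent of
control,

$$\%C = 100\,\frac{S_{compound} - S_{blank}}{S_{positive} - S_{blank}},$$

with blank wells (PBMCs/medium only, DMSO) and positive wells (DMSO plus
cancer cells) averaged within their plate. $\%C$ is invariant under any
common affine rescaling of the signals, so gain settings cancel. Values
outside $[0, 100]$ are reported unclamped — they distinguish proliferative
from cytotoxic responses.

The immune-killing selectivity index is
$SI = \%C_{-PBMC} / \%C_{+PBMC}$: $SI \approx 1$ for inert or
immune-independent compounds, $SI \gg 1$ when killing requires immune cells.
Where $\%C_{+PBMC} \leq 0$ (killing saturated below blank) the ratio is
reported as `Inf`, a sentinel ranked above every finite value rather than an
error. Replicates: $\%C$ is computed per replicate well, averaged within
arm, and $SI$ taken from the two arm means — means tame the noise of a ratio
of noisy quantities. The nomination cutoff $SI \geq 2$ is a package default:
no threshold is inherent to the statistic, and 2 corresponds to "the immune
arm at most half the viability of the alone arm", comfortably above the
$SI \approx 1 \pm$ CV band of inert compounds at realistic noise.

PBMC-dose killing curves are summarized by `killing_curve_auc()`: a
trapezoidal AUC of viability against $\log_{10}$ effector dose, normalized
by the flat-100% area so 1 means no killing and 0 complete killing.

## Dose–response fitting

`fit_4pl()` fits the variable-slope logistic
$y = bottom + (top - bottom) / (1 + 10^{(\log_{10} EC_{50} - \log_{10} d)
\cdot h})$ by Levenberg–Marquardt, estimating the midpoint on the
$\log_{10}$ scale (which keeps it positive and symmetrizes its error). One
parameterization serves activation and inhibition; the sign of the hill
slope $h$ distinguishes them. Requirements: at least 4 dose points spanning
at least 2 decades — below that, top/bottom/midpoint are not jointly
identifiable and the fit refuses rather than extrapolates. Three starting
points (data-driven asymptotes, midpoint-nearest dose or median dose,
unit or doubled slope) are tried and the best converged fit kept;
non-convergence is reported in the return value, not thrown. Convergence
tolerances are $10^{-15}$ on both relative RSS and parameter change, so
noiseless synthetic curves are recovered to ~$10^{-12}$ relative error.

## Downstream formulas

* Comparative Ct: $\Delta Ct = Ct_{target} - Ct_{reference}$ per condition,
  $\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{control}$, relative
  expression $2^{-\Delta\Delta Ct}$. Replicate Ct values are averaged per
  (gene, condition) before differencing; Ct outside 10–40 cycles triggers a
  warning (plausible-range check, not an error).
* Differential-expression filtering retains $|\log_2 FC| \geq 1$ and
  adjusted $p \leq 0.05$, both inclusive; the DE model that produces the
  table is upstream of this package.
* Caliper tumor volume $= length \times width^2 / 2$ mm³; a width recorded
  larger than its length is swapped with a warning, making the formula
  argument-order safe. Percent reduction is relative to the
  treatment-start volume.

## What the synthetic generators emulate — and what they do not

`generate_bret_screen()` emits an 85-gene acceptor library against a single
donor with 16 true interactors, four replicate titration series per
construct over the grid $X \in \{0.25, 0.5, 1, 2, 4, 8\}$ (a plausible
titration ladder; real acceptor/donor grids vary by screen), two
empty-vector control series and dedicated donor-only baseline wells per
1536-well plate. True interactors get $BRET_{max} \sim U(0.1, 0.3)$ and
$\log BRET_{50} \sim U(\log 0.5, \log 4)$; non-interactors and controls sit
at a small bystander plateau of 0.02. Noise is additive Gaussian on net
BRET with sd equal to `noise_sd_frac` (default 5%) of a fixed reference
plateau of 0.2 — a plate-wide noise floor shared by hits, nulls and
controls, which is what makes the null hit rate testable: if noise scaled
with each gene's own plateau, null genes would be artificially quiet.
Donor luminescence varies lognormally (10% CV) around $10^5$ counts, and
the raw ratio rides on a donor-only baseline of 0.10 that the pipeline must
re-estimate from the blank wells.

`generate_htip_screen()` emits paired −PBMC/+PBMC 384-well plates (16 blank
and 16 positive control wells each) for a 2036-compound library with three
planted sensitizers of true SI 5, three replicate wells per compound per
arm, and mean-1 lognormal multiplicative noise (default 10% CV) on
viability signals — multiplicative because fluorescent viability readouts
scale with cell number. `generate_dose_response()` draws from the 4PL model
with multiplicative Gaussian noise.

All generators are pure functions of their specification including the
seed: repeated calls are byte-identical and the caller's RNG state is
restored.

Not simulated: plate-position (edge/evaporation) effects, transfection
efficiency gradients, carry-over between wells, compound
autofluorescence, donor-saturation artifacts, and day-to-day batch effects.
Passing tests on these generators therefore demonstrate that the *calculus*
— normalization, fitting, scoring, calling — is correct and calibrated
under its stated noise model, not that any particular instrument dataset is
free of the artifacts above; real screens would still need plate-level QC
upstream of this package.

## Problem sizes and calibration checks

The test suite exercises the scoring statistics at the scale the designs
call for: 2000 simulated null screens for the false-positive calibration of
the $p \leq 0.001$ cutoff (observed null hit fraction a few per thousand),
ten 85-gene screens with planted AUC fold-of-change 8 at 5% noise for
sensitivity/false-discovery (observed 1.00 / 0.00), 200 replicate-level
simulations for $BRET_{50}$ recovery (median error under 10% at 5% noise),
and full end-to-end runs of both screens through plate-table serialization
that recover exactly the planted hit sets. Each of these is recomputed at
test time; none is a stored constant.

## Known limitations

* The equal-variance t-test on 4-vs-8 AUCs is the screen's own convention;
  with strongly heteroscedastic replicates a Welch test would be more
  robust, and the small replicate count limits power for marginal
  interactions regardless.
* The saturation AUC compares conditions only over the jointly covered $X$
  range; a pair whose expression never reaches the controls' range is
  scored conservatively.
* The selectivity index is a ratio of normalized means; compounds with
  $\%C_{-PBMC}$ near zero in *both* arms (pan-toxic) get unstable finite
  SI values and should be triaged by their $\%C$ values, which the result
  table retains.
* No multiple-testing adjustment is applied to $P_{FOC}$ — the screen's
  stringent conjunctive cutoff stands in for it — so the per-gene p-values
  are comparable within a screen but are not posterior error rates.
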