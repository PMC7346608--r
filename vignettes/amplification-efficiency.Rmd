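---
title: "Estimating qPCR amplification efficiency: correct fits, correlated pairs, and what precision claims mean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating qPCR amplification efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampeff)
```

## The problem

Absolute quantification by qPCR needs the amplification efficiency $E$, the
per-cycle multiplicative growth factor of the target ($1 \le E \le 2$,
ideally 2).  In the early growth phase of a baselined amplification curve,

$$y = y_0 E^x,$$

and for a dilution series with factor $D$ (curve $j$ diluted $D^j$-fold),

$$y_{ij} = y_0\,E^{x_{ij}} / D^j,$$

so all growth-zone points of all curves can be fitted *jointly* for the two
parameters $(y_0, E)$.  `ampeff` implements that direct fit, two estimators
derived from pairwise combinations of the same points — a naive fit of all
pairwise differences and a weighted average of pairwise intensity ratios —
a correlated-data GLS that fits differences *correctly*, and the classical
standard-curve ($C_q$ vs $\log N_0$) calibration.  A simulation engine
measures what each estimator's error bars are actually worth.

## Why pairwise schemes overstate precision

From $n$ growth-zone points one can form $\binom{n}{2}$ pairwise differences
or ratios.  These derived observations are *not* independent: each raw point
enters $n-1$ of them, and at most $\lfloor n/2 \rfloor$ pairs can be formed
without reusing a point (`max_disjoint_pairs()`).  Treating the pairs as
independent data divides standard errors by roughly the square root of the
inflation in apparent sample size — the same arithmetic as averaging each of
9 numbers four times and claiming the SE of the mean shrank by 2.  No scheme
that recombines the same raw values can manufacture information beyond the
original $n$ points.

The package exposes this three ways:

* `fit_differences_naive()` fits all differences as if independent and
  reports the falsely small SEs (the result object records the assumption).
* `fit_differences_gls()` handles the correlation exactly.  Differences are
  a linear map $d = Ly$ with one $+1$ and one $-1$ per row; under constant
  independent noise the correct weight matrix is $W = (LL^{\top})^{-1}$.
  That inverse exists only while the rows are independent: with $n$ points,
  at most $n-1$ difference rows (whose pair graph must span all points,
  checked by union–find) can be used, plus one identity "anchor" row to
  complete an invertible transform $M$.  Minimizing
  $r^{\top}(MM^{\top})^{-1}r$ then reproduces the direct fit's parameters
  *and* SEs exactly — algebraically, because
  $M^{\top}(MM^{\top})^{-1}M = I$ for invertible $M$.  Supplying $\ge n$
  rows raises a singularity error reporting $\det(LL^{\top}) = 0$.
* `run_mc_comparison()` simulates many noisy replicates of one design and
  compares, per estimator, the ensemble SD of the point estimates (actual
  precision) with the average reported SE (apparent precision).

## The pairwise ratio estimator

Each pair of points with distinct cycles gives
$\ln E_{ij} = [\ln y_j - \ln y_i + (j_j - j_i)\ln D]/(x_j - x_i)$ (same-cycle
pairs are excluded; with the default 9-point layout, 36 pairs reduce to 31).
The per-pair variances differ enormously, so averaging requires weights from
first-order error propagation:

$$\sigma_Z^2 = \frac{\sigma_y^2}{(\Delta x)^2}
  \left(\frac{1}{y_i^2} + \frac{1}{y_j^2}\right),
\qquad
w_{ij} \propto \frac{(\Delta x)^2\, y_i^2 y_j^2}{y_i^2 + y_j^2},$$

which strongly favors widely separated, high-signal pairs.  The absolute
scale $\sigma_y$ is taken from the direct fit's $s_y$ on the same points (the
estimator needs an internal noise estimate; only relative weights affect the
mean).  $\sigma_E = E_{\mathrm{ref}}\,\sigma_Z$ uses a first-pass unweighted
mean as $E_{\mathrm{ref}}$, then one re-weighting pass with the weighted
mean; the estimates are narrowly distributed, so further passes change
nothing material.  Estimates in the outlier zone ($E < 1.60$ or $E > 2.15$
by default) are flagged but never deleted: their weights are orders of
magnitude below the maximum, so deletion is moot.

## Cq calibration

Full curves are fitted by a Richards-type log-logistic plus sloping linear
baseline,

$$y(x) = a + bx + \frac{y_{\max}}{\left(1 + e^{-k(x - x_m)}\right)^{s}},$$

six parameters in all.  At $s=1$ the growth term is exactly the symmetric
logistic $y_0 y_{\max} E_0^x / (y_0 E_0^x + y_{\max} - y_0)$ with
$E_0 = e^{k}$; $s \ne 1$ allows asymmetry.  This stands in for the published
seven-parameter log-log model: the extra flexibility of that model is not
identifiable on clean synthetic curves, while the sloping baseline — the
feature that matters for systematic-error compensation — is retained.  This
is a documented fidelity gap.

Markers are computed on the baseline-subtracted fitted curve with analytic
derivatives: threshold crossing (bisection to $10^{-6}$ cycle), first- and
second-derivative maxima (grid-bracketed golden-section to $10^{-6}$; the
grid step is needed because the derivatives are flat far from the rise), and
Cy0, the $x$-intercept of the tangent at the FDM.  For these models
SDM < FDM and Cy0 < FDM always, and all markers are equivariant under cycle
translation.  The standard curve $C_q = \alpha + \beta \log N_0$ gives
$\hat E = \mathrm{base}^{-1/\beta}$, invariant to the logarithm base used
consistently on the abscissa.

## The synthetic world

`point_design()` emulates a 9-point, 3-curve, dilution-factor-2 growth-zone
design with $E = 1.85$ and additive constant-$\sigma$ Gaussian noise
$\sigma_y = 2.4$ RFU.  The source design's cycle layout and $y_0$ were never
printed, so this package fixes cycles $\{14,15,16\}, \{15,16,17\},
\{16,17,18\}$ (a one-cycle stagger approximates the factor-2 shift at
$E \approx 1.85$) and $y_0 = 0.009$.  With that layout the exact values span
42.4–169.4 RFU; the max/min ratio of the layout is exactly 4, so a wider
span such as 25–175 is geometrically impossible, and $y_0$ was chosen to
center the values in the 20–180 RFU zone.  The layout reproduces the
reference pair counts (36 pairs, 31 after same-cycle exclusion).  Because
the true design is an assumption, simulation results reproduce published
precision *factors* only approximately; the qualitative signature is what
the acceptance tests pin down.

`curve_design()` generates full logistic curves (plateau $y_{\max} = 600$
RFU, $E_0 = 1.9$, $y_0 = 0.02$ at cycle 0 for the most concentrated of 6
two-fold dilutions, 40 cycles, $\sigma_y = 2.4$, optional linear baseline).
$y_0$ is not a published value; it was chosen once so that every curve
plateaus well within 40 cycles and Cq markers fall mid-range.  The generator
emulates additive homoscedastic noise only — no pipetting-volume
variability, instrument drift, or non-Gaussian tails — so a green simulation
test establishes correctness of the estimators under the stated noise model,
not robustness to everything real plates do.

## Numerical choices

* All fits share one damped Gauss–Newton (Levenberg–Marquardt) engine:
  convergence when the largest relative parameter change drops below
  $10^{-10}$, at most 200 iterations; analytic Jacobians for the exponential
  and histogram models, central finite differences for the sigmoid.
  A priori SEs are $s_y^2 (J^{\top}J)^{-1}$ with $s_y^2 = \chi^2/\nu$.
* In the Monte Carlo summary, the apparent SE is averaged on the variance
  scale ($\sqrt{\overline{s^2}}$).  The plain mean of SEs is biased low by
  the $c_4$ factor ($\approx 0.965$ at $\nu = 7$), which would shift the
  direct estimator's actual/apparent ratio by $\sim$3.5% for a reason that
  has nothing to do with the estimator itself.
* Histogram normal fits use equal-width bins over mean $\pm 4$ SD, weights
  $1/\mathrm{count}$ (Poisson approximation), and exclude zero-count bins,
  where that weight is undefined; $\nu$ = used bins $-$ 3.  The default 30
  bins matches the convention that leaves $\nu \approx 27$.
* Growth-zone selection takes the first contiguous in-zone run entered from
  below and never includes points after the curve first exceeds the upper
  bound; bounds are inclusive (the natural reading of "20–180").  This
  guards against baseline spikes and plateau re-entry that a human fitter
  excludes by eye.

## Bias of growth-zone fits on logistic data

When growth is logistic, the local efficiency has already declined by the
time the signal is measurable, so exponential fits of the 20–180 RFU window
are biased low.  The package reproduces this at the default design
($E_0 = 1.9$), and single-curve fits are biased low at every rate tested.
One caveat found during validation: the *joint* multi-curve fit mixes the
(biased) within-curve slope with the cross-curve spacing, which reflects
$E_0$ faithfully; together with integer-cycle quantization of zone
membership this can, for particular rates (e.g. $E_0 = 1.80$ with the
default geometry), leave the joint estimate marginally *above* $E_0$.  The
low bias is the typical, not the universal, outcome for joint fits.

## Known limitations

* The seven-parameter log-logistic Cq model is replaced by the five-plus-two
  parameter form above; published Cq values that depend on the full model
  and on external raw data are out of scope.
* The pairwise estimator's apparent SEs are reported as defined — they are
  *meant* to be wrong under correlation; the Monte Carlo module is the tool
  that quantifies by how much.
* Ensemble dispersion beyond random noise (e.g. volumetric imprecision
  between replicate sets) is not modeled.
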