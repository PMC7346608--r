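# ampeff

Estimation of the qPCR amplification efficiency *E* from dilution-series
fluorescence data, with honest error bars.

qPCR quantification hinges on *E*, the per-cycle growth factor
(1 ≤ *E* ≤ 2).  In the exponential growth zone of a baselined curve,
*y* = *y*₀ *E*ˣ, and a dilution series with factor *D* obeys
*y*ᵢⱼ = *y*₀ *E*^xᵢⱼ / *D*ʲ.  `ampeff` implements, side by side:

* **`fit_direct()`** — the statistically correct joint NLS fit of all
  growth-zone points for (*y*₀, *E*);
* **`fit_differences_naive()`** — a fit of all C(n,2) pairwise differences
  that (deliberately) treats them as independent, demonstrating the
  pseudo-replication fallacy: reusing each raw point *n*−1 times shrinks the
  *apparent* SE by ~2× while the *actual* precision gets no better;
* **`fit_differences_gls()`** — the correlated-data GLS that fits any
  spanning set of *n*−1 differences plus one anchor point with weight matrix
  (*LL*ᵀ)⁻¹ and reproduces the direct fit's parameters *and* SEs exactly;
* **`estimate_pairwise()`** — the pairwise intensity-ratio estimator
  ln *E*ᵢⱼ = [ln *y*ⱼ − ln *y*ᵢ + (*j*ⱼ−*j*ᵢ) ln *D*]/(*x*ⱼ−*x*ᵢ) with
  proper error-propagation weights *w* ∝ (Δx)² yᵢ²yⱼ²/(yᵢ²+yⱼ²) and
  outlier-zone flagging (*E* < 1.60, *E* > 2.15);
* **`fit_sigmoid_curve()` / `compute_cq()` / `standard_curve_fit()`** — Cq
  standard-curve calibration (threshold, FDM, SDM, Cy0 markers on a
  log-logistic + sloping-baseline fit; slope = −1/log *E*);
* **`simulate_points()` / `simulate_curves()` / `run_mc_comparison()`** — a
  seeded synthetic-data generator (exponential and logistic growth, additive
  constant-σ Gaussian noise) and a Monte Carlo engine comparing apparent
  vs. actual estimator precision.

## Worked example

Simulate one 6-concentration, dilution-factor-2 series of logistic curves
(plateau 600 RFU, *E*₀ = 1.9, σ_y = 2.4 RFU), then estimate *E* three ways:

```r
library(ampeff)
ser <- simulate_curves(curve_design(), n_sets = 1, seed = 42)[[1]]
pts <- select_growth_zone(ser, growth_zone(20, 180))

fit_direct(pts)
#> <exp_fit: direct>
#>   E  = 1.84704 (se 0.0124)
#>   y0 = 0.0254833 (se 0.00295)
#>   chisq = 938.583 on nu = 22  (s_y = 6.532); converged in 7 iter

estimate_pairwise(pts)
#> <pairwise_summary>
#>   weighted   E = 1.8487 (a priori se 0.0049, post-se 0.0041)
#>   unweighted E = 1.8391 (se 0.0102)
#>   chisq = 181.2 on nu = 252; 253 pairs
#>   NOTE: apparent SEs only; pairwise estimates are correlated

cqs <- vapply(ser$curves, function(crv)
  compute_cq(fit_sigmoid_curve(crv), "Cy0")$cq, numeric(1))
js <- vapply(ser$curves, `[[`, integer(1), "dilution_exponent")
standard_curve_fit(cqs, -js * log10(2), base = 10)
#> <calibration_fit> slope = -3.6233 (se 0.0474), E = 1.88795 (se 0.01569)
#>   chisq = 0.01424 on nu = 4 (n = 6, log base 10)
```

Reading: the growth-zone fits land near 1.85 — *below* the generating
*E*₀ = 1.9, because by 20–180 RFU logistic growth has already slowed — while
Cy0 calibration recovers 1.888 ± 0.016.  The pairwise estimator's a priori
SE (0.0049) looks 2.5× better than the direct fit's (0.0124), but that
precision is an artifact of reusing 24 points in 253 correlated pairs, as
the Monte Carlo study shows:

```r
run_mc_comparison(mc_config(n_sim = 2000, seed = 7))
#> <mc_result> 2000 simulations (seed 7, 0 non-converged)
#>   direct          actual SD 0.01399 | apparent SE 0.01398 | ratio 1.00
#>   naive_diffs     actual SD 0.01600 | apparent SE 0.00663 | ratio 2.41
#>   pairwise_ratio  actual SD 0.01463 | apparent SE 0.00749 | ratio 1.95
#>   actual SD, pairs / direct: 1.046
```

The direct fit's error bars mean what they say (ratio 1.00); both
pairs-based estimators claim ~2× more precision than they deliver, and their
actual scatter is *worse* than the direct fit's.

## Command line

```sh
Rscript -e 'ampeff::ampeff_cli()' simulate --seed 4 --out series.csv
Rscript -e 'ampeff::ampeff_cli()' fit      --in series.csv --out fit.json
Rscript -e 'ampeff::ampeff_cli()' pairwise --in series.csv --out pairs.json
Rscript -e 'ampeff::ampeff_cli()' gls      --in series.csv --out gls.json
Rscript -e 'ampeff::ampeff_cli()' calibrate --in series.csv --out cal.json --cq-out cq.csv
Rscript -e 'ampeff::ampeff_cli()' mcstudy  --n-sim 4000 --seed 1 --out mc.json
```

Global flags: `--growth-zone 20,180`, `--dilution-factor 2`, `--seed`,
`--config FILE` (key-value overrides), `--out`.  Input is tidy CSV with
columns `well, dilution_exponent, cycle, fluorescence`; reports are JSON
that round-trips at full precision.  Same seed ⇒ byte-identical output.

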