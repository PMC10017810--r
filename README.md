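# prowave

Multi-scale diagnostics for temperature–light species distribution models
(SDMs) of marine picoplankton, built around surface-ocean
*Prochlorococcus*.

Global statistical SDMs for *Prochlorococcus* predict abundance from sea
surface temperature and photosynthetically active radiation (PAR), and
score well globally. But a global R² can be carried almost entirely by the
existence of a thermal range boundary — the poleward drop from ~10⁵
cells/mL to near zero — rather than by any within-range response to the
covariates. `prowave` implements the diagnostics that make this
decomposition explicit:

- **A two-state threshold niche model** as the minimal competitor,

  $$\mathcal{C}(T) = \begin{cases} C & T \ge T_0 \\ 0 & T < T_0 \end{cases}$$

  with threshold $T_0 = 13\,^{\circ}\mathrm{C}$ and the viable-state
  constant $C$ estimated by minimizing the residual variance; the
  closed-form solution is the difference of conditional mean abundances
  above and below the threshold. `fit_two_state()` returns a classed model
  with `print`, `summary`, `coef`, `predict`, `residuals`, `simulate` and
  `plot` methods.
- **Haar-wavelet transition detection** on along-track abundance series:
  the sustained-change statistic
  $S(t) = [\bar f_{[t, t+\alpha)} - \bar f_{[t-\alpha, t)}]/\alpha$
  (cells/mL/km; equal to the slope on linear ramps and to height/α at an
  ideal step), with a 10 cells/mL/km filter, a 100 km separation rule and
  a 75,000 cells/mL regime-crossing flag (`detect_transitions()`,
  `scalogram()`).
- **Scale-dependent correlation** between Haar-filtered abundance and
  temperature across 10–3000 km (`scale_correlation()`), which localizes
  where in scale the temperature–abundance association lives.
- **Satellite colocalization** with the daily same-date rule, ±0.25°
  temperature and 9 km PAR tolerances, and exponential PAR attenuation
  with $k = 0.1\ \mathrm{m}^{-1}$ (`colocalize_records()`,
  `attenuate_par()`).
- **Monthly station fluctuation statistics**: cruise means, monthly bins,
  consecutive-month deltas, bootstrap Pearson uncertainties, quadrant
  fractions and a two-predictor R² (`pearson_boot()`,
  `quadrant_fractions()`, `bivariate_r2()`).
- **Model comparison** in linear and log space, with the zero-abundance
  convention $\log_{10}(\max(x, 1))$ (`compare_models()`, `goodness()`,
  `log10_clip()`).
- **Seeded synthetic generators** for all three data kinds — global
  surface snapshots, cruise tracks with planted transitions, station
  series with planted delta-correlations — each returning ground truth so
  every estimator is covered by parameter-recovery tests.

## Worked example

```r
library(prowave)

# a synthetic global surface snapshot with the planted two-state structure
g   <- generate_global_surface(5000, seed = 1)
fit <- fit_two_state(g$observations)
summary(fit)
#> Two-state threshold niche model
#>   threshold: 13 degC (fixed)
#>   c_high:    43037.5 cells/mL (objective: variance, linear space)
#>   fitted on 5000 observations (3480 above / 1520 below threshold)
#>   R^2 (linear): 0.3091   residual variance: 8.759e+08
#>   R^2 (log):    0.9660   residual variance: 0.1393
```

The fitted constant recovers the planted 42,000 cells/mL to within the
viable-state noise; the high log-space R² against the low linear-space R²
is the signature of skill dominated by the high/low split rather than
within-state variation.

```r
# a 2000 km track with one planted niche transition at 500 km
tr <- generate_cruise_track(
  cruise_track_cfg(boundaries_km = 500, means = c(5000, 155000)), seed = 7)
detect_transitions(tr$track)[, c("distance_km", "statistic",
                                 "crosses_regime_threshold")]
#>   distance_km statistic crosses_regime_threshold
#> 1         340 -10.06775                    FALSE
#> 2         500 962.33457                     TRUE
#> 3         700 -12.80214                    FALSE
#> ...
```

The planted boundary is found at 500 km with statistic ≈ 10³ cells/mL/km
(the step height 1.5×10⁵ over α = 150 km) and is the only detection that
crosses the 75,000 cells/mL regime threshold; the small-magnitude entries
are within-regime noise peaks that pass the 10 cells/mL/km filter but not
the regime-crossing criterion.

```r
# station series with a planted dPAR-dPro correlation of -0.35
st <- generate_station_series(seed = 1)
de <- consecutive_deltas(st$monthly)
pearson_boot(de$dPAR, de$dPro, seed = 1)
#> Pearson R = -0.402 +/- 0.045 (R^2 = 0.162, n = 359, bootstrap)
```

A full staged run (synthetic inputs → fit → evaluation → fluctuations →
transitions → scale curve, with CSV outputs and a checksummed manifest):

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "prowave_out")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/prowave.R run-all --seed 1 --out-dir prowave_out`.

See `vignettes/multiscale-diagnostics.Rmd` for the model derivations,
discretization choices, generator assumptions and limitations.

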