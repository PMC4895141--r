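# ricepheno

Rice phenology models, cultivar calibration and warming-bias analysis.

## What this package is for

Climate-impact projections for rice stand on the phenology submodel of a
crop model: how fast a cultivar develops from emergence to flowering and to
maturity as a function of temperature. Models that agree on historical
seasons can diverge sharply when extrapolated to warmer ones, and the shape
of the temperature response decides how. `ricepheno` is for crop modellers
and agro-climatologists who want to quantify that effect: it implements
four canonical temperature-response families, auto-calibration of cultivar
parameters on cooler trials, validation on warmer trials, and a
quantile-regression analysis of how prediction bias trends with
growing-season warming — together with a synthetic multi-site trial
generator with known ground truth, so the whole pipeline is testable end to
end.

## The model

The daily development rate is driven by the daily mean temperature
`T = (Tmin + Tmax)/2` through one of four response functions:

| family | rate r(T) | shape |
|---|---|---|
| GDD | max(0, T − Tb) | linear, no optimum |
| exponential | 1 − exp(−TSEN (T − Tb)) | saturating, no optimum |
| bilinear | rise (T−Tb)/(To−Tb), fall (Tc−T)/(Tc−To) | optimum at To, zero at Tc |
| beta | [((T−Tb)/(To−Tb)) ((Tc−T)/(Tc−To))^((Tc−To)/(To−Tb))]^TSEN | unimodal, max 1 at To |

A stage is reached on the first day the cumulative rate meets the stage's
thermal requirement (theta_flowering < theta_maturity; whole days, day
after emergence = DAE 1). Calibration minimizes the summed squared day
errors over both stages; the thermal requirements have a closed-form inner
solution (the mean accumulated units at the observed stage dates), and the
shape parameters are searched by exhaustive grid (one free parameter) or a
seeded Latin-hypercube multistart with local refinement (several).

The analysis design: within each cultivar, every trial's growing season
temperature (GST; mean daily temperature from emergence to maturity) is
referenced to the coolest trial (delta-GST). Trials with delta-GST at or
below 1, 2 or 3 degrees Celsius calibrate the model; warmer trials validate it.
Percent bias `100 (sim − obs)/obs` of the validated predictions is
regressed on delta-GST at the 0.025, 0.5 and 0.975 quantiles (an exact
check-loss minimizer implemented in the package) and tested per cultivar
with an OLS slope t-test at the 5% level.

## Worked example

Generate one synthetic cultivar (30 trials spanning ~6 C of GST, monotone
GDD truth, 2 days of observation noise), calibrate the bilinear family on
the cooler trials and examine its bias on the warmer ones:

```r
library(ricepheno)

tp <- default_truth_params("IR_demo", model = "gdd", seed = 2)
d  <- trial_design(n_cultivars = 1, trials_range = 30, target_gst_span = 6,
                   obs_noise_sd = 2, seed = 42)
ds <- generate_trials(d, true_params = tp)
tg <- assign_delta_gst(ds$trials, ds$weather)
sp <- split_experiment(tg, "IR_demo", 2)
#> <calibration experiment: cultivar IR_demo, threshold 2 | 9 calibration, 21 validation trials>

cal <- ds$trials[ds$trials$trial_id %in% sp$calibration_ids, ]
fit <- calibrate_cultivar(cal, ds$weather, "bilinear", seed = 1)
summary(fit)
#> Calibrated bilinear phenology model for cultivar IR_demo
#> <bilinear response: Tb=9.7, To=30.7, Tc=38>
#>   thermal requirements: flowering 68.89, maturity 103.09 units
#>   calibration trials: 9 | objective: 42.805 days^2 | converged: TRUE
#>
#> Calibration agreement (simulated vs observed DAE):
#>   flowering: n=9  MAD=1.22 d  alpha=0.767  beta=20.33 d  R2=0.837  NRMSE=1.89%
#>   maturity:  n=9  MAD=1.22 d  alpha=0.920  beta=10.46 d  R2=0.857  NRMSE=1.36%

val <- ds$trials[ds$trials$trial_id %in% sp$validation_ids, ]
v   <- validate_cultivar(fit, val, ds$weather, trials_gst = tg)
pb  <- percent_bias(v$obs_maturity, v$sim_maturity)
quantile_trend(v$delta_gst, pb, tau = 0.5)
#> <tau=0.500 quantile trend: bias = -14.029 +6.896 * dGST  (n=21)>
cultivar_bias_test(v$delta_gst, pb)
#>    n  slope p_value significant mean_bias mean_bias_p
#> 1 21 6.4686       0        TRUE   10.4218           0
```

The calibration fit looks excellent (MAD 1.2 days, NRMSE under 2%), yet the
bilinear model — whose optimum-temperature shape contradicts the monotone
truth — overestimates maturity duration progressively as seasons warm: the
median bias grows by about 6.9 percentage points per degree of delta-GST,
and the per-cultivar trend test flags it decisively. Refitting with
`model = "gdd"` (the matched family) gives a flat trend; that contrast is
the package's central experiment, run at scale by `mismatch_experiment()`
and `run_experiment()`.

`run_experiment()` orchestrates the full grid (models x thresholds x
cultivars, including the all-data control), writing calibrated parameters,
a Table-of-metrics summary, bias records, quantile trends, per-cultivar
tests, per-trial predicted stage dates (for downstream yield modelling) and
a manifest — all seeded and byte-reproducible. A thin command-line wrapper
lives at `inst/scripts/ricepheno.R`.

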