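# egretwatch

Synthetic-scene generation and post-detector analysis for camera-based
monitoring of roosting egrets.

Automated bird monitoring pairs an object detector with two computational
workloads that this package implements end to end, at desk scale, in R:

1. **Domain-randomized training scenes.** Procedural bird sprites
   (great egret / little egret / other) are pasted onto textured
   backgrounds with three operators — direct alpha copy, Gaussian-feathered
   alpha, and Poisson gradient-domain blending (per channel, solve
   `∇²f = ∇·∇g` on the sprite region with the background as Dirichlet
   boundary) — under randomized size (uniform 0.04%–0.56% of frame area),
   lighting (uniform 0.6–1.0 multiplicative), 2D pose (rotation, flip,
   shear) and placement, writing COCO annotations.
2. **Detection-stream analysis.** From time-stamped scored boxes:
   - IoU-matched evaluation: precision–recall curves and AP/mAP at a fixed
     IoU threshold, AP as the area under the precision envelope over
     recall 0→1;
   - daily maximum counts (occupancy proxy), inter-species Pearson
     correlation, and departure/return schedules as argmaxes of the
     backward 1-h moving average in morning/evening windows, with paired
     t-tests (two-tailed for equal departures; one-tailed for the return
     order);
   - spatio-temporal heatmaps on a 200-px cell grid:
     `x_i = Σ_j exp(−β·d(p_i,p_j))·c_j`, then exponential time smoothing
     `s_t = λ·x_t + (1−λ)·s_{t−1}`, averaged per period, rendered
     red/blue per species;
   - detrended weather regression: quadratic-in-time detrending of
     log counts and of twelve daily weather factors, then a no-intercept
     multivariable fit with t/F tests and a table-shaped report;
   - feature-map visualization: split features against the downstream
     affine operator via `AAᵀx̂ = Ax`, `x_r = Aᵀx̂`, `x_n = x − x_r`;
     PCA to three fields; combine with the grayscale weights
     `V = 0.7152·V₁ + 0.2126·V₂ + 0.0722·V₃`; viridis overlay.

A synthetic-data module simulates the whole monitoring world — 2139×1281
frames, recording 04:00–20:00 over 62 days, a diurnal occupancy trapezoid,
a multi-day trend with a migration surge, vertical stratification of the
two egret species, and weather linked to log counts through known
coefficients — and emits a ground-truth ledger so every estimator is
tested by parameter recovery. See `vignettes/egretwatch-methods.Rmd` for
the model details and design choices.

## Worked example

```r
library(egretwatch)

cfg <- sim_config(day_span = seq(as.Date("2019-09-23"), by = "day",
                                 length.out = 14),
                  frame_interval = 300, rng_seed = 7)
sim <- simulate_detections(cfg)          # 52,056 detection records

great  <- daily_count(sim$records, "great_egret")
little <- daily_count(sim$records, "little_egret")
head(great, 3)
#>         date count
#> 1 2019-09-23    29
#> 2 2019-09-24    57
#> 3 2019-09-25    42
pearson(great, little)
#> [1] 0.855        # the two species' daily counts co-vary strongly

sg <- daily_schedule(sim$records, "great_egret")
sl <- daily_schedule(sim$records, "little_egret")
ht <- schedule_tests(sg$departure_min, sl$departure_min,
                     sg$return_min, sl$return_min)
c(HT1 = ht$ht1$p_value, HT2 = ht$ht2$p_value)
#>     HT1     HT2
#> 0.759   0.00279
# HT1: no evidence the departure times differ (they are planted equal);
# HT2: the little egret returns significantly later (planted +45 min).

sw <- simulate_weather(sim_config(rng_seed = 7), noise_sd = 0.25)
wr <- weather_regression(sw$weather)
wr$report
#> Multivariable linear regression (detrended)
#>   n = 62   R^2 = 0.984   F p-value = 1.189e-40
#>                   factor estimate p_value mark
#>        mean_pressure_hpa  -0.0031   0.780
#>           abs_max_temp_c   0.2152   0.000    *
#>              mean_temp_c  -0.8470   0.000    *
#>           abs_min_temp_c   0.0100   0.727
#>         mean_dew_point_c   0.7107   0.000    *
#>    mean_rel_humidity_pct  -0.1904   0.000    *
#>           mean_cloud_pct  -0.0018   0.271
#>        total_rainfall_mm  -0.0159   0.204
#>  total_bright_sunshine_h  -0.1316   0.000    *
#>      mean_wind_speed_kmh   0.0108   0.143
#>          wind_dir_ew_deg   0.0065   0.000    *
#>          wind_dir_ns_deg   0.0019   0.002    *
#>   * p < 0.05 (significant)   ** p < 0.10 (marginal)
# Estimates sit on the planted coefficients (e.g. mean temperature
# planted at -0.8448, recovered -0.8470); at noise_sd = 0 recovery is
# exact to 1e-8.
```

Compose a synthetic training set and run the whole pipeline:

```r
generate_dataset("scenes", n_images = 1000, seed = 7)   # COCO annotations
run_pipeline(load_run_config(), out_dir = "demo_run")   # all 7 stages
```

or from the shell via the CLI (`inst/cli/egretwatch`):

```sh
Rscript inst/cli/egretwatch run --config inst/config/demo.yaml --out demo_run
Rscript inst/cli/egretwatch compose --n 1000 --seed 7 --paste poisson --out scenes
```

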