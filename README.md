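# efferotrack

Quantitative analysis of live-imaging data on microglial efferocytosis —
the engulfment and removal of apoptotic neurons by brain-resident
macrophages. Microglia engulf dying neurons either at the tip of long
branches (branch-mediated, BM) or directly at the soma (NBM), and the
position of the centrosome relative to the forming phagosome predicts
whether an attempt succeeds. This package implements the measurements that
support such studies, working from the tabular exports of tracking and
segmentation tools (per-object coordinate time series, event tables,
per-frame volume/surface measurements) rather than from raw images.

It provides, as pipeable functions over data frames:

* **Motility** — mean speed along the track; the time-averaged mean square
  displacement
  ξ(n) = (1/(N−n+1)) Σᵢ ‖x₍ᵢ₊ₙ₎ − xᵢ‖², its log–log OLS slope α
  (anomalous-diffusion exponent), and regime classification
  (subdiffusive / diffusive / superdiffusive / ballistic).
* **Morphology** — sphericity ψ = π^⅓(6V)^⅔ / A from segmented volume and
  area, time series and paired before/after comparisons; branch lengths;
  branch-tip extension/retraction speeds.
* **Events** — attempt rates, success and BM fractions; rank-based group
  comparisons (Mann–Whitney, Kruskal–Wallis, Friedman with Dunn follow-ups)
  with the conventional star banding.
* **Spatial statistics** — first-nearest-neighbour distances; waiting time
  vs spatial separation of consecutive engulfments with OLS fit and 95%
  confidence band.
* **Centrosome–phagosome geometry** — the cc–cs–p triangle per frame,
  event-aligned ±10 min windows, mean ± SD averages, alignment angles at a
  fixed offset after onset, circular variance (Jammalamadaka–SenGupta,
  1 − R̄), polar-frame centrosome tracks, radial probability maps.
* **Synthetic data** — generators with known ground truth (random-walk
  regimes, hard-core point populations, a full efferocytosis scenario in
  which the centrosome drifts toward successful targets before onset, shape
  series, double-centrosome variants), so every analysis stage is testable
  without imaging data.

Fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(efferotrack)
library(dplyr)

cfg <- sim_config(seed = 1)      # defaults emulate the study conditions
ds  <- efferocytosis_scenario(cfg)
ds
#> <effero_dataset> 10 cells, 80 events, 7850 track rows

windows <- event_windows(ds)                 # cc-cs-p triangle, +/- 10 min
angles  <- angles_at_offset(windows, offset = 1) |> filter(!is.na(theta))
angles |>
  group_by(outcome) |>
  summarise(mean_theta = mean(theta),
            circ_var = circular_variance(theta), n = n())
#>   outcome    mean_theta circ_var     n
#> 1 aborted         1.66    0.187     30
#> 2 successful      0.400   0.0639    50
```

One minute after onset, the centrosome of a *successful* attempt points
almost directly at the phagosome (mean angle 0.40 rad ≈ 23°, circular
variance 0.06 — tightly concentrated), while for *aborted* attempts the
angle is near the isotropic expectation π/2 (1.66 rad) with an order of
magnitude more dispersion: centrosomal alignment discriminates outcomes.

```r
tr <- ds$tracks |> filter(role == "centre", cell_id == "cell01") |>
  rename(object_id = cell_id)
tidy(fit_msd(tr))
#>   object_id alpha intercept r_squared n_used regime
#> 1 cell01    0.687     -1.49     0.975     90 subdiffusive
```

The simulated cell centre is confined (OU) motion, and its MSD exponent
α ≈ 0.7 < 1 classifies it as subdiffusive — matching how resting microglia
move in vivo.

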