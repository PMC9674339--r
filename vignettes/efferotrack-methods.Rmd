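---
title: "Quantifying microglial efferocytosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial efferocytosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efferotrack)
library(dplyr)
library(ggplot2)
```

efferotrack analyses tabular exports from live imaging of microglia engulfing
apoptotic neurons (efferocytosis): per-object coordinate time series ("track
tables"), engulfment-event tables, and per-frame volume/surface measurements.
This vignette explains the quantitative models behind each analysis, the
parameters that matter, and the choices made where the design was open.
All internal units are micrometres and minutes; readers convert declared
source units at load.

## Motility: mean speed and the MSD exponent

`mean_speed()` divides the cumulative path length by the total tracking time.
We read "displacement along the track" as path length, not net start-to-end
displacement: an out-and-back excursion of 1 µm each way over 2 min has mean
speed 1 µm/min, not 0. Net displacement is deliberately used nowhere else, so
the two conventions cannot be confused downstream.

Persistence of migration is quantified by the time-averaged mean square
displacement. For a uniformly sampled track with $N$ steps,

$$\xi(n) = \frac{1}{N-n+1}\sum_{i=0}^{N-n}\lVert x_{i+n}-x_i\rVert^2,
\qquad n = 1,\dots,N,$$

and `msd_alpha()` fits $\alpha$ as the ordinary least-squares slope of
$\log\xi(n)$ against $\log n$. The regression is unweighted; the default uses
every integer $n$ with $\xi(n)>0$. Because $\xi$ at large $n$ averages very
few displacement pairs, `n_range` (or `n_max` in `msd()`) lets the caller
restrict the fit; the Brownian-recovery checks in the test suite use
$n \le N/4$, a common compromise between bias and variance in
single-particle tracking. Uniform sampling is required (relative tolerance
$10^{-6}$ on the frame interval); irregular tracks are rejected with advice
to resample rather than silently interpolated.

Regime classification follows the standard single-particle-tracking
convention: $\alpha \approx 1$ ordinary diffusion, $\alpha < 1$
subdiffusion, $1 < \alpha < 2$ superdiffusion, $\alpha = 2$ ballistic.
Part of the source literature's prose garbles these thresholds (placing
"regular diffusion" at $\alpha = 0$), which is internally inconsistent with
$\alpha = 2$ for straight tracks; the package keeps the standard convention.
Point thresholds are softened by a configurable band `epsilon` (default 0.1)
so that estimated exponents near a boundary are not classified on noise.

```{r msd-example}
cfg <- sim_config(seed = 42, n_steps = 100)
fit <- fit_msd(walker_track(cfg, "brownian"), n_max = 25)
tidy(fit)
```

## Morphology: sphericity

Sphericity is computed from segmented volume and surface area,
$\psi = \pi^{1/3}(6V)^{2/3}/A$, equal to 1 for a sphere and smaller for any
other closed surface (isoperimetric inequality). Segmentation itself is out
of scope; the package consumes $(V, A)$ tables. `sphericity_series()` adds a
paired before/after comparison around a treatment time $t_0$ — by default
the single nearest frame on each side, or window means when widths are
given — matching how a morphology switch (e.g. branched to amoeboid after
microtubule depolymerisation) is scored.

The test suite checks $\psi$ against exact polyhedral geometry from
`star_mesh()`/`mesh_volume_area()`: a refined lat-long sphere mesh converges
to $\psi = 1$ within $10^{-3}$, and random smooth star-shaped meshes always
give $\psi \le 1$ because area and volume are computed exactly for the
polyhedron itself.

## Events: rates, composition, statistics

`event_summary()` reports attempts per hour (count over observation time),
the successful fraction, and the branch-mediated (BM) fraction. Events with
unknown mode are excluded from the BM denominator — reporting a proportion
over unscored events would bias it toward whatever the scorer skipped.
Empty inputs give rate 0 and undefined (`NA`) fractions.

`compare_groups()` delegates to `wilcox.test`, `kruskal.test` and
`friedman.test` as appropriate to the design, with Bonferroni-corrected
pairwise Mann–Whitney follow-ups for independent groups and Dunn's rank-sum
follow-ups for the repeated design. These are deliberately thin wrappers:
the package adds only the design dispatch and the star banding
(`p_stars()`), not new statistics.

## Spatial statistics

`nearest_neighbour_distances()` returns each point's distance to its closest
other point (k = 1), computed from the full pairwise distance matrix —
exact, vectorised, and fast at tissue scale (tens to hundreds of cells).

`event_pair_table()` forms, within each cell, consecutive pairs of
*successful* events ordered by onset, yielding the waiting time $\Delta t$
and the spatial separation $\Delta d$ of the two engulfment positions. By
default positions are taken relative to the cell centre at each event time
(`relative_to_cell = TRUE`): the biological question is how far the cell had
to repolarise, not how far apart the targets sat in the tissue. Both
conventions are available and tested. `spacetime_correlation()` then fits
$\Delta t \sim \Delta d$ by OLS with a pointwise 95% confidence band;
because pooling cells with different event rates can induce or mask
correlation, per-cell fits are reported alongside the pooled fit whenever a
cell contributes at least 3 pairs.

## Centrosome–phagosome geometry

The core analysis tracks the triangle formed by the cell centre (cc), the
centrosome (cs) and the phagosome (p) around each engulfment attempt:

* `d_cs_cc` — centrosome distance from the cell centre;
* `theta` — angle between the vectors cc→cs and cc→p, in $[0, \pi]$, via
  the arccosine of the normalised dot product (0 = centrosome exactly on
  the axis toward the phagosome);
* `d_p_cc` — phagosome distance from the cell centre.

Windows span ±10 min around onset and are *truncated* at track boundaries
rather than discarded — a window reaching "up to" the half-width implies
partial windows are kept, and discarding them would bias averages toward
events far from recording edges. Phagosome positions before tracking starts
use the temporally closest known location (typically the first tracked
frame); exact-tie lookups resolve to the earlier frame. Frames where cs
coincides with cc yield a missing angle rather than an error, so one
degenerate frame cannot abort a series.

`align_and_average_windows()` aligns windows at onset and averages per grid
point, reporting mean, SD and the number of contributing windows. The
default grid is the native frame interval (no interpolation); an explicit
`grid_dt` supports pooling across sampling rates. `angles_at_offset()` reads
the angle at the grid point nearest a requested offset (default +1 min after
onset) — nearest-frame lookup, never interpolation, because averaging angles
across frames risks wrap artefacts.

`circular_variance()` implements the Jammalamadaka–SenGupta estimator
$1-\bar R$, with $\bar R$ the mean resultant length: 0 when all angles
coincide, 1 when they cancel completely. Parts of the source literature's
prose describe the opposite convention (0 = homogeneous); the cited
estimator and its reference implementations behave as implemented here, and
the package follows the estimator, not the prose.

`polar_track()` re-expresses the centrosome in a per-event polar frame
(origin cc(t), zero-angle axis cc→p(t), re-derived every frame). In 2D,
$\varphi$ is the ordinary signed angle. In 3D a sign needs a reference
normal; we fix it as the unit cross product (p−cc)×(cs−cc) at the first
non-degenerate frame. The rule is arbitrary but deterministic, and because
proper rotations commute with the cross product the resulting $(r, \varphi)$
are rigid-motion invariant — verified directly in the tests.

`radial_probability_map()` histograms $\lVert cs-cc\rVert/R$ (cell radius
$R$ from soma oval fits) into probability masses summing to 1, and
`centrosome_distance_at_events()` collects `d_cs_cc` at onset per outcome
and treatment group, ready for `compare_groups()`.

## The synthetic-data generator

Raw light-sheet recordings are large and interactive tracking is manual, so
every analysis stage is exercised against generated data with known ground
truth. `efferocytosis_scenario()` encodes the qualitative biology as a
minimal stochastic model:

* cell centres wander slowly (Ornstein–Uhlenbeck, speed scale
  `cc_speed` = 0.6 µm/min, matching reported microglia speeds of
  ~0.01 µm/s);
* engulfment targets sit at branch tips (BM, length ~N(20, 3) µm) or at the
  soma edge (NBM, `cell_radius` = 5 µm);
* the centrosome is an OU walk around the cell centre (noise scaled so its
  relative speed is ~2 µm/min, stationary spread ~1.6 µm) that, for
  successful events only, acquires a drift of strength
  `bias_strength × approach_speed` toward the phagosome from
  `bias_leadtime` = 5 min before onset until onset, then returns to the
  soma. Aborted attempts get no bias at any time.

The OU-plus-drift bias model is an artifact of this package — consistent
with, but not prescribed by, the imaging literature it emulates. Defaults
(`dt` = 0.5 min emulating 30-s light-sheet sampling; 10 cells × 8 events;
60% success, 70% BM; `bias_strength` = 0.8) were chosen once to mirror the
reported magnitudes and a clearly polarised successful cohort; with them the
successful/aborted contrast in alignment angle and per-cell circular
variance holds across every seed of the 20-seed test battery, and with
`bias_strength = 0` the two outcome classes are statistically
indistinguishable, with mean angle at the isotropic expectation $\pi/2$ and
pooled circular variance near the uniform-sphere value $1-\pi/4$.

Outcome and mode labels are assigned in exact per-cell proportions with
randomised order rather than independent coin flips, so every cell
contributes both outcomes to per-cell statistics regardless of seed.
Consecutive attempts are spaced `event_spacing` = 22 min apart — wider than
the real per-cell attempt rate — so that the ±10 min event-aligned windows
of consecutive events never overlap and each window reflects a single
attempt's dynamics; analyses that need realistic rates can lower the
spacing explicitly.
All generators are pure functions of their `sim_config()`; equal configs
give bit-identical output.

What the generator does *not* emulate: segmentation error and tracking
dropouts, anisotropic point-spread blur, cell–cell contact, branch geometry
(targets are points, not tips of a resolved branch skeleton), and any
signalling dynamics. Passing tests therefore demonstrate that the analysis
recovers known structure from data of the assumed form — not that real
imaging data satisfy those assumptions.

`cell_population()` places ~30 microglia with a 20-µm hard-core rule in a
160 × 160 × 80 µm box (nearest-neighbour spacing ~30 µm) with a uniform
scatter of apoptotic-neuron points; `shape_series()` produces constant-volume
$(V, A)$ series whose area relaxes to the spherical bound after a switch
time, guaranteeing a monotone sphericity increase; `two_centrosome_variant()`
adds a second centrosome and temporally overlapping successful events to
flagged cells, with the serving centrosome recorded in the ground truth.

## Numerical choices and edge cases

* Angles use `acos` of a dot product clamped to $[-1, 1]$; zero-length
  vectors yield `NA` angles, never errors mid-series.
* MSD requires ≥ 2 frames; single-frame tracks error on `mean_speed()`
  ("undefined speed"); tracks with all $\xi(n)=0$ error as degenerate in
  the $\alpha$ fit.
* Track CSVs are written with `%.17g` formatting and parsed with base R's
  correctly-rounded reader, so read → write round-trips are bit-exact.
* Problem sizes in the test suite (e.g. 5000 × 100-step Brownian tracks for
  exponent recovery, $10^5$ points for the radial-map law, 20-seed
  discrimination battery) were chosen as the smallest sizes at which the
  theoretical values are sharp enough to test against at the stated
  tolerances.

## Worked example

```{r pipeline}
cfg <- sim_config(seed = 1)
ds <- efferocytosis_scenario(cfg)
ds

windows <- event_windows(ds)
angles <- angles_at_offset(windows, offset = 1)
angles %>%
  filter(!is.na(theta)) %>%
  group_by(outcome) %>%
  summarise(mean_theta = mean(theta),
            circ_var = circular_variance(theta), n = n())
```

```{r plot, fig.width = 6, fig.height = 6}
autoplot(align_and_average_windows(windows, outcome = "successful"))
```

## Known limitations

Dialect readers for proprietary exports are best-effort emulations of
commonly seen column layouts, not format specifications. The nearest-
neighbour search is quadratic in the number of points; fine for cell-scale
point sets, not for millions of localisations. Hypothesis tests reproduce
the reporting conventions of the imaging literature but make no claim of
reproducing any particular study's p-values, which depend on the underlying
raw data.
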