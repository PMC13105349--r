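---
title: "From larval mortality to trans-oceanic dispersal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From larval mortality to trans-oceanic dispersal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleplan)
```

`teleplan` couples two models that marine ecologists usually keep in separate
toolboxes: an exponential survival model for larval cultures, and a
Lagrangian particle-tracking model for ocean dispersal. The link between
them is the *clutch-exhaustion pelagic larval duration* (PLD): how long the
ocean has to move a larva before the last member of its clutch has died.
This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions behind the implementation.

## The survival model and its estimator

Larval abundance in a culture is modelled as exponential decay,

$$N_t = N_0 \, e^{-Mt},$$

where $N_0$ is the initial abundance, $M$ the instantaneous mortality rate
(day$^{-1}$), and $t$ days since the time origin (conventionally hatching).
Abundance is not observed directly: a culture of container volume $V$ is
censused by counting a few well-mixed aliquots of volume $v$, and the
abundance estimate is the mean aliquot count scaled by $V/v$
(`counts_to_abundance()`).

`fit_mortality()` estimates $M$ by ordinary least squares of
$\ln N_t$ on $t$; $M$ is minus the slope and the intercept estimates
$\ln N_0$. Two fitting scopes are offered because raw census data come as
replicate cultures: `"pooled"` (default) regresses all replicate-census
points together, `"replicate"` fits each replicate and averages the slopes.
For balanced designs the two give nearly identical point estimates; the
pooled scope uses all points in one regression and is the default.

Numerical and statistical choices:

* **Zero counts.** A census with zero estimated abundance has no logarithm.
  Such censuses are dropped with a warning rather than pseudocounted;
  pseudocounts of arbitrary size would bias the tail of sparse series, and
  dropping is unbiased under the Poisson observation model whenever most
  censuses are positive.
* **Time origin.** Census times are taken relative to hatching (cultures are
  typically standardized at hatching, e.g. to 2 embryos/mL). A `t0` offset
  argument shifts the origin when times are recorded on another scale.
* **Precision.** The information in a census design is set by Poisson
  counting noise. At a typical design — 2000 larvae at hatching, six daily
  censuses, triplicate 1 mL aliquots of a 100 mL container, ten replicates —
  the standard error of $\hat M$ is about 0.012–0.014 day$^{-1}$ regardless
  of the estimator (this is close to the Fisher-information bound for the
  design), so individual fits carry relative errors of 5–10% at
  $M \approx 0.1\text{–}0.17$. The test suite measures exactly this
  recovery error on simulated data.

Fecundity ($N_0$ of a whole clutch) is estimated from serial dilutions
(`estimate_fecundity()`): eggs standardized to a total volume, diluted by
known factors, and counted in small aliquots; the point estimate is the mean
count scaled back through the dilution arithmetic.

## Pelagic larval duration and scenario arithmetic

The clutch-exhaustion PLD solves $N_0 e^{-Mt} = 1$:

$$t^\ast = \frac{\ln N_0}{M}.$$

It is the *maximum* dispersal window of a clutch — the age at which even the
last larva is expected dead — and is strictly increasing in fecundity and
decreasing in mortality. Because $t^\ast$ depends on $N_0$ only through a
logarithm, order-of-magnitude uncertainty in fecundity moves the PLD by
days, not months, while a mortality difference moves it proportionally.
With a clutch of $\sim 2\times 10^7$ eggs, mortality rates of 0.093 and
0.165 day$^{-1}$ give durations of 181 and 102 days — a 1.8× difference
from a 1.8× rate difference, since the fecundity is shared.

Two convenience ratios complete the arithmetic: `survival_ratio()` is the
ratio of surviving fractions of two scenarios at a common age,
$e^{(M_b - M_a)t}$; `duration_ratio()` is the longer-over-shorter PLD.

## Synthetic oceans

`make_ocean()` builds gridded velocity fields from analytic recipes defined
through stream functions in a tangent plane anchored at the domain's
reference latitude. Incompressibility is therefore exact in the analytic
field, and trajectories have closed forms that serve as oracles for the
advection kernel:

* `uniform` — constant flow; RK4 is exact here, so displacement must equal
  $u \cdot t$ to rounding.
* `solid_body` — rotation about a centre; the zonal component carries a
  $\cos\phi / \cos\phi_c$ factor so the trajectory is an exact circle in
  tangent-plane coordinates even under the spherical metric used by the
  integrator.
* `double_gyre` — the standard two-gyre benchmark on the domain rectangle,
  with optional time-periodic gyre-boundary oscillation.
* `coastal_jet_with_eddies` — an alongshore Gaussian jet whose axis meanders
  on and off a continental shelf, plus an optional ocean-crossing zonal
  current and a propagating eddy field. Streamlines of the steady jet are
  meander-parallel curves, so particles released on the shelf are swept off
  and back on shelf at predictable along-shore intervals — the feature used
  to exercise settlement and generation stepping.

Geometry: an optional meridional coastline marks everything east of
`coast_lon` as land; bathymetry shoals linearly from the 500 m isobath at
the shelf edge (`shelf_width_km` from the coast) to the coastline, and deep
ocean is a constant (default 4000 m). The shelf strip is thus exactly the
ocean cells shallower than 500 m, matching the isobath convention used to
delimit settleable habitat. Velocities are undefined (`NA`) on land. Fields
are stored at daily snapshots by default, mirroring the daily-mean output of
ocean circulation models; the sampler interpolates linearly in time.

What the synthetic fields deliberately do **not** emulate: mesoscale
turbulence spectra, realistic coastline geometry, vertical shear, seasonal
cycles. Tests passing on these fields demonstrate the correctness of the
kernels and rules, not skill against a real ocean; runs on real model output
require only that the velocities be expressed on the same lon–lat–time grid
structure.

## Synthetic censuses

`simulate_survival()` draws aliquot counts as Poisson with mean
$N_t \, v / V$ — the natural model for counting a small subvolume of a
well-mixed suspension; no observation-noise model beyond this is assumed,
and the latent decay is deterministic. `simulate_dilution_counts()` applies
the same Poisson subsampling to the serial-dilution geometry. Both are
seeded and bit-reproducible, and both restore the caller's RNG state.

## The advection kernel

`run_release()` advances particles with the classical fourth-order
Runge–Kutta scheme (`step_rk4()`), converting velocities to angular rates
with the spherical metric ($\cos\phi$ on the zonal term). Default step
`dt = 1/12` day (2 h), a conventional accuracy choice against daily-mean
fields; the quarter-period solid-body error halves sixteen-fold per `dt`
halving until the bilinear field-representation floor (~$10^{-5}$ degrees on
a 0.05° grid) is reached. Velocity sampling (`sample_velocity()`) is
bilinear in space and linear in time; land nodes are excluded from the
stencil with weight renormalization, so near-coast particles feel only
ocean velocities.

Boundary policy (`apply_boundary()`): a step that would land on a land cell
or leave the domain is rejected — the particle keeps its position for that
step and is flagged as a stranding candidate. Stranding never kills a
particle; settlement is decided solely by the settlement rules. This
"revert and flag" anti-beaching policy avoids artificial particle loss on
idealized coastlines and is recorded per particle so runs can be audited.
Release positions are jittered uniformly within the release cell (seeded)
and clamped into the domain; release depth is drawn uniformly in 0–30 m and
carried as metadata — advection is single-layer by design, since vertical
structure adds nothing at desk scale for passive particles; layered fields
can be run one layer at a time.

Two bookkeeping invariants are enforced and tested: released = pending +
active + expired at every instant, and runs are bit-identical given
identical (field, schedule, seed, dt). The random draws depend only on the
schedule and seed — not on the lifetime — so two runs differing only in
lifetime see identical trajectories. `run_scenarios()` exploits this:
passive particles make "detect settlement at lifetime $L_1$ vs $L_2$ on one
trajectory set" exactly equivalent to two separate runs, giving a perfectly
paired design in which every metric difference is attributable to pelagic
duration alone.

## Settlement rules and metrics

A particle settles at its first trajectory sample over a settleable-shelf
cell with age strictly greater than the minimum competency age (default
25 days — pre-competent shelf contacts are ignored, implementing the rule
that arrivals in 25 days or less are not counted) and at most the lifetime.
Settlement is terminal. Three per-cohort metrics summarize the outcome:
settled abundance, mean great-circle displacement from release to
settlement, and settled area (count of distinct occupied mask cells × cell
area, a grid-native measure). "Distance" is displacement, not along-path
length; along-path length can be reconstructed from the stored trajectories
if needed. `first_arrival()` reports the earliest age at which any particle
samples a region, with `Inf` when unreached, and `arrival_ratio()` converts
an arrival day into multiples of a PLD.

## Scenario statistics and generations

`compare_paired()` log-transforms the per-cohort metric pairs (natural log;
dispersal metrics are positive and right-skewed), computes the paired
two-tailed t test via `stats::t.test`, and reports the effect as the ratio
of back-transformed means $e^{\bar d}$. Degenerate cases are flagged rather
than fudged: zero-variance differences (identical scenarios) give $t = 0$,
$p = 1$, ratio 1; constant non-zero differences leave $t$ undefined with
the ratio still reported; cohorts with non-positive metric values are
dropped with a count.

`iterate_generations()` implements stepping-stone range expansion:
generation 0 releases from origin cells, each later generation releases
from the previous generation's settlement cells with a multinomial draw of
the particle budget weighted by per-cell settled abundance (the resampling
rule is our choice; the inputs — settlement location and abundance — define
it up to the rule). Iteration stops at the first generation intersecting
the target region, at a zero-settlement generation (not reached), or at the
cap. Per-generation seeds derive deterministically from the run seed.

## Problem sizes and defaults

Desk-scale defaults keep every stage runnable in seconds to minutes on one
core: fields of a few thousand cells, release budgets of $10^2$–$10^4$
particles, one to a few simulated years, `dt` of 0.25 day in the test suite
(2 h for production accuracy), daily trajectory sampling. The full-scale
design this mirrors — 10,000 particles weekly for ten years over an
eddy-rich Atlantic model, multi-million-particle line seedings — is
accepted through the same interfaces (`release_schedule()`,
`seed_line_release()`) and differs only in budget, not code path.

## Known limitations

* Advection is horizontal and single-layer; no vertical migration, swimming
  behaviour, or diffusion term (particles are passive by design).
* Settlement uses geography only — no temperature, habitat-suitability, or
  behaviour gating.
* The exponential survival model is a single-rate description; it is not a
  Kaplan–Meier or parametric survival-regression framework and will not
  capture age-varying mortality.
* Synthetic fields are idealized; conclusions about any real coastline
  require real velocity fields on the same grid structure.
* Serialization is plain text (JSON/CSV/YAML) for portability and
  inspectability; very large trajectory sets are better kept in memory or
  thinned before writing.
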