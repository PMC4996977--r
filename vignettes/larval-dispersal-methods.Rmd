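---
title: "Modelling coral larval dispersal across an open-ocean barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coral larval dispersal across an open-ocean barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvadrift)
```

## The model

`larvadrift` implements a two-dimensional, surface-ocean, stochastic
Lagrangian individual-based model of coral larval dispersal, together with
the accounting needed to turn simulated settlement into seascape-connectivity
statistics and to compare those statistics with population-genetic
differentiation.

A larva is a passive surface particle. Its position evolves under

* **advection** through a gridded daily (00Z) surface-velocity field,
  integrated with classical 4th-order Runge–Kutta on a 4-hour step.
  Velocities are sampled by bilinear interpolation in space between the two
  bracketing daily snapshots, linear in time. Sampled metres per second are
  converted to angular rates with $1/(R\cos\phi \cdot \pi/180)$ zonally and
  $1/(R \cdot \pi/180)$ meridionally, $R = 6\,371$ km;
* **turbulent diffusion**, an independent Gaussian random-walk impulse per
  horizontal axis at every step with standard deviation $\sqrt{2 D \Delta t}$
  metres, so the two-dimensional ensemble mean squared displacement grows as
  $4 D t$. The default $D = 7\ \mathrm{m^2\,s^{-1}}$ represents sub-grid
  turbulence not resolved by eddy-resolving (circa 1/12°) forcing;
* **biology**, applied at each 00Z day boundary before that day's
  integration steps: larvae age by one day, are terminated when their age
  reaches the maximum pelagic duration (default 120 days, the longest
  competency duration reported for any broadcast-spawning coral), and
  otherwise die with a constant daily probability (default 0.02, a
  half-life of about 35 days);
* **competency and settlement**: each larva draws an integer competency
  onset day uniformly from days 1–10, so 10% of each cohort becomes
  competent per day across the ramp. From its onset day onward, a larva
  found inside any habitat cell at a step's settlement check settles there
  — including its natal cell (self-seeding is legal). Checks are discrete:
  a path that crosses a cell entirely between two checks does not settle.

The parameterisation deliberately maximises long-distance dispersal
potential for a generic broadcast-spawning coral rather than describing any
single species; year-round daily releases provide an oceanographically
driven baseline over which real, species-specific spawning seasonality
would only reduce connectivity.

### Event ordering and edge cases

Published descriptions of models of this kind rarely pin down scheduling,
so the package fixes and documents one ordering: *daily biology at 00Z → (advect →
diffuse → settle-check) per 4-hour step*. Mortality is a per-day process and
settlement a per-pass process, which this ordering respects. Other numerical
choices, each made once:

* a displacement (advective or diffusive) that would land a particle on a
  land cell is cancelled — the particle holds position for that sub-step —
  which avoids beaching artefacts and keeps behaviour bounded;
* a particle whose trajectory (including any RK4 sub-sample) leaves the
  forcing domain is terminated with status `exited` rather than clamped;
* land nodes contribute zero velocity to interpolation with no re-weighting,
  so currents taper smoothly toward coasts;
* habitat-cell intervals are half-open and lower-inclusive, making point
  location deterministic on shared edges;
* mixed-region graticule squares take the majority region of their reef
  points, ties broken toward the lexicographically smallest code (and
  reported);
* release happens at 00Z at cell centres; a newly released cohort faces its
  first mortality draw at the following 00Z.

Every run satisfies exact particle conservation:
`released = settled + dead + expired + exited`, and identical inputs plus
seed reproduce the event table bit-for-bit.

### Habitat geometry

Reef point data are collapsed onto a 1/6° graticule (about 18.5 km at the
equator), one habitat cell per occupied square, released from the square
centroid. The whole square is the settlement zone. Because cells align to
the graticule rather than to the coastline of the forcing grid, the
distance a larva can approach "the reef" before counting as settled varies
from cell to cell (between about 1/12° and 1/6°); that emergent variability
is intentional, in contrast to small-scale modelling practice of drawing a
uniform sensory buffer around known reef outlines.

## The synthetic ocean

Real applications drive the model with ocean-reanalysis currents and
surveyed reef distributions. For development, testing and self-contained
reruns the package generates all of its inputs:

* **Current bands.** The zonal component is a sum of Gaussian jets in
  latitude — westward SEC and NEC, eastward NECC — with
  $u(\phi, t) = \sum_b \mathrm{peak}_b\, e^{-(\phi - c_b(t))^2 / 2w_b^2}
  \cdot \mathrm{season}_b(t) \cdot (1 + g_b\, \mathrm{enso}(t))$.
  The seasonal factor peaks mid-way through a configurable month (default
  October for the NECC, echoing its boreal-autumn strengthening); ENSO
  coupling is confined by default to the NECC, whose speed gains 0.25 per
  positive index unit and whose axis shifts 0.75° southward per index unit
  — the direction characteristic of eastern-Pacific-type El Niño events.
  The magnitudes of both couplings are free parameters chosen once for
  plausibility; no observational calibration exists to pin them down, and
  they are not tuned thereafter.
* **Eddies.** Mesoscale perturbations come from a Gaussian-smoothed random
  streamfunction $\psi$ via $(u, v) = (-\partial\psi/\partial y,\,
  \partial\psi/\partial x)$, discretised with centred differences on a
  constant metric taken at the domain-centre latitude. Cross-derivatives
  then cancel exactly, so the eddy field is discretely divergence-free by
  construction (verified numerically to round-off in the tests). The
  streamfunction evolves as a daily AR(1) process with a 10-day
  decorrelation time; the field is scaled to a prescribed RMS eddy speed.
* **Seascape.** Two provinces of disc-shaped reef clusters separated by a
  configurable reef-free longitude gap — the dispersal barrier. The default
  study seascape places an eastern province (an offshore archipelago on the
  SEC axis plus a lower-latitude coastal cluster) about 25° (~2,800 km)
  east of a western two-cluster province: wide enough that only sustained
  jet transport, never diffusion alone, can bridge the gap within a 120-day
  larval lifetime.
* **Genetics.** A ground-truth surrogate for pairwise $F'_{ST}$:
  differentiation rises linearly with $-\log_{10}$ of dispersal
  probability, plus Gaussian noise, clamped to $[0, 1]$. With zero noise
  and a shared probability floor the log-mode model–genetic Mantel
  correlation is exactly 1, which anchors the pipeline-recovery test.

What the generator does *not* emulate: coastlines with realistic geometry,
wind-driven Ekman flow, tropical-instability-wave phase locking,
bathymetry, temperature-dependent biology. Passing tests on synthetic data
therefore demonstrate correctness of the numerics and accounting, not skill
against any real ocean.

## Connectivity accounting

Settlement events aggregate into region × region count matrices (source
rows, destination columns; the diagonal is within-region self-recruitment),
with the west-of-barrier block ordered first so the barrier sits at a fixed
index. On top of these the package provides:

* June-through-May annual release windows (inclusive endpoints), centred on
  the boreal-winter peak of El Niño / La Niña events;
* monthly cross-barrier connection series by source region and direction;
* larval-number saturation analysis: inter-regional connections — counted
  as *directed off-diagonal region pairs with at least one settler* — per
  run as the per-release larval number N grows, plus gained/lost difference
  sets between consecutive runs (cumulative runs are nested, so their
  totals are provably non-decreasing);
* trajectory-density grids: distinct particles per 1/6° cell, each particle
  counted once per cell regardless of re-entry, for advection-only
  "oceanographic range" runs.

## Model–genetic comparison

Directed counts fold into a directionless half-matrix ($h_{ij} = c_{ij} +
c_{ji}$, diagonal dropped), are normalised by the larvae released from each
pair ($p_{ij} = h_{ij} / (\mathrm{rel}_i + \mathrm{rel}_j)$), and inverted
into a dissimilarity comparable with $F'_{ST}$. Two interpretations of
"inversion" were open; the package uses the order-reversing rescale
$(p_{\max} - p)$ mapped to $[0, 1]$ rather than the reciprocal, which
explodes on rare connections and is undefined at zero. The log mode
rescales $-\log_{10}(\max(p, \varepsilon))$, with $\varepsilon$ defaulting
to half the smallest nonzero probability; the floor is applied via
$\max(\cdot)$ so nonzero probabilities are untouched and equal decades of
probability map to equal distance increments. Geographic separation uses
haversine great-circle distance ($R = 6\,371$ km): at basin scale the
chord underestimates separation materially, and surface distance is the
quantity of biological interest.

The Mantel test correlates vectorised half-matrices (Pearson), with
significance from random row/column co-permutations of the second matrix
and the +1-corrected one-sided p-value $p = (1 + \#\{r^* \ge r\}) / (1 +
n_{\mathrm{perm}})$. Variance explained is reported as $100 r^2$; that
reading of "percent of variation explained" is a labelled choice. The
implementation is the package's own and is cross-checked against
`vegan::mantel` in the test suite.

## Problem sizes

Simulations in the tests and the acceptance script are sized to run on one
CPU in minutes, a deliberate package choice: synthetic forcing at 1/2°–1/4°
resolution over a 40° × 12° domain and 200 days; campaigns of 20 larvae per
cell per release from ~100 cells on 3 release dates (~6,000 particles for
up to 120 days at 4-hour steps); diffusion and survival ensembles of
10^5^–4·10^5^ particles; Mantel calibration over 500 replicate null pairs
at 999 permutations. The physics and bookkeeping are scale-free, so these
sizes exercise every code path the full-scale configuration (1,600 larvae
per cell per day from 636 cells over 14.5 years, 5.14 billion paths) would.

## Known limitations

Two-dimensional surface transport only — no vertical migration, buoyancy
structure, or swimming; no temperature-dependent biology or
bleaching-linked fecundity loss; no rafting of adults on debris; no
antimeridian wraparound (synthetic domains are chosen away from the
discontinuity); the velocity-file format is the package's own serialised
layout rather than a community archive format; and genetic comparison
starts from supplied (or generated) differentiation matrices — the package
does not compute $F'_{ST}$ from genotypes.
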