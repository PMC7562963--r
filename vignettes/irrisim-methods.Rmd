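---
title: "Methods: soil water, greenhouse evapotranspiration and irrigation risk under uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil water, greenhouse evapotranspiration and irrigation risk under uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irrisim)
```

`irrisim` evaluates greenhouse irrigation strategies by simulating the soil
water balance of a vertical column and propagating the two input
uncertainties that dominate in practice — the evapotranspiration demand and
the identity of the soil — into the three quantities an irrigation decision
trades off: drainage (water loss and nutrient leaching), cumulative water
use, and the risk of crop water stress.

## The water-flow model

Vertical unsaturated flow is described by the Richards equation in its
mixed form,

$$\frac{\partial \theta}{\partial t}
  = \frac{\partial}{\partial z}\!\left(K \frac{\partial h}{\partial z}\right)
  - \frac{\partial K}{\partial z} - S_r ,$$

with $z$ (cm) positive downwards, $\theta$ the volumetric water content
(ml cm⁻³), $h$ the pressure head (cm, negative in unsaturated soil), $K$
the hydraulic conductivity (cm d⁻¹) and $S_r$ a sink for root water uptake
(ml cm⁻³ d⁻¹). The constitutive closure is Van Genuchten retention

$$S(h) = \frac{\theta - \theta_r}{\theta_s - \theta_r}
       = \bigl(1 + |\alpha h|^{\,n}\bigr)^{-m}, \qquad h \le 0,\; m = 1 - 1/n,$$

with $S \equiv 1$ for $h > 0$, and Mualem conductivity

$$K_r(S) = S^{\lambda}\bigl[1 - (1 - S^{1/m})^{m}\bigr]^{2}, \qquad K = K_s K_r .$$

`m` is always derived from `n`; a catalogue cannot carry an inconsistent
independent `m`. When a catalogue entry omits $\lambda$ the classical
Mualem value 0.5 is used. Before exponentiation $S$ is clamped to
$[10^{-12}, 1]$, since $K_r$ is singular in floating point at $S = 0$ for
some exponent combinations.

Root uptake is distributed uniformly over the cells of the root zone
(default: the top 30 cm), with the depth integral equal to the potential
transpiration demand by construction. Uptake is a *demand*, not a
Feddes-type reduced flux: the pressure head is used downstream purely as a
stress signal. The only cap is physical — uptake per cell cannot draw
$\theta$ below $\theta_r + \varepsilon$ with $\varepsilon = 10^{-3}$
ml cm⁻³; the shortfall is reported as unmet demand. The cushion value
bounds the dry-end head at roughly $-10^2$ to $-10^3$ cm; without it the
always-potential assumption can push $\theta$ to machine-residual and the
head towards $-10^6$ cm, which makes dry coarse-textured runs needlessly
stiff while changing the water balance by under $10^{-3}$ ml cm⁻³ per cell.

### Boundary conditions

* **Top**: flux type, $q_{top} = q_{irr} - E_{pot}$, capped at the
  infiltration capacity implied by a saturated surface ($h_{surf} = 0$
  half-cell Dirichlet ghost); rejected water is reported as runoff — there
  is no ponding state. On the drying side the flux is capped at the
  exfiltration capacity implied by an air-dry surface
  ($h_{surf} = -10^5$ cm, configurable).
* **Bottom**: free drainage (unit total head gradient), $q_{bot} = K(h_N)$,
  the conventional greenhouse soil-column choice; a sealed (zero-flux)
  base is available for equilibrium testing.

## The evapotranspiration model

Greenhouse demand follows the radiation/heating-pipe (De Graaf) form

$$ET = \bigl(a\,R + b\,\lvert T_{tube} - T_{gh}\rvert\bigr)\frac{L}{L_{max}}
 \quad \text{[mm per forcing step]},$$

with $R$ the global plus supplementary radiation (J cm⁻²), $T_{tube}$ and
$T_{gh}$ the heating-pipe and indoor air temperatures (°C), and $a$
(mm cm² J⁻¹), $b$ (mm °C⁻¹ per step) empirical crop factors. The demand is
partitioned by canopy light extinction,

$$T_{pot} = ET\bigl(1 - e^{-k\,\mathrm{LAI}}\bigr),\qquad
  E_{pot} = ET - T_{pot},$$

with $k = 0.6$ by default ($k$ is crop-dependent in the wider literature
and is configurable). For a full-grown crop (`full_grown = TRUE`) the
partition short-circuits to $T_{pot} = ET$, $E_{pot} = 0$ — the closed
canopy shades the soil surface — while the general path remains available
and tested. $T_{pot} + E_{pot} = ET$ holds exactly by construction.

**Units contract.** The ET model produces mm per forcing step; the solver
works in cm and days. The conversion (÷10 × steps-per-day) happens once,
at the solver boundary, inside `simulate_column()`.

## Numerical scheme

The solver uses cell-centred finite volumes, backward Euler in time, and
mass-conservative modified-Picard iteration on the mixed θ–h form, with
inter-cell conductivity the arithmetic mean of the neighbours. Each
iteration solves a tridiagonal system (Thomas algorithm) for the head
update. Convergence is declared when either

* the head update satisfies $\max_i |\delta h_i| < 10^{-4}$ cm
  (`tol_h`), or
* the mass residual satisfies
  $\sum_i |r_i|\,\Delta t\,\Delta z < 0.01\,\mathrm{tol_{mb}}$ —
  near-saturated cells sit on the flat part of $\theta(h)$, where the
  head can chatter at the $h = 0$ kink while the balance is already
  closed to far below reporting precision.

On failure after 50 iterations the step is halved, down to
$\Delta t_{min} = 10^{-6}$ d; exhausting the cascade raises an error
naming the simulated time and last residual. Easy steps (≤ 5 iterations)
are re-doubled. Per sub-step the ledger recomputes all fluxes from the
converged profile and verifies $|\Delta \mathrm{storage} -
(q_{top} - q_{bot} - \mathrm{uptake})\Delta t| \le \mathrm{tol_{mb}}$
(default $10^{-3}$ cm) as a hard error — a broken balance signals a broken
scheme, not a hard problem.

Three stabilisations affect only the iteration path, never the converged
solution (a zero update still requires a zero residual):

1. a $10^{-5}$ specific-storage floor on the diagonal — a fully
   saturated column under flux boundary conditions is otherwise a
   singular Neumann problem (the constant head mode is unconstrained);
2. a ±50 cm per-iteration clamp on the head update plus adaptive
   under-relaxation when updates stop shrinking — this kills the
   two-cycle limit oscillations typical of sharp wetting fronts;
3. binding boundary fluxes are taken implicitly: a binding infiltration
   cap contributes its half-cell Dirichlet derivative, and free drainage
   contributes the chord slope of $K(h_N)$, to the Jacobian diagonal.

**Grid and stepping defaults.** 100 cm column, 1 cm cells, hourly forcing
with internal sub-stepping; the monitored "first soil layer" is the top 8
cells. All are configurable. The test suite and acceptance script run a
100-cell column for the 10-day balance check and coarser 15–50-cell
columns for ensemble work; these sizes are chosen to make the grid error
visibly subordinate to the input uncertainties being propagated, as the
self-convergence test documents.

## Crop stress ratio

Per hour, the mean pressure head over the monitored root-zone cells
(default: cells 5–8, the lower half of the 8-cell first layer — the
"bottom planes" convention) is compared with a threshold; the crop stress
ratio is the fraction of hours strictly below it. Values exactly at the
threshold count as unstressed — ties are measure-zero in practice but the
convention must be fixed for exact tests. The ratio is a frequency, so it
is invariant to the time-ordering of the trace and monotone in the
threshold. The threshold is crop- and substrate-specific; the package
ships no scientific default. The fixture configuration writes −80 cm as
an illustrative value for a coarse greenhouse substrate and marks it as a
placeholder to replace.

## Monte Carlo design

Two uncertainty sources, independently switchable:

* **Evapotranspiration** — a day-level bootstrap. The deterministic ET
  series is aggregated to daily totals; each simulated day's total is
  drawn uniformly with replacement from that pool, then redistributed
  over the day's hours proportionally to the original within-day profile
  (uniformly for an all-zero day). Resampling at the day level preserves
  the diurnal structure the solver needs while capturing day-to-day
  demand variability.
* **Soil** — a categorical draw over the catalogue entries of the active
  texture class (sand or clay). Soil uncertainty is uncertainty about
  *which* soil one has, not a continuous perturbation of parameters;
  a continuous mode is deliberately out of scope.

One root seed drives everything. It is expanded into one sub-seed per
Monte Carlo sample; sample *k* reuses its draws (soil and resampled ET)
across all irrigation strategies. These common random numbers make
strategy comparisons paired — the strategy effect is isolated from the
sampling noise — which is what lets the drainage/risk trend across the
sweep emerge clearly at 20 samples. Ensembles are reproducible to the
byte from the seed, and with both switches off every sample equals the
deterministic run, so all standard deviations are exactly zero.

## The synthetic fixture generator

The generator emulates the *shape* of greenhouse data, not any site:
a half-sine radiation course (06:00–18:00, exact zeros at night, mild
noise), a stable indoor temperature with heating pipes +25 °C at night,
and an 8-strategy irrigation sweep of increasing daily totals
(2–16 mm d⁻¹ by default) spread over 08:00–17:00. The crop factors
$a = 0.002$ mm cm² J⁻¹ and $b = 0.008$ mm °C⁻¹ are illustrative
placeholders chosen so a default day yields ≈ 4.7 mm of ET — inside the
agronomically sane 0–10 mm d⁻¹ band the tests enforce. The soil catalogue
carries three sand-class and three clay-class parameter sets taken from
widely used literature compilations; they are representative values, not
site measurements.

What passing tests on these fixtures show is that the machinery is
correct: conservation, convergence, determinism, and the qualitative
trade-off (drainage rising, stress risk falling along the sweep). They do
not show that any particular greenhouse is well described: real forcing
has weather autocorrelation, equipment downtime and measurement error
that the generator deliberately omits, and real soils are layered and
hysteretic (see limitations).

## Known limitations

* One-dimensional, single uniform soil profile; no layering, macropores,
  hysteresis or solute transport.
* No ponding state: irrigation beyond the infiltration capacity is
  runoff immediately.
* Crop length and LAI are constants per run — no growth dynamics.
* Very fine textures with $n \approx 1.09$ (the literature clay entries)
  have near-zero moisture capacity everywhere; ponded infiltration on
  them converges slowly. The ensemble defaults use the sand class; the
  clay entries remain available for retention/conductivity work.
* The stress ratio is a dryness signal only; there is no uptake
  reduction, yield model or oxygen (too-wet) stress.

## A minimal run

```{r example, eval = FALSE}
dir <- tempfile()
cfg <- make_fixtures(dir, fixture_spec(seed = 42), n_samples = 20, seed = 1)
ens <- run_from_config(cfg, quiet = TRUE)
ens$summary
```

The summary holds one row per strategy with mean/std of stress risk,
cumulative drainage and cumulative ET — the machine-readable trade-off
table — and `plot_tradeoff()` renders the companion figure with drainage
and risk error bars against total irrigation over the ET uncertainty
band.
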