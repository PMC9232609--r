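# permwalk

Monte Carlo random-walk simulation of one-dimensional diffusion in layered
media whose compartments have different diffusion coefficients and are
separated by semi-permeable membranes — the geometry that arises when
modelling water exchange across cell membranes for diffusion-weighted MRI
(e.g. cardiomyocytes imaged perpendicular to their long axis), and equally in
heat conduction through coated layers or transport in stratified porous
media.

The package is aimed at researchers who need fast, validated walker-based
solvers for layered diffusion: it provides two membrane transit rules, a
semi-analytical eigenmode propagator and a finite-volume solver as
independent gold standards, membrane-flux analytics, synthesis of
histology-based domains from cell-size statistics, and narrow-pulse
diffusion-weighted signal/ADC computation.

## The model

A domain is an array of `m` compartments `[L_1, ..., L_m]` (µm), each with a
constant diffusivity `D_i` (µm²/ms), separated by membranes with
permeability `κ_i` (µm/ms); the ends are sealed (`κ_0 = κ_m = 0`). Within a
compartment the density obeys `∂U/∂t = D_i ∂²U/∂x²`, and at each internal
interface

```
D_i ∂U/∂x |_L  =  D_j ∂U/∂x |_R  =  κ_i (U|_R − U|_L).
```

Walkers step by `δx = ±√(2 D_i δt)`, with `δt ≤ δt_max = min_i L_i²/(2 D_i)`
so that at most one membrane interaction occurs per step. A step that would
cross a membrane is split at the barrier; a uniform draw against a transit
probability decides between elastic reflection and transmission with the
residual sub-step rescaled by `√(D_j/D_i)`.

Two transit rules are implemented:

* **reference model** — `p = 2κδx_i / (D_i + 2κδx_i)`, with `δx_i` the
  walker's distance to the barrier. Accurate only for vanishing transit
  probability, which forces extremely small time steps when `D` jumps across
  the membrane.
* **hybrid model** — the membrane and the diffusivity step are treated as
  two interactions separated by an infinitesimal gap, with the membrane on
  the low-diffusivity side: `p = p_b · p_d`, where
  `p_d = min(1, √(D_j/D_i))` is the diffusivity-step acceptance and `p_b` is
  the reference rule evaluated in the low-diffusivity medium with the
  distance mapped into it. This preserves the interface reflection condition
  at any `κ` and lifts the severe step-size restriction.

Both are validated against the eigenmode expansion of the layered diffusion
operator (characteristic-equation root finding, normalised piecewise
trigonometric modes, delta/uniform initial conditions) and against a
conservative Crank–Nicolson finite-volume oracle.

## Worked example

The benchmark from the package's validation suite: two 20 µm compartments,
`D_L = 0.5`, `D_R = 2.5` µm²/ms, membrane `κ = 0.05` µm/ms.

```r
library(permwalk)

dom <- build_domain(c(20, 20), c(0.5, 2.5), 0.05)
max_timestep_domain(dom)
#> [1] 80

sp <- find_eigenvalues(dom, lambda_max = 200, scan_points = 5e4)
sp
#> Layered-diffusion eigen spectrum: 185 modes, lambda in [0, 199] 1/ms

# transient flux through the membrane after a point release at x0 = 10 um
fa <- analytical_flux(sp, 1, seq(1, 1000), "delta:10")
peak_time(fa)
#> [1] 58.53376

# Monte Carlo run, all walkers uniform in the left compartment
run <- run_simulation(dom, sim_config(dt = 20, T_total = 1000, Np = 1e6,
                                      seeding = "interval:0,20",
                                      model = "hybrid", seed = 1,
                                      record_flux = TRUE))
fn <- numerical_flux(run, 1)
endpoint_relative_error(fn, analytical_flux(sp, 1, fn$times, "interval:0,20"))
#> [1] -0.01558804
```

The peak time says the membrane flux from a central point release crests at
t ≈ 58.5 ms; the endpoint value says that even at the largest admissible
step (δt = 20 ms) the hybrid model under-transports walkers across the
membrane by only ≈ 1.6 % of the analytical cumulative flux by t = 1 s — the
reference model's error on the same run is ≈ −10.4 %, and after uniform
seeding it piles up a ≈ +10.6 % steady-state excess in the left compartment
where the hybrid model stays uniform to Monte Carlo noise.

Histology-based domains are synthesised from cell-size statistics (mean
cross-sectional area 120 µm² ↔ mean diameter 12.4 µm, SD 40 µm²,
extracellular gaps uniform on 3–5 µm, total length 49.5 µm):

```r
set.seed(3)
dom <- synthesize_histology_domain()   # alternating ICS/ECS, 49.5 um total
q <- q_from_b(b = 1, Delta = 1000)     # narrow-pulse wave number
```

A command-line front end over the same functions is installed at
`system.file("cli/permwalk.R", package = "permwalk")` with subcommands
`synth-domain`, `simulate`, `eigen`, `propagate`, `flux`, `dwi`, `oracle`,
and `reproduce`.

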