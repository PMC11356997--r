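# porewalk

Brownian dynamics of capsule-shaped particles translocating a cylindrical
channel.

## The problem

Resistive-pulse sensing reads single particles — proteins, bacteriophages,
bacteria, synthetic rods — as they diffuse through a pore. Most transport
theory covers spheres; rod-like objects add rotational degrees of freedom and
a shape-dependent interplay with the confining wall. `porewalk` is for anyone
who wants a minimal, fully reproducible model of that interplay: it simulates
a rigid spherocylinder (a cylinder of length *l* and diameter *d* capped by
two hemispheres, aspect ratio *f* = 1 + *l*/*d*) performing an overdamped
random walk inside a cylindrical channel of unit diameter and length *L*,
with a reflecting entrance at *z* = 0 and an absorbing exit at *z* = *L*.

Each time step makes one translation attempt, Δx⃗ = σₓ ξ⃗ with
ξ⃗ ~ N(0, I₃), and one rotation attempt by an angle
Δφ ~ N(0, σ_φ²(Â)) about a uniformly random axis Â through the particle
centre; attempts that would push the capsule through the wall (or the centre
below *z* = 0) are rejected, and rejected jumps still cost a time step. The
rotation scale obeys energy equipartition through the particle's inertia
tensor *M*:

    σ_φ(Â) = σₓ (Âᵀ M Â)^(−1/2)

with *M* the uniform-density capsule tensor (total mass normalised to 1).

Three analyses quantify the transport:

* **Diffusion type** — ensemble mean squared displacement fitted as
  ⟨x⃗²(t)⟩ = 2*D* t^α over [0.01 t_min, t_min], t_min the minimal observed
  passage time (α = 1 is normal diffusion);
* **First passage** — Kaplan–Meier survival S(t) with exponential tail rate
  λ and median passage time M_t;
* **Exit orientation** — the angle θ between particle and channel axes at
  exit, histogrammed with sphere-measure reweighting (so isotropic
  orientations are flat, p(θ) = 1/π) and summarised by
  σ = (∫θ²p dθ)^(1/2); π/√3 ≈ 1.814 is the free-rotation reference.

## Worked example

```r
library(porewalk)
p <- spherocylinder(d = 0.45, f = 2.9)
p
#> Spherocylinder: l = 0.855, d = 0.45 (f = 2.9)
#>   masses: m1 = 0.7403 (core), m2 = 0.1299 (each cap)
#>   inertia (body frame): Mxx = Myy = 0.125931, Mzz = 0.0239976

cfg <- sim_config(p, channel(14.3), n_traj = 200, seed = 42)
ens <- run_ensemble(cfg)
summary(ens)
#> n = 200 (censored 0)
#> FPT steps: min 11046, median 83116.5, mean 115756
#> acceptance rates: translation 0.730, rotation 0.823

analyze_ensemble(ens)
#> D = 0.0008713, alpha = 0.991, lambda = 1.015e-05, Mt = 83116.5, sigma_theta = 0.230 (censored 0)
```

Reading the numbers: this moderately long rod diffuses normally
(α ≈ 0.99) but 27% of its translation attempts hit the wall, so its
effective diffusion constant (D ≈ 8.7×10⁻⁴ channel-widths²/step) sits well
below the free axial value σₓ²/2 = 1.25×10⁻³; it needs a median of ~83,000
steps to cross the channel, its survival tail decays at λ ≈ 1.0×10⁻⁵ per
step, and it exits tightly aligned with the pore axis
(σ_θ = 0.23 rad versus 1.814 for free rotation).

Parameter sweeps over shape grids (`run_sweep()`), plain-text run
directories (`write_ensemble()`, `write_analysis()`), YAML configs
(`load_config()`) and a CLI
(`system.file("cli", "porewalk", package = "porewalk")` with `simulate`,
`analyze` and `sweep` subcommands) are included; every run is reproducible
from its seed alone. See the vignette
`vignettes/confined-capsule-diffusion.Rmd` for the model details, numerical
choices and limitations.

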