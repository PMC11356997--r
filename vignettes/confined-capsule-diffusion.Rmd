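---
title: "Confined Brownian dynamics of capsule-shaped particles in a cylindrical pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confined Brownian dynamics of capsule-shaped particles in a cylindrical pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porewalk)
```

## The model

`porewalk` simulates a rigid spherocylinder (a capsule: a cylinder of length
$l$ and diameter $d$ capped by two hemispheres) performing overdamped Brownian
motion inside a cylindrical channel. The channel diameter is the unit of
length, so the channel is the cylinder of radius $0.5$ about the $z$-axis,
with the entrance at $z = 0$ and the exit at $z = L$. The particle's shape is
summarised by its aspect ratio $f = 1 + l/d$; $f = 1$ ($l = 0$) is a sphere.

In the overdamped limit there is no velocity variable: positions and
orientations follow a discretised Wiener process. One time step consists of

1. a **translation attempt** $\Delta\vec x = \sigma_x\,\vec\xi$ with
   $\vec\xi \sim \mathcal N(0, I_3)$, accepted iff the displaced capsule does
   not intersect the channel wall and the centre keeps $z \ge 0$;
2. a **rotation attempt** by an angle
   $\Delta\varphi \sim \mathcal N(0, \sigma_\varphi^2(\hat A))$ about an axis
   $\hat A$ drawn uniformly on the sphere and passing through the particle
   centre, accepted iff the rotated capsule does not intersect the wall;
3. the clock advances by exactly one step, whether or not either attempt was
   accepted (rejected jumps cost time).

The rotational step scale follows energy equipartition,
$$\sigma_\varphi(\hat A) = \sigma_x\,\bigl(\hat A^{T} M \hat A\bigr)^{-1/2},$$
where $M$ is the particle's inertia tensor. In the body frame ($z$ along the
particle axis) $M$ is diagonal with
$$M_{xx} = M_{yy} = m_1\!\left(\tfrac{l^2}{12} + \tfrac{r^2}{4}\right)
  + 2 m_2\!\left(\tfrac{2r^2}{5} + \tfrac{l^2}{4} + \tfrac{3lr}{8}\right),
  \qquad
  M_{zz} = \left(\tfrac{m_1}{2} + \tfrac{4m_2}{5}\right) r^2,$$
with $r = d/2$, $m_1$ the mass of the cylindrical core and $m_2$ the mass of
one hemispherical cap. Uniform density fixes $m_1/m_2 = 3l/(2r)$. We verified
analytically that the transverse formula is exactly the uniform-density
parallel-axis result for a capsule (the hemisphere's moment about its own
centre of mass, $\tfrac{83}{320} m r^2$, shifted by $l/2 + 3r/8$), and the
test suite checks the tensor against an independent volume quadrature to a
relative tolerance of $10^{-6}$.

**Mass normalisation.** Only the mass *ratio* is fixed by uniform density; an
overall scale is needed to make $\sigma_\varphi$ concrete. We normalise the
total mass to $1$ for every particle, so the rotational mobility depends on
shape only, never on absolute size. This is the one free convention in the
model; it sets the absolute magnitude of $\sigma_\varphi$ and therefore how
tightly long particles align before their rotations are wall-limited.

**Boundary semantics.** The radial wall is material for the whole capsule
surface and is treated as infinite in $z$: the caps may protrude past the
channel ends while the centre is inside. The entrance is reflecting for the
centre (moves to $z < 0$ are rejected); the exit is absorbing
(an accepted translation reaching $z \ge L$ terminates the trajectory, and
that step still counts). At absorption the exit angle $\theta$ between the
particle axis and the channel axis is recorded immediately, before any
further rotation — the rotation sub-step of the absorbing step is skipped, so
the compiled loop and the pure-R reference stepper consume the random stream
identically and replay bit-for-bit.

Because the channel cross-section is convex, the collision test is exact and
cheap: the radial distance from the axis is convex along the capsule's core
segment, so the capsule pokes out iff
$\max(\text{endpoint radial distance}) + r > 0.5$. The test suite keeps a
brute-force surface-sampling oracle and checks agreement on a thousand random
configurations.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `sigma_x` | translational step scale (lengths/step) | 0.05 | resolves the narrowest clearances studied while keeping passage times tractable |
| `L` | channel length (channel widths) | 14.3 | the elongated-pore geometry the study conditions prescribe |
| `d` | particle diameter | — | studied range 0.03–0.9 |
| `f` | aspect ratio $1 + l/d$ | — | studied range 1–5.6 |
| `n_traj` | trajectories per ensemble | 5000 | reference ensemble size; analyses here use 500 per cell (see below) |
| `max_steps` | per-trajectory cap | $100 L^2/\sigma_x^2$ | ~100 mean passage times; censoring essentially impossible, and always flagged, never dropped |
| `record_stride` | position-recording interval | 100 | keeps full ensembles in memory; passage times and exit angles are always exact |

Reproducibility: every ensemble takes one master seed; per-trajectory
sub-seeds are drawn from it once, so runs are independent of execution order,
replayable trajectory-by-trajectory, and any run directory can be regenerated
exactly from its `run_meta.json`.

## The three observables

**Diffusion type.** The ensemble mean squared displacement of the centre,
$\langle \vec x^2(t)\rangle = 2 D t^\alpha$, is fitted by ordinary least
squares in log–log coordinates over the window $[0.01\,t_{\min}, t_{\min}]$,
where $t_{\min}$ is the minimal observed first-passage time. Below
$t_{\min}$ every trajectory is still inside, so absorption attrition cannot
bias the average; the lower edge discards the initial transient in which the
lateral coordinates have not yet felt the wall. Averages at each time use the
trajectories still alive there, and the alive count is reported with the
curve. Note that $t_{\min}$ is an extreme-value statistic: it moves with
ensemble size and from seed to seed, which in turn moves the fitted $D$ by
tens of percent — fluctuations the fitting methodology itself creates.

**First-passage statistics.** The survival function $S(t)$ (fraction still
inside at step $t$) is estimated by Kaplan–Meier (via the survival package),
so censored trajectories contribute correctly as right-censored. Its long-time
tail is exponential, $S(t) \sim A e^{-\lambda t}$, and $\lambda$ is fitted by
least squares on $\log S$ over the tail window — from the median uncensored
passage time, trimming the last 1% of event times where the step estimate is
noisiest. The median passage time $M_t$ summarises the bulk of the
distribution, which the tail rate deliberately ignores.

**Exit orientation.** Exit angles are histogrammed on $[0, \pi]$ (36 bins by
default) and each bin is divided by its exact sphere-measure weight
$\int_{\text{bin}} \sin\theta\,d\theta$ before normalising to unit integral;
using the exact bin integral keeps the bins at $\theta \approx 0, \pi$
finite. Under this reweighting an isotropically oriented particle is flat,
$p(\theta) = 1/\pi$, whose second moment
$\sigma = (\int_0^\pi \theta^2 p\,d\theta)^{1/2} = \pi/\sqrt3 \approx 1.814$
serves as the free-rotation reference; wall-aligned particles drive $\sigma$
down. $\sigma$ is computed by midpoint quadrature on the histogram; the raw
(unweighted) histogram is also emitted for comparison. Angles are not folded
to $[0, \pi/2]$ despite head–tail symmetry, matching the $[0, \pi]$
integration range of the definition.

## What the simulations do and do not emulate

The generator's defaults are the study conditions themselves
($\sigma_x = 0.05$, $L = 14.3$, $f \in [1, 5.6]$, $d \in [0.03, 0.9]$); the
packaged analyses and acceptance checks run a $3\times3$ corner grid
($f \in \{1, 2.9, 5.6\}$, $d \in \{0.03, 0.45, 0.9\}$) at 500 trajectories
per cell, a size chosen so the full grid completes in minutes on one core
while keeping Monte-Carlo errors on medians and tail rates at the few-percent
level. The model has no hydrodynamics, no wall interactions beyond hard-core
rejection, isotropic translational noise (no parallel/perpendicular mobility
split), and no external driving — passing its tests says nothing about those
effects in real pores.

Two closed-form limits anchor the point-particle case ($d \to 0$, $l = 0$),
where the axial motion is a 1D reflected–absorbed random walk with
$D_z = \sigma_x^2/2$ per step: mean passage time $L^2/\sigma_x^2$ and tail
rate $\lambda = \sigma_x^2 \pi^2 / (8 L^2)$. The simulator reproduces both,
with a caveat worth stating plainly: even a tiny particle's *centre* is
confined by the wall, its lateral coordinates equilibrate against the channel
radius within ~50 steps, and thereafter roughly 8% of translation attempts
are rejected. Since a rejected attempt discards the axial component too, the
effective axial diffusivity is the free value times the translation
acceptance rate. At $d = 0.03$ this is a ~8% correction (the measured mean
passage time sits ~7% above $L^2/\sigma_x^2$, inside the 10% band we test).

The same mechanism dominates at strong confinement, and there it is no small
correction: a $d = 0.9$ sphere has a lateral clearance of $0.05$ — one
standard deviation of the proposal — and its acceptance rate drops to
$\approx 0.33$ (we verified this against an independent two-dimensional
disk accept/reject simulation). Long thick rods also pay for orientation
fluctuations and fall to $\approx 0.18$. Consequently the fitted $D$ spans
roughly $2\times10^{-4}$ to $2\times10^{-3}$ across the grid — a wider
spread than the factor ~2.4 the narrow-confinement intuition suggests — the
survival tail rate $\lambda$ falls with confinement in the same proportion,
and at $d = 0.9$ the median passage time is *not* flat in particle length.
These are direct consequences of counting rejected jumps in the clock, which
the update rule prescribes; the corresponding acceptance checks assert the
narrower literature bands and are expected to flag exactly these cells. At
small and moderate diameters the classic picture holds: normal diffusion
($\alpha \approx 1$ everywhere), thickness-controlled medians flat in length,
and shape-insensitive tails.

## Numerical choices

* Single-attempt rejection (the particle stays put for that sub-step) rather
  than redraw-until-accepted: with rejected jumps counted in the time unit
  the two give the same axial statistics, and single-attempt makes the time
  accounting exact and replayable.
* Orientation vectors are renormalised after every rotation (tolerance
  $10^{-12}$) to stop floating-point drift over $10^5$–$10^6$ steps.
* The uniform rotation axis is a normalised standard-normal 3-vector, with a
  redraw guard at norm $< 10^{-12}$.
* The degenerate-norm guard, the absorbing-step rotation skip and the fixed
  per-step draw order (3 translation normals, 3 axis normals, 1 angle) are
  shared between the compiled loop and the R reference stepper, which the
  tests hold to $10^{-12}$ agreement along whole trajectories.
* `fit_diffusion` refuses windows with fewer than 5 grid points and
  `fit_lambda` tails with fewer than 10; at the default stride this sets a
  practical minimum ensemble size (and short channels need a finer stride).
* The log–log MSD fit is unweighted least squares on the recording grid —
  the simplest scheme consistent with straight-line fitting, and the one
  whose window sensitivity is characterised above.

## Known limitations

* The mass-scale convention (total mass 1) is a choice, not a derivation;
  absolute passage times for elongated particles would shift under a
  different convention, though all sphere results and all geometric
  quantities are unaffected.
* The MSD mixes the saturating lateral coordinates with the diffusive axial
  one; the fitted $(D, \alpha)$ therefore depend on the fitting window, and
  through $t_{\min}$ on the ensemble size. Comparisons should fix both.
* Kaplan–Meier tails with few events are noisy; the 1% trim is a pragmatic
  guard, not an optimal estimator.
* Trajectory-level parallelism is by sub-seed design safe, but the current
  driver executes serially.
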