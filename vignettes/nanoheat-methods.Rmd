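---
title: "Methods: heat dissipation across a sheet-water-membrane interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat dissipation across a sheet-water-membrane interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoheat)
```

# The physical picture

A graphene or graphene-oxide sheet lying on a lipid bilayer traps a
nanometre-scale water layer between them. When the sheet is heated (Joule
heating in a device, or deliberately in thermotherapy), the heat must cross
the sheet/water/lipid interface to reach the aqueous environment on the far
side of the membrane, which acts as a heat sink at $T_e = 300$ K. Two
material facts dominate the problem:

* the confined water is **structured**: its density profile $\rho(z)$ shows
  near-wall peaks above the bulk density, and water within the layered
  region diffuses more slowly than bulk water;
* the interface presents a large **Kapitza resistance**: the temperature
  drops abruptly between sheet and water, by far more than across the water
  or the lipid interior.

`nanoheat` quantifies both, and wraps them in a one-dimensional
serial-resistor model that predicts device and membrane temperatures from a
handful of parameters.

# Descriptors of the intercalated water

**Density profile.** Particles are binned into slabs along the interface
normal $z$ (origin at the sheet plane, increasing toward the membrane), the
per-slab mass is divided by $A\,\Delta z$ and averaged over frames. The
default slab width of 0.1 nm is shared with the temperature profiling so one
binning convention serves both analyses. Binning conserves the selected mass
exactly — this is asserted in the tests to float precision.

**Bulk reference.** The layer descriptors compare $\rho(z)$ against a bulk
density. The reference is either supplied (0.997 g cm$^{-3}$ for ambient
water) or estimated as the mean over a user-designated far-field window;
the package does not guess a window because what counts as "far field"
depends on the geometry.

**Layer thickness $t_W$** is the span of the region with
$\rho(z) \ge \rho_\mathrm{bulk}$. On sampled profiles a strict reading is
fragile — a single noisy bin can split the region — so the implementation
takes the maximal contiguous super-bulk run containing the first peak and
bridges isolated sub-bulk dips of at most one bin. The resolution of $t_W$
is therefore one bin width. Water that penetrates the bilayer itself (real
interfaces show a decaying density tail about 1 nm deep) is excluded: the
descriptor characterises the gallery, not the membrane interior.

**First-peak mass $M_1$** is $A\int_{z_0}^{z_1}\rho(z)\,dz$ over the first
peak, integrated by the trapezoidal rule on the bin centres and extended to
the exact boundaries $z_0, z_1$ by linear interpolation (dropping the edge
half-bins biases $M_1$ low by several percent at 0.05-nm bins).

**Peak detection** finds local maxima above the bulk reference. Extrema are
located on a 3-bin running mean so single-bin jitter does not spawn peaks,
but amplitude, position and prominence are measured on the raw profile —
smoothing a 3-bin-wide layering peak would otherwise crush its prominence
below any sensible threshold. Interior maxima must rise above their flanking
minima by at least 10% of the profile's super-bulk excursion; boundary ties
break toward the wall.

# Diffusivity

The diffusion coefficient follows the Einstein relation
$D = \lim_{t\to\infty}\langle|\mathbf r(t)-\mathbf r(0)|^2\rangle/(2 d_i t)$
with $d_i$ the analysed dimensionality. The MSD uses every frame as a time
origin; the $O(N^2)$ origin sum is evaluated with the standard FFT
decomposition, verified in the tests against a brute-force oracle to
$10^{-13}$. Two windows matter:

* **maximum lag**: 25% of the trajectory by default. Longer lags average
  over few origins and dominate the fit with correlated noise; a quarter of
  the trajectory keeps the estimator's sampling error at the percent level
  for the sizes used here.
* **fit window**: 10–50% of the maximum lag. The lower cut skips the
  short-time regime (ballistic or cage-rattling in real data), the upper cut
  avoids the worst-sampled tail.

With 500 particles and 2000 frames the single-run estimate recovers a known
$D$ to within a few percent; averaging independent runs (supported directly
by `diffusion_coefficient()`) tightens it further. Coordinates must be
unwrapped; a single-step displacement exceeding half the box on a periodic
axis aborts with advice rather than silently corrupting the MSD.

# Interfacial conductance from relaxation

A pulse-relaxation protocol heats the sheet (100 ps to about 500 K by
default) and releases it; the sheet temperature then decays exponentially
toward the sink. `relaxation_time()` fits
$T(t) = T_e + \Delta T_0 e^{-t/\tau}$ by nonlinear least squares
(`minpack.lm`), initialised from a log-linear regression so convergence does
not depend on a user guess. All points are weighted equally — the estimator
is used on noiseless or homoscedastic series. The Kapitza conductance is the
intensive form $G_K = \rho_g c_g d/\tau$, independent of sheet area by
construction.

Sheet constants default to graphene: density 2.265 g cm$^{-3}$, van der
Waals thickness 0.34 nm, and the Dulong–Petit specific heat
$c_g = 3 N_A k_B$ per gram of carbon $= 2.1$ J g$^{-1}$ K$^{-1}$ — the
classical high-temperature limit, appropriate because the lattice modes that
carry the heat here are fully excited at the temperatures involved. These
give an areal heat capacity $\rho_g c_g d = 1.617\times10^{-3}$
J m$^{-2}$ K$^{-1}$, so $\tau \approx 159$ ps corresponds to
$G_K \approx 10$ MW m$^{-2}$ K$^{-1}$.

**Kinetic temperatures** use three translational degrees of freedom per
particle. Constraint corrections (SHAKE-type bond freezing in real MD)
are not applied; slab temperatures of constrained atomistic trajectories
would be biased low by the missing DOF correction. This is a documented
limitation, acceptable because the package analyses its own surrogate data
and generic unconstrained input. Never-occupied slabs are reported `NA`,
not 0 K.

# The serial-resistor model

Heat flow is taken as diffusive (Fourier, $J = \kappa A\,dT/dx$): the
interfaces scatter heat carriers strongly and the interactions across them
are weak, so ballistic transport is not a concern. The stack is two
resistors in series — the sheet/water/lipid interface (conductance $G_C$)
and the lipid slab (conductivity $\kappa_L$, thickness $\delta$) — ending in
the sink at $T_e$. The intercalated water is treated as isothermal: its
conductivity ($\approx 0.61$ W m$^{-1}$ K$^{-1}$) is five times the lipid's
($\approx 0.12$), so its internal gradient is negligible.

With through-interface flux $q = \eta p$:

$$T_W = T_e + \frac{q\,\delta}{\kappa_L}, \qquad
  T_G = T_W + \frac{q}{G_C},$$

with a linear profile inside the lipid. The closure $T_W = T(z_s)$ — the
water plateau pinned to the lipid inner surface — is a design choice: the
plateau must meet the lipid boundary for the steady flux to be continuous,
and flux continuity is asserted exactly in the tests.

**The partition factor $\eta \in [0,1]$** is the fraction of the injected
power that crosses the serial path; the remainder leaks through bulk water
around the confined region. The default $\eta = 1$ is the pure serial model.
$\eta$ exists because the serial model with realistic parameters
overpredicts steady temperatures compared to full atomistic simulations
(e.g. the lumped plateau $p/G_C \approx 1599$ K at
$p = 16.25$ GW m$^{-2}$, $G_C = 10.16$ MW m$^{-2}$ K$^{-1}$, against
$\sim1150$ K observed in MD): treating $\eta$ as fittable reconciles the
magnitudes without altering the model equations, and the package reports an
$\eta$ obtained this way as a fitted partition, never a prediction. No
attempt is made to force the serial model onto the MD magnitudes.

**Transient.** The sheet is a single lumped node,
$\rho_g c_g d\,\dot T = \eta p - G_C (T - T_W)$ with $T(0) = T_W$, giving an
exponential approach to $T_W + \eta p/G_C$ with time constant
$\rho_g c_g d/G_C$. The closed form is verified against an independent
numerical ODE integration to $10^{-6}$.

**Fitting.** `fit_steady_parameters()` recovers $\kappa_L$ from the lipid
regression slope and $G_C$ from the sheet-minus-plateau drop — the exact
least-squares solution for the piecewise model, with delta-method standard
errors. A vanishing interfacial drop makes $G_C$ unidentifiable and is
flagged (`Inf` with a warning) rather than returned as a large number.
`fit_transient()` fits the lumped solution for $G_C$ by nonlinear least
squares; series much shorter than the time constant carry no conductance
information (the early response is linear in $t$ regardless of $G_C$) and
are flagged as weakly identified.

**Critical power.** Inverting the steady solution at a threshold membrane
rise $\Delta T_c$ gives $p_c = \kappa_L \Delta T_c/(\eta\delta)$ at the
lipid surface, twice that for the bilayer volume average of the linear
profile. The conventional threshold is $\Delta T_c = 20$ K, the reported
rise a cell tolerates before viability is compromised; $\delta$ defaults to
4 nm, a typical POPC bilayer thickness. `critical_power()` separately
locates the threshold crossing on a *measured* $\Delta T(p)$ curve by
monotone piecewise-linear interpolation, so model and measurement routes
can be compared.

# The synthetic generators

The generators provide data with the statistical structure the analyses
assume, at desk scale, with every draw reproducible by seed.

**Layered density.** The target profile is a bulk plateau plus Gaussian
peaks; positions are drawn by inverse-CDF sampling on a 4096-point grid and
per-particle masses are set so the binned profile converges to the target in
absolute units. Gaussians are chosen because the mixture has closed-form
integrals, which makes exact oracles possible for $M_1$; real nanoconfined
water has asymmetric, non-Gaussian peaks, so passing tests validate the
*estimators*, not any claim about real profile shapes. The default gallery
(plateau 1.05 g cm$^{-3}$, peaks at 0.32 and 0.65 nm, gap 1.82 nm) emulates
a $\sim$1.8 nm gallery with two near-wall layering peaks; the plateau sits
slightly above bulk water so that the thickness descriptor, referenced to
0.997 g cm$^{-3}$, spans the full gallery as it does in such systems.

**Brownian walkers** have exact Gaussian increments of variance
$2D\,\Delta t$ per axis, so the ensemble MSD is $2 d_i D t$ by construction
— the analytic slope is the oracle for the whole MSD/diffusion pipeline.
There is no hydrodynamics, no caging, no ballistic regime: recovery tests
certify the estimator under its own assumptions only.

**The heat-conduction lattice** is a chain of lumped thermal nodes in three
layers (sheet, water, lipid) with per-layer site capacities and link
conductances, distinct junction conductances at the two interfaces, and a
sink coupled to the far lipid site. The update is explicit forward Euler on
$C_i\,dT_i = \sum_j g_{ij}(T_j - T_i)\,dt + s_i\,dt$; the pairwise exchange
is antisymmetric, so with the sink decoupled total energy is conserved to
machine precision (asserted at $10^{-6}$ over $10^5$ steps). Specs whose
$\Delta t\,g_\mathrm{max}/C_\mathrm{min} \ge 0.5$ are rejected at
construction, and runtime divergence aborts with a diagnostic. The heating
protocol injects constant power into the sheet layer; the pulse protocol
drives the sheet toward 500 K for 100 ps (both overridable) through a
first-order pull with a time constant of one tenth of the pulse, standing in
for velocity-rescale heating whose per-step details are not part of this
package's scope. `noise_amplitude` is applied as observation noise on the
recorded series — the interior dynamics stay deterministic — which keeps the
conservation invariant exact while still exercising fits against scatter.
The lattice is a surrogate for protocol logic and estimator validation in
the diffusive regime, not a replacement for atomistic simulation: parameters
are chosen per test (e.g. a bottleneck junction for lumped-limit checks),
not calibrated to any material.

# Numerical choices and degenerate inputs

* Bins are half-open with the rightmost edge closed; particles outside the
  requested range fold into the edge bins (`findInterval(all.inside)`).
* The steady-profile generator places one sheet bin left of $z = 0$; region
  membership in the fit uses the same bin-centre rule, so noiseless round
  trips are exact.
* Exponential fits initialise from log-linear regression; non-decaying
  series and series starting at $T_e$ are errors, not silent failures.
* A negative fitted MSD slope returns $D = 0$ with a warning.
* Flat $\Delta T(p)$ curves below threshold raise an error that reports the
  maximum rise reached.

# Problem sizes

The test suite and the pipeline default configuration use generator sizes
chosen to hold estimator sampling error at or below the few-percent level
while the whole suite runs in well under a minute: $10^4$–$10^5$ molecules
for density fixtures, 500 × 2000 (particles × frames) for the headline
diffusivity recovery, $10^5$ lattice steps for conservation checks. These
are statements about estimator statistics, not about any physical system
size.

# Known limitations

* One-dimensional: no lateral heat spreading, no temperature-dependent
  conductivities.
* Kinetic temperatures assume three unconstrained DOF per particle.
* The water plateau closure ties $T_W$ to the lipid surface; models where
  the plateau floats (e.g. strong convection) are out of scope, as the
  convective contribution is negligible in the nanoconfined gallery.
* Only extended-XYZ and LAMMPS-dump trajectory dialects are read; convert
  anything else upstream.
* The synthetic generators validate estimators under idealised assumptions;
  agreement here does not certify behaviour on real MD output with
  hydrogen-bond dynamics, constrained bonds, or anisotropic diffusion.
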