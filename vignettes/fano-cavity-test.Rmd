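---
title: "Condensed-history electron transport in magnetic fields and the Fano cavity test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensed-history electron transport in magnetic fields and the Fano cavity test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Monte Carlo codes transport electrons in *condensed-history* (CH) steps:
many elastic and inelastic interactions are lumped into one straight
segment with an aggregate energy loss and an aggregate angular
deflection. In an external magnetic field the true trajectory is curved,
so a straight CH step is an approximation whose quality depends on the
step length relative to the gyroradius

$$ r_G = \frac{pc}{2.99792\, B \sin\theta} \quad [\mathrm{cm}], $$

with $pc$ in MeV, $B$ in tesla and $\theta$ the angle between flight
direction and field. At 1 MeV and 1.5 T, $r_G \approx 0.32$ cm — the size
of an ionization-chamber cavity. The engine therefore limits every step to

$$ s \le \texttt{em\_estepe} \times r_G, $$

so the step adapts automatically to energy and field strength. Without a
field the usual fractional energy-loss limit applies
($s \le \texttt{estepe}\, T / (S\rho)$, default `estepe = 0.25`), plus the
geometric chord to the nearest region surface. `em_estepe` defaults to
0.25 (the unrestricted baseline at the top of the studied range; 0.02 is
the historical default of the EGSnrc field macros).

The **Fano cavity test** validates this machinery: for media that share
the same mass stopping power and differ only in density, a monoenergetic,
isotropic source whose emission density is proportional to the local mass
density produces a charged-particle fluence independent of the density
distribution — even in a uniform external magnetic field. The absorbed
dose in region $i$ then has the closed form

$$ D_i = \frac{n_i E_0}{m_i}, $$

with $n_i$ the number of particles emitted in the region and $m_i$ its
mass. Any statistically significant deviation of the simulated dose from
$D_i$ is a transport artifact, not physics.

## The transport model

*Kinematics and energy loss.* Electrons are tracked from $E_0$ down to a
1 keV kinetic-energy cutoff (`ecut`), below which the remainder is
deposited locally. The collision stopping power is the Møller/ICRU form
for water without density-effect correction; under Fano conditions every
medium uses this same mass stopping power, so its absolute accuracy is a
sanity band (within about 3% of published water tables), not a contract.
Energy is advanced through an exact CSDA mass-range table
($R(T) = \int \mathrm{d}T'/S$, 16384-point log grid with binary-search
inverse) rather than a per-step quadrature rule. This matters for the
test itself: media of different density take very different step sizes
per unit mass thickness, and any step-size-dependent discretization of
the energy-loss map would act like a different cross-section in each
medium. The same reasoning shapes the scattering model below.

*Multiple scattering.* Deflections use a Gaussian (Highland) model whose
logarithmic thickness correction is evaluated at an energy-dependent
reference thickness $t_{\mathrm{ref}}(E) = 0.25\,T/S(T)$, making the
angular variance exactly additive in mass thickness: the *scattering
power* $q(E)$ (rad² cm²/g) is a pure function of energy, identical in all
media. Large per-step variances are applied as several sub-rotations
(variance ≤ 0.05 rad² each) whose Rayleigh width is adjusted so that
$\mathrm{E}[\cos\theta]$ composes exactly as $e^{-v}$ — the first
spherical-harmonic moment of the angular diffusion semigroup. The
transport mean free path per unit mass is then the same in air and in
water regardless of how the mass is chopped into steps. During
development, the naive alternatives (bracket evaluated at the actual step
thickness; one Gaussian kernel per step) produced spurious Fano
deviations of several percent in low-density regions at *all* step sizes,
which is precisely the failure mode the additivity argument predicts.

*The random hinge (scattering only).* Within a step the scattering
deflection is applied at a uniformly random fraction $\xi$ of the step,
and the remainder $(1-\xi)s$ continues along the new direction with a
fresh geometric chord check. This reproduces the correct lateral and
longitudinal spatial moments of the scattering process for coarse steps;
applying the whole deflection at the step end instead biased the
boundary-crossing fluence enough to produce a $-9\%$ dose error in a
0.5 cm air gap at `estepe = 0.25` with no field at all. With scattering
disabled (oracle runs) the step is a single deterministic segment.

*Magnetic deflection.* The direction is rotated about $\hat B$ **once per
step, at the end of the straight chord**, by
$\alpha = s / r_G(E, B, \sin\theta)$ — an exact rotation of the
transverse component that preserves the parallel component and the norm
to machine precision and reduces to
$\mathrm{d}\vec u/\mathrm{d}s \propto \vec u \times \vec B$ for small
steps. The single end-of-step update is deliberate: treating the field
deflection as one aggregate kick per straight condensed-history segment
*is* the approximation under study, and `em_estepe` is the dial that
controls how well the curved trajectory is resolved. (Refining the field
rotation inside the step — e.g. hinging it along with the scattering —
was tried during development and measurably suppresses the coarse-step
artifact; it would make the engine a better transport code but a worse
testbed for the phenomenon the package exists to study.) A first-order
variant of the rotation is available behind
`transport_params(first_order = TRUE)` for comparison studies. The
rotation sense follows $+\,\vec u \times \vec B$; the Fano test is
insensitive to the sense by mirror symmetry, so no attempt is made to
match any particular code's sign convention. Because the rotation rate
is a function of $\theta$ alone, the flow is measure-preserving on the
sphere and cannot itself break the isotropy the Fano theorem needs.

## Geometry and fixtures

Geometries are box phantoms tiled by nested axis-aligned boxes and
z-axis cylinders with carve-out priority (later regions carve earlier
ones). Volumes and masses are closed-form; point location scans priority
downward with a $10^{-10}$ cm surface skin resolving to the
higher-priority region. Step lengths are bounded by the nearest surface
crossing of *any* shape along the ray **and** by the exit distance from
the tolerance-expanded current shape — the latter guards against a
particle located in a boundary skin taking a long step at the wrong
density. A particle landing on a surface is nudged $10^{-8}$ cm along its
post-deflection direction before relocation.

Three water-equivalent fixtures ship with the package (every region has
the water mass stopping power and its own density):

* `chamber_like` — a simplified thimble chamber: PMMA wall, graphite
  liner, a 0.07 cm³ air cavity around a 0.04 cm radius aluminium
  electrode, and a PMMA stem with three thin air gaps; 10×10×12 cm³
  phantom, 5×5×7 cm³ source box.
* `diode_like` — PMMA housing, epoxy body, a 3.4×10⁻⁴ cm³ silicon chip,
  one air gap.
* `slab` — water / 2×2×0.5 cm³ air gap / water, the oracle geometry: the
  large gap gives roughly fifty times the statistical power of the
  chamber cavity per history.

The cavity, electrode and chip dimensions are the published detector
values; wall, liner, stem and housing dimensions and the material
densities are fixture parameters chosen to be representative. The stem
air gaps exist to reproduce the qualitative finding that small air
volumes buried in solid material also fail the test at coarse steps.
Every scoring region except the background water lies at least one CSDA
reach inside the source box, which is what makes the per-region
expectation $n_i E_0/m_i$ exact for all regions (the background region
follows by energy conservation). A 20×20×20 cm³ phantom with a 9×9×10 cm³
source box is substituted automatically for energies above 1 MeV.

What the fixtures deliberately do not emulate: photon transport,
bremsstrahlung and delta-ray production (the test needs none of them),
the proprietary multi-region CAD models of real detectors, and non-water
cross sections. Passing the test here validates the stepping algorithm,
not a clinical detector model.

## Statistics

Two expectation conventions are implemented. The default uses the
**realized** emission counts $n_i$; its deviation uncertainty comes from
a history-by-history accumulator of $y_h = d_h - E_0\,\mathbf 1(\text{emitted
in } i)$, which folds the correlation between deposits and counts exactly
(for a large self-absorbing region most source noise cancels; for a small
region fed from outside, the Poisson noise of $n_i$ dominates honestly).
The **analytic** convention replaces $n_i$ by its expectation
$N \rho_i V_i / \sum_j \rho_j V_j$ (closed-form, since all detector
regions lie inside the source box) and is used where statistical power on
small regions matters, e.g. the step-size inflation studies.

The per-region pass rule is $|\Delta_i| \le \max(0.1\%,\, 2\sigma_i)$ —
0.1% is the conventional pass level of the test, and the $2\sigma$ guard
makes explicit how statistical noise is folded in. The headline scalar
(`fano_headline`) reports $\max_i \max(0, |\Delta_i| - z\sigma_i)$, a
conservative lower bound on the worst true deviation; because it takes a
maximum over many regions, its guard $z$ is Šidák-corrected for the
number of regions tested (at the 3σ base level in the acceptance
pipeline), keeping the family-wise false-alarm rate at the single-region
level. Uncertainties combined over several regions use root-sum-square;
the efficiency figure of merit is $\epsilon = 1/(T\sigma^2)$ with $T$ in
hours and $\sigma$ in percent.

At desk-scale history counts (10⁵–10⁷ per run, seconds to minutes on one
CPU) the per-region σ of the chamber cavity is a few percent — resolving
the 0.1% level there would take ~10¹⁰ histories. The shipped runs
therefore verify the absence of transport bias *at the resolution the
statistics afford*, with the slab gap providing sub-percent resolution on
exactly the low-density mechanism. With this engine the unrestricted step
size (`em_estepe = 0.25`) biases the slab-gap dose by about +2.5% — a
clearly significant inflation relative to the fine-step arms, though far
smaller than the artifact reported for production-code field macros,
whose magnitude is implementation-specific.

## Numerical choices

* Units: cm, g, MeV, tesla, rad. Electron rest energy 0.5110 MeV;
  $r_G\,[\mathrm{cm}] = pc/(2.99792\,B)$.
* Surface skin $10^{-10}$ cm; boundary nudge $10^{-8}$ cm; exit-distance
  floor $2\times10^{-10}$ cm so a skin-trapped particle always makes
  progress; ray-surface extent slack $10^{-9}$ cm (wider than the skin,
  so a skin-located particle still sees its shape's side surfaces).
* Range table: 16384 log-spaced energies from 0.1 keV, Simpson per
  interval, binary-search inverse; interpolation error ≲ $5\times10^{-6}$
  relative.
* Scattering substep variance cap 0.05 rad²; substep width solves
  $\sigma^4/3 - \sigma^2 + (1 - e^{-w}) = 0$ so the first angular moment
  is exact.
* Per-history RNG sub-streams: xoshiro256++ seeded via splitmix64 from
  `base_seed XOR (golden_ratio_64 * (history + 1))`; results are
  independent of batching and execution order. The R reference stepper
  uses R's own RNG and serves as the independent cross-check (exact
  step-by-step agreement with the compiled engine in deterministic mode).
* Step-count circuit breaker at 10⁷ steps per history (a trip indicates a
  stepping bug, and aborts the run with diagnostics).
* Ties at surfaces resolve to the higher-priority (later-listed) region.

## Known limitations

* No photon or secondary-electron transport: CSDA with local absorption.
  This keeps the Fano theorem exactly applicable but means the code is a
  consistency testbed, not a dose engine for clinical beams.
* The Gaussian scattering model composes correctly by construction, but
  its shape is not Molière theory; absolute angular distributions are
  approximate. Fano consistency is insensitive to this by design, and
  the test suite verifies insensitivity by globally doubling the
  stopping power.
* Single-scattering boundary modes and curved-arc substeps are not
  implemented; the straight-chord convention with the hinge is the
  declared step model, and `em_estepe` is the dial that controls its
  curvature resolution — which is exactly the effect under study.
* Very low energies (≤ a few keV) are handled by freezing the stopping
  power below the cutoff; sub-keV transport fidelity is out of scope.
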