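---
title: "Acoustic models behind sonochamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic models behind sonochamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonochamber)
```

`sonochamber` models the acoustics of a thin, rigid-walled, microliter-scale
exposure chamber: a liquid sample trapped in a 10–20 µm gap between a 1.2 mm
microscope slide and a 0.17 mm coverslip, insonified obliquely at 26.5° by a
calibrated 1 MHz flat piston through a water bath, with air behind the
coverslip. This vignette records the models, the defaults, and the reasoning
behind every choice that was genuinely open.

## Layered-media model

The stack is solved as plane layers with a conserved lateral wavenumber
(Snell's law). Conventions: time dependence $e^{+i\omega t}$, propagation
along $+z$, $z = 0$ at the first interface, amplitudes relative to a unit
incident pressure, and complex wavenumbers $k = \omega/c - i\alpha(f)$
carrying attenuation. The radiation condition forces the backward amplitude
in the final half-space to zero exactly.

Two solvers share these conventions:

* `solve_normal()` chains 2×2 transfer matrices in pressure and normal
  velocity. At normal incidence mode conversion vanishes, so solids are
  propagated with their longitudinal properties only.
* `solve_oblique()` assembles a global matrix over displacement potentials,
  with both longitudinal and vertically polarized shear waves in solid
  layers. Boundary conditions: normal displacement and normal stress
  continuous everywhere; tangential displacement and shear stress continuous
  at solid–solid interfaces; shear stress vanishing where a solid meets a
  fluid. This is what lets energy cross the slide beyond the longitudinal
  critical angle — first through the slower shear branch (with its own,
  larger critical angle), and past both critical angles through evanescent
  tunnelling, which is non-negligible for a 1.2 mm layer at 1 MHz.

Displacement and stress rows of the global matrix differ in magnitude by
roughly $\rho\omega^2 \sim 10^{13}$, so the matrix is equilibrated (each row
and column scaled by its largest entry) before the complex `solve()`; without
this the system is reported as numerically singular. True isolated
singularities (layer resonances at measure-zero angles) are handled by
re-solving with a $10^{-6}$-degree nudge and a warning. Zero-thickness
interior layers are elided at construction, matching the vanishing-layer
limit of the solvers.

`brute_force_five_layer()` is the independent check: it writes out the eight
unknown wave amplitudes of a five-layer stack (reflected, three interior
pairs, transmitted) and solves the full boundary-condition system directly.
The test suite requires agreement with the transfer-matrix path to better
than $10^{-9}$ relative on 1000 seeded random stacks, and energy
conservation $|T + R - 1| < 10^{-9}$ on every lossless one.

### Standing waves in the gap

Inside the sample the forward and backward waves interfere; the peak
magnitude over the gap is computed analytically for a lossless fluid layer
(the extremum of $|A e^{-i\nu\zeta} + B e^{i\nu\zeta}|$ over the interval)
and on a dense grid otherwise. Two consequences the tests pin down:

* the peak is periodic in the gap $L$ with period exactly half the sample
  wavelength (740 µm at 1 MHz in water), once $L$ spans at least that
  half-wavelength — below it, the peak tracks where the gap sits inside the
  standing-wave pattern anchored at the pressure-release air backing;
* glass walls (impedance 14 MPa·s/m) make the in-gap peak far more sensitive
  to $L$ than polystyrene walls (2.5 MPa·s/m), because the stiffer cavity
  stores a stronger standing wave. Wall-material comparisons are run at
  normal incidence over a full half-wavelength sweep, the conditions under
  which the five-layer gap analysis is formulated.

## Material constants

The registry ships pinned handbook-range values because reproducibility
requires fixed constants; none are measured here. Density, speeds (m/s) and
attenuation (dB/cm at 1 MHz, power-law exponent in parentheses):

| material | ρ (kg/m³) | c_long | c_shear | α₀ (exp) |
|---|---|---|---|---|
| water | 1000 | 1480 | – | 0.0022 (2) |
| glass (borosilicate) | 2500 | 5600 | 3400 | 0.20 (1) |
| polystyrene | 1050 | 2350 | 1120 | 0.35 (1) |
| adiprene (soft polyurethane) | 880 | 1650 | – | 2.0 (1) |
| polyethylene | 950 | 1950 | 950 | 1.1 (1) |
| air | 1.204 | 343 | – | 1.64 (2) |

Choices that were open:

* **Glass attenuation.** The characterization quotes both "about 5 % loss"
  for the 1.2 mm slide and "no more than 5 %" for a hypothetical 10 mm slab;
  a single power-law coefficient cannot produce both. The stricter 10 mm
  bound wins: α₀ = 0.20 dB/cm gives a 4.5 % power loss over 10 mm
  ($1 - e^{-2\alpha d}$) and 0.55 % over 1.2 mm. Microscope slides may be
  soda-lime rather than borosilicate; the borosilicate constants are a
  pinned convention, not a measurement.
* **Adiprene.** The water/adiprene pair is the textbook case where both a
  critical and an intromission angle exist. In the fluid-modelled closed
  form ($\sin^2\theta = (m-1)/(m-n)$ with $m = (r_2/r_1)^2$,
  $n = (c_2/c_1)^2$) that requires an impedance *below* water with a speed
  *above* it; ρ = 880, c = 1650 (soft polyurethane range) satisfies it and
  yields an intromission angle of 21.4° with a critical angle at 63.8°.
  Stiffer handbook polyurethanes (ρ ≈ 1100) do not show the fluid-branch
  intromission angle at all — the choice is recorded here as the package's
  own pinning.
* **Moduli.** K, G, E in the table are derived self-consistently from the
  pinned speeds ($G = \rho c_s^2$, $K = \rho c_l^2 - 4G/3$,
  $E = 9KG/(3K+G)$), so the constructor's cross-check between stored speeds
  and moduli-implied speeds passes by construction. The bar speed
  $\sqrt{E/\rho}$ (relevant for slender parts like slides) is exposed through
  `speeds_from_moduli()` but stacks propagate with the stored `c_long`.
* **Shear attenuation** reuses each solid's longitudinal power law; no
  separate shear coefficient is published for these parts, and at the
  chamber's sub-millimetre thicknesses the distinction is far below the
  other modelling errors.

## Piston fields

The reference characterization simulated its transducer inside a
finite-element model of the sealed tube. This package substitutes free-field
semi-analytic models — the closed-form baffled piston on axis, O'Neil's
spherical-cap model for focused on-axis pressure, and the Rayleigh surface
integral for full $(r, z)$ maps (Gauss–Legendre quadrature, 96×96 nodes by
default; the on-axis column agrees with the closed form to well under 0.5 %).
Focused maps use the conjugate-spherical lens phase
$e^{+ik(\sqrt{\sigma^2+R^2}-R)}$, which puts all source contributions in
phase at the geometric focus. Consequences:

* the focal distance and the orderings between flat and focused transducers
  (shorter focal region, narrower width, smaller iso-areas, higher peak) are
  claimed and tested;
* the absolute iso-surface areas of the tube simulation are *not* claimed.

The active element radius of the hardware is not published (only the
12.5 mm external radius); the default a = 9.43 mm is chosen so that
$a^2/\lambda$ = 60 mm at 1 MHz in water, reproducing the stated 6 cm focal
distance, and is echoed in every design report's assumption block. The
focused comparison geometry (a = 19 mm, curvature radius 65 mm) is chosen so
its true on-axis peak also lands at 60 mm — "matched focal distance" — since
a weakly focused cap peaks well short of its curvature centre.

Focal metrics adopt −6 dB for the length/width criterion (none is published;
the choice is recorded in the metrics' attributes). Iso-pressure "areas" are
surfaces of revolution of the 2D iso-contour about the beam axis, and only
the connected region containing the focal peak is measured — the flat
piston's near-field lobes reach the same 2 p₀ amplitude and would otherwise
contaminate the 25 % band.

## Microbubbles

The shelled-bubble resonance
$\omega_0^2 = \frac{1}{\rho R_0^2}\left[3\gamma\left(P_0 + \frac{2\sigma}{R_0}
+ \frac{2\chi}{R_0}\right) - \frac{2\sigma}{R_0} - \frac{6\chi}{R_0}\right]$
reduces exactly to the Minnaert resonance at $\sigma = \chi = 0$, which the
suite verifies to machine precision across 0.5–10 µm. Defaults γ = 1.07
(perfluorocarbon-like gas), σ = 0.072 N/m, χ = 0.55 N/m are typical
lipid-shell literature values; no published number here depends on them, and
they are always overridable. With these defaults a 3 µm bubble resonates at
1.196 MHz, conveniently near the 1 MHz drive. The mechanical index follows
the kPa-and-Hz convention, numerically identical to MPa/√MHz. Cavitation
*regimes* are named but not classified — no threshold is defined in the
source characterization, so none is invented. Dynamic (Rayleigh–Plesset
/Marmottant) simulation is out of scope.

## The evaluation pipeline

`evaluate_design()` chains: (1) calibration — the piston source amplitude is
solved so the free-field focal peak equals the measured 500 kPa (for the flat
closed form the peak is exactly $2p_0$); (2) the five-layer solve at the
design angle under a focal-zone plane-wave approximation (no beam-spread
correction over the 60 mm path — the focal region is far larger than the
stack thickness); (3) the standing-wave excursion across the declared
10–20 µm gap range, per-layer attenuation losses, critical-angle verdicts,
bubble resonance and in-sample mechanical index; (4) the classical-bath
comparison $\lceil \pi R^2 H \rceil$ in mL, with R the 12.5 mm external
transducer radius and H the 60 mm focal distance (both lower bounds, hence
the ceiling). 26.5° is treated purely as the *design incidence angle*: it
sits close to, but is not identified with, the 25.8° shear critical angle of
the pinned glass, and the report never asserts which acoustic angle it is.
The report prints this model's transmitted pressure next to the 380 kPa
full-wave reference value with an explicit model-difference note, because the
two models are not interchangeable.

## Randomized fixtures

`generate_random_stack()` draws fluid-modelled media with impedances spanning
more than three orders of magnitude (densities $10^2$–$10^4$ kg/m³, speeds
300–6000 m/s) and interior thicknesses log-uniform over 10 µm–10 mm,
deterministically per seed and without touching the global RNG state. This
emulates the *mathematical* range of layered problems — strong contrast,
thickness/wavelength ratios from deeply sub-wavelength to many wavelengths —
not real laboratory materials: no shear branches, no dispersion, no
correlated property combinations. Passing the 1000-stack oracle equivalence
therefore certifies the solver algebra, not the realism of any particular
material model.

## Problem sizes and tolerances

The suite's heavier computations are sized to stay comfortably interactive:
Rayleigh maps of roughly 30×110 (flat) and 60×110 (focused) points at 96×96
quadrature nodes, 1000-stack oracle sweeps, and ~850-point gap sweeps — a
full run takes well under a minute. Key numeric tolerances: oracle
equivalence and lossless energy conservation at $10^{-9}$; Minnaert limit at
$10^{-14}$ relative; the gap-sweep period at 0.1 % (peaks located by
quadratic interpolation on a 2 µm grid); Rayleigh-vs-closed-form at 0.5 %.
The `resonant_radius()` inversion brackets 10 nm–100 µm at $10^{-6}$
relative tolerance and reports a clear error when no sign change exists.

## Known limitations

No tube-wall reverberation, no plate-wave (Lamb) dispersion, no transverse
horizontal shear, no nonlinear propagation, no temperature or salinity
dependence of sound speed, no transducer bandwidth model. The transmitted
sample pressure is a free-field plane-wave estimate: it shares the full-wave
reference's qualitative conclusions (transmission below the calibration
pressure, survival of transmission beyond the critical angles, glass walls
more gap-sensitive than polystyrene) but not its exact numbers.
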