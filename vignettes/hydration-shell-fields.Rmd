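---
title: "Hydration-shell electrostatics at the DNA backbone phosphate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell electrostatics at the DNA backbone phosphate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellfield)
```

## The physical picture

The phosphate groups of the DNA backbone sit at the water interface and
feel strong, fluctuating electric fields from the first two hydration
layers — time-averaged amplitudes of tens of MV/cm. When the water shell
is heated (for instance by depositing an OH-stretch quantum that
thermalises within about a picosecond into a "hot ground state"), the
shell structure loosens slightly, the field at the phosphate changes, and
every backbone vibration that couples linearly to that field shifts in
frequency. In a pump–probe experiment this appears as a reshaping of the
v = 0 → 1 bands: a bleach on one side, an enhanced absorption displaced
from it, growing in with the kinetics of the shell rearrangement.

`shellfield` implements that chain as a pipeline of small, testable
pieces:

1. **Sampling** — equilibrium configurations of rigid five-site waters
   around a rigid dimethylphosphate (DMP) anion, the minimal model of a
   backbone phosphate, generated by Metropolis Monte Carlo at a set of
   temperatures.
2. **Electrostatics** — the solvent field at the midpoint of the free
   O–O axis, projected on the C2 symmetry axis of the PO2⁻ group, from
   point charges and optionally distributed dipoles/quadrupoles.
3. **Shell structure** — radial distribution functions, normalised field
   distributions per temperature, their occurrence differences, and
   mean-field changes with bootstrap errors.
4. **Stark mapping** — Δν = a·ΔE with the published tuning rate of the
   symmetric PO2 stretch, and pure-shift difference spectra.
5. **Kinetics** — simulation and least-squares fitting of the
   mono-exponential and biphasic transient models, including global fits
   with shared time constants.
6. **Dosimetry** — photon energetics, excited-molecule fraction and the
   temperature jump of the hot ground state.

## Why Monte Carlo rather than molecular dynamics

Everything downstream needs only *equilibrium ensembles* at fixed
temperatures, not dynamics. Rigid-body Metropolis MC delivers exactly
that with far less machinery: single-molecule translation + rotation
moves accepted with probability min(1, exp(−ΔU/kT)). No integrator,
thermostat, or constraint algorithm is needed; the solute is simply never
moved. Users with real MD trajectories can bypass the sampler entirely
through `read_frames()` (multi-frame XYZ or PDB).

The acceptance rule is validated against closed forms, not against
itself: a single particle in an isotropic harmonic well must show a
position variance of kT/k per axis and a Gaussian marginal
(Kolmogorov–Smirnov distance below 0.03 on thinned samples). The
compiled droplet sampler and an independent R implementation of the
potential energy are cross-checked per frame to ~1e-9 kJ/mol.

### Interaction model and cells

Waters interact through an oxygen-centred Lennard-Jones term and Coulomb
sums over the four charged sites (TIP5P parameters shipped as data in
`inst/extdata/tip5p.yaml`, overridable). The DMP solute carries per-atom
LJ parameters and partial charges constrained to net −1 e. **The solute
charge set is synthetic**: the ESP-derived charges used in the original
force-field work are not printed anywhere we can cite as data, so
`dmp_gg_synthetic.yaml` ships a plausible stand-in (P +1.2, free O
−0.8, ester O −0.5, united CH3 +0.2). Absolute field magnitudes
therefore carry no quantitative claim; temperature *differences* of the
same model are the meaningful output.

Two cells are offered: a spherical droplet with a hard wall on the
oxygen positions (default, radius 14 Å ≈ two-plus hydration layers,
~250 waters), and a cubic periodic box with molecule-based minimum
imaging and a 9 Å cutoff. There is no Ewald summation — at these system
sizes and for field *differences* the truncation error is part of the
declared desk-scale approximation.

### Desk-scale sizes

The packaged defaults (2×10⁵ sweeps, 20% equilibration, stride 100)
replace the long production averaging of a full MD study. The
qualitative temperature tests in the test suite run three chains per
temperature of 65 waters in an 8 Å droplet for 8000 sweeps each; at that
size the chain-to-chain scatter of the first-shell coordination number
is about ±0.2 waters, which is why the occupancy comparison carries a
stated 0.3-water tolerance and tests only the direction (heating must
not *tighten* the first shell). The broadening of the field
distribution with temperature is robust at this scale; the small
decrease of the first-layer occupancy seen in full MD sits below the
resolution of these short chains, and the tests are honest about that.

## Field evaluation

The field at the probe is a superposition of closed-form kernels, in
MV/cm with coordinates in Å and charges in e:

* point charge: `E = k q n / r²`,
* point dipole: `E = k (3(μ·n)n − μ) / r³`,
* Buckingham traceless quadrupole (`Θ = (3M − tr M · I)/2` from primitive
  second moments `M`): `E = k (5(n·Θn)n − 2Θn) / r⁴`.

`k = 1439.96 MV/cm per e/Å²` is derived from CODATA 2018 constants and
pinned by a test against an independently hand-evaluated Coulomb field
(159.9961 MV/cm for +1 e at 3.0 Å). Each kernel is verified against a
finite point-charge oracle (two charges at r/1000 for the dipole, a
four-charge arrangement evaluated at 100× its size for the quadrupole).

By default waters act as point charges — consistent with the model that
generated the configurations. Per-site dipoles and quadrupoles in the
water body frame can be supplied (`read_multipoles()`) and are rotated
with each molecule; this is an EFP-style fidelity option, but no damping
or screening functions are applied, a documented gap relative to full
effective-fragment electrostatics. The solute's own charges never
contribute: the quantity of interest is the field *imposed by the
solvent*. The sign convention makes E∥ positive along the axis from P
through the O–O midpoint into the solvent; hydrogens pointing at the
anionic oxygens therefore give negative E∥, and "field amplitude"
statements refer to |E∥|.

## Distributions and their differences

`field_distribution()` bins E∥ with a default 2 MV/cm width (the bin
width is a free choice; nothing downstream depends on it because the
mean and standard deviation are always computed bin-free from the raw
samples). `occurrence_difference()` subtracts two *normalised*
distributions on an identical grid — mismatched grids are an error, no
silent rebinning — so the differences sum to zero exactly, and reports
the locations of the differential extrema by parabolic refinement. For
a small mean shift δ ≪ σ between two near-Gaussian distributions the
extrema separation tends to 2σ (the inflection distance), *not* δ: the
package exposes both numbers and the tests document the distinction.
`mean_field_change()` reports the signed difference of means with a
seeded bootstrap standard error (default 1000 resamples); block
averaging (`block_error()`, default 10 blocks) is available when frames
are more strongly correlated than the default stride assumes.

## Stark mapping

`stark_shift()` is deliberately trivial — Δν = a·ΔE, exactly linear, no
hidden factors — because its value lies in being composed with the rest
of the pipeline. Only the symmetric PO2 stretch has a published tuning
rate (a = 0.4 cm⁻¹/(MV/cm), an ab-initio input, not something this
package derives); coefficients for other backbone modes must be supplied
explicitly and are never defaulted. `difference_spectrum()` implements
the pure-shift band reshaping on Gaussian or Lorentzian profiles
(Gaussian by default; the experimental lineshapes are not stated, and
amplitude changes beyond a optional uniform scaling are out of scope).
`extrema_separation()` approaches the shift itself only when the shift
is large against the band width — for a 10 cm⁻¹ shift of a ~20 cm⁻¹ wide
band the bleach/enhancement separation and the shift happen to be of
the same order, which is the regime the experiment sits in.

## Kinetic models and fitting

Three forms cover the observed transients (t in ps, ΔA in mOD):

* `mono_decay_offset`: A·exp(−t/τ) + C — direct backbone excitation,
  v = 1 depopulation within a few ps;
* `biphasic_rise`: A₁(1−exp(−t/τ₁)) + A₂(1−exp(−t/τ₂)) — response to
  water-shell excitation: fast ~1 ps hot-ground-state formation plus a
  slow tens-of-ps energy-equilibration rise;
* `decay_plus_rise`: A₁·exp(−t/τ₁) + A₂(1−exp(−t/τ₂)) — positions where
  the fast component appears as a decay; with A₂ = 0 it is the
  neat-water control.

Fits minimise raw residuals by Levenberg–Marquardt (`minpack.lm`),
which remains well behaved when an amplitude collapses to zero and its
time constant becomes unidentifiable — a full nls model matrix would
reject that point as singular. Starting values are automatic (offset
from the tail mean, decay constant from a log-linear tail regression,
amplitudes by linear least squares at the initial constants) and
overridable. Time constants of the biphasic rise are ordered τ₁ < τ₂
post hoc; constants converging within 10% of each other set an
ill-conditioning flag on the result rather than failing. Uncertainties
are 1σ values from the Jacobian-based covariance scaled by the residual
variance; a Monte-Carlo calibration test checks that the mean reported
σ(τ) tracks the replicate-to-replicate spread within 30%. Non-convergence
is flagged in the result object, never thrown, and the residual RMS is
reported either way.

The default fit window starts at 0.2 ps, clear of the ~100 fs
instrument response; an analytic Gaussian-IRF convolution of every
exponential term is available (`irf_fwhm`) but off by default, since at
these delays it changes nothing beyond ~1 ps and the plain exponential
is the published description of the data. `global_fit()` stacks the
residuals of several traces, sharing selected time constants while every
trace keeps its own amplitudes; shared constants are log-parameterised
internally so positivity never binds, with delta-method standard errors.

Synthetic traces carry i.i.d. Gaussian noise at the 0.03 mOD detection
floor of the experiment. The amplitude ratios underlying the published
figures are not printed; the generator defaults to A₁/A₂ = 3 (declared
choice) with amplitudes of order 1 mOD.

## Dosimetry

`photon_energy()` is hc·ν̃ with CODATA constants (41.3 kJ/mol at
3450 cm⁻¹). `excited_fraction()` divides the pump photons by the number
of water molecules in a flat-top cylinder (spot area × penetration
depth); whether "excited" counts incident photons or only those absorbed
within one 1/e depth (factor 1 − 1/e) is not stated in the source
experiment, so both conventions are exposed, defaulting to the absorbed
one, which lands at ≈3% for the solution-sample parameters (1.6 μJ,
100 μm spot, 2.4 μm depth, 44 M). `temperature_jump()` assumes every
deposited quantum thermalises in the water (molar heat capacity 75.3
J mol⁻¹ K⁻¹, overridable; no heat partition into the DNA at this level),
giving ΔT ≈ 22 K at a 4% fraction.

## Numerical and design choices, collected

* Constants: CODATA 2018 throughout; one field-conversion constant
  shared by all kernels and pinned by test.
* RNG: every stochastic entry point takes an explicit seed; the MC
  sampler refuses to run without one. The pipeline derives per-stage
  seeds from the global seed by fixed offsets.
* Degenerate inputs: coincident interaction sites, collinear probe
  atoms, empty selections, mixed-temperature samples, mismatched
  histogram grids and too-narrow spectral grids are all hard errors
  with specific messages rather than silent repairs.
* Droplet initialisation places waters by rejection sampling with
  minimum-distance constraints; an impossible packing is an
  initialisation error, not a hang (bounded attempts).
* The trajectory container is a plain long-format tibble (one row per
  interaction site) so that dplyr verbs, the RDF, the field evaluation
  and the writers all speak the same dialect; metadata rides in
  attributes.

## Known limitations

* Absolute field scales depend on the synthetic DMP charges and the
  charges-only default; only temperature differences within one model
  are meaningful, and no claim is made that the desk-scale droplet
  reproduces full-MD shell structure quantitatively.
* No polarisation, induction, exchange repulsion or EFP damping.
* No microscopic model of the vibrational relaxation cascade; the
  kinetics module fits phenomenological exponentials, which is also how
  the experiments are analysed.
* The water-excitation pathway and the backbone response are linked
  only through the Stark arithmetic, not through a coupled dynamical
  model.
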