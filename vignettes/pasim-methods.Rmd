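---
title: "Models and methods behind pasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pasim` simulates the photoacoustic signal chain — tissue model, light
transport, acoustic propagation, noise, image reconstruction and
multispectral post-processing — as exchangeable pipeline elements that
communicate only through one hierarchical HDF5 store. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions that were genuinely open, so a user can judge what results
obtained with the package do and do not show.

## Tissue properties and mixing

A `Molecule` carries wavelength-dependent optical properties as knot tables
(`Spectrum`): absorption and scattering coefficients in cm⁻¹ and the
scattering anisotropy *g* (unitless), plus scalar acoustic properties:
speed of sound ν (m/s), density ρ (kg/m³), acoustic attenuation α
(dB cm⁻¹ MHz⁻¹) and the Grüneisen parameter Γ (unitless). Spectra are
interpolated piecewise-linearly between knots; queries outside the knot
range are **clamped** to the nearest endpoint rather than extrapolated —
linear extrapolation of steep hemoglobin slopes can produce negative
coefficients, clamping cannot.

A `MolecularComposition` mixes molecules linearly by volume fraction.
Two fraction semantics coexist deliberately:

* optical μₐ and μₛ scale with the **absolute** fractions — a fraction
  deficit behaves as transparent filler, which keeps Beer–Lambert
  reasoning exact;
* the acoustic scalars ν, ρ, α and Γ are **renormalized** over the present
  fractions, so a voxel always has a defined sound speed and density.

The literature does not fix a mixing rule for acoustic properties (linear
in ν versus linear in compressibility); linear mixing in each scalar is
used and documented here. The anisotropy is averaged weighted by each
member's scattering contribution (the mean cosine of a scatterer mixture);
where total scattering is zero the plain fraction-weighted mean is used.
Blood oxygen saturation sO₂ is defined as the oxyhemoglobin fraction of all
hemoglobin members and is `NA` wherever a composition contains none.

The bundled chromophore tables (oxy-/deoxyhemoglobin as whole-blood
absorption at 150 g/L, water, lipid, melanosome; 15 knots over
650–1000 nm) and the tissue library (blood, epidermis, dermis, fat,
muscle, bone, water, generic background) are digitized from the public
compilations in common use and tuned so that each tissue's mixed
properties fall inside the literature ranges exposed by
`literatureRanges()`. They are representative library constants, not
measurements; the anisotropy default is g = 0.9 for all scattering
tissues.

## Volume creation

The computational grid is isotropic (`GridSpec`): voxel edge `spacing_mm`,
voxel centers at `origin + (i − 0.5)·spacing`, z pointing into the tissue.
Structures (layer, sphere, elliptical tube, cuboid, parallelepiped,
random-walk vessel tree, background) are rasterized to per-voxel occupancy
fractions. With partial-volume sampling each voxel is probed on a regular
k³ sub-grid with **k = 3** (27 points) — the default balances boundary
accuracy (sphere volumes converge to the analytic value within 2 % at
0.15 mm spacing) against a 27× rasterization cost; it is a documented,
configurable constant.

Voxel capacity is shared by **descending priority**: each structure claims
its fractional occupancy from what higher priorities left, and the single
mandatory background absorbs the remainder, so claims always sum to one.
This capacity-sharing rule (rather than winner-take-all) makes
partial-volume boundaries blend smoothly; because claims are exclusive, at
most one structure can hold more than half a voxel, which defines the
segmentation label. Ties in priority are broken by list order, and
permuting structures with distinct priorities cannot change the result.

Vessel trees grow by a random walk: each step of `step_mm` (default 1 mm)
deflects the direction by at most `max_bend_deg` (15°), and with
probability `bifurcation_prob` (0.05) the walker splits into two children
separated by `branch_angle_deg` (40°) whose radii shrink by
`radius_decay = 2^(−1/3)` — a Murray-law-like choice: the literature the
generator follows does not state a rule, and Murray's cube-law exponent
keeps total cross-section roughly conserved. Branches stop below
`min_radius_mm` or on leaving the bounding box. The same seed always
reproduces the same tree.

Surface deformation is a **height field only** (no volumetric warping): a
sum of `n_modes` random-phase sinusoids rescaled so the maximum offset
equals the requested amplitude. Only structures that opt in
(`adhere_to_deformation`) evaluate their membership at the shifted depth —
skin layers and near-surface vessels adhere; deep structures need not.

Segmentation-based creation maps integer label grids to compositions
voxel-by-voxel with no blending; interfaces stay sharp and the mask is
stored verbatim as the segmentation.

## Optical Monte Carlo

The fluence solver is a weighted-photon voxel Monte Carlo written in C++:

* free paths are sampled from the local scattering coefficient while the
  photon weight decays continuously with absorption along every sub-step
  (`w ← w·exp(−μₐ·ℓ)`);
* fluence uses the **track-length estimator**
  `φ += ∫ w dl / (V·N)` — unbiased also in non-absorbing voxels, and with
  lower variance than a collision estimator;
* scattering angles follow Henyey–Greenstein via its inverse CDF, with a
  uniform azimuth and a local-frame direction update;
* Russian roulette below weight 10⁻⁴ with survival probability 0.1;
* photons that leave the grid are terminated (**matched boundary**;
  refractive-index mismatch is a documented non-feature).

Properties stored in cm⁻¹ are converted to mm⁻¹ at solver entry; grid
lengths are mm throughout; stored time metadata uses ms while the acoustic
solver works in seconds internally. Fluence is normalized per launched
photon, so `Γ·μₐ·φ` yields the initial pressure in arbitrary units
(`computeInitialPressure`). With roulette disabled the energy bookkeeping
(absorbed + escaped = launched) is exact to machine precision; with
roulette it holds in expectation. The transport RNG (xoshiro256+, seeded
explicitly) is independent of R's RNG, so simulations never perturb, and
are never perturbed by, the session's random state.

Launch positions come from collimated illumination geometries (pencil,
pencil array, slit, disk, Gaussian truncated at 3σ); angular divergence is
a known limitation.

## Acoustic k-space solver

Acoustic propagation is solved in **2-D** on the imaging (x–z) plane of
the device — the 3-D initial pressure is sliced at the array plane. This
is a deliberate desk-scale divergence from full 3-D solvers: linear and
curved arrays image a plane, and the contracts the package tests
(time-of-flight, localization, reciprocity, linearity) are plane
contracts. Out-of-plane effects are absent from simulated time series.

The solver advances first-order linear acoustics (pressure / particle
velocity / acoustic density) with spectral spatial derivatives on
staggered grids, the k-space temporal correction `sinc(c_ref·k·Δt/2)` with
`c_ref = max(ν)`, and a split-field PML with a quadratic absorption ramp
over 8 grid points. The time step is `Δt = CFL·Δx / max(ν)` with CFL 0.3;
an explicit Δt above the limit is refused. The domain is padded by the PML
width with edge-replicated medium before solving, so the absorbing layer
lies **outside** the physical volume — detector arrays at the tissue
surface would otherwise sit inside the PML and record attenuated signals.
Nonlinearity, shear waves and heterogeneous absorption inside the wave
solver are out of scope; a post-hoc homogeneous attenuation filter
(`10^(−α·f·d/20)` per channel, with a single distance proxy) is provided
instead and documented as a simplification.

A note on arrival times: in 2-D the pressure waveform of a compact source
is bipolar with a wake, and its raw positive peak physically leads the
time of flight `d/c` by a small, resolution-dependent amount. Arrival is
therefore measured on the **envelope** of the recorded trace (standard
practice in ultrasound time-of-flight estimation); the envelope peak lands
within one time step of `d/c`.

## Reconstruction

All reconstruction modes are compositions of four primitives in a fixed
order — Tukey bandpass, differential (first-derivative) mode, beamforming,
envelope detection — toggled by flags, so any mode equals the explicit
composition of its parts. The bandpass multiplies the per-channel spectrum
by a Tukey window spanning the band (defaults: α = 0.5, 1 kHz–8 MHz),
applied symmetrically to negative frequencies so the output stays real and
zero-phase. Delays use **linear interpolation** between samples (nearest-
sample rounding produces gridding artifacts), samples outside the record
contribute zero, and no apodization is applied. The beamforming sound
speed defaults to the mean of the medium map, a scalar choice the user can
override.

DMAS uses the signed-square-root pair formulation
`Σ_{i<j} sign(dᵢdⱼ)√|dᵢdⱼ|`, computed through the algebraic identity
`((Σy)² − Σy²)/2` with `y = sign(d)√|d|`; the signed variant (sDMAS)
multiplies each pair term by `sign(dᵢ + dⱼ)` — a documented implementation
choice for polarity preservation, as the method family only fixes the pair
kernel. Time reversal re-injects the time-reversed recorded signals as
additive pressure sources at the element grid nodes while the k-space
solver runs; the image is the final-step field restricted to the FOV.

## Noise models

Five models (Gaussian, uniform, Gamma, Poisson, salt-and-pepper) apply as
pipeline elements to any stored field or time series. Poisson noise is
implemented as scaled shot noise (`rpois(x/s)·s`) so arbitrary-unit data
remain usable; salt-and-pepper extremes are taken from the data's own
range, a documented choice since no canonical alternative exists for
arbitrary-unit data. Defaults are conservative (e.g. Gaussian σ = 0.01)
and live in the settings tree.

## Multispectral processing

Linear unmixing solves `A·c ≈ p` per pixel via the SVD pseudoinverse,
**unconstrained** — negative concentrations are allowed in the estimate
and only clipped for sO₂ reporting; a non-negativity constraint is a noted
extension, not the default, because unconstrained least squares keeps the
estimator linear and exactly scale-equivariant. Rank-deficient endmember
matrices are rejected with their condition number. sO₂ is reported only
where total hemoglobin exceeds a small threshold (10⁻⁸ of its maximum).

The iterative absorption recovery (qPAI) runs the package's own Monte
Carlo as forward model — the model-match regime; model-mismatch studies
are out of scope. Starting from a uniform guess (`mua_init`, default
0.5 cm⁻¹), each iteration simulates φ for the current estimate and updates
`μₐ ← p₀/(Γ·φ)`, floored at zero and capped at `mua_max` (20 cm⁻¹).
Two numerical choices matter:

* the **same RNG stream is reused in every iteration** (fixed-sample
  iteration): the fixed point is then a deterministic function of one
  photon sample instead of chasing a fresh noise realization per
  iteration, which destabilizes the update in weakly illuminated voxels;
* "illuminated" voxels, the support for error metrics and convergence
  traces, are those with φ above 10⁻⁴ of its maximum; voxels where the
  simulated fluence vanishes while the measured pressure does not are
  flagged unrecoverable and excluded.

Plain fixed-point iteration with an iteration cap is used; no damping or
stopping rule is applied beyond the cap, as the convergence trace is
returned for the user to inspect.

## Pipeline, store and reproducibility

`runSimulation(pipeline, settings, device)` is the entry point (the name
`simulate` is avoided because `stats::simulate` is an S3 generic with an
incompatible signature). For each wavelength all non-multispectral
elements run in list order; multispectral elements run once afterwards.
Every element reads its inputs from and writes its outputs to the HDF5
store only, which is what makes elements exchangeable: swapping DAS for
time reversal, or moving a noise element, changes no other element's
settings. Forward results computed once can feed any number of
reconstruction elements through the store.

Each element draws a seed derived from the global seed, its pipeline
position and the wavelength index, and every randomized routine restores
R's RNG state on exit — two runs with the same inputs are byte-identical
in their `Simulations` payloads, and sequential runs in one process cannot
influence each other. Settings are persisted under `/Settings`
(non-atomic values as YAML strings), the device twin under `/Device`, the
ordered element names under `/pipeline`. Stores can be repacked with gzip
compression without changing any value, and detector data exports to an
IPASC-style HDF5 layout — a minimal metadata subset (sampling rate,
element positions, sound speed), not certified format compliance.

The command-line interface (`inst/scripts/pasim`, or `cliRun()` from R)
wraps the same functions: `run` executes a YAML-declared pipeline, `demo`
runs bundled scenes, `inspect` prints a store's group tree.

## Synthetic scenes and what the tests show

The randomized scene generator draws vessel count, lateral positions,
depths, radii and oxygenations plus a skin-curvature amplitude uniformly
from configurable ranges (defaults: 2–6 vessels of 0.5–2 mm radius at
3–12 mm depth, sO₂ 0–1, curvature up to 1.5 mm) and assembles a layered
forearm-like scene — epidermis, dermis, muscle background, vessels along
the elevation axis. These scenes emulate the geometry and contrast
structure of real extremity imaging: layered skin, discrete absorbers,
depth-dependent fluence. They do **not** emulate heterogeneous background
perfusion, device-specific artifacts, out-of-plane signal, angular
illumination divergence, or transducer impulse responses, so passing tests
demonstrate correctness of the modeled physics and contracts, not realism
of any specific commercial system. The bundled device presets are generic
parameterized archetypes, deliberately not calibrated to vendor hardware.

Test problem sizes are chosen to probe each contract at the smallest scale
where the physics is clean: Beer–Lambert and the diffusion asymptote on
narrow/wide columns at 0.15–0.5 mm spacing, time-of-flight on a 256² grid
at 0.15 mm, the localization sweep at 0.15/0.35/0.55 mm with 10⁵ photons,
qPAI on a 10 mm two-layer cube at 0.5 mm with 2×10⁵ photons, and
determinism over twenty sequential small pipeline runs.

## Known limitations

* Acoustics are 2-D and linear; no shear waves, no nonlinearity, no
  heterogeneous attenuation inside the solver.
* Optical boundaries are matched (no internal reflection); illumination
  is collimated.
* One anisotropy default (g = 0.9) for all tissues; chromophore tables
  are coarse 25 nm digitizations.
* The qPAI solver assumes known scattering, anisotropy and Γ.
* Device presets are generic; element directivity and impulse response
  are not modeled.
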