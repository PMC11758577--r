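---
title: "Models and methods behind nanoscint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoscint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nanoscint` simulates keV X-ray energy deposition in SiO₂/ZnO
nanoscintillator assemblies and decomposes their radioluminescence (RL)
spectra into signed Gaussian components. This vignette records the physical
models, the numerical choices, and the limits of what the package's tests
demonstrate. It states no result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. Atomic data

Transport needs, per element, photoelectric/incoherent/coherent mass
attenuation coefficients, K-shell quantities (edge, K-α energy,
fluorescence yield, mean L binding) and electron total stopping powers over
0.25–15 keV. The shipped tables for H, C, N, O, Si, Ar and Zn are
**approximate reference tables** produced by the package's own
parameterization (`data-raw/build_tables.R`):

* *Photoelectric*: piecewise log-log power laws through per-element anchor
  values, split discontinuously at the K edge. The anchors for C, N, O, Si
  and Ar are total attenuation values from standard reference compilations;
  they reproduce the standard dry-air and liquid-water composites at the
  anchor energies (e.g. air at 10 keV evaluates to 5.116 cm²/g against the
  reference 5.120). Zn is anchored through the Cu/Zn K-shell systematics
  (above-edge slope ≈ E^−2.7, K-jump ratio 7.4); the classical Cu value at
  its own K-α line is reproduced within ~2%. Only the K edge is resolved
  discontinuously — L/M structure is smoothed, so the sub-1.2 keV rows for
  Zn are rough. Photons in the benchmark simulations live between 1.7 and
  10 keV, where the tables are most accurate.
* *Incoherent*: Klein–Nishina total cross section per electron times an
  incoherent-function suppression `S(E) = E/(E + 1.5√Z)`.
* *Coherent*: a form-factor-scaled Thomson power law
  `2.76 · Z^2.37/A · E^−1.9` cm²/g, capped at `0.75 Z² σ_T N_A/A`.
* *Electron stopping*: the Joy–Luo low-energy modification of the Bethe
  collision formula, `S/ρ = 78500 (Z/A) E^{-1} ln(1.166(E + 0.85J)/J)`
  keV·cm²/g with J the mean ionization energy — the standard choice for
  sub-10 keV electrons (it reproduces the reference water stopping power at
  10 keV within ~3%).

Scatter channels are ≤2–4% of the total attenuation of SiO₂ and ZnO below
10 keV, so the parameterization's accuracy is dominated by the
photoelectric anchors. The energy-partition observable depends on
*ratios* of attenuation coefficients; the acceptance tolerance of the
headline partition absorbs the residual table uncertainty.

Interpolation is log-log linear with **no extrapolation** (hard error):
silent extrapolation would corrupt partition fractions. The K edge appears
as a duplicated grid energy (below-edge row, then above-edge row); queries
at the edge itself return the above-edge value. Tests run on *toy* tables
(`make_toy_tables()`, pure `C·E⁻³` laws with a prescribed edge jump) so the
whole suite is self-contained.

Materials are mass-fraction mixtures: SiO₂ (2.65 g/cm³), ZnO (5.61 g/cm³),
TCPP (C₄₈H₃₀N₄O₈, 1.3 g/cm³) and standard dry air
(N 75.5 / O 23.2 / Ar 1.3 wt%, 1.205×10⁻³ g/cm³) — when a setup is only
described as "air", standard dry air is the natural reading.

## 2. Geometry

Two assemblies, both with closed-form ray tracing (sphere/cylinder
quadratics):

* **satellite**: one SiO₂ sphere (default 80 nm diameter) with `n_zno` ZnO
  nanoparticles (5 nm) whose centers sit **exactly on the tangency sphere**
  `R + r` — the micrographs show surface-decorating particles and no
  embedding depth is documented, so tangency is the minimal assumption.
  Placement is uniform on the sphere with rejection of center pairs closer
  than one NP diameter (1e6 attempts per particle; at n = 215 the
  surface-coverage margin is large).
* **powder**: `n_nanosystems` core–shell spheres uniform in an air-filled
  cylinder (8.5 µm diameter × 1 µm height; an alternative 8.25 µm
  diameter, sometimes quoted for the same holder, is selectable via
  `holder_diameter_um`). The ZnO shell thickness defaults to the
  equal-volume solution `(R³ + 215·r³)^{1/3} − R = 0.688 nm` (≈0.7 nm).
  Non-overlap is enforced with a cell list; random sequential addition
  handles the benchmark packing fraction (~0.25) comfortably below its
  ~0.38 saturation. Spheres are fully contained in the holder (wall contact
  is not allowed: full containment is the simpler, unambiguous contract).

The world volume for the satellite geometry is an air sphere of
configurable radius (default 2 µm). Energy leaving the world is scored as
*escaped*, not as air dose; the air fraction of the partition therefore
depends mildly on the world radius (sub-percent effects at the default).

Determinism: the same `(config, seed)` reproduces bit-identical body lists;
placement uses an isolated RNG state that does not disturb the caller's.

## 3. Transport

Primaries are parallel photons from a uniform disc circumscribing the
target's projected footprint (the beam width is not documented; a
circumscribing disc makes every solid reachable and only dilutes
per-primary counts), tilted 26° from the cylinder/geometry axis, from
15 cm away. The optional `air_column` attenuates primaries over that 15 cm
air path; it defaults **off** because conditional partition fractions are
insensitive to it, and **on** is recommended for count observables.

* **Forced first interaction**: the primary's first collision is sampled
  from the truncated exponential across the solid segments of its ray; the
  history weight is the unconditional interaction probability
  `(1 − e^{−Σμl})`, times the upstream air transmission when `air_column`
  is on. Everything downstream is analog. Rays missing every solid carry
  weight 0. Per-history energy bookkeeping satisfies
  `weight·E_beam = Σ(weighted deposits) + weighted escape` to 10⁻⁹
  relative, and the engine counts violations (always zero in the suite).
* **Channels**: sampled proportionally to the partial attenuation
  coefficients. Compton uses Klein–Nishina rejection sampling on a free
  electron at rest (no Doppler broadening/binding — a documented deviation,
  acceptable because incoherent scattering is a minor channel below
  10 keV); the recoil electron follows the Compton kinematics angle.
  Rayleigh redirects by the Thomson law `(1 + cos²θ)`. By default a
  Rayleigh event *does* tag the "first interaction"
  (`tag_rayleigh = FALSE` restricts tags to energy-transferring events; the
  partition is insensitive to this choice at these energies).
* **Photoelectric and relaxation**: the target element is sampled from the
  per-element photoelectric shares; above its K edge the K shell is chosen
  with probability `1 − 1/jump`, the photoelectron carries `E − E_K`
  isotropically, and the vacancy relaxes either radiatively (probability
  ω_K: a K-α photon is tracked, the residual L binding deposits locally) or
  non-radiatively. For the non-radiative branch
  `run_config(relaxation = ...)` offers two models:
  `"local"` (default) deposits the whole K binding energy at the
  interaction point — this mirrors the reference Livermore physics
  configuration, in which fluorescence is tracked but Auger-electron
  generation is disabled; `"single-auger"` emits one KLL-like Auger
  electron of energy `E_K − 2⟨E_L⟩` instead. The choice matters for a 5 nm
  ZnO particle: a 7.5 keV Auger electron has a ~450 nm CSDA range and
  carries the binding energy out of the particle, while local deposition
  keeps it inside. The package's benchmark observables use the default,
  which reproduces the reference behaviour; the tests exercise both.
* **Electrons**: condensed history with fixed 1 nm steps in solids
  (a 5 nm NP is crossed in ≥5 steps) and safety-distance steps in air
  (distance to the nearest solid surface, 1–1000 nm) — a fixed 1 nm step in
  air would make a keV electron's mm-scale air range intractable while
  depositing negligible energy per step. Each step loses
  `S(E, medium)·step`, scored at the step midpoint **to the medium whose
  stopping power was applied** (the step-start medium): attributing to the
  midpoint's medium would systematically leak one step's energy across
  boundaries. Below the 0.25 keV cutoff the residual deposits locally.
  Multiple scattering applies a Gaussian polar deflection per step with
  variance `σ² = K·step/R_CSDA(E)`; with exponential direction
  decorrelation the straight-line/path detour over a full range is
  `(2/K)(1 − e^{−K/2})`, and `K = 2.2` sets it to ≈0.6, a standard
  condensed-history detour at these energies.
* **RNG**: xoshiro256++ with splitmix64 seeding; every history gets an
  independent substream derived from the master seed, so runs are
  reproducible regardless of execution order.

## 4. Scoring

The engine aggregates per-history weighted deposits per medium, radial
histograms conditioned on the first-interaction medium, and batch sums
(50 batches) from which partition statistical errors are estimated as the
standard error of per-batch fractions. Event-level output (every electron
step is a deposition event) is only collected for small runs
(`record_events`); the event-table and engine-aggregate code paths are
cross-checked against each other in the tests.

Radial anchors: `r_SiO2` — distance to the host-sphere center, for
histories whose first interaction is in SiO₂; `r_ZnO` — distance to the
struck nanoparticle's center, for first-in-ZnO histories; `r` (powder) —
distance to the center of the nanosystem *where the energy is deposited*
(anchoring to the
first-interaction nanosystem is available through the engine's
`powder_anchor_first` switch). Bin widths default to 1 nm (satellite) and
5 nm (powder), with an overflow bin so that profile mass always equals the
conditioned deposited energy exactly.

## 5. RL spectral decomposition

The model is a sum of area-normalized Gaussians; area parameterization
(rather than amplitude) was chosen because the sign constraints become a
clean signed-log transform `A = ±e^u`. Center bounds (used for the four
Q-band absorption components, ±0.05 eV) map through a smooth tanh box.
The Levenberg–Marquardt loop uses the analytic Jacobian, multiplicative
damping (×ν on rejection, ÷ν on acceptance, ν = 2), a trust-region-style
step cap (parameters are O(1)-scaled), and convergence at a relative
chi-square decrease < 10⁻⁸ over at most 500 accepted steps. Two
robustness devices matter in practice and are covered by tests: a
component pinned on the saturated tail of its tanh box freezes its
Jacobian column, so stalls pull such coordinates back to the box middle
and re-seed the damping (up to 3 restarts, never returning a point worse
than the best visited); and initial areas are solved by sign-clipped
weighted linear least squares (`default_component_set(spectrum = )`),
since areas enter the model linearly.

Weighting: uncertainty-weighted least squares when per-point uncertainties
are given (the synthetic generator provides Poisson ones), unweighted
otherwise — the CCD noise model of real spectra is not documented.
Parameter standard errors come from the delta method on
`σ²(JᵀJ)⁻¹`; with weights, σ² = 1, otherwise χ²/dof.

The default initial component sets are schematic (centers at the known
band positions, widths 0.15 eV, Q-band dips 0.05 eV): no reference set of
fitted numerical parameters is available, so the defaults encode only band
positions. The fit window is the native eV axis of the
spectrum; the Soret-tail re-absorption above 3 eV is deliberately *not*
modelled.

## 6. Synthetic data: what it emulates, and what it does not

`example_truth_components("functionalized")` defines the study conditions
for the recovery benchmark: six positive components (porphyrin bands at
1.55/1.72/1.90 eV with the 1.72 eV J-aggregate band dominant, as in the
functionalized samples; ZnO defect band at 2.22 eV, σ = 0.28 eV; a green
defect shoulder at 2.60 eV; the excitonic band at 3.09 eV) plus four
negative Q-band components with clearly visible dips (areas −0.15 to
−0.25). Counting noise is Poisson at 2×10⁴ counts per intensity unit over
a 100-count background — ordinary statistics for a cooled-CCD RL spectrum
with distinct, well-exposed bands. The widths/amplitudes were chosen once,
from identifiability considerations (band separations ≳2.5 combined σ), to
represent a *well-conditioned* decomposition; strongly degenerate band
systems (overlapping components separated by ≲2σ) make the likelihood
multimodal, and no fitter's 3σ intervals cover nominally there. Passing
recovery tests therefore demonstrate correct estimation on resolvable
spectra, not the ability to disambiguate arbitrarily overlapped bands.
Similarly, the generator produces idealized spectra: no detector spectral
response, no baseline drift, no Soret tail.

The transport generator's defaults *are* the study conditions
(80 nm core, 5 nm NPs, 0/10/100/215 satellites, 0.7 nm shell, 8.5 µm × 1 µm
holder, 3.3/6.6/10 keV, 26° tilt, 15 cm source distance). The benchmark
suite reduces the powder count to 2×10³ nanosystems by default (the full
5×10⁴ is available via `full_powder = TRUE`): partition fractions are
intensive observables and the reduction preserves them while keeping the
ray-segmentation cost (which is linear in the sphere count) manageable.

## 7. Problem sizes and statistical choices

The acceptance computation uses 2.4×10⁵ forced histories at 10 keV
(≥2×10⁵ of them interacting), giving batch statistical errors of ~0.1
percent points on the ZnO fraction. The trend checks use 6×10⁴ histories
per energy; the estimator-equivalence checks use 3×10⁴ forced vs 10⁵
analog histories on a toy assembly; sampling oracles use 10⁶ draws. These
sizes put Monte Carlo errors an order of magnitude below every tolerance
being checked.

## 8. Known limitations

* The cross-section tables are parameterized approximations, not a
  particular evaluated library; partition observables inherit a few-percent
  table uncertainty (anchored composites suggest ~1–10% depending on
  element and energy).
* Atomic relaxation is single-step (K-α or one Auger / local deposition);
  full cascades, L-shell fluorescence and electron-impact ionization below
  0.25 keV are out of scope.
* Compton ignores binding and Doppler broadening; pair production is
  irrelevant below 1.022 MeV and absent.
* Bremsstrahlung of secondaries is not modelled (sub-10 keV electrons,
  radiative yield ≪1%).
* The condensed-history multiple-scattering model is a single-parameter
  Gaussian small-angle model, not a Molière/Goudsmit–Saunderson theory.
* Polychromatic tube spectra are not simulated; the monochromatic energies
  are the mean energies of the corresponding tube settings, and
  observables that depend on the full bremsstrahlung distribution are
  outside the package's claims.
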