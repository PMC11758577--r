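# nanoscint

Monte Carlo nanodosimetry and radioluminescence spectral decomposition for
hybrid SiO₂/ZnO nanoscintillators under keV X-rays.

Porphyrin-functionalized SiO₂/ZnO nanosystems are candidates for X-ray
activated photodynamic therapy (X-PDT): a dense inorganic core absorbs keV
photons and its radioluminescence (RL) excites a grafted photosensitizer
(the porphyrin TCPP). Two computational questions decide whether that works:
*where does the deposited energy end up* at the nanometre scale, and *how do
the RL spectra decompose* into emission and re-absorption components?
`nanoscint` addresses both for researchers in nanomedicine, radiation
physics and scintillator spectroscopy.

## What the package computes

**Energy deposition.** A compiled photon/electron Monte Carlo transports a
monochromatic parallel beam (3.3, 6.6 or 10 keV in the benchmark) through
either of two assemblies:

* `satellite` — one 80 nm SiO₂ sphere decorated with *n* tangent ZnO
  nanoparticles (5 nm diameter; 0/10/100/215 in the benchmark grid), in air;
* `powder` — up to 5×10⁴ SiO₂ spheres coated by an equal-volume 0.7 nm ZnO
  shell, packed at random in an air-filled micro-cylinder (8.5 µm × 1 µm).

Photons undergo photoelectric absorption (with the Zn K edge at 9.66 keV
resolved discontinuously, K-α fluorescence with yield ω_K, and configurable
non-radiative relaxation), Klein–Nishina Compton scattering and
Thomson-law Rayleigh scattering. Electrons follow a condensed-history walk
(1 nm steps in solids, 0.25 keV cutoff, Gaussian multiple scattering).
A forced-first-interaction mode samples the primary's interaction point
conditionally on hitting a solid, with the unconditional probability
`1 − exp(−Σ μᵢ lᵢ)` as statistical weight — the analog estimator would waste
~10³–10⁴ histories per interaction at these optical depths.

Scoring produces the study's observables: the per-medium energy partition
(% of deposited energy in SiO₂ / ZnO / air), radial deposition profiles
conditioned on where the *first* interaction occurred (distance `r_SiO2`
from the host center, `r_ZnO` from the struck nanoparticle center, or `r`
from the depositing nanosystem center in the powder), and per-primary
interaction probabilities.

**Spectral decomposition.** RL spectra are modelled as a sum of
area-normalized Gaussians,

    I(E) = Σₖ Aₖ / (σₖ√(2π)) · exp(−(E − cₖ)² / 2σₖ²),

with ≥6 positive emission components (ZnO excitonic ~3.09 eV, defect
~2.22 eV, porphyrin bands 1.5–2 eV) and, for functionalized samples, four
**negative-area** components at the porphyrin Q-band energies
(2.01 / 2.2 / 2.34 / 2.5 eV) describing re-absorption dips. The fitter is a
Levenberg–Marquardt damped least-squares with analytic Jacobian, signed-log
area parameterization (sign constraints) and tanh box transforms (center
bounds). Beer–Lambert dye quantification (`c = A/(εd)`) rounds out the
workflow.

## Worked example: energy partition at 10 keV

```r
library(nanoscint)
model <- build_assembly(assembly_config("satellite", n_zno = 215), seed = 1)
run <- run_transport(model,
                     beam_config(10, n_histories = 3e4),
                     run_config(seed = 1, mode = "forced"))
partition_by_medium(run, "all")
#> Energy partition (condition: all )
#>   air       0.27697 keV    0.58 % (+/- 0.01 pp)
#>   SiO2       9.9613 keV   20.76 % (+/- 0.22 pp)
#>   ZnO        37.753 keV   78.67 % (+/- 0.22 pp)
count_interactions(run)
#>   n_histories interacting  per_primary
#> 1       30000    13.67284 0.0004557613
```

Although the 215 nanoparticles hold only ~5% of the solid volume, at 10 keV
— just above the Zn K edge — ZnO receives ~78% of the deposited energy: the
K-shell photoelectrons and the non-radiative relaxation energy are released
inside the 5 nm particles. At 3.3 keV the same geometry deposits >90% in
the silica core; `count_interactions()` shows the per-photon interaction
probability falling with beam energy.

## Worked example: decomposing a functionalized RL spectrum

```r
truth <- example_truth_components("functionalized")
spec  <- simulate_rl_spectrum(truth, seed = 42)          # Poisson counting noise
init  <- default_component_set("functionalized", spectrum = spec)
fit   <- fit_rl_spectrum(spec, init)
fit
#> <rl_fit> chi-square 686.905 (dof 691), 61 iterations, converged
head(component_report(fit), 4)
#>   center_eV center_nm   fwhm_eV      area share_pos_pct
#> 1  1.720011       721 0.1648787 2.2018097     26.875788
#> 2  1.549979       800 0.1059238 0.4991886      6.093209
#> 3  1.900321       652 0.2122693 0.7999542      9.764422
#> 4  2.220683       558 0.6598313 3.0126789     36.773441
```

All ten component centers are recovered (χ²/dof ≈ 1); the four fitted
negative areas sit at the Q-band dips, e.g. 2.01 eV ↔ 617 nm via
`ev_to_nm()`.

A thin command-line wrapper over these functions is installed at
`inst/scripts/nanoscint.R` (`simulate`, `fit-spectrum`, `synth`,
`quantify`), driven by YAML run configurations (`run_simulation()` /
`validate_config()` document the schema).

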