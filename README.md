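# minibeam

Dose modelling and tissue-response analysis for **proton pencil minibeam
radiotherapy** — spatially fractionated irradiation in which the dose is
delivered as a square lattice of sub-millimetre Gaussian pencil beams
instead of a homogeneous field, so that healthy tissue between the beams
is spared.

The package is written for radiotherapy physicists and radiobiologists
working on minibeam/GRID-type dose schemes. It covers the computational
chain of a skin-response beam-size study end to end:

* **Lattice dose model.** Gaussian beams of standard deviation σ at
  center-to-center spacing *c*, normalized so the infinite lattice
  averages to a prescribed mean dose D̄. The dose separates into per-axis
  theta-like sums, `D(x,y) = A θ(x) θ(y)` with
  `A = D̄ c² / (2π σ²)`, giving the peak-to-valley dose ratio in closed
  form, `PVDR = [θ(0)/θ(c/2)]²` — a function of σ/c alone. Rendered
  maps, diagonal profile cuts, profile-based PVDR with uncertainty and
  lower bounds under a film noise floor, and Gaussian beam-width fits.
* **Counting dosimetry.** Fluence-to-dose conversion
  `D = N·LET/(ρA)` for counted protons at nearly constant LET, its exact
  inverse for planning, and dead-time corrections from loss fractions or
  film darkening ratios.
* **Beam transport.** Bragg–Kleeman range–energy relation
  `R = αE^p` and Fermi–Eyges integration of the Highland scattering
  formula for beam growth σ(d) with depth in water; lattice-spacing
  planning via a PVDR homogeneity cap at the proximal target edge.
* **Clonogenic survival.** Linear–quadratic survival
  `S = exp(−αD − βD²)` averaged over one lattice unit cell — the
  first-order tissue surrogate that explains why narrow-beam lattices
  spare skin at 60 Gy mean dose.
* **In-vivo response analysis.** Longitudinal ear-thickness and
  skin-score time courses (triplicates → mice → group mean ± SEM),
  per-group swelling statistics (maximum, t₅₀), and the centerpiece
  model object: `fit_threshold()` regresses group maximum thickness on
  σ/c and extrapolates the no-effect threshold σ_min/c where the fit
  intersects the control thickness.
* **Synthetic campaign.** `simulate_mice()` generates a full 7-group ×
  8-mouse × 90-day measurement campaign with the calibrated statistical
  structure of the study (baseline 225 µm, ~610 µm maximum swelling for
  near-homogeneous fields, threshold 0.032), so every analysis stage is
  testable without animal data; `generate_film()` produces film-like
  noisy dose images.

## Worked example

```r
library(minibeam)

# the smallest studied beam: sigma 95 um on a 1.8 mm lattice at 60 Gy
sp <- beam_spec(sigma = 95, ctc = 1800, mean_dose = 60)
sp
#> Minibeam lattice (gaussian): sigma = 95 um, ctc = 1800 um (ratio 0.053)
#>   grid: infinite, mean dose 60 Gy

# mean clonogenic survival per unit cell across the studied ratios
survival_curve(c(0.053, 0.11, 0.17, 0.228, 0.312, 0.491), 60)
#>   ratio mean_survival
#> 1 0.053      8.66e-01
#> 2 0.110      5.33e-01
#> 3 0.170      1.09e-01
#> 4 0.228      4.75e-04
#> 5 0.312      2.12e-29
#> 6 0.491      6.13e-95

# a synthetic measurement campaign, analyzed end to end
d <- simulate_mice(generator_config(), seed = 1)
analyze_response(d, ctc = 1800)$threshold
#> No-effect beam-size threshold (linear extrapolation)
#>   max thickness = 198.1 + 836.6 * ratio   (R = 1.000, 6 groups)
#>   intersection with control t0 = 223.517 um:
#>     ratio_min = 0.0304;  sigma_min = 54.7 um;  FWHM = 128.8 um (ctc = 1800 um)
```

Reading the output: mean survival collapses from 87 % to effectively zero
as σ/c grows from 0.053 (isolated narrow beams, huge PVDR) to 0.491
(near-homogeneous field whose valley dose of ~58 Gy is itself lethal) —
the computational counterpart of the observed skin sparing. The threshold
fit recovers, from one simulated campaign, a no-effect ratio near the
generator's true 0.032, i.e. a beam size of roughly 55–60 µm
(FWHM ≈ 130–140 µm) at 1.8 mm spacing. The transport module places the
1.8 mm lattice at clinically relevant depth:
`energy_from_range(5.0)` → 78.8 MeV and `energy_from_range(8.5)` →
106.3 MeV bracket the proton energies for a 5–8.5 cm deep target.

## Documentation

Every exported function carries full help pages;
`vignettes/minibeam-methods.Rmd` describes the models, their assumptions,
the numerical choices, the synthetic generator's calibration, and known
limitations.
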