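---
title: "Models and methods behind the minibeam package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the minibeam package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibeam)
```

## The problem

Spatially fractionated proton therapy replaces a homogeneous field with a
lattice of sub-millimetre pencil beams ("minibeams"). Tissue between the
beams receives only the overlapping Gaussian tails, and this dose
modulation spares healthy tissue even when the *mean* dose is unchanged.
Two dimensionless numbers summarize a lattice of beams of standard
deviation $\sigma$ at center-to-center spacing $c$: the ratio
$\sigma/c$, and the peak-to-valley dose ratio (PVDR). As the beams widen
with depth through multiple Coulomb scattering, $\sigma/c$ grows along the
beam path until the field is effectively homogeneous at the target — so a
single skin-level experiment scanning $\sigma/c$ at fixed $c$ reads out
the tissue response at every depth of a deep treatment.

This package implements that entire chain: the lattice dose model, the
counting dosimetry that delivers a prescribed mean dose, the growth of
$\sigma$ with depth, the translation of dose patterns into clonogenic
survival, and the analysis of a longitudinal mouse-ear swelling study,
including extrapolation of the beam size below which no reaction is
expected. A calibrated generator stands in for the animal data.

## Lattice dose model

Ideal Gaussian beams of standard deviation $\sigma$ are placed on an
infinite square lattice with spacing $c$; the unit cell is
$[-c/2, c/2]^2$ with the valley at its corners. The dose separates into
per-axis sums,
$$D(x, y) = A\,\theta(x)\,\theta(y), \qquad
  \theta(x) = \sum_i e^{-(x - i c)^2 / 2\sigma^2},$$
with the single-beam amplitude fixed by the mean-dose normalization
$A = \bar D\, c^2 / (2\pi\sigma^2)$ (one beam of integral
$2\pi\sigma^2 A$ per cell of area $c^2$). Two consequences are used
throughout:

* the PVDR is $[\theta(0)/\theta(c/2)]^2$ and depends only on
  $\sigma/c$ — it is `pvdr_analytic()`;
* any cell-averaged functional of the dose (e.g. mean survival) also
  depends only on $\sigma/c$ at fixed mean dose.

The lattice sums are truncated at $K = \lceil 6\sigma/c\rceil + 1$
neighbours, where the neglected tail is below $10^{-8}$; tests compare
$K$ against $2K$. `render_dose_map()` samples pixel centers (midpoint
rule, spectrally accurate for this periodic integrand), refuses pixels
coarser than $c/32$, and exploits the separability so a map costs one
outer product. Diagonal profile cuts — the cut that exposes both the true
peak and the true valley, with peaks $c\sqrt 2$ apart — use bilinear
interpolation at half-pixel steps.

`pvdr_from_profile()` averages interior local maxima and minima and
propagates their standard deviations in quadrature. When the mean valley
falls below a noise floor (default 0.5 % of the mean peak — radiochromic
film cannot resolve valleys under its noise level, and no film noise value
is published, so the floor is a parameter) only a flagged lower bound
`mean(peaks)/floor` is reported. Ideal-lattice PVDRs and film-measured
ones need not agree at intermediate ratios (measured 2.69 at
$\sigma/c = 0.312$ vs. ideal 3.3): beam tails and film response are not
modelled, and the package reports both numbers without forcing agreement.

Beam widths are quoted by fitting
$b + A e^{-(x - \mu)^2/2\sigma^2}$ with Levenberg–Marquardt
(`minpack.lm::nls.lm`). Standard errors use a heteroscedasticity-consistent
(sandwich) estimator because film noise is predominantly multiplicative;
with homoscedastic errors the two estimators agree.

## Counting dosimetry

With LET nearly constant across a thin target, $N$ protons through area
$A$ deposit $D = N \cdot \mathrm{LET} / (\rho A)$. For the study values —
$16 \times 4.58\times 10^8$ protons, 2.7 keV/µm, 7.2 × 7.2 mm² — this
gives 61.1 Gy, consistent with the delivered 60 ± 3 Gy.
`protons_for_dose()` is the exact algebraic inverse (it returns
$4.49\times10^8$ per beam for 60 Gy; the ~2 % gap to the quoted count is
within the stated dose uncertainty and is not reconciled further).
Counting losses from detector dead time are corrected by
$1/(1-\mathrm{loss})$, or measured as the darkening ratio of a low-rate
and a high-rate film under a linear film-response assumption
(`deadtime_factor()`); a 20 % loss gives factor 1.25.

## Beam transport and lattice planning

Ranges use the Bragg–Kleeman power law $R = \alpha E^p$ with water
defaults $\alpha = 0.0022$ cm MeV$^{-p}$, $p = 1.77$ (these reproduce the
79 / 107 MeV energies for 5.0 / 8.5 cm targets to better than 1 %; the
quoted ~4.6 mm range of 20 MeV protons comes out ~4 % shorter, a known
limitation of the power law at low energy). Lateral spread uses
Fermi–Eyges integration of the Highland formula,
$$\sigma_{\mathrm{mcs}}^2(d) = \Big[1 + 0.038\ln\tfrac{d}{X_0}\Big]^2
  \int_0^d \Big(\frac{14.1\ \mathrm{MeV}}{p(z)v(z)}\Big)^2
  \frac{(d - z)^2}{X_0}\, dz,$$
with $pv$ from the residual Bragg–Kleeman energy and $X_0 = 36.08$ cm.
The integral is a composite Simpson rule (512 intervals by default;
self-convergence below $10^{-3}$ is tested at 256 vs. 512) and the
initial beam size adds in quadrature. This formula-based model replaces
the scattering-database values the study quotes, which are not published
as equations; agreement is qualitative (the model gives ~766 µm at 5 cm
for 107 MeV protons starting at 95 µm, within 25 % of the quoted 883 µm),
and depth mappings from this module should be read with that accuracy in
mind.

`plan_ctc()` encodes the planning rule that beams must overlap into a
near-homogeneous field at the proximal edge of the target: it returns the
largest spacing whose PVDR at the proximal $\sigma$ stays below a cap
(default 1.11, the measured near-homogeneous pattern). Because PVDR
depends only on $\sigma/c$, the planned spacing is exactly linear in
$\sigma$.

## Survival averaging

Cell killing follows the linear–quadratic model
$S = e^{-\alpha D - \beta D^2}$ with keratinocyte coefficients
$\alpha = 0.2$ /Gy, $\beta = 0.06$ /Gy² as defaults. The tissue-level
quantity is the mean of $S$ over one unit cell of the lattice normalized
to the prescribed mean dose (`mean_unitcell_survival()`), computed on a
midpoint grid (512² start, doubled until the mean changes by less than
$10^{-3}$ relative). Survival is accumulated from log-survival, so peak
doses of thousands of gray underflow cleanly to zero rather than
producing NaNs. An optional high-dose extension continues $\log S$
linearly beyond a transition dose (default 10 Gy when enabled, off by
default): the LQ model is only validated up to ~10 Gy, but since
in-beam survival is effectively zero either way, the extension barely
moves the cell averages.

Two independent cross-checks guard the implementation: a brute-force 2D
double sum over beams, and — for $\sigma/c \le 0.1$, where beams are
effectively isolated — a 1D radial-deficit integral
$S = 1 - (2\pi\sigma^2/c^2)\int_0^A [1 - S(u)]\,du/u$. Both agree with
the midpoint average within 1 %. At 60 Gy these give mean survival
≈ 86.6 % at $\sigma/c = 0.053$ and ≈ 60 % at $0.1$; a published statement
that survival exceeds 90 % for all ratios below 0.1 is not reproducible
from the stated procedure under any integration variant we constructed,
and the package reports its own computed values.

## In-vivo response analysis

Records are one row per mouse × day with triplicate ear-thickness
measurements and the two visual scores (erythema 0/0.5/1.5/3,
desquamation 0/1/2/3, total score their sum). The analysis averages
replicates within mouse, then mice within group (the animal is the
statistical unit; SEM across mice); missing days stay missing — the
schedule is irregular by design, so no imputation is defensible.

Per group, `swelling_stats()` reads the maximum thickness off the
group-mean curve (the construction consistent with plotting mean ± SEM
over time; a per-mouse-maximum variant is available through
`mouse_max_thickness()`), and $t_{50}$ as the first linear-interpolated
crossing of half-maximal swelling, which by construction precedes the day
of maximum. Baseline swelling is referenced to the contemporaneous
control-group mean rather than each group's day-0 value: the control mean
is the quantity the threshold extrapolation intersects, and it is less
noisy than a single day's measurement.

`fit_threshold()` regresses group maximum thickness on $\sigma/c$ by OLS
over the irradiated groups only — the sham group carries no radiation
effect and would drag the line towards a spurious shallow slope — and
intersects the fit with the control thickness to obtain
$\sigma_{\min}/c$, then $\sigma_{\min}$ and its FWHM
($2\sqrt{2\ln 2}\,\sigma_{\min}$) at a given spacing. Group contrasts use
a two-sided Welch test on per-mouse maxima; this is a declared convention
(the original analysis does not name its test), and a permutation test
agrees with it to within 0.02 in $p$ on moderate separations.

## The synthetic campaign

`simulate_mice()` emulates the design of the study: 7 groups
($\sigma/c = 0$ sham, 0.053, 0.11, 0.17, 0.228, 0.312, 0.491) of 8 mice,
triplicate thickness readings on a 1–4-day schedule over 90 days (denser
early, when the reaction evolves fastest), baselines
$\mathcal N(225, 12^2)$ µm across mice, and replicate noise of 8 µm.
Swelling follows a gamma-shaped pulse
$a\,(t/t_p)^k e^{k(1 - t/t_p)}$ ($k = 4$; zero at $t=0$, maximal $a$ at
$t_p$) with peak times increasing linearly from 18 to 32 days across the
irradiated ratios, plus a logistic residual plateau of 35 µm for the
wide-beam groups ($\sigma/c > 0.23$) rising around day 55 with a 5-day
time constant — i.e. during the resolution phase, so the acute maximum
stays at $a$ and the late steady state carries the persisting thickening.
The amplitude is linear in the ratio above a threshold:
$a = \max\{0, 840.6\,(\sigma/c - 0.032)\}$ µm, the slope being derived
from the calibration endpoints (610 µm maximum at the widest beams,
225 µm control, no effect below 0.032). Scores are produced by
thresholding the normalized swelling severity, so their onset shifts with
each group's peak time. The curve shape itself is invented — only the
calibration points, the threshold, the plateau magnitude and the
direction of the $t_{50}$ trend are constrained by data — and the
per-group peak times are placeholders in the published range, all
config-overridable.

What the generator does *not* emulate: individual-mouse biology (immune
response, wound healing), serial correlation of measurement errors,
film spatial autocorrelation, or any dependence of the response on the
absolute beam size at fixed $\sigma/c$. Passing recovery tests therefore
demonstrates that the *analysis* is unbiased under the stated noise
model, not that the biological model is correct.

Under the default configuration, the end-to-end chain (generate →
time courses → group maxima → threshold fit) recovers the generator's
threshold 0.032 with bias below 0.005 and RMSE below 0.015 across 100
seeds; this is tested. Randomness is a single seeded RNG stream, so a
`(config, seed)` pair reproduces a campaign byte for byte.

## Numerical choices and problem sizes

* Lattice truncation $K = \lceil 6\sigma/c \rceil + 1$; render default
  256 px per $c$; profile interpolation bilinear at half-pixel steps.
* Unit-cell survival: midpoint 512², doubled until $<10^{-3}$ relative
  change, error at 8192² if unconverged (never observed for the studied
  ratios).
* Transport quadrature: Simpson, 512 intervals, checked against 256;
  depth root-finds by `uniroot` to $10^{-6} R$; depths capped at
  $0.999\,R$ where the Highland integrand is still integrable.
* Test-suite problem sizes: dose maps up to 256 px per cell, 100-seed
  recovery loops for the beam-width fit and the threshold chain, $10^4$
  permutations for the test cross-check — the full suite runs in well
  under a minute.
* Degenerate inputs: flat profiles return PVDR 1 with zero uncertainty;
  all-flat swelling curves have undefined $t_{50}$ (returned as `NA`);
  zero-variance group comparisons short-circuit to $p = 1$ on equal
  means; zero mean dose yields survival 1 everywhere.

## Known limitations

* The transport model is formula-based (Highland/Fermi–Eyges over
  Bragg–Kleeman residual energy); it tracks database-derived beam sizes
  only to ~25 %, has no nuclear interactions or energy straggling, and
  makes no statement about depth–dose (Bragg peak) shapes.
* Ideal Gaussian lattices ignore beam tails and film response, so
  measured PVDRs at intermediate ratios fall below the ideal values.
* The LQ survival averages are first-order tissue surrogates; no repair,
  migration or cell-death-pathway kinetics are modelled, and the
  known overestimation of killing at very high dose is mitigated only by
  the optional linear extension.
* The threshold extrapolation is linear by construction; it is exact on
  collinear input but its validity below the smallest measured ratio is
  an assumption inherited from the study design.
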