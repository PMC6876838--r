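# 1 keV in joule
KEV_J <- 1.602e-16

#' Particle-counting fluence dosimetry
#'
#' With the linear energy transfer (LET) nearly constant across a thin
#' target, the absorbed dose of `N` counted protons spread over area `A` is
#' `D = N * LET / (rho * A)` -- energy deposited per unit mass in a uniform
#' slab. `irradiation_setup()` bundles the counting parameters;
#' `mean_dose_from_protons()` applies the conversion and
#' `protons_for_dose()` inverts it exactly.
#'
#' @param protons_per_beam Counted protons per minibeam.
#' @param n_beams Number of beams in the pattern.
#' @param field_area_mm2 Irradiated field area (mm^2).
#' @param let_kev_um LET in keV/um.
#' @param density Medium density (g/cm^3); water/soft tissue by default.
#' @return `irradiation_setup()`: an `irradiation_setup` object;
#'   `mean_dose_from_protons()`: mean dose in Gy; `protons_for_dose()`:
#'   protons per beam.
#' @examples
#' su <- irradiation_setup(4.58e8, 16, 7.2^2, 2.7)
#' mean_dose_from_protons(su)   # ~61 Gy
#' @export
irradiation_setup <- function(protons_per_beam, n_beams, field_area_mm2,
                              let_kev_um, density = 1.0) {
  if (field_area_mm2 <= 0) stop("field area must be positive", call. = FALSE)
  if (n_beams <= 0 || let_kev_um <= 0 || density <= 0)
    stop("'n_beams', 'let_kev_um' and 'density' must be positive", call. = FALSE)
  if (protons_per_beam < 0)
    stop("'protons_per_beam' must be non-negative", call. = FALSE)
  structure(list(protons_per_beam = protons_per_beam, n_beams = n_beams,
                 field_area_mm2 = field_area_mm2, let_kev_um = let_kev_um,
                 density = density),
            class = "irradiation_setup")
}

#' @rdname irradiation_setup
#' @param setup An `irradiation_setup`.
#' @export
mean_dose_from_protons <- function(setup) {
  stopifnot(inherits(setup, "irradiation_setup"))
  let_j_cm <- setup$let_kev_um * 1e4 * KEV_J       # keV/um -> J/cm
  area_cm2 <- setup$field_area_mm2 / 100
  mass_per_cm <- setup$density * area_cm2 * 1e-3   # kg per cm of path
  setup$protons_per_beam * setup$n_beams * let_j_cm / mass_per_cm
}

#' @rdname irradiation_setup
#' @param target_dose Desired mean dose (Gy).
#' @export
protons_for_dose <- function(target_dose, n_beams, field_area_mm2,
                             let_kev_um, density = 1.0) {
  if (target_dose < 0) stop("'target_dose' must be non-negative", call. = FALSE)
  unit <- mean_dose_from_protons(
    irradiation_setup(1, n_beams, field_area_mm2, let_kev_um, density))
  target_dose / unit
}

#' Dead-time correction factor for counting dosimetry
#'
#' Counting chains miss particles during their dead time; the true count is
#' the registered count times a factor `>= 1`. Given a fractional loss
#' `loss`, the factor is `1 / (1 - loss)`. Alternatively the factor can be
#' measured as the darkening ratio of two films exposed to the same nominal
#' count at low and high rate (assuming a linear film response): the
#' low-rate film records the full fluence, so `factor = low / high`.
#'
#' @param loss_fraction Fraction of particles lost, in `[0, 1)`.
#' @param darkening Length-2 numeric `c(low_rate, high_rate)` film signals.
#'   Exactly one of the two arguments must be given.
#' @return Multiplicative correction factor (`>= 1`).
#' @examples
#' deadtime_factor(loss_fraction = 0.20)      # 1.25
#' deadtime_factor(darkening = c(1.25, 1.0))  # 1.25
#' @export
deadtime_factor <- function(loss_fraction = NULL, darkening = NULL) {
  if (is.null(loss_fraction) == is.null(darkening))
    stop("give exactly one of 'loss_fraction' or 'darkening'", call. = FALSE)
  if (!is.null(loss_fraction)) {
    if (loss_fraction < 0 || loss_fraction >= 1)
      stop("'loss_fraction' must lie in [0, 1)", call. = FALSE)
    return(1 / (1 - loss_fraction))
  }
  if (length(darkening) != 2 || any(darkening <= 0))
    stop("'darkening' must be two positive signals c(low_rate, high_rate)",
         call. = FALSE)
  if (darkening[2] > darkening[1])
    stop("inconsistent input: high-rate signal exceeds low-rate signal",
         call. = FALSE)
  darkening[1] / darkening[2]
}
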