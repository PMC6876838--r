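#' Configuration of the synthetic in-vivo dataset generator
#'
#' Defines the study design the generator emulates: 7 groups (one sham) of
#' 8 mice each, triplicate ear-thickness measurements on an irregular 1-4
#' day schedule over 90 days, and visual skin scores on the standard
#' erythema/desquamation scales. The swelling model is a gamma-shaped pulse
#' peaking at `t_peak` plus a logistic late plateau; its amplitude is
#' linear in `sigma/ctc` above a threshold:
#' `amplitude = max(0, slope * (ratio - threshold_ratio))`.
#' The calibration (baseline 225 um, ~610 um maximum for the widest beams,
#' threshold ratio 0.032, slope (610 - 225)/(0.491 - 0.032) = 840.6 um per
#' unit ratio, 30-40 um residual plateau for the wider-beam groups, peak
#' times growing from ~18 to ~32 days with ratio) mirrors the measured
#' study endpoints.
#'
#' @param group_ratios `sigma/ctc` per group, 0 for the sham group.
#' @param n_mice_per_group Mice per group.
#' @param schedule Measurement days in `[0, 90]` with 1-4 day spacing.
#' @param baseline_mean,baseline_sd Inter-mouse baseline ear thickness (um).
#' @param slope Swelling amplitude per unit ratio (um).
#' @param threshold_ratio Ratio below which no swelling is induced.
#' @param pulse_k Shape parameter of the gamma pulse.
#' @param t_peak_range Peak-time range (days) mapped linearly onto the
#'   irradiated ratio range.
#' @param plateau Residual late thickening (um) for groups with
#'   `ratio > plateau_above`.
#' @param plateau_above Ratio above which the plateau applies.
#' @param plateau_tau Time constant (days) of the logistic plateau rise.
#' @param plateau_onset Day around which the residual plateau develops
#'   (during the resolution phase of the acute reaction).
#' @param noise_sd Measurement noise per thickness replicate (um).
#' @param score_thresholds Normalized-severity cut points for the erythema
#'   and desquamation scales.
#' @return A `generator_config` object.
#' @export
generator_config <- function(
    group_ratios = c(0, 0.053, 0.11, 0.17, 0.228, 0.312, 0.491),
    n_mice_per_group = 8,
    schedule = c(0, seq(2, 28, by = 2), seq(31, 46, by = 3), seq(50, 90, by = 4)),
    baseline_mean = 225, baseline_sd = 12,
    slope = (610 - 225) / (0.491 - 0.032),
    threshold_ratio = 0.032,
    pulse_k = 4, t_peak_range = c(18, 32),
    plateau = 35, plateau_above = 0.23, plateau_tau = 5, plateau_onset = 55,
    noise_sd = 8,
    score_thresholds = list(erythema = c(0.05, 0.3, 0.7),
                            desquamation = c(0.15, 0.45, 0.8))) {
  if (any(schedule < 0 | schedule > 90) || any(diff(sort(schedule)) < 1) ||
      any(diff(sort(schedule)) > 4))
    stop("config error: schedule must span [0, 90] days at 1-4 day spacing",
         call. = FALSE)
  if (baseline_sd < 0 || noise_sd < 0)
    stop("config error: noise SDs must be non-negative", call. = FALSE)
  structure(list(group_ratios = group_ratios,
                 n_mice_per_group = n_mice_per_group,
                 schedule = sort(schedule),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slope = slope, threshold_ratio = threshold_ratio,
                 pulse_k = pulse_k, t_peak_range = t_peak_range,
                 plateau = plateau, plateau_above = plateau_above,
                 plateau_tau = plateau_tau, plateau_onset = plateau_onset,
                 noise_sd = noise_sd,
                 score_thresholds = score_thresholds),
            class = "generator_config")
}

#' Parametric ear-swelling time course
#'
#' Swelling above baseline as a gamma-shaped pulse
#' `amplitude * (t/t_peak)^k * exp(k (1 - t/t_peak))` -- zero at `t = 0`,
#' maximal (equal to `amplitude`) at `t = t_peak` -- plus a logistic
#' residual plateau that rises around `onset` (by default well after the
#' acute pulse, during the resolution phase) and is shifted/rescaled to
#' vanish at `t = 0`. Keeping the plateau onset clear of the pulse maximum
#' preserves the calibration `max swelling = amplitude`.
#'
#' @param t Days post-irradiation (`>= 0`).
#' @param amplitude Pulse height (um).
#' @param t_peak Day of the pulse maximum.
#' @param k Pulse shape (`> 0`); larger is narrower.
#' @param plateau Late residual thickening (um).
#' @param tau Plateau rise time constant (days).
#' @param onset Center (days) of the logistic plateau rise.
#' @return Swelling (um above baseline), vectorized over `t`.
#' @export
swelling_curve <- function(t, amplitude, t_peak, k = 4, plateau = 0, tau = 5,
                           onset = t_peak + 25) {
  if (any(t < 0) || amplitude < 0 || plateau < 0 || k <= 0)
    stop("invalid swelling-curve parameters", call. = FALSE)
  pulse <- amplitude * (t / t_peak)^k * exp(k * (1 - t / t_peak))
  pulse[t == 0] <- 0
  p0 <- stats::plogis(-onset / tau)
  plat <- plateau * (stats::plogis((t - onset) / tau) - p0) / (1 - p0)
  pulse + plat
}

# map normalized severity (swelling / full-scale amplitude) to a score scale
severity_to_score <- function(severity, cuts, scale_values) {
  idx <- findInterval(severity, cuts) + 1L
  scale_values[idx]
}

#' Generate a synthetic in-vivo measurement dataset
#'
#' Draws a full measurement campaign from the generator model: per-mouse
#' baselines, group swelling curves with measurement noise on every
#' thickness replicate, and skin scores obtained by thresholding the
#' normalized swelling severity (so score onset shifts with each group's
#' peak time). The output is reproducible: identical `(config, seed)`
#' yield identical data.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the single RNG stream.
#' @return Data frame of mouse records ([read_mouse_records()] layout) with
#'   the per-group ground truth (amplitude, peak time, threshold, slope) in
#'   attribute `"truth"`.
#' @examples
#' d <- simulate_mice(generator_config(), seed = 1)
#' head(d)
#' @export
simulate_mice <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  irr <- config$group_ratios[config$group_ratios > 0]
  r_lo <- min(irr); r_hi <- max(irr)
  tp <- config$t_peak_range
  full_amp <- config$slope * (r_hi - config$threshold_ratio)
  rows <- vector("list", length(config$group_ratios) * config$n_mice_per_group)
  truth <- list(threshold_ratio = config$threshold_ratio,
                slope = config$slope, groups = list())
  k <- 0L
  for (r in config$group_ratios) {
    amplitude <- max(0, config$slope * (r - config$threshold_ratio))
    plateau <- if (r > config$plateau_above) config$plateau else 0
    t_peak <- if (r == 0) mean(tp) else
      tp[1] + (tp[2] - tp[1]) * (r - r_lo) / (r_hi - r_lo)
    truth$groups[[as.character(r)]] <-
      list(ratio = r, amplitude = amplitude, t_peak = t_peak,
           plateau = plateau)
    sw <- if (r == 0) rep(0, length(config$schedule)) else
      swelling_curve(config$schedule, amplitude, t_peak, config$pulse_k,
                     plateau, config$plateau_tau, config$plateau_onset)
    severity <- sw / full_amp
    ery <- severity_to_score(severity, config$score_thresholds$erythema,
                             ERYTHEMA_SCALE)
    des <- severity_to_score(severity, config$score_thresholds$desquamation,
                             DESQUAMATION_SCALE)
    for (m in seq_len(config$n_mice_per_group)) {
      base <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
      mu <- base + sw
      reps <- matrix(stats::rnorm(3 * length(mu), 0, config$noise_sd),
                     ncol = 3) + mu
      reps <- pmax(reps, 1)  # a gauge cannot read non-positive thickness
      k <- k + 1L
      rows[[k]] <- data.frame(
        mouse_id = sprintf("g%s_m%02d", format(r), m),
        group_ratio = r, day = config$schedule,
        thickness_um_1 = reps[, 1], thickness_um_2 = reps[, 2],
        thickness_um_3 = reps[, 3],
        erythema = ery, desquamation = des)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate a film-like noisy dose image
#'
#' Renders the ideal lattice dose map and degrades it the way a scanned
#' radiochromic film is degraded to first order: multiplicative Gaussian
#' noise (response/scanner gain) and additive Gaussian noise (read-out
#' floor), clipped at zero dose. With both noise terms zero the output
#' equals [render_dose_map()] exactly.
#'
#' @param spec A [beam_spec()].
#' @param extent,pixel_size As in [render_dose_map()].
#' @param noise_mult SD of the multiplicative noise (fraction, e.g. 0.02).
#' @param noise_add SD of the additive noise (Gy).
#' @param seed Optional integer seed.
#' @return A `dose_field`.
#' @export
generate_film <- function(spec, extent, pixel_size, noise_mult = 0.02,
                          noise_add = 0, seed = NULL) {
  if (noise_mult < 0 || noise_add < 0)
    stop("config error: noise parameters must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- render_dose_map(spec, extent, pixel_size)
  v <- f$values
  if (noise_mult > 0)
    v <- v * matrix(stats::rnorm(length(v), 1, noise_mult), nrow = nrow(v))
  if (noise_add > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, noise_add), nrow = nrow(v))
  f$values <- pmax(v, 0)
  f
}

#' Write a synthetic dataset with its ground truth
#'
#' @param records Output of [simulate_mice()].
#' @param path CSV path; the truth block goes to `<path>.json`.
#' @export
write_synthetic_dataset <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  jsonlite::write_json(attr(records, "truth"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
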