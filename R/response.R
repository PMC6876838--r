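ERYTHEMA_SCALE <- c(0, 0.5, 1.5, 3)
DESQUAMATION_SCALE <- c(0, 1, 2, 3)

#' Total acute skin-response score
#'
#' The acute skin reaction is scored on two visual scales -- erythema
#' (reddening: none 0, mild 0.5, definite 1.5, severe 3) and desquamation
#' (peeling: none 0, dry 1, crust formation 2, moist 3) -- whose sum is the
#' total skin score in `[0, 6]`.
#'
#' @param erythema Erythema score(s), on `{0, 0.5, 1.5, 3}`.
#' @param desquamation Desquamation score(s), on `{0, 1, 2, 3}`.
#' @return Total score(s).
#' @examples
#' total_score(1.5, 2)   # 3.5
#' @export
total_score <- function(erythema, desquamation) {
  if (!all(erythema %in% ERYTHEMA_SCALE))
    stop("erythema scores must lie on {0, 0.5, 1.5, 3}", call. = FALSE)
  if (!all(desquamation %in% DESQUAMATION_SCALE))
    stop("desquamation scores must lie on {0, 1, 2, 3}", call. = FALSE)
  erythema + desquamation
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Read per-mouse measurement records from CSV
#'
#' Expected columns: `mouse_id`, `group_ratio` (sigma/ctc, 0 for sham),
#' `day` (days post-irradiation, 0-90), `thickness_um_1..3` (triplicate ear
#' thickness, um), `erythema`, `desquamation`.
#'
#' @param path CSV file path.
#' @return Validated data frame of mouse records.
#' @export
read_mouse_records <- function(path) {
  validate_mouse_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_mouse_records
#' @param records Data frame in the layout above.
#' @export
validate_mouse_records <- function(records) {
  need <- c("mouse_id", "group_ratio", "day",
            paste0("thickness_um_", 1:3), "erythema", "desquamation")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$day < 0 | records$day > 90))
    stop("'day' must lie in [0, 90]", call. = FALSE)
  th <- as.matrix(records[paste0("thickness_um_", 1:3)])
  if (any(th <= 0)) stop("thickness values must be positive", call. = FALSE)
  total_score(records$erythema, records$desquamation)  # scale validation
  records
}

#' Per-group time courses of ear thickness and skin score
#'
#' For each mouse and day the triplicate thickness measurements are
#' averaged; group means and standard errors are then taken across mice
#' (the animal is the statistical unit). Missing days are simply absent --
#' no imputation. Groups with a single mouse get `NA` standard errors and a
#' warning.
#'
#' @param records Mouse records ([read_mouse_records()] layout).
#' @return A `group_summary` data frame: one row per `group_ratio` x `day`
#'   with `mean_thickness`, `sem_thickness`, `mean_score`, `sem_score`,
#'   `n_mice`.
#' @export
group_timecourse <- function(records) {
  records <- validate_mouse_records(records)
  th <- rowMeans(records[paste0("thickness_um_", 1:3)])
  sc <- total_score(records$erythema, records$desquamation)
  per_mouse <- data.frame(group_ratio = records$group_ratio,
                          day = records$day, mouse_id = records$mouse_id,
                          thickness = th, score = sc)
  agg <- function(f) stats::aggregate(
    cbind(thickness, score) ~ group_ratio + day, per_mouse, f)
  m <- agg(mean); s <- agg(sem); n <- agg(length)
  out <- data.frame(group_ratio = m$group_ratio, day = m$day,
                    mean_thickness = m$thickness, sem_thickness = s$thickness,
                    mean_score = m$score, sem_score = s$score,
                    n_mice = n$thickness)
  if (any(out$n_mice < 2)) {
    warning("groups with fewer than 2 mice: SEM undefined", call. = FALSE)
    out$sem_thickness[out$n_mice < 2] <- NA_real_
    out$sem_score[out$n_mice < 2] <- NA_real_
  }
  out <- out[order(out$group_ratio, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Swelling statistics of one group's time course
#'
#' The maximum ear thickness is read off the group-mean curve (the maximum
#' falls on different days in different groups). `t50` is the first
#' linearly-interpolated time at which the swelling (mean thickness minus
#' baseline) crosses half its maximum; it always precedes the day of
#' maximum. A curve that never rises above baseline has no defined `t50`.
#'
#' @param summary A `group_summary` restricted to (or filtered for) one
#'   group, or any data frame with `day` and `mean_thickness`.
#' @param baseline Baseline ear thickness (um), typically the
#'   contemporaneous control-group mean.
#' @param group_ratio If `summary` holds several groups, which one to use.
#' @return List with `max_thickness`, `day_of_max`, `t50` (NA when
#'   undefined), `baseline`.
#' @export
swelling_stats <- function(summary, baseline, group_ratio = NULL) {
  if (!is.null(group_ratio))
    summary <- summary[summary$group_ratio == group_ratio, ]
  if (!nrow(summary)) stop("empty time course", call. = FALSE)
  summary <- summary[order(summary$day), ]
  sw <- summary$mean_thickness - baseline
  imax <- which.max(sw)
  max_th <- summary$mean_thickness[imax]
  half <- sw[imax] / 2
  t50 <- NA_real_
  if (sw[imax] > 0) {
    up <- which(sw[seq_len(imax)] >= half)[1]  # first crossing before the max
    if (up == 1L) {
      t50 <- summary$day[1]
    } else {
      d0 <- summary$day[up - 1]; d1 <- summary$day[up]
      s0 <- sw[up - 1]; s1 <- sw[up]
      t50 <- d0 + (half - s0) / (s1 - s0) * (d1 - d0)
    }
  }
  list(max_thickness = max_th, day_of_max = summary$day[imax],
       t50 = t50, baseline = baseline)
}

#' Per-mouse maxima of the replicate-averaged thickness curve
#'
#' The per-animal alternative to reading the maximum off the group-mean
#' curve: each mouse's replicate-averaged thickness is maximized over its
#' own measurement days. Used as the default endpoint of
#' [compare_groups()].
#'
#' @param records Mouse records ([read_mouse_records()] layout).
#' @return Data frame with `group_ratio`, `mouse_id` and the maximum `x`.
#' @export
mouse_max_thickness <- function(records) {
  records <- validate_mouse_records(records)
  th <- rowMeans(records[paste0("thickness_um_", 1:3)])
  stats::aggregate(th,
                   list(group_ratio = records$group_ratio,
                        mouse_id = records$mouse_id),
                   max)
}

#' Extrapolate the no-effect beam-size threshold
#'
#' Fits maximum ear thickness against the beam-size-to-spacing ratio
#' `sigma/ctc` by ordinary least squares over the irradiated groups (the
#' sham group is excluded: it carries no radiation effect and would bias
#' the slope). The fitted line is intersected with the control ear
#' thickness `control_t0` to extrapolate `ratio_min = sigma_min/ctc`, the
#' ratio below which no swelling is expected; at a given lattice spacing
#' this corresponds to `sigma_min = ratio_min * ctc` and a full width at
#' half maximum of `2 sqrt(2 ln 2) * sigma_min`.
#'
#' @param data Data frame with one row per irradiated group, containing the
#'   ratio and maximum-thickness columns named in `formula`.
#' @param formula Model formula, default `max_thickness ~ ratio`.
#' @param control_t0 Control-group ear thickness (um).
#' @param ctc Lattice spacing (um) used to convert `ratio_min` to a beam
#'   size.
#' @return An object of class `threshold_fit` with components `slope`,
#'   `intercept`, `r` (Pearson correlation), `ratio_min`, `sigma_min`,
#'   `fwhm_min`, `control_t0`, `ctc`, `data` and the underlying `lm`.
#' @examples
#' d <- data.frame(ratio = c(0.053, 0.11, 0.17, 0.228, 0.312, 0.491))
#' d$max_thickness <- 225 + 840.6 * (d$ratio - 0.032)
#' fit_threshold(d, control_t0 = 225, ctc = 1800)
#' @export
fit_threshold <- function(data, formula = max_thickness ~ ratio,
                          control_t0, ctc = 1800) {
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) < 3)
    stop("need at least 3 irradiated groups for the fit", call. = FALSE)
  fit <- stats::lm(formula, data = data)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  if (slope <= 0)
    stop("no-threshold error: fitted slope is not positive", call. = FALSE)
  ratio_min <- (control_t0 - intercept) / slope
  structure(list(
    slope = slope, intercept = intercept,
    r = stats::cor(mf[[2]], mf[[1]]),
    ratio_min = ratio_min,
    sigma_min = ratio_min * ctc,
    fwhm_min = 2 * sqrt(2 * log(2)) * ratio_min * ctc,
    control_t0 = control_t0, ctc = ctc,
    formula = formula, data = mf, lm = fit),
    class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("No-effect beam-size threshold (linear extrapolation)\n")
  cat(sprintf("  max thickness = %.1f + %.1f * ratio   (R = %.3f, %d groups)\n",
              x$intercept, x$slope, x$r, nrow(x$data)))
  cat(sprintf("  intersection with control t0 = %g um:\n", x$control_t0))
  cat(sprintf("    ratio_min = %.4f;  sigma_min = %.1f um;  FWHM = %.1f um (ctc = %g um)\n",
              x$ratio_min, x$sigma_min, x$fwhm_min, x$ctc))
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying regression:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    ratio_min = object$ratio_min, sigma_min = object$sigma_min,
    fwhm_min = object$fwhm_min)
}

#' @export
predict.threshold_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.threshold_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.threshold_fit <- function(x, ...) {
  ratio <- x$data[[2]]; th <- x$data[[1]]
  graphics::plot(ratio, th, xlim = c(0, max(ratio) * 1.05),
                 ylim = range(c(th, x$control_t0)) + c(-20, 20),
                 xlab = "sigma / ctc", ylab = "max ear thickness [um]", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  graphics::abline(h = x$control_t0, lty = 2)
  graphics::abline(v = x$ratio_min, lty = 2)
  invisible(x)
}

#' Compare a per-mouse endpoint between two groups
#'
#' Two-sided Welch t-test on a per-mouse summary metric (default: each
#' mouse's maximum replicate-averaged ear thickness). The choice of test is
#' a convention of this package. Degenerate inputs with zero variance in
#' both groups short-circuit to `p = 1` when the means coincide.
#'
#' @param records_a,records_b Mouse records of the two groups.
#' @param metric Function mapping a group's records to one value per mouse;
#'   default per-mouse maximum thickness.
#' @return List with `p_value`, `statistic`, `estimate` (group means).
#' @export
compare_groups <- function(records_a, records_b,
                           metric = function(r) mouse_max_thickness(r)$x) {
  a <- metric(records_a); b <- metric(records_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 mice per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(p_value = if (mean(a) == mean(b)) 1 else 0,
                statistic = NA_real_, estimate = c(mean(a), mean(b))))
  }
  tt <- stats::t.test(a, b)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       estimate = unname(tt$estimate))
}

#' Full in-vivo response analysis
#'
#' Runs the complete analysis on a set of mouse records: group time
#' courses, per-group swelling statistics (baseline = contemporaneous
#' control-group mean thickness), and the no-effect threshold
#' extrapolation over the irradiated groups.
#'
#' @param records Mouse records ([read_mouse_records()] layout).
#' @param ctc Lattice spacing (um).
#' @param control_ratio `group_ratio` value identifying the sham group.
#' @param baseline Baseline thickness override (um); defaults to the
#'   control-group mean over all days.
#' @return List with `summary` (group time courses), `swelling` (per-group
#'   stats), `threshold` (a [fit_threshold()] object), `baseline`.
#' @export
analyze_response <- function(records, ctc = 1800, control_ratio = 0,
                             baseline = NULL) {
  gs <- group_timecourse(records)
  ratios <- sort(unique(gs$group_ratio))
  if (is.null(baseline)) {
    if (!(control_ratio %in% ratios))
      stop("no control group found and no 'baseline' given", call. = FALSE)
    baseline <- mean(gs$mean_thickness[gs$group_ratio == control_ratio])
  }
  irr <- setdiff(ratios, control_ratio)
  sw <- lapply(irr, function(r) swelling_stats(gs, baseline, group_ratio = r))
  names(sw) <- as.character(irr)
  pts <- data.frame(ratio = irr,
                    max_thickness = vapply(sw, `[[`, 0, "max_thickness"))
  list(summary = gs, swelling = sw,
       threshold = fit_threshold(pts, control_t0 = baseline, ctc = ctc),
       baseline = baseline)
}
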