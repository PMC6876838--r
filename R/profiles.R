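# bilinear interpolation of a dose_field at arbitrary points (um)
interp_field <- function(field, x, y) {
  ax <- field_axes(field)
  px <- field$pixel_size
  cx <- (x - ax$x[1]) / px + 1
  cy <- (y - ax$y[1]) / px + 1
  nx <- ncol(field$values); ny <- nrow(field$values)
  if (any(cx < 1 - 1e-9) || any(cx > nx + 1e-9) ||
      any(cy < 1 - 1e-9) || any(cy > ny + 1e-9))
    stop("geometry error: requested points fall outside the field extent",
         call. = FALSE)
  cx <- pmin(pmax(cx, 1), nx); cy <- pmin(pmax(cy, 1), ny)
  i0 <- pmin(floor(cx), nx - 1); j0 <- pmin(floor(cy), ny - 1)
  fx <- cx - i0; fy <- cy - j0
  v <- field$values
  v[cbind(j0, i0)] * (1 - fx) * (1 - fy) +
    v[cbind(j0, i0 + 1)] * fx * (1 - fy) +
    v[cbind(j0 + 1, i0)] * (1 - fx) * fy +
    v[cbind(j0 + 1, i0 + 1)] * fx * fy
}

#' Profile cut through a dose field
#'
#' A 1D dose profile sampled along a line. Diagonal cuts run along the
#' lattice diagonal through the beam centers, so successive dose peaks are
#' spaced `ctc * sqrt(2)` apart and the cut passes through the true valley
#' at the unit-cell corner.
#'
#' @param positions Sample positions (um) along the cut, strictly increasing.
#' @param doses Dose values (Gy).
#' @param cut_kind `"axis"` or `"diagonal"`.
#' @return A `profile_cut` object.
#' @export
profile_cut <- function(positions, doses, cut_kind = c("diagonal", "axis")) {
  cut_kind <- match.arg(cut_kind)
  stopifnot(length(positions) == length(doses))
  if (any(diff(positions) <= 0))
    stop("'positions' must be strictly increasing", call. = FALSE)
  structure(list(positions = as.numeric(positions), doses = as.numeric(doses),
                 cut_kind = cut_kind),
            class = "profile_cut")
}

#' @export
print.profile_cut <- function(x, ...) {
  cat(sprintf("%s profile cut: %d samples over %.0f um, dose %.3g-%.3g Gy\n",
              x$cut_kind, length(x$positions), diff(range(x$positions)),
              min(x$doses), max(x$doses)))
  invisible(x)
}

#' @export
plot.profile_cut <- function(x, ...) {
  graphics::plot(x$positions, x$doses, type = "l",
                 xlab = "position along cut [um]", ylab = "dose [Gy]", ...)
  invisible(x)
}

#' Extract the diagonal dose profile of a rendered lattice
#'
#' Samples the field by bilinear interpolation along the 45-degree lattice
#' diagonal through the origin (a beam center for the standard frame), which
#' exposes both the absolute maxima (beam centers) and the absolute minima
#' (cell-corner valleys) of the pattern. Positions are measured as distance
#' along the diagonal, so peaks appear at multiples of `ctc * sqrt(2)`.
#'
#' @param field A `dose_field`.
#' @param step Sampling step along the diagonal (um); defaults to half a
#'   pixel for sub-pixel peak location.
#' @return A [profile_cut()] with `cut_kind = "diagonal"`.
#' @export
extract_diagonal_profile <- function(field, step = field$pixel_size / 2) {
  stopifnot(inherits(field, "dose_field"))
  ax <- field_axes(field)
  lo <- max(ax$x[1], ax$y[1])
  hi <- min(ax$x[length(ax$x)], ax$y[length(ax$y)])
  if (hi <= lo)
    stop("geometry error: diagonal does not intersect the field", call. = FALSE)
  if (!is.null(field$spec) && (hi - lo) < 2 * field$spec$ctc)
    stop("geometry error: field must cover the diagonal through >= 2 beam centers",
         call. = FALSE)
  u <- seq(lo, hi, by = step / sqrt(2))  # coordinate along each axis
  profile_cut(u * sqrt(2), interp_field(field, u, u), cut_kind = "diagonal")
}

# local extrema of a profile; window = half-width in samples a point must
# dominate to count. Returns interior extrema only (never the endpoints).
local_extrema <- function(doses, window) {
  n <- length(doses)
  idx <- seq_len(n)
  is_ext <- function(cmp) vapply(idx, function(i) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    i > 1L && i < n && all(cmp(doses[i], doses[seq(lo, hi)][-(i - lo + 1L)]))
  }, TRUE)
  list(peaks = which(is_ext(`>=`) & doses > stats::median(doses)),
       valleys = which(is_ext(`<=`) & doses < stats::median(doses)))
}

# collapse runs of adjacent indices (plateaus) to their midpoint
collapse_runs <- function(idx) {
  if (!length(idx)) return(integer(0))
  grp <- cumsum(c(1L, diff(idx) > 1L))
  as.integer(round(tapply(idx, grp, function(v) mean(range(v)))))
}

#' Peak-to-valley dose ratio from a measured profile
#'
#' Detects interior dose peaks and valleys in a profile cut and reports
#' `PVDR = mean(peaks) / mean(valleys)` with an uncertainty from Gaussian
#' propagation of the peak and valley standard deviations. When the valley
#' doses fall below a noise floor (a fraction of the mean peak dose,
#' mirroring the sensitivity limit of radiochromic film), only a lower
#' bound `mean(peaks) / floor` can be quoted and the result is flagged.
#'
#' @param cut A [profile_cut()].
#' @param noise_floor Noise floor as a fraction of the mean peak dose
#'   (default 0.005, i.e. 0.5 percent).
#' @param window Half-width, in samples, of the local-extremum test;
#'   defaults to 1/20 of the profile length.
#' @return List with `pvdr`, `se` (NA for lower bounds), `lower_bound`
#'   (logical), and the detected `peak`/`valley` doses.
#' @export
pvdr_from_profile <- function(cut, noise_floor = 0.005, window = NULL) {
  stopifnot(inherits(cut, "profile_cut"))
  d <- cut$doses
  if (max(d) - min(d) <= 1e-12 * max(d, 1)) {
    return(list(pvdr = 1, se = 0, lower_bound = FALSE,
                peak = max(d), valley = min(d)))
  }
  if (is.null(window)) window <- max(3L, length(d) %/% 20L)
  ext <- local_extrema(d, window)
  pk <- collapse_runs(ext$peaks); vl <- collapse_runs(ext$valleys)
  if (length(pk) < 1)
    stop("no interior peak detected", call. = FALSE)
  peaks <- d[pk]
  floor_dose <- noise_floor * mean(peaks)
  valleys <- d[vl]
  if (length(vl) < 1 || mean(valleys) < floor_dose) {
    return(list(pvdr = mean(peaks) / floor_dose, se = NA_real_,
                lower_bound = TRUE, peak = peaks, valley = valleys))
  }
  r <- mean(peaks) / mean(valleys)
  rel <- 0
  if (length(peaks) > 1) rel <- rel + stats::sd(peaks)^2 / mean(peaks)^2
  if (length(valleys) > 1) rel <- rel + stats::sd(valleys)^2 / mean(valleys)^2
  list(pvdr = r, se = r * sqrt(rel), lower_bound = FALSE,
       peak = peaks, valley = valleys)
}

#' Fit a Gaussian to a single-beam dose profile
#'
#' Nonlinear least squares of `dose = baseline + A exp(-(x - mu)^2 / (2
#' sigma^2))`, the standard way of quoting the size (standard deviation) of
#' a pencil beam from a film profile. Works on a window dominated by one
#' beam.
#'
#' @param x A [profile_cut()], a `dose_field` (the horizontal line through
#'   its maximum is used), or a numeric vector of positions.
#' @param doses Dose values when `x` is a numeric position vector.
#' @return List with `sigma`, `se` (standard error), `center`, `amplitude`,
#'   `baseline` and the underlying `fit`.
#' @examples
#' xs <- seq(-500, 500, by = 5)
#' pr <- profile_cut(xs, 10 * exp(-xs^2 / (2 * 95.3^2)), "axis")
#' fit_beam_sigma(pr)$sigma
#' @export
fit_beam_sigma <- function(x, doses = NULL) {
  if (inherits(x, "dose_field")) {
    ax <- field_axes(x)
    j <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
    pos <- ax$x; d <- x$values[j[1], ]
  } else if (inherits(x, "profile_cut")) {
    pos <- x$positions; d <- x$doses
  } else {
    pos <- x; d <- doses
  }
  base0 <- min(d)
  a0 <- max(d) - base0
  m0 <- pos[which.max(d)]
  above <- pos[d - base0 > a0 / 2]
  s0 <- max(diff(range(above)) / 2.355, diff(range(pos)) / 50)
  model <- function(p) p[1] + p[2] * exp(-(pos - p[3])^2 / (2 * p[4]^2))
  fit <- minpack.lm::nls.lm(
    par = c(b = base0, a = a0, m = m0, s = s0),
    fn = function(p) d - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5, 9))
    stop("Gaussian fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  # standard errors from the analytic Jacobian at the solution
  E <- exp(-(pos - p["m"])^2 / (2 * p["s"]^2))
  J <- cbind(1, E,
             p["a"] * (pos - p["m"]) / p["s"]^2 * E,
             p["a"] * (pos - p["m"])^2 / p["s"]^3 * E)
  # heteroscedasticity-consistent (sandwich) variance: film noise scales
  # with the signal, so the homoscedastic formula understates the error
  nd <- length(d)
  vc <- tryCatch({
    bread <- solve(crossprod(J))
    meat <- crossprod(J * fit$fvec)
    nd / max(1L, nd - 4L) * bread %*% meat %*% bread
  }, error = function(e) NULL)
  se <- if (is.null(vc)) 0 else sqrt(pmax(diag(vc), 0))
  list(sigma = abs(unname(p["s"])),
       se = unname(if (length(se) == 4) se[4] else se),
       center = unname(p["m"]),
       amplitude = unname(p["a"]),
       baseline = unname(p["b"]),
       fit = fit)
}

#' Write a profile cut as two-column CSV
#' @param cut A [profile_cut()].
#' @param path Output CSV path (columns `position_um`, `dose_gy`).
#' @export
write_profile <- function(cut, path) {
  utils::write.csv(data.frame(position_um = cut$positions,
                              dose_gy = cut$doses),
                   path, row.names = FALSE)
  invisible(path)
}
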