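#' Minibeam lattice specification
#'
#' Describes a square lattice of pencil minibeams: either ideal Gaussian
#' beams of standard deviation `sigma` or square top-hat beams of side
#' `width`, spaced `ctc` apart (center-to-center) and normalized so that an
#' infinite lattice delivers `mean_dose` on average. All lengths are in
#' micrometres, doses in gray. Beam centers sit at integer multiples of
#' `ctc`, so the unit cell is `[-ctc/2, ctc/2]^2` with the dose valley at
#' its corners.
#'
#' @param sigma Gaussian beam standard deviation (um). Required for
#'   `shape = "gaussian"`.
#' @param ctc Center-to-center lattice spacing (um).
#' @param mean_dose Field-mean dose of the infinite lattice (Gy).
#' @param grid_n Number of beams per side; `Inf` (default) for the infinite
#'   lattice. A finite `grid_n` places `grid_n x grid_n` beams centered on
#'   the origin.
#' @param shape `"gaussian"` or `"square_tophat"`.
#' @param width Side length of a square top-hat beam (um). Required for
#'   `shape = "square_tophat"`; must not exceed `ctc`.
#'
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec(sigma = 95, ctc = 1800, mean_dose = 60)
#' beam_spec(width = 180, ctc = 1800, mean_dose = 60, shape = "square_tophat")
#' @export
beam_spec <- function(sigma = NULL, ctc, mean_dose = 60, grid_n = Inf,
                      shape = c("gaussian", "square_tophat"), width = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(ctc) || length(ctc) != 1L || ctc <= 0)
    stop("invalid geometry: 'ctc' must be a single positive length", call. = FALSE)
  if (!is.numeric(mean_dose) || mean_dose < 0)
    stop("'mean_dose' must be non-negative", call. = FALSE)
  if (!(is.infinite(grid_n) || (grid_n == as.integer(grid_n) && grid_n >= 1)))
    stop("'grid_n' must be a positive integer or Inf", call. = FALSE)
  if (shape == "gaussian") {
    if (is.null(sigma) || !is.numeric(sigma) || sigma <= 0)
      stop("invalid geometry: Gaussian beams need 'sigma' > 0", call. = FALSE)
    width <- NULL
  } else {
    if (is.null(width) || !is.numeric(width) || width <= 0)
      stop("invalid geometry: top-hat beams need 'width' > 0", call. = FALSE)
    if (width > ctc)
      stop("invalid geometry: top-hat 'width' exceeds 'ctc'", call. = FALSE)
    sigma <- NULL
  }
  structure(
    list(shape = shape, sigma = sigma, width = width, ctc = ctc,
         grid_n = grid_n, mean_dose = mean_dose,
         ratio = if (shape == "gaussian") sigma / ctc else width / ctc),
    class = "beam_spec"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  size <- if (x$shape == "gaussian")
    sprintf("sigma = %g um", x$sigma) else sprintf("width = %g um", x$width)
  cat(sprintf("Minibeam lattice (%s): %s, ctc = %g um (ratio %.3f)\n",
              x$shape, size, x$ctc, x$ratio))
  cat(sprintf("  grid: %s, mean dose %g Gy\n",
              if (is.infinite(x$grid_n)) "infinite" else
                sprintf("%d x %d beams", x$grid_n, x$grid_n),
              x$mean_dose))
  invisible(x)
}

#' Central amplitude of a single Gaussian minibeam
#'
#' The single-beam peak dose `A` that makes an infinite square lattice of
#' Gaussian beams average to `mean_dose`: since each beam integrates to
#' `2 pi sigma^2 A` over the plane and there is one beam per `ctc^2` of
#' area, `A = mean_dose * ctc^2 / (2 pi sigma^2)`.
#'
#' @param mean_dose Field-mean dose (Gy).
#' @param sigma Beam standard deviation (um).
#' @param ctc Lattice spacing (um).
#' @return Peak dose of an isolated beam (Gy).
#' @examples
#' amplitude_from_mean(60, 95, 1800)   # ~3428 Gy
#' @export
amplitude_from_mean <- function(mean_dose, sigma, ctc) {
  if (any(sigma <= 0) || any(ctc <= 0))
    stop("invalid geometry: 'sigma' and 'ctc' must be positive", call. = FALSE)
  if (any(mean_dose < 0))
    stop("'mean_dose' must be non-negative", call. = FALSE)
  mean_dose * ctc^2 / (2 * pi * sigma^2)
}

#' Peak dose of square top-hat minibeams
#'
#' For square beams of side `width` on a `ctc` lattice the dose is
#' concentrated on a fraction `(width/ctc)^2` of the area, so the in-beam
#' dose is `mean_dose * (ctc/width)^2`.
#'
#' @inheritParams amplitude_from_mean
#' @param width Side of the square beam (um); must satisfy
#'   `0 < width <= ctc`.
#' @return In-beam (peak) dose (Gy).
#' @examples
#' tophat_peak(60, 180, 1800)  # 6000 Gy
#' @export
tophat_peak <- function(mean_dose, width, ctc) {
  if (any(width <= 0) || any(ctc <= 0) || any(width > ctc))
    stop("invalid geometry: need 0 < width <= ctc", call. = FALSE)
  mean_dose * (ctc / width)^2
}
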