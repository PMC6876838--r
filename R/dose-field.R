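# 1D lattice sum of unit-amplitude Gaussians centered at multiples of ctc,
# truncated at +-K lattice sites around the nearest neighbours of x.
# K defaults to ceiling(6*sigma/ctc) + 1 so the neglected tail is < 1e-8.
lattice_sum_1d <- function(x, sigma, ctc, K = NULL) {
  if (is.null(K)) K <- ceiling(6 * sigma / ctc) + 1L
  i0 <- round(x / ctc)
  s <- numeric(length(x))
  for (k in -K:K)
    s <- s + exp(-(x - (i0 + k) * ctc)^2 / (2 * sigma^2))
  s
}

# 1D sum over the finite beam positions of a grid_n-wide lattice
finite_sum_1d <- function(x, sigma, centers) {
  s <- numeric(length(x))
  for (c0 in centers)
    s <- s + exp(-(x - c0)^2 / (2 * sigma^2))
  s
}

# beam center coordinates of a finite grid, centered on the origin
grid_centers <- function(spec) {
  n <- spec$grid_n
  (seq_len(n) - 1 - (n - 1) / 2) * spec$ctc
}

#' Dose of a minibeam lattice at given points
#'
#' Evaluates the lattice dose `D(x, y) = A * sum_ij exp(-((x - i ctc)^2 +
#' (y - j ctc)^2) / (2 sigma^2))` with the single-beam amplitude `A` set by
#' [amplitude_from_mean()]. For an infinite lattice the sum is truncated at
#' a lattice order where further terms change the result by less than 1e-6
#' relative; a finite `grid_n` sums over its `grid_n x grid_n` beams only.
#' Square top-hat lattices return the in-beam dose ([tophat_peak()]) inside
#' a beam and zero outside.
#'
#' @param spec A [beam_spec()].
#' @param x,y Coordinates (um) in the lattice frame (beam centers at integer
#'   multiples of `ctc`). Recycled to a common length.
#' @return Dose in Gy, vectorized over the points.
#' @examples
#' sp <- beam_spec(sigma = 95, ctc = 1800, mean_dose = 60)
#' dose_at(sp, 0, 0)          # ~ single-beam amplitude; neighbours negligible
#' dose_at(sp, 900, 900)      # valley dose
#' @export
dose_at <- function(spec, x, y) {
  stopifnot(inherits(spec, "beam_spec"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (spec$shape == "square_tophat") {
    peak <- tophat_peak(spec$mean_dose, spec$width, spec$ctc)
    if (is.infinite(spec$grid_n)) {
      dx <- abs(x - round(x / spec$ctc) * spec$ctc)
      dy <- abs(y - round(y / spec$ctc) * spec$ctc)
      return(ifelse(dx <= spec$width / 2 & dy <= spec$width / 2, peak, 0))
    }
    cen <- grid_centers(spec)
    inx <- vapply(x, function(xx) any(abs(xx - cen) <= spec$width / 2), TRUE)
    iny <- vapply(y, function(yy) any(abs(yy - cen) <= spec$width / 2), TRUE)
    return(ifelse(inx & iny, peak, 0))
  }
  A <- amplitude_from_mean(spec$mean_dose, spec$sigma, spec$ctc)
  if (is.infinite(spec$grid_n)) {
    A * lattice_sum_1d(x, spec$sigma, spec$ctc) *
      lattice_sum_1d(y, spec$sigma, spec$ctc)
  } else {
    cen <- grid_centers(spec)
    A * finite_sum_1d(x, spec$sigma, cen) * finite_sum_1d(y, spec$sigma, cen)
  }
}

#' Sampled 2D dose map
#'
#' Construct / render a pixelated dose field. `render_dose_map()` samples
#' [dose_at()] at pixel centers over a rectangular extent; because the
#' lattice dose separates into a product of per-axis sums, rendering costs
#' one outer product. The midpoint sampling means the spatial mean over
#' whole unit cells reproduces the lattice mean dose to high accuracy.
#'
#' @param spec A [beam_spec()].
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` in um. Must cover at
#'   least one unit cell in each direction.
#' @param pixel_size Pixel side (um); must be at most `ctc/32`.
#' @return A `dose_field`: list with `values` (matrix, rows indexing y,
#'   columns x), `pixel_size`, and `origin` (center of pixel `[1, 1]`).
#' @examples
#' sp <- beam_spec(sigma = 199, ctc = 1800, mean_dose = 60)
#' f <- render_dose_map(sp, c(-900, 900, -900, 900), 1800 / 64)
#' mean(f$values)   # ~ 60 Gy
#' @export
render_dose_map <- function(spec, extent, pixel_size) {
  stopifnot(inherits(spec, "beam_spec"), length(extent) == 4)
  if (pixel_size > spec$ctc / 32)
    stop("resolution error: 'pixel_size' must be <= ctc/32", call. = FALSE)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (w < spec$ctc || h < spec$ctc)
    stop("'extent' must cover at least one unit cell", call. = FALSE)
  nx <- floor(w / pixel_size + 1e-9)
  ny <- floor(h / pixel_size + 1e-9)
  xs <- extent[1] + (seq_len(nx) - 0.5) * pixel_size
  ys <- extent[3] + (seq_len(ny) - 0.5) * pixel_size
  if (spec$shape == "gaussian") {
    if (is.infinite(spec$grid_n)) {
      sx <- lattice_sum_1d(xs, spec$sigma, spec$ctc)
      sy <- lattice_sum_1d(ys, spec$sigma, spec$ctc)
    } else {
      cen <- grid_centers(spec)
      sx <- finite_sum_1d(xs, spec$sigma, cen)
      sy <- finite_sum_1d(ys, spec$sigma, cen)
    }
    A <- amplitude_from_mean(spec$mean_dose, spec$sigma, spec$ctc)
    vals <- A * outer(sy, sx)
  } else {
    vals <- matrix(dose_at(spec, rep(xs, each = ny), rep(ys, nx)), nrow = ny)
  }
  dose_field(vals, pixel_size, origin = c(xs[1], ys[1]), spec = spec)
}

#' @rdname render_dose_map
#' @param values Dose matrix (Gy), rows indexing y and columns x.
#' @param origin Coordinates (um) of the center of pixel `[1, 1]`.
#' @export
dose_field <- function(values, pixel_size, origin = c(0, 0), spec = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("dose values must be non-negative", call. = FALSE)
  if (pixel_size <= 0) stop("'pixel_size' must be positive", call. = FALSE)
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin), spec = spec),
            class = "dose_field")
}

#' @export
print.dose_field <- function(x, ...) {
  cat(sprintf("Dose field: %d x %d px at %g um/px, dose %.3g-%.3g Gy (mean %.3g)\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
plot.dose_field <- function(x, ...) {
  xs <- x$origin[1] + (seq_len(ncol(x$values)) - 1) * x$pixel_size
  ys <- x$origin[2] + (seq_len(nrow(x$values)) - 1) * x$pixel_size
  graphics::image(xs, ys, t(x$values), xlab = "x [um]", ylab = "y [um]",
                  col = grDevices::hcl.colors(64, "inferno"), useRaster = TRUE, ...)
  invisible(x)
}

# x/y axis coordinates of the pixel centers
field_axes <- function(field) {
  list(x = field$origin[1] + (seq_len(ncol(field$values)) - 1) * field$pixel_size,
       y = field$origin[2] + (seq_len(nrow(field$values)) - 1) * field$pixel_size)
}

#' Analytic peak-to-valley dose ratio of an infinite Gaussian lattice
#'
#' For an infinite square lattice of Gaussian beams the dose factorizes
#' into per-axis theta-like sums `theta(x) = sum_i exp(-(x - i ctc)^2 /
#' (2 sigma^2))`, so the PVDR is `[theta(0) / theta(ctc/2)]^2` -- the dose
#' at a beam center over the dose at the cell-corner valley. It depends on
#' the geometry only through `sigma/ctc`, is always at least 1, and
#' decreases monotonically as the beams widen. For very small `sigma/ctc`
#' the ratio overflows double precision and `Inf` is returned.
#'
#' @param spec A [beam_spec()] with an infinite Gaussian lattice, or a bare
#'   `sigma/ctc` ratio.
#' @return PVDR (dimensionless, `>= 1`; `Inf` on overflow).
#' @examples
#' pvdr_analytic(beam_spec(sigma = 883, ctc = 1800))  # ~1.07
#' pvdr_analytic(0.1)                                 # ~1.8e10
#' @export
pvdr_analytic <- function(spec) {
  if (inherits(spec, "beam_spec")) {
    if (spec$shape != "gaussian" || !is.infinite(spec$grid_n))
      stop("PVDR formula requires an infinite Gaussian lattice", call. = FALSE)
    ratio <- spec$ratio
  } else {
    ratio <- spec
    if (!is.numeric(ratio) || any(ratio <= 0))
      stop("'spec' must be a beam_spec or a positive sigma/ctc ratio", call. = FALSE)
  }
  vapply(ratio, function(r) {
    tp <- lattice_sum_1d(0, r, 1)
    tv <- lattice_sum_1d(0.5, r, 1)
    # log-domain guard: the valley sum underflows long before the peak does
    if (tv == 0) return(Inf)
    exp(2 * (log(tp) - log(tv)))
  }, numeric(1))
}

#' Write / read dose fields as plain-text matrix CSV with a JSON sidecar
#'
#' The matrix goes to `<path>` as headerless CSV (rows = y); pixel size,
#' origin and any attached beam spec go to `<path>.json`.
#'
#' @param field A `dose_field`.
#' @param path CSV file path.
#' @return `write_dose_field()` returns `path` invisibly; `read_dose_field()`
#'   returns the reconstructed `dose_field`.
#' @export
write_dose_field <- function(field, path) {
  stopifnot(inherits(field, "dose_field"))
  utils::write.table(field$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_size = field$pixel_size, origin = field$origin)
  if (!is.null(field$spec)) meta$spec <- unclass(field$spec)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dose_field
#' @export
read_dose_field <- function(path) {
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- NULL
  if (!is.null(meta$spec)) {
    s <- meta$spec
    spec <- beam_spec(sigma = s$sigma, ctc = s$ctc, mean_dose = s$mean_dose,
                      grid_n = if (is.null(s$grid_n) || s$grid_n == "Inf") Inf
                               else s$grid_n,
                      shape = s$shape, width = s$width)
  }
  dose_field(vals, meta$pixel_size, meta$origin, spec = spec)
}
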