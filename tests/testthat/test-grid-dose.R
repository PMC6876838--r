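test_that("single-beam amplitude follows the lattice normalization", {
  # closed form A = D * ctc^2 / (2 pi sigma^2)
  expect_equal(amplitude_from_mean(60, 95, 1800), 3428.224, tolerance = 1e-6)
  expect_equal(amplitude_from_mean(60, 180, 1800), 954.9297, tolerance = 1e-6)
  expect_identical(amplitude_from_mean(0, 95, 1800), 0)
  expect_error(amplitude_from_mean(60, -1, 1800), "invalid geometry")
  expect_error(amplitude_from_mean(60, 95, 0), "invalid geometry")
})

test_that("amplitude inverts back to the analytic lattice mean", {
  # mean of the infinite lattice = A * 2 pi sigma^2 / ctc^2
  for (r in ratios_table2) {
    A <- amplitude_from_mean(60, r * 1800, 1800)
    expect_equal(A * 2 * pi * (r * 1800)^2 / 1800^2, 60, tolerance = 1e-9)
  }
})

test_that("lattice dose matches the brute-force double sum", {
  set.seed(42)
  for (r in c(0.053, 0.228, 0.491)) {
    sp <- beam_spec(sigma = r * 1800, ctc = 1800, mean_dose = 60)
    x <- stats::runif(5, -2700, 2700)
    y <- stats::runif(5, -2700, 2700)
    expect_equal(dose_at(sp, x, y),
                 mapply(oracle_dose_2d, x, y,
                        MoreArgs = list(sigma = r * 1800, ctc = 1800,
                                        mean_dose = 60)),
                 tolerance = 1e-9)
  }
})

test_that("dose at a beam center approaches the isolated-beam amplitude for narrow beams", {
  sp <- beam_spec(sigma = 95, ctc = 1800, mean_dose = 60)  # ratio 0.053
  expect_equal(dose_at(sp, 0, 0), amplitude_from_mean(60, 95, 1800),
               tolerance = 1e-12)
})

test_that("valley dose of the near-homogeneous lattice is close to the mean dose", {
  sp <- beam_spec(sigma = 0.491 * 1800, ctc = 1800, mean_dose = 60)
  expect_equal(dose_at(sp, 900, 900), 57.96, tolerance = 1e-3)
})

test_that("a 1x1 grid is a single Gaussian everywhere", {
  sp1 <- beam_spec(sigma = 300, ctc = 1800, mean_dose = 60, grid_n = 1)
  A <- amplitude_from_mean(60, 300, 1800)
  x <- seq(-2000, 2000, length.out = 41)
  expect_equal(dose_at(sp1, x, 0), A * exp(-x^2 / (2 * 300^2)),
               tolerance = 1e-12)
})

test_that("lattice truncation is converged: K and 2K agree", {
  for (r in c(0.1, 0.3, 0.491)) {
    K <- ceiling(6 * r) + 1
    x <- c(0.1, 0.45, 0.5) * 1800
    d1 <- oracle_theta(x, r * 1800, 1800, K = K)
    d2 <- oracle_theta(x, r * 1800, 1800, K = 2 * K)
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("infinite-lattice dose factorizes into per-axis sums", {
  # D(x,y) * D(0,0) = D(x,0) * D(0,y)
  sp <- beam_spec(sigma = 400, ctc = 1800, mean_dose = 60)
  set.seed(7)
  x <- stats::runif(10, -900, 900); y <- stats::runif(10, -900, 900)
  lhs <- dose_at(sp, x, y) * dose_at(sp, 0, 0)
  rhs <- dose_at(sp, x, 0) * dose_at(sp, 0, y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("rendered unit cells conserve the mean dose at every studied ratio", {
  for (r in ratios_table2) {
    sp <- beam_spec(sigma = r * 1800, ctc = 1800, mean_dose = 60)
    f <- render_dose_map(sp, c(-900, 900, -900, 900), 1800 / 256)
    expect_equal(mean(f$values), 60, tolerance = 1e-3)
  }
})

test_that("doubling the render resolution barely moves the map mean", {
  sp <- beam_spec(sigma = 0.11 * 1800, ctc = 1800, mean_dose = 60)
  m1 <- mean(render_dose_map(sp, c(-900, 900, -900, 900), 1800 / 128)$values)
  m2 <- mean(render_dose_map(sp, c(-900, 900, -900, 900), 1800 / 256)$values)
  expect_equal(m1, m2, tolerance = 1e-4)
})

test_that("render validates resolution and extent", {
  sp <- beam_spec(sigma = 200, ctc = 1800, mean_dose = 60)
  expect_error(render_dose_map(sp, c(-900, 900, -900, 900), 100),
               "resolution")
  expect_error(render_dose_map(sp, c(0, 500, 0, 500), 10), "unit cell")
})

test_that("a finite 4x4 grid renders over the experimental 7.2 x 7.2 mm field", {
  sp <- beam_spec(sigma = 95, ctc = 1800, mean_dose = 60, grid_n = 4)
  f <- render_dose_map(sp, c(-3600, 3600, -3600, 3600), 1800 / 32)
  # 16 beams at +-900, +-2700: dose at each center ~ amplitude
  A <- amplitude_from_mean(60, 95, 1800)
  expect_equal(dose_at(sp, c(900, -2700), c(900, 2700)), rep(A, 2),
               tolerance = 1e-10)
  # total energy of 16 isolated Gaussians: 16 * 2 pi sigma^2 A
  px <- 1800 / 32
  expect_equal(sum(f$values) * px^2, 16 * 2 * pi * 95^2 * A, tolerance = 1e-3)
})

test_that("analytic PVDR matches theta-sum values and is monotone in the ratio", {
  expect_equal(pvdr_analytic(0.491), 1.071026, tolerance = 1e-4)
  expect_equal(pvdr_analytic(0.1), 1.8e10, tolerance = 1e-2)
  pv <- pvdr_analytic(ratios_table2)
  expect_true(all(pv >= 1))
  expect_true(all(diff(pv) < 0))
  expect_equal(pvdr_analytic(50), 1, tolerance = 1e-9)   # flat-field limit
  expect_identical(pvdr_analytic(0.01), Inf)             # overflow sentinel
})

test_that("top-hat peak dose concentrates the mean by the area ratio", {
  expect_identical(tophat_peak(60, 180, 1800), 6000)
  expect_identical(tophat_peak(60, 1800, 1800), 60)
  expect_identical(tophat_peak(30, 600, 1800), 270)
  expect_error(tophat_peak(60, 2000, 1800), "invalid geometry")
})

test_that("dose fields round-trip through CSV + JSON sidecar", {
  sp <- beam_spec(sigma = 400, ctc = 1800, mean_dose = 60)
  f <- render_dose_map(sp, c(-900, 900, -900, 900), 1800 / 64)
  path <- file.path(tempdir(), "map.csv")
  write_dose_field(f, path)
  g <- read_dose_field(path)
  expect_equal(g$values, f$values, tolerance = 1e-12)
  expect_equal(g$pixel_size, f$pixel_size)
  expect_equal(g$origin, f$origin)
  expect_equal(g$spec$sigma, 400)
  unlink(c(path, paste0(path, ".json")))
})
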