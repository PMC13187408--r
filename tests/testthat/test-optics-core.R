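test_that("pupil mask discretizes the aperture disk", {
  n <- 512; ds <- 1; D <- n * ds / 2
  g <- make_pupil(n, ds, D)
  expect_equal(sum(g$mask) * ds^2 / (pi * (D / 2)^2), 1, tolerance = 0.015)
  # 90-degree rotation leaves the mask unchanged (odd grid: the rotation
  # center coincides with the grid center sample)
  go <- make_pupil(129, 1, 60)
  rot90 <- function(m) t(m[rev(seq_len(nrow(m))), ])
  expect_equal(rot90(go$mask), go$mask)
  expect_equal(g$rho[floor(n / 2) + 1, floor(n / 2) + 1], 0)
  expect_error(make_pupil(64, 1, 64), "does not fit")
})

test_that("defocus phase is the quadratic with edge value psi", {
  g <- make_pupil(64, 1, 30)   # aperture edge falls on a grid sample
  ph <- defocus_phase(g, 7)
  ctr <- floor(64 / 2) + 1
  expect_equal(ph[ctr, ctr], 0)
  # the aperture-edge pixel carries exactly psi_z (rho = 1 there)
  edge_col <- ctr + 15
  expect_equal(g$rho[ctr, edge_col], 1)
  expect_equal(ph[ctr, edge_col], 7)
  # additivity
  expect_equal(defocus_phase(g, 2) + defocus_phase(g, 3),
               defocus_phase(g, 5))
})

test_that("unaberrated PSF is a centered, unit-sum Airy-like pattern", {
  g <- small_grid(64)
  p <- pupil_to_psf(g, 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  ctr <- floor(64 / 2) + 1
  expect_equal(which(p == max(p)), (ctr - 1) * 64 + ctr)
  expect_error(pupil_to_psf(make_pupil(16, 1, 15.9), 0), NA)
})

test_that("linear pupil ramp shifts the PSF by one pixel (shift theorem)", {
  g <- small_grid(64)
  set.seed(3)
  base_phase <- defocus_phase(g, 4)
  p0 <- pupil_to_psf(g, base_phase)
  ctr <- floor(g$n / 2) + 1
  ramp <- 2 * pi * (col(matrix(0, g$n, g$n)) - ctr) / g$n
  p1 <- pupil_to_psf(g, base_phase + ramp)
  shifted <- p0[, c(g$n, seq_len(g$n - 1))]  # circular shift by one column
  err <- max(abs(p1 - shifted))
  if (err > 1e-10) {
    shifted2 <- p0[, c(2:g$n, 1)]
    err <- min(err, max(abs(p1 - shifted2)))
  }
  expect_lt(err, 1e-10)
})

test_that("phase-only modulation conserves pupil energy (Parseval)", {
  g <- small_grid(64)
  set.seed(5)
  e0 <- {
    u <- g$mask
    A <- fft(u)
    sum(Mod(A)^2)
  }
  ph <- matrix(rnorm(64^2, 0, 2), 64)
  e1 <- {
    u <- g$mask * exp(1i * ph)
    A <- fft(u)
    sum(Mod(A)^2)
  }
  expect_equal(e1 / e0, 1, tolerance = 1e-8)
})

test_that("unaberrated lateral FWHM matches the Airy oracle within 3%", {
  g <- fine_grid(256)
  p <- pupil_to_psf(g, 0)
  measured <- edofco:::fwhm_profile(p)
  oracle <- airy_fwhm_px(g$n, g$ds, g$pupil_diameter)
  expect_lt(abs(measured - oracle) / oracle, 0.03)
})

test_that("radial MTF is DC-normalized, band-limited and monotone", {
  g <- fine_grid(128)
  p <- pupil_to_psf(g, 0)
  m <- mtf_radial(p)
  expect_equal(m$value[1], 1)
  expect_true(all(m$value >= 0))
  # beyond the incoherent cutoff the MTF vanishes (pupil autocorrelation
  # support); binned leakage stays below 1e-3
  expect_lt(max(m$value[m$rho > 1]), 1e-3)
  # non-increasing within one binning quantum for the unaberrated system
  inside <- m$value[m$rho <= 1]
  expect_true(all(diff(inside) <= max(1 / length(inside), 1e-3)))
  # oracle: normalized autocorrelation of the pupil disk at matching shifts
  ac <- Re(fft(Mod(fft(g$mask))^2, inverse = TRUE)) / length(g$mask)
  ac <- ac / ac[1, 1]
  shifts <- round(m$rho * g$pupil_diameter / g$ds)
  ok <- shifts < g$n / 2
  expect_lt(max(abs(m$value[ok] - ac[cbind(1, shifts[ok] + 1)])), 2e-2)
  # MTF is invariant under circular PSF shifts
  m2 <- mtf_radial(p[, c(64:128, 1:63)], ds = g$ds,
                   pupil_diameter = g$pupil_diameter)
  expect_lt(max(abs(m2$value - m$value)), 1e-10)
})

test_that("PSF stacks satisfy their contracts across depth and wavelength", {
  config <- toy_optical_config()
  D_um <- config$pupil_diameter * 1000
  grid <- make_pupil(64, 2 * D_um / 64, D_um)
  depths <- sample_depths(3, config$nominal_focus, 50, "grid")
  st <- psf_stack(config, depths, grid)
  for (zi in 1:3) for (li in 1:2)
    expect_equal(sum(st$values[, , zi, li]), 1, tolerance = 1e-12)
  # zero modulation at z0 equals the unaberrated PSF per wavelength
  st0 <- psf_stack(config, config$nominal_focus, grid)
  for (li in 1:2)
    expect_equal(st0$values[, , 1, li], unclass(pupil_to_psf(grid, 0)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # defocus strictly spreads energy: central pixel dimmer at the DoF edge
  ctr <- floor(64 / 2) + 1
  for (li in 1:2)
    expect_gt(st0$values[ctr, ctr, 1, li], st$values[ctr, ctr, 1, li])
})

test_that("PSF stacks round-trip through TIFF + JSON sidecar", {
  config <- toy_optical_config()
  D_um <- config$pupil_diameter * 1000
  grid <- make_pupil(32, 2 * D_um / 32, D_um)
  st <- psf_stack(config, c(2980, 3020), grid)
  path <- tempfile(fileext = ".tif")
  write_psf_stack(st, path)
  back <- read_psf_stack(path)
  expect_equal(back$depths, st$depths)
  expect_equal(back$wavelengths, st$wavelengths)
  expect_lt(max(abs(back$values - st$values)), 1e-6)  # 32-bit float storage
})
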