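test_that("surrogate library is monotone, dispersive and spans 2 pi", {
  lib <- surrogate_library()
  # zero width = no pillar = zero relative phase
  lib0 <- surrogate_library(widths = c(0, 100, 200))
  expect_equal(unname(lib0$phases[1, ]), rep(0, 4))
  # phase strictly increasing in width at every wavelength
  expect_true(all(apply(lib$phases, 2, function(p) all(diff(p) > 0))))
  # defaults span at least 2 pi per wavelength
  expect_true(all(apply(lib$phases, 2, function(p) diff(range(p))) >= 2 * pi))
  # dispersion: different wavelengths get different phases for one width
  expect_true(all(abs(lib$phases[30, 1] - lib$phases[30, -1]) > 0.1))
  expect_error(surrogate_library(widths = c(100, 400)), "period")
  expect_error(surrogate_library(widths = c(100, 100)), "increasing")
})

test_that("library text format round-trips and rejects malformed input", {
  lib <- surrogate_library(widths = seq(50, 300, by = 50),
                           wavelengths = c(433, 681))
  path <- tempfile(fileext = ".csv")
  save_library(lib, path)
  back <- load_library(path)
  expect_identical(back$widths, lib$widths)
  expect_equal(unname(back$phases), unname(lib$phases))
  expect_identical(back$wavelengths, lib$wavelengths)

  writeLines(c("width_nm, phase_433", "100, 1.0", "100, 1.2"),
             path)
  expect_error(load_library(path), "duplicate")
  writeLines(c("width_nm, phase_433", "100, 1.0, 9"), path)
  expect_error(load_library(path), "line 2")
  writeLines(c("size_nm, phase_433", "100, 1.0"), path)
  expect_error(load_library(path), "width_nm")
  writeLines(c("width_nm, phase_433", "100, 1.0", "90, 0.9"), path)
  expect_error(load_library(path), "increasing")
})

test_that("width-to-phase lookup interpolates and differentiates", {
  lib <- surrogate_library(wavelengths = c(433, 681))
  # table nodes reproduce exactly
  expect_equal(width_to_phase(lib, lib$widths[10], 433),
               unname(lib$phases[10, 1]))
  # midpoint of two nodes is the arithmetic mean
  mid <- (lib$widths[5] + lib$widths[6]) / 2
  expect_equal(width_to_phase(lib, mid, 681),
               unname(lib$phases[5, 2] + lib$phases[6, 2]) / 2)
  # analytic derivative = segment slope (finite-difference oracle)
  g0 <- c(72, 131, 204, 287)   # away from table nodes
  err <- fd_gradient_error(function(g)
    ad_sum(width_to_phase(lib, g, 433) * c(1, -2, 3, 0.5)), g0, h = 1e-4)
  expect_lt(err, 1e-6)
  expect_error(width_to_phase(lib, 100, 550), "not tabulated")
})

test_that("radial replication is rotationally symmetric, local and linear", {
  g <- make_pupil(65, 1, 32)   # odd grid: exact 90-degree rotation
  gamma <- seq(100, 240, length.out = 8)
  m <- radial_map(gamma, g)
  rot90 <- function(x) t(x[rev(seq_len(nrow(x))), ])
  expect_equal(rot90(m), m)
  # constant vector maps to a constant inside the mask
  mc <- radial_map(rep(150, 8), g)
  expect_true(all(mc[g$mask == 1] == 150))
  expect_true(all(mc[g$mask == 0] == 0))
  # perturbing bin i changes exactly the annulus-i pixels
  bins <- radial_bins(g, 8)
  g2 <- gamma; g2[4] <- g2[4] + 7
  m2 <- radial_map(g2, g)
  expect_true(all((m2 != m) == (bins == 4)))
  # exact linearity of the replication operator
  a <- runif(8); b <- runif(8)
  expect_equal(radial_map(2 * a + 3 * b, g),
               2 * radial_map(a, g) + 3 * radial_map(b, g))
})

test_that("flat-pi initialization hits pi within one lookup quantum", {
  lib <- surrogate_library(wavelengths = c(433, 521, 601, 681))
  des <- metaoptic_design(lib, 12)
  ph <- width_to_phase(lib, des$gamma_init, 433)
  quantum <- max(abs(diff(lib$phases[, 1])))
  expect_true(all(abs(ph - pi) <= quantum))
})

test_that("meta-optic phase composes clamp, replication and lookup", {
  g <- small_grid(64)
  lib <- surrogate_library(wavelengths = c(433, 681))
  des <- metaoptic_design(lib, 8)
  # delta = 0: phase fully determined by gamma_init
  p0 <- metaoptic_phase(des, lib, 433, g)
  expect_equal(p0, radial_map(width_to_phase(lib, des$gamma_init, 433), g))
  # same width map, different wavelength: different phases (dispersion)
  p1 <- metaoptic_phase(des, lib, 681, g)
  expect_gt(max(abs((p0 - p1)[g$mask == 1])), 0.1)
  # clamping contract: out-of-range perturbations saturate, not error
  des$delta_gamma <- rep(1e4, 8)
  expect_equal(unname(effective_widths(des)), rep(des$width_bounds[2], 8))
  # end-to-end gradient through PSF chain wrt the width perturbation
  set.seed(2)
  wmat <- matrix(rnorm(64^2), 64)
  f <- function(delta) {
    phase <- metaoptic_phase(des, lib, 433, g, delta_gamma = delta)
    q <- edofco:::ad_psf_intensity(phase, g$mask)
    ad_sum((q / ad_sum(q)) * wmat)
  }
  expect_lt(fd_gradient_error(f, rnorm(8, 0, 3), h = 1e-3), 1e-4)
})

test_that("design export writes a width map with metadata", {
  g <- small_grid(32)
  lib <- surrogate_library(wavelengths = c(433, 681))
  des <- metaoptic_design(lib, 6)
  path <- tempfile(fileext = ".tif")
  export_design(des, g, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n, 32)
  wmap <- tiff::readTIFF(path) * meta$width_scale_nm
  expect_equal(max(abs(wmap - radial_map(des$gamma_init, g))) < 1e-3, TRUE)
})
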