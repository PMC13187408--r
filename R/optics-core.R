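# Discrete scalar Fourier-optics core: pupil grids, defocus phase, PSF and
# radial MTF. All lengths here are in micrometers (the pupil-plane sampling
# pitch `ds` and the pupil diameter both in um); configuration objects store
# the pupil diameter in mm and are converted at the psf_stack() boundary.

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

#' Discretize the pupil aperture
#'
#' Builds an `n x n` pupil-plane grid with sample pitch `ds` (um), the binary
#' aperture mask of a circular pupil of diameter `pupil_diameter` (um), and
#' the normalized radius map `rho` with `rho = 1` at the aperture edge. The
#' grid center sits at index `floor(n/2) + 1` along each axis, matching the
#' zero-frequency sample of a centered discrete Fourier transform.
#'
#' @param n Grid samples per side (>= 16).
#' @param ds Pupil-plane sample pitch in um.
#' @param pupil_diameter Pupil diameter D in um; must satisfy `n * ds > D`.
#' @return A `pupil_grid`: list with `n`, `ds`, `aperture_radius`, `rho`
#'   (n x n), `mask` (n x n, 0/1), `pupil_diameter`.
#' @examples
#' g <- make_pupil(64, 1, 24)
#' sum(g$mask) / (pi * (24 / 2)^2)  # ~1: disk area in samples
#' @export
make_pupil <- function(n, ds, pupil_diameter) {
  stopifnot(n >= 16, ds > 0, pupil_diameter > 0)
  if (n * ds <= pupil_diameter)
    stop(sprintf(
      "pupil does not fit in the grid: need n * ds > D but %g * %g <= %g",
      n, ds, pupil_diameter), call. = FALSE)
  ctr <- floor(n / 2) + 1
  coord <- (seq_len(n) - ctr) * ds
  r <- sqrt(outer(coord^2, coord^2, `+`))
  radius <- pupil_diameter / 2
  structure(
    list(n = as.integer(n), ds = ds, aperture_radius = radius,
         pupil_diameter = pupil_diameter,
         rho = r / radius,
         mask = (r <= radius) * 1),
    class = "pupil_grid"
  )
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf(
    "Pupil grid: %d x %d @ %g um, D = %g um (%d samples across, %d in mask)\n",
    x$n, x$n, x$ds, x$pupil_diameter, round(x$pupil_diameter / x$ds),
    sum(x$mask)))
  invisible(x)
}

#' Quadratic defocus phase on a pupil grid
#'
#' `phase = psi_z * rho^2` inside the aperture, zero outside; `psi_z` is the
#' defocus coefficient so the phase at the aperture edge equals `psi_z`
#' exactly.
#'
#' @param grid A [make_pupil()] grid.
#' @param psi_z Defocus coefficient in radians (any finite value).
#' @return An `n x n` phase matrix in radians.
#' @export
defocus_phase <- function(grid, psi_z) {
  stopifnot(inherits(grid, "pupil_grid"), is.finite(psi_z))
  psi_z * grid$rho^2 * grid$mask
}

#' Incoherent PSF from a pupil phase
#'
#' The intensity point spread function of the phase-only pupil
#' `P = mask * exp(i * phase)`: the squared magnitude of the centered
#' discrete Fourier transform of `P`, normalized to unit sum. The result is
#' zero-frequency-centered (peak of an unaberrated pupil at the grid center
#' sample).
#'
#' @param grid A [make_pupil()] grid.
#' @param phase `n x n` phase matrix in radians (e.g. [defocus_phase()] plus
#'   a meta-optic modulation); use `0` for the unaberrated system.
#' @param wavelength,numerical_aperture Optional; when both are given the
#'   object-space pixel pitch of the PSF plane,
#'   `(lambda / (2 NA)) * D / (n * ds)` um, is attached as attribute
#'   `"pitch"` (wavelength in nm).
#' @return `n x n` non-negative matrix summing to 1, with attributes `ds` and
#'   `pupil_diameter` carried from the grid (used by [mtf_radial()]).
#' @export
pupil_to_psf <- function(grid, phase = 0, wavelength = NULL,
                         numerical_aperture = NULL) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (length(phase) == 1L) phase <- matrix(phase, grid$n, grid$n)
  stopifnot(nrow(phase) == grid$n, ncol(phase) == grid$n)
  if (sum(grid$mask) == 0) stop("degenerate pupil: all-zero mask", call. = FALSE)
  u <- grid$mask * exp(1i * phase)
  A <- fftshift2(stats::fft(ifftshift2(u)))
  psf <- Re(A * Conj(A))
  psf <- psf / sum(psf)
  attr(psf, "ds") <- grid$ds
  attr(psf, "pupil_diameter") <- grid$pupil_diameter
  if (!is.null(wavelength) && !is.null(numerical_aperture)) {
    attr(psf, "pitch") <- (wavelength / 1000 / (2 * numerical_aperture)) *
      grid$pupil_diameter / (grid$n * grid$ds)
  }
  psf
}

#' Depth- and wavelength-resolved PSF stack
#'
#' For every depth `z` and configured wavelength, composes the defocus phase
#' (from the configuration's nominal focus and pupil diameter) with an
#' optional meta-optic modulation phase and computes the incoherent PSF.
#'
#' @param config An [optical_config()].
#' @param depths Depth positions in um (absolute distances, same convention
#'   as `config$nominal_focus`).
#' @param grid A [make_pupil()] grid whose `pupil_diameter` matches
#'   `config$pupil_diameter * 1000` (checked).
#' @param modulation `NULL` for the conventional (zero-modulation) system, or
#'   a function `function(wavelength_nm, grid)` returning an `n x n` phase
#'   matrix in radians, or a list of such matrices named by wavelength.
#' @return A `psf_stack`: list with `values` (array `n x n x depths x
#'   wavelengths`), `depths`, `wavelengths`, `pitch` (object-space um per
#'   pixel, one per wavelength), `ds`, `pupil_diameter`.
#' @export
psf_stack <- function(config, depths, grid, modulation = NULL) {
  stopifnot(inherits(config, "optical_config"), inherits(grid, "pupil_grid"),
            length(depths) >= 1, all(depths > 0))
  D_um <- config$pupil_diameter * 1000
  if (abs(grid$pupil_diameter - D_um) > 1e-6 * D_um)
    stop("grid pupil diameter does not match the configuration", call. = FALSE)
  nl <- length(config$wavelengths)
  out <- array(0, c(grid$n, grid$n, length(depths), nl))
  pitch <- numeric(nl)
  for (li in seq_len(nl)) {
    lam <- config$wavelengths[li]
    mod_phase <- if (is.null(modulation)) {
      matrix(0, grid$n, grid$n)
    } else if (is.function(modulation)) {
      modulation(lam, grid)
    } else {
      modulation[[li]]
    }
    for (zi in seq_along(depths)) {
      psi <- defocus_coefficient(depths[zi], config$nominal_focus, lam,
                                 config$pupil_diameter)
      slice <- pupil_to_psf(grid, defocus_phase(grid, psi) + mod_phase,
                            wavelength = lam,
                            numerical_aperture = config$numerical_aperture)
      out[, , zi, li] <- slice
      pitch[li] <- attr(slice, "pitch")
    }
  }
  structure(
    list(values = out, depths = depths, wavelengths = config$wavelengths,
         pitch = pitch, ds = grid$ds, pupil_diameter = grid$pupil_diameter),
    class = "psf_stack"
  )
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf(
    "PSF stack: %d x %d px, %d depth(s) x %d wavelength(s)\n",
    dim(x$values)[1], dim(x$values)[2], length(x$depths),
    length(x$wavelengths)))
  cat(sprintf("  depths (um): %s\n",
              paste(signif(x$depths, 6), collapse = ", ")))
  cat(sprintf("  wavelengths (nm): %s\n",
              paste(x$wavelengths, collapse = ", ")))
  invisible(x)
}

#' DC-normalized radial MTF profile
#'
#' Magnitude of the PSF's discrete Fourier transform, normalized by its
#' zero-frequency value and azimuthally averaged into radial bins of
#' normalized frequency `rho`, where `rho = 1` is the incoherent cutoff
#' (`2 NA / lambda`). On the discrete grid the OTF support equals the pupil
#' autocorrelation support, so one frequency sample corresponds to a pupil
#' displacement of `ds` and `rho = r_samples * ds / D`; bins are one
#' frequency sample wide.
#'
#' @param psf A PSF slice from [pupil_to_psf()] (or any non-negative unit-sum
#'   matrix with `ds` / `pupil_diameter` attributes).
#' @param ds,pupil_diameter Override the attributes if absent.
#' @param rho_max Largest normalized frequency retained (default 1.25; the
#'   region `rho > 1` carries only numerical leakage for a physical pupil).
#' @return An `mtf_profile`: list with `rho` (bin centers), `value`
#'   (`value[1] == 1` at DC), `ds`, `pupil_diameter`.
#' @export
mtf_radial <- function(psf, ds = attr(psf, "ds"),
                       pupil_diameter = attr(psf, "pupil_diameter"),
                       rho_max = 1.25) {
  stopifnot(is.matrix(psf), !is.null(ds), !is.null(pupil_diameter))
  total <- sum(psf)
  if (total <= 0) stop("zero total energy in PSF slice", call. = FALSE)
  n <- nrow(psf)
  M <- Mod(stats::fft(psf)) / total
  Mc <- fftshift2(M)
  ctr <- floor(n / 2) + 1
  idx <- seq_len(n) - ctr
  r_samples <- sqrt(outer(idx^2, idx^2, `+`))
  bin <- round(r_samples)
  rho_bin <- bin * ds / pupil_diameter
  keep <- rho_bin <= rho_max
  prof <- tapply(Mc[keep], bin[keep], mean)
  bins <- as.integer(names(prof))
  structure(
    list(rho = bins * ds / pupil_diameter, value = as.numeric(prof),
         ds = ds, pupil_diameter = pupil_diameter),
    class = "mtf_profile"
  )
}

#' @export
print.mtf_profile <- function(x, ...) {
  cat(sprintf("Radial MTF profile: %d bins, rho in [0, %.3g]\n",
              length(x$rho), max(x$rho)))
  invisible(x)
}

#' @export
plot.mtf_profile <- function(x, ...) {
  graphics::plot(x$rho, x$value, type = "l", xlab = "normalized frequency rho",
                 ylab = "MTF", ylim = c(0, 1), ...)
  graphics::abline(v = 1, lty = 3)
  invisible(x)
}

#' Write / read a PSF stack as multipage TIFF with a JSON sidecar
#'
#' Pages are ordered depth-major (all wavelengths of depth 1, then depth 2,
#' ...); each page is a 32-bit float image. The sidecar (`<path>.json`)
#' stores the depth and wavelength axes, per-wavelength pixel pitch and the
#' pupil-plane sampling.
#'
#' @param stack A [psf_stack()].
#' @param path TIFF output path.
#' @return `write_psf_stack()` the path, invisibly; `read_psf_stack()` a
#'   `psf_stack`.
#' @export
write_psf_stack <- function(stack, path) {
  stopifnot(inherits(stack, "psf_stack"))
  pages <- list()
  for (zi in seq_along(stack$depths))
    for (li in seq_along(stack$wavelengths))
      pages[[length(pages) + 1L]] <- stack$values[, , zi, li]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(depths = stack$depths, wavelengths = stack$wavelengths,
               pitch = stack$pitch, ds = stack$ds,
               pupil_diameter = stack$pupil_diameter,
               page_order = "depth-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_psf_stack
#' @export
read_psf_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(meta$depths); nl <- length(meta$wavelengths)
  n <- nrow(pages[[1]])
  values <- array(0, c(n, n, nz, nl))
  k <- 1L
  for (zi in seq_len(nz)) for (li in seq_len(nl)) {
    values[, , zi, li] <- pages[[k]]
    k <- k + 1L
  }
  structure(
    list(values = values, depths = meta$depths, wavelengths = meta$wavelengths,
         pitch = meta$pitch, ds = meta$ds,
         pupil_diameter = meta$pupil_diameter),
    class = "psf_stack"
  )
}

# Half-maximum width of the central row/column profile by linear
# interpolation; used for diffraction-limit checks. Returns width in samples.
fwhm_profile <- function(psf) {
  ctr <- which(psf == max(psf), arr.ind = TRUE)[1, ]
  row <- psf[ctr[1], ]
  half <- max(row) / 2
  above <- which(row >= half)
  lo <- min(above); hi <- max(above)
  # interpolate the crossings on each side
  left <- if (lo > 1) {
    lo - (row[lo] - half) / (row[lo] - row[lo - 1])
  } else lo
  right <- if (hi < length(row)) {
    hi + (row[hi] - half) / (row[hi] - row[hi + 1])
  } else hi
  right - left
}
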