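# Shared fixtures and a central finite-difference gradient checker.

# relative max deviation between the tape gradient of f at x and central
# finite differences
fd_gradient_error <- function(f, x, h = 1e-6) {
  node <- ad_param(x)
  loss <- f(node)
  ad_backward(loss)
  g <- node$grad
  if (is.null(g)) g <- x * 0
  gn <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    gn[i] <- (ad_value(f(ad_const(xp))) - ad_value(f(ad_const(xm)))) / (2 * h)
  }
  max(abs(g - gn)) / max(abs(gn), 1e-12)
}

# small pupil grid used across optics tests
small_grid <- function(n = 64, frac = 2) {
  make_pupil(n, 1, n / frac - 0.5)
}

# fine grid where the PSF is well resolved (pupil = n*ds/8)
fine_grid <- function(n = 256) {
  make_pupil(n, 1, n / 8)
}

# numerically computed Airy-profile FWHM in PSF-grid pixels for a pupil of
# diameter D on an n*ds grid: the first half-maximum crossing of
# (2 J1(v) / v)^2 maps to FWHM = (2 v*/pi) * (n ds / D) pixels.
airy_fwhm_px <- function(n, ds, D) {
  vstar <- stats::uniroot(function(v) (2 * besselJ(v, 1) / v)^2 - 0.5,
                          c(1, 2), tol = 1e-12)$root
  2 * vstar / pi * (n * ds / D)
}

toy_gt <- function(channels = 2L, out_size = 64L, psf_size = 64L,
                   seed = 11L) {
  toy_phantoms(1, channels = channels, out_size = out_size,
               psf_size = psf_size, seed = seed)[[1]]
}
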