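#' Space-bandwidth product at one wavelength
#'
#' Number of resolvable samples the system conveys at wavelength `lambda`:
#' `SBP = (2 Lx f_pass) * (2 Ly f_pass)` where the passed object-space
#' bandwidth `f_pass = min(f_c, f_Nyq)` is the smaller of the incoherent
#' cutoff `f_c = 2 NA / lambda` and the camera Nyquist frequency mapped to
#' object space `f_Nyq = M / (2 p)`, and `L_{x,y} = N_{x,y} p / M` is the
#' object-space field of view.
#'
#' @param config An [optical_config()].
#' @param wavelength Wavelength in nm (any positive value; defaults are taken
#'   per configured channel elsewhere).
#' @return The dimensionless space-bandwidth product (a scalar count).
#' @examples
#' space_bandwidth(demo_config(), 433)  # ~4.2e6
#' @export
space_bandwidth <- function(config, wavelength) {
  stopifnot(inherits(config, "optical_config"))
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("`wavelength` must be a single positive length (nm)", call. = FALSE)
  lam_um <- wavelength / 1000
  f_c <- 2 * config$numerical_aperture / lam_um            # cycles / um
  f_nyq <- config$magnification / (2 * config$sensor_pitch)
  f_pass <- min(f_c, f_nyq)
  L <- config$sensor_counts * config$sensor_pitch / config$magnification
  (2 * L[1] * f_pass) * (2 * L[2] * f_pass)
}

#' Defocus coefficient of a quadratic pupil phase
#'
#' The amplitude `psi_z` of the quadratic defocus phase at the pupil edge for
#' an emitter at distance `z` when the system is focused at `z0`:
#' `psi_z = (pi / lambda) * (1/z - 1/z0) * (D/2)^2`. The sign is preserved:
#' `psi_z` is negative for depths beyond the nominal focus.
#'
#' @param z Emitter distance in um (> 0).
#' @param z0 Nominal focus distance in um (> 0).
#' @param wavelength Wavelength in nm.
#' @param pupil_diameter Entrance-pupil diameter D in mm.
#' @return Defocus coefficient in radians (dimensionless phase amplitude).
#' @examples
#' defocus_coefficient(3000, 3020, 433, 6.64)
#' @export
defocus_coefficient <- function(z, z0, wavelength, pupil_diameter) {
  if (any(z == 0)) stop("invalid depth: z = 0", call. = FALSE)
  stopifnot(all(z > 0), z0 > 0, wavelength > 0, pupil_diameter > 0)
  lam_um <- wavelength / 1000
  r_um <- pupil_diameter * 1000 / 2
  (pi / lam_um) * (1 / z - 1 / z0) * r_um^2
}

#' Plan the Fourier-plane sampling grid
#'
#' Sizes the pupil-plane simulation grid for a target depth-of-field range.
#' The worst-case defocus amplitude over the symmetric range `z0 +/- Delta`
#' at the shortest configured wavelength bounds the critical Fourier sampling
#' pitch `ds_crit = pi (D/2) / (8 psi_max)`; the working pitch oversamples it
#' by the factor `alpha`: `ds = ds_crit / alpha`. Space-bandwidth requirements
#' per wavelength are reported alongside.
#'
#' The ratio `SBP_total / SBP(lambda_min)` is reported as a diagnostic
#' (`alpha_sbp_ratio`); `alpha` itself is an independent configuration scalar.
#' `margin_factor = alpha^2 * SBP(lambda_min) / SBP_total` estimates the
#' bandwidth margin the oversampled grid provides relative to the total
#' requirement, and `margin_over_threefold` flags when it exceeds 3.
#'
#' @param config An [optical_config()].
#' @param dof_halfwidth Half the target depth range, um; must be < z0.
#' @param alpha_oversample Oversampling factor alpha >= 1 (default 4).
#' @param snap_pitch Optional pitch quantum in um; when given, `ds` is snapped
#'   down to the nearest multiple (never coarser than computed).
#' @return A `sampling_plan` with fields `psi_max`, `ds_crit`, `ds`,
#'   `alpha_oversample`, `sbp_per_wavelength`, `sbp_total`,
#'   `alpha_sbp_ratio`, `margin_factor`, `margin_over_threefold`.
#' @examples
#' plan_sampling(demo_config(), dof_halfwidth = 25, alpha_oversample = 4)
#' @export
plan_sampling <- function(config, dof_halfwidth,
                          alpha_oversample = 4, snap_pitch = NULL) {
  stopifnot(inherits(config, "optical_config"), alpha_oversample >= 1)
  z0 <- config$nominal_focus
  if (dof_halfwidth >= z0)
    stop("invalid range: `dof_halfwidth` must be smaller than the nominal ",
         "focus distance", call. = FALSE)
  lam_min <- min(config$wavelengths)
  psi_near <- defocus_coefficient(z0 - dof_halfwidth, z0, lam_min,
                                  config$pupil_diameter)
  psi_far <- defocus_coefficient(z0 + dof_halfwidth, z0, lam_min,
                                 config$pupil_diameter)
  psi_max <- max(abs(psi_near), abs(psi_far))
  r_um <- config$pupil_diameter * 1000 / 2
  ds_crit <- pi * r_um / (8 * psi_max)
  ds <- ds_crit / alpha_oversample
  if (!is.null(snap_pitch)) {
    stopifnot(snap_pitch > 0)
    ds <- snap_pitch * max(1, floor(ds / snap_pitch))
    ds <- min(ds, ds_crit)   # snapping never violates the critical bound
  }
  sbp <- vapply(config$wavelengths, function(l) space_bandwidth(config, l),
                numeric(1))
  names(sbp) <- paste0(config$wavelengths, "nm")
  sbp_total <- sum(sbp)
  sbp_min <- sbp[[which.min(config$wavelengths)]]
  margin <- alpha_oversample^2 * sbp_min / sbp_total
  structure(
    list(
      psi_max = psi_max,
      ds_crit = ds_crit,
      ds = ds,
      alpha_oversample = alpha_oversample,
      sbp_per_wavelength = sbp,
      sbp_total = sbp_total,
      alpha_sbp_ratio = sbp_total / sbp_min,
      margin_factor = margin,
      margin_over_threefold = margin > 3,
      dof_halfwidth = dof_halfwidth,
      wavelength_min = lam_min
    ),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Fourier-plane sampling plan\n")
  cat(sprintf("  psi_max  : %.2f rad (lambda = %g nm, Delta = %g um)\n",
              x$psi_max, x$wavelength_min, x$dof_halfwidth))
  cat(sprintf("  ds_crit  : %.4g um\n", x$ds_crit))
  cat(sprintf("  ds       : %.4g um (alpha = %g)\n", x$ds, x$alpha_oversample))
  cat(sprintf("  SBP      : %s (x1e6), total %.3g M\n",
              paste(sprintf("%.2f", x$sbp_per_wavelength / 1e6),
                    collapse = ", "),
              x$sbp_total / 1e6))
  cat(sprintf("  SBP ratio: %.2f; margin factor %.2f%s\n",
              x$alpha_sbp_ratio, x$margin_factor,
              if (x$margin_over_threefold) " (>3x margin)" else ""))
  invisible(x)
}

#' Recover the worst-case defocus model from two operating points
#'
#' For a symmetric depth range `z0 +/- Delta` the worst-case defocus amplitude
#' occurs at the near edge, `psi_max(Delta) = C * Delta / (z0 * (z0 - Delta))`
#' with `C = (pi / lambda) * (D/2)^2`. Given exactly two (Delta, psi_max)
#' pairs this inverts that relation in closed form for the unique `(z0, C)`,
#' letting published operating points be checked for mutual consistency and
#' extrapolated to other depth ranges.
#'
#' @param pairs A 2-row, 2-column numeric matrix (or list of two length-2
#'   vectors): each row is `(dof_halfwidth_um, psi_max_rad)`.
#' @return A `defocus_model` with elements `z0` (um) and `curvature` (`C`,
#'   um radians); supports [predict()] with argument `dof_halfwidth`.
#' @examples
#' m <- fit_defocus_model(rbind(c(12.5, 110.20), c(25, 221.32)))
#' predict(m, dof_halfwidth = 37.5)  # ~333.4
#' @export
fit_defocus_model <- function(pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (!is.numeric(pairs) || nrow(pairs) != 2L || ncol(pairs) != 2L)
    stop("`pairs` must supply exactly two (dof_halfwidth, psi_max) pairs",
         call. = FALSE)
  d1 <- pairs[1, 1]; p1 <- pairs[1, 2]
  d2 <- pairs[2, 1]; p2 <- pairs[2, 2]
  if (d1 == d2)
    stop("degenerate system: the two half-widths must be distinct",
         call. = FALSE)
  if (sign(p1) != sign(p2) || p1 == 0 || p2 == 0)
    stop("degenerate system: psi_max values must be nonzero with equal sign",
         call. = FALSE)
  r <- p1 / p2
  z0 <- d1 * d2 * (r - 1) / (r * d2 - d1)
  if (!is.finite(z0) || z0 <= max(d1, d2))
    stop("degenerate system: no physical z0 solves the two pairs",
         call. = FALSE)
  curvature <- p1 * z0 * (z0 - d1) / d1
  structure(list(z0 = z0, curvature = curvature, pairs = pairs),
            class = "defocus_model")
}

#' @export
print.defocus_model <- function(x, ...) {
  cat(sprintf("Worst-case defocus model: z0 = %.1f um, C = %.4g um rad\n",
              x$z0, x$curvature))
  invisible(x)
}

#' @rdname fit_defocus_model
#' @param object A `defocus_model`.
#' @param dof_halfwidth Half-widths Delta (um) at which to evaluate psi_max.
#' @param ... Unused.
#' @export
predict.defocus_model <- function(object, dof_halfwidth, ...) {
  stopifnot(all(dof_halfwidth >= 0), all(dof_halfwidth < object$z0))
  object$curvature * dof_halfwidth /
    (object$z0 * (object$z0 - dof_halfwidth))
}
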