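# Sensor-image synthesis: linear convolution of a depth-independent ground
# truth with the depth/wavelength PSF, center crop, and additive sensor
# noise; plus the diopter-uniform depth schedule.

#' Depth schedule uniform in diopters
#'
#' Depth planes whose reciprocals `1/z` are uniformly spaced (`grid` mode,
#' both endpoints included) or uniformly sampled (`random` mode) over
#' `[1/(z0 + Delta), 1/(z0 - Delta)]`, matching the linearity of the defocus
#' phase in `1/z`.
#'
#' @param k_depths Number of planes K (>= 1). The published operating points
#'   use K = 5 for 25 and 50 um targets and K = 7 for 75 um (see
#'   [default_k_depths()]).
#' @param z0 Nominal focus in um.
#' @param dof_halfwidth Half the target depth range, um (< z0).
#' @param mode `"grid"` or `"random"`.
#' @return Depths in um, ascending.
#' @export
sample_depths <- function(k_depths, z0, dof_halfwidth,
                          mode = c("grid", "random")) {
  mode <- match.arg(mode)
  stopifnot(k_depths >= 1)
  if (dof_halfwidth >= z0)
    stop("dof_halfwidth must be smaller than z0", call. = FALSE)
  if (dof_halfwidth == 0 || k_depths == 1) return(z0)
  s_lo <- 1 / (z0 + dof_halfwidth)
  s_hi <- 1 / (z0 - dof_halfwidth)
  s <- switch(mode,
              grid = seq(s_lo, s_hi, length.out = k_depths),
              random = stats::runif(k_depths, s_lo, s_hi))
  sort(1 / s)
}

#' Published depth-plane counts per DoF target
#'
#' K = 5 training depths for the 25 and 50 um targets, K = 7 for 75 um.
#' @param target_dof Target DoF in um.
#' @return Integer K.
#' @export
default_k_depths <- function(target_dof) {
  ifelse(target_dof > 50, 7L, 5L)
}

#' Add sensor noise
#'
#' Additive Gaussian (default, zero-mean) or Poisson-Gaussian shot noise
#' with a configurable photon budget. Reproducible under the caller's RNG
#' seed; the expectation is preserved for both models.
#'
#' @param img Numeric array.
#' @param model `"gaussian"` or `"poisson_gaussian"`.
#' @param sd Read-noise standard deviation in normalized units (>= 0).
#' @param photons Photon count at unit intensity (Poisson-Gaussian only).
#' @return Noisy array of the same shape (not clipped; clipping is left to
#'   downstream configuration).
#' @export
add_noise <- function(img, model = c("gaussian", "poisson_gaussian"),
                      sd = 0.01, photons = 1000) {
  model <- match.arg(model)
  if (sd < 0) stop("noise sd must be non-negative", call. = FALSE)
  out <- img
  if (model == "poisson_gaussian")
    out <- array(stats::rpois(length(img), pmax(img, 0) * photons) / photons,
                 dim(img) %||% length(img))
  if (sd > 0)
    out <- out + array(stats::rnorm(length(img), 0, sd),
                       dim(img) %||% length(img))
  out
}

#' Simulate a sensor image
#'
#' Per channel, the depth-independent ground truth is convolved (full linear
#' convolution) with the unit-sum PSF of the assigned depth, center-cropped
#' to `out_size` to suppress boundary artifacts, and sensor noise is added:
#' `SI = GT (*) PSF + eta`.
#'
#' @param gt Ground-truth patch, `[H, W, C]` array in `[0, 1]` (one matrix
#'   is treated as one channel). Must be at least
#'   `out_size + psf_size - 1` on each side for a fully valid crop.
#' @param psfs List of per-channel PSF matrices (unit sum), or a
#'   [psf_stack()] together with `depth_index`.
#' @param out_size Output side length; defaults to the fully valid region
#'   `nrow(gt) - psf_size + 1`.
#' @param depth_index When `psfs` is a `psf_stack`: which depth slice.
#' @param noise_sd,noise_model Passed to [add_noise()]; `noise_sd = 0`
#'   disables noise.
#' @return `[out_size, out_size, C]` array with attributes `depth` (if
#'   available) and `noise`.
#' @export
render_sensor <- function(gt, psfs, out_size = NULL, depth_index = 1L,
                          noise_sd = 0.01,
                          noise_model = "gaussian") {
  if (is.matrix(gt)) gt <- array(gt, c(dim(gt), 1L))
  C <- dim(gt)[3]
  depth <- NA_real_
  if (inherits(psfs, "psf_stack")) {
    if (length(psfs$wavelengths) != C)
      stop("channel count of gt does not match the PSF stack wavelengths",
           call. = FALSE)
    depth <- psfs$depths[depth_index]
    psfs <- lapply(seq_len(C), function(li) psfs$values[, , depth_index, li])
  }
  if (length(psfs) != C)
    stop("need one PSF per channel", call. = FALSE)
  nk <- nrow(psfs[[1]])
  if (is.null(out_size)) out_size <- nrow(gt) - nk + 1
  if (out_size < 1 || nrow(gt) < out_size)
    stop("ground truth smaller than requested output", call. = FALSE)
  out <- array(0, c(out_size, out_size, C))
  for (c in seq_len(C))
    out[, , c] <- ad_value(ad_conv_crop(gt[, , c], psfs[[c]], out_size))
  out <- add_noise(out, model = noise_model, sd = noise_sd)
  attr(out, "depth") <- depth
  attr(out, "noise") <- list(model = noise_model, sd = noise_sd)
  out
}

#' Ground-truth patch size needed for a given output size
#'
#' `out_size + psf_size - 1`: the patch margin consumed by the valid center
#' crop of the full convolution.
#' @param out_size Sensor patch side after cropping.
#' @param psf_size PSF support side.
#' @return Required ground-truth side length.
#' @export
gt_size_for <- function(out_size, psf_size) out_size + psf_size - 1L
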