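# Image-fidelity metrics (PSNR, SSIM), Gaussian-fit PSF metrology, and the
# multi-term reconstruction loss used for end-to-end training.

#' Gaussian convolution kernel
#'
#' @param size Odd kernel side length.
#' @param sigma Standard deviation in pixels.
#' @return `size x size` matrix summing to 1.
#' @export
gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# same-size convolution of a matrix with a centered kernel (zero padding)
.blur2 <- function(x, k) {
  nk <- nrow(k)
  full <- conv_full_fft(x, k)
  off <- floor(nk / 2)
  full[off + seq_len(nrow(x)), off + seq_len(ncol(x)), drop = FALSE]
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB; identical images give `Inf`
#' (excluded from averages by the evaluation helpers).
#'
#' @param a,b Images of identical shape.
#' @param peak Peak signal value (default 1).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = 1) {
  stopifnot(length(a) == length(b))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' The standard windowed formulation with an 11 x 11 Gaussian window
#' (sigma 1.5), stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' at data range `L`, and sample statistics replaced by window-weighted
#' moments. The similarity map's border of half a window is cropped before
#' averaging so padding never enters the score.
#'
#' @param a,b Single-channel matrices or `[H, W, C]` arrays (channel scores
#'   are averaged).
#' @param data_range Dynamic range `L` (default 1).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 1) {
  stopifnot(all(dim(a) == dim(b)))
  if (length(dim(a)) == 3L) {
    return(mean(vapply(seq_len(dim(a)[3]),
                       function(c) ssim(a[, , c], b[, , c], data_range),
                       numeric(1))))
  }
  k <- gaussian_kernel(11L, 1.5)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- .blur2(a, k); mu_b <- .blur2(b, k)
  va <- .blur2(a * a, k) - mu_a^2
  vb <- .blur2(b * b, k) - mu_b^2
  cab <- .blur2(a * b, k) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  pad <- 5L
  idx_r <- (pad + 1):(nrow(a) - pad)
  idx_c <- (pad + 1):(ncol(a) - pad)
  mean(s[idx_r, idx_c])
}

#' Loss weights for the multi-term reconstruction loss
#'
#' Per-(depth, wavelength) patch the loss is
#' `w_rmse * RMSE + w_ssim * (1 - SSIM) + w_grad * l_grad + w_lp *
#' MSE(LP(oi), LP(gt))` where `l_grad` matches horizontal and vertical
#' finite differences and `LP` is a fixed Gaussian low-pass filter. RMSE
#' dominates under the default weighting.
#'
#' @param w_rmse,w_ssim,w_grad,w_lp Non-negative term weights.
#' @param lp_size,lp_sigma Low-pass kernel size and width (pixels).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_rmse = 1.0, w_ssim = 0.2, w_grad = 0.1,
                         w_lp = 0.1, lp_size = 9L, lp_sigma = 1.5) {
  stopifnot(w_rmse >= 0, w_ssim >= 0, w_grad >= 0, w_lp >= 0)
  if (w_rmse + w_ssim + w_grad + w_lp <= 0)
    stop("at least one loss weight must be positive", call. = FALSE)
  structure(list(w_rmse = w_rmse, w_ssim = w_ssim, w_grad = w_grad,
                 w_lp = w_lp, lp_size = as.integer(lp_size),
                 lp_sigma = lp_sigma),
            class = "loss_weights")
}

# SSIM composed from tape ops on a [H, W, C] pair; returns the mean over
# channels of the border-cropped similarity map.
.ad_ssim <- function(oi, gt, data_range = 1) {
  d <- dim(ad_value(oi))
  k <- gaussian_kernel(11L, 1.5)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- ad_fixed_blur(oi, k); mu_b <- ad_fixed_blur(gt, k)
  va <- ad_fixed_blur(oi * oi, k) - mu_a * mu_a
  vb <- ad_fixed_blur(gt * gt, k) - mu_b * mu_b
  cab <- ad_fixed_blur(oi * gt, k) - mu_a * mu_b
  s <- ((2 * (mu_a * mu_b) + C1) * (2 * cab + C2)) /
    ((mu_a * mu_a + mu_b * mu_b + C1) * (va + vb + C2))
  pad <- 5L
  s <- ad_crop3(s, (pad + 1):(d[1] - pad), (pad + 1):(d[2] - pad))
  ad_mean(ad_cmean(s))
}

#' Multi-term reconstruction loss
#'
#' Average over spectral channels (and, via [Reduce()] by the caller, over
#' depths) of the weighted sum of RMSE, structural dissimilarity, gradient
#' matching and low-pass MSE. Works on plain arrays (returns a numeric
#' scalar) or tape nodes (returns a scalar `advar` through which the whole
#' optical chain can be differentiated). Equals 0 exactly iff `oi == gt`.
#'
#' @param oi,gt Reconstruction and ground truth, `[H, W, C]` arrays or tape
#'   nodes of that shape.
#' @param weights A [loss_weights()].
#' @return Scalar loss (numeric or `advar` matching the input type).
#' @export
recon_loss <- function(oi, gt, weights = loss_weights()) {
  was_ad <- is_ad(oi) || is_ad(gt)
  d <- dim(ad_value(oi))
  if (!identical(dim(ad_value(gt)), d))
    stop("shape mismatch between reconstruction and ground truth",
         call. = FALSE)
  if (length(d) == 2L) {
    oi <- ad_reshape(if (is_ad(oi)) oi else ad_const(oi), c(d, 1L))
    gt <- ad_reshape(if (is_ad(gt)) gt else ad_const(gt), c(d, 1L))
    d <- c(d, 1L)
  } else {
    if (!is_ad(oi)) oi <- ad_const(oi)
    if (!is_ad(gt)) gt <- ad_const(gt)
  }
  w <- weights
  diff <- oi - gt
  total <- NULL
  add <- function(a, b) if (is.null(a)) b else a + b
  if (w$w_rmse > 0) {
    # epsilon keeps the sqrt gradient finite at oi == gt; the offset makes
    # the term exactly zero there
    mse_c <- ad_cmean(diff * diff)
    total <- add(total, w$w_rmse * ad_mean(sqrt(mse_c + 1e-24) - 1e-12))
  }
  if (w$w_ssim > 0)
    total <- add(total, w$w_ssim * (1 - .ad_ssim(oi, gt)))
  if (w$w_grad > 0) {
    gh <- ad_mean(abs(ad_diff_h(oi) - ad_diff_h(gt)))
    gv <- ad_mean(abs(ad_diff_v(oi) - ad_diff_v(gt)))
    total <- add(total, w$w_grad * (gh + gv))
  }
  if (w$w_lp > 0) {
    lk <- gaussian_kernel(w$lp_size, w$lp_sigma)
    dl <- ad_fixed_blur(oi, lk) - ad_fixed_blur(gt, lk)
    total <- add(total, w$w_lp * ad_mean(ad_cmean(dl * dl)))
  }
  if (was_ad) total else ad_value(total)
}

#' Lateral FWHM by 2-D Gaussian fitting
#'
#' Fits an elliptical 2-D Gaussian (amplitude, center, per-axis sigma,
#' constant offset) to a PSF image by nonlinear least squares and reports
#' the full width at half maximum per axis, `FWHM = 2 sqrt(2 ln 2) sigma`,
#' in physical units.
#'
#' @param psf_image Matrix with a single dominant peak.
#' @param pitch Pixel pitch in um.
#' @return List with `fwhm_x`, `fwhm_y` (um), `sigma_x`, `sigma_y` (px),
#'   `center` (px), `amplitude`, `offset`, `converged`, `resid_norm`.
#' @examples
#' g <- outer(dnorm(1:31, 16, 2), dnorm(1:31, 16, 2))
#' fwhm_gaussian_fit(g, pitch = 0.1)$fwhm_x  # 2 sqrt(2 log 2) * 2 px * 0.1
#' @export
fwhm_gaussian_fit <- function(psf_image, pitch = 1) {
  stopifnot(is.matrix(psf_image), pitch > 0)
  H <- nrow(psf_image); W <- ncol(psf_image)
  pk <- unname(which(psf_image == max(psf_image), arr.ind = TRUE)[1, ])
  df <- data.frame(
    x = rep(seq_len(W), each = H),
    y = rep(seq_len(H), times = W),
    v = as.vector(psf_image)
  )
  # moment-based starting sigmas around the peak
  w0 <- pmax(psf_image - stats::median(psf_image), 0)
  sx0 <- sqrt(sum(w0 * (df$x - pk[2])^2) / sum(w0))
  sy0 <- sqrt(sum(w0 * (df$y - pk[1])^2) / sum(w0))
  start <- list(A = max(psf_image) - min(psf_image),
                x0 = pk[2], y0 = pk[1],
                sx = max(sx0, 0.5), sy = max(sy0, 0.5),
                off = min(psf_image))
  fit <- try(minpack.lm::nlsLM(
    v ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))) + off,
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(fwhm_x = NA_real_, fwhm_y = NA_real_, converged = FALSE,
                resid_norm = NA_real_))
  }
  cf <- stats::coef(fit)
  k <- 2 * sqrt(2 * log(2))
  list(
    fwhm_x = k * abs(cf[["sx"]]) * pitch,
    fwhm_y = k * abs(cf[["sy"]]) * pitch,
    sigma_x = abs(cf[["sx"]]), sigma_y = abs(cf[["sy"]]),
    center = c(x = cf[["x0"]], y = cf[["y0"]]),
    amplitude = cf[["A"]], offset = cf[["off"]],
    converged = fit$convInfo$isConv %||% TRUE,
    resid_norm = sqrt(sum(stats::resid(fit)^2))
  )
}
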