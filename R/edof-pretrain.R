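# MTF-guided extended depth-of-field pre-optimization of the meta-optic
# alone: push the DC-normalized radial MTF toward a target passband at every
# depth and wavelength, aggregating depth errors with a log-sum-exp
# (soft-max) and channel scores with a focus-weighted log-sum-exp.

#' EDoF objective configuration
#'
#' @param rho_cut Passband cutoff in normalized frequency (0, 1].
#' @param alpha_lse Sharpness inside the depth exponent.
#' @param beta_lse Depth-aggregation coefficient (large values approach the
#'   worst-case depth, small values the mean over depths). Defaults equal to
#'   `alpha_lse`, making the operator the standard soft-max in the large
#'   limit.
#' @param eta_lse Channel-aggregation coefficient.
#' @param lambda_focus Weight in `[0, 1]` on the currently limiting channel.
#' @param epochs Pre-optimization epochs (default 30).
#' @param learning_rate Adam step size in nm per epoch on the width
#'   perturbation.
#' @return An `edof_config`.
#' @export
edof_config <- function(rho_cut = 0.5, alpha_lse = 50, beta_lse = alpha_lse,
                        eta_lse = 10, lambda_focus = 0.5, epochs = 30L,
                        learning_rate = 2) {
  stopifnot(rho_cut > 0, rho_cut <= 1, alpha_lse > 0, beta_lse > 0,
            eta_lse > 0, lambda_focus >= 0, lambda_focus <= 1, epochs >= 1,
            learning_rate > 0)
  structure(list(rho_cut = rho_cut, alpha_lse = alpha_lse,
                 beta_lse = beta_lse, eta_lse = eta_lse,
                 lambda_focus = lambda_focus, epochs = as.integer(epochs),
                 learning_rate = learning_rate),
            class = "edof_config")
}

#' Target passband
#'
#' `T(rho) = 1` for `rho <= rho_cut`, else 0, evaluated on the given MTF
#' bins.
#'
#' @param rho Normalized-frequency bin centers in `[0, 1]`.
#' @param rho_cut Cutoff.
#' @return 0/1 vector over the bins.
#' @export
target_passband <- function(rho, rho_cut = 0.5) {
  stopifnot(all(rho >= 0))
  as.numeric(rho <= rho_cut)
}

# numerically stable log-sum-exp
.lse <- function(a) {
  m <- max(a)
  m + log(sum(exp(a - m)))
}

#' Per-wavelength EDoF depth aggregation
#'
#' `(1 / beta) * log sum_z exp(alpha * ||M(., z) - T||_1)` where the L1
#' deviation is the mean over radial bins (grid-size independent). Large
#' `beta` emphasizes the worst-case depth; small `beta` the average.
#'
#' @param m Matrix of MTF values, depths in rows, radial bins in columns
#'   (or a list of per-depth [mtf_radial()] profiles restricted to
#'   `rho <= 1`).
#' @param target Passband values over the same bins.
#' @param cfg An [edof_config()].
#' @return Scalar channel loss.
#' @export
edof_channel_loss <- function(m, target, cfg = edof_config()) {
  if (is.list(m))
    m <- do.call(rbind, lapply(m, function(p) p$value[p$rho <= 1]))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (nrow(m) == 0) stop("empty depth set", call. = FALSE)
  if (ncol(m) != length(target))
    stop("MTF profiles and target do not share binning", call. = FALSE)
  errs <- rowMeans(abs(sweep(m, 2, target)))
  .lse(cfg$alpha_lse * errs) / cfg$beta_lse
}

#' Across-channel EDoF aggregation
#'
#' `lambda_focus * L_max + (1 - lambda_focus) * (1/eta) log sum exp(eta L)`,
#' placing extra weight on the currently limiting channel.
#'
#' @param channel_losses Per-wavelength scalars.
#' @param cfg An [edof_config()].
#' @return Scalar total loss.
#' @export
edof_total_loss <- function(channel_losses, cfg = edof_config()) {
  stopifnot(length(channel_losses) >= 1)
  cfg$lambda_focus * max(channel_losses) +
    (1 - cfg$lambda_focus) * .lse(cfg$eta_lse * channel_losses) / cfg$eta_lse
}

# ---- differentiable PSF -> radial MTF chain ------------------------------

# precomputed binning context for a grid: bin map in *unshifted* FFT layout
.mtf_bins <- function(grid) {
  n <- grid$n
  ctr <- floor(n / 2) + 1
  idx <- seq_len(n) - ctr
  r <- sqrt(outer(idx^2, idx^2, `+`))
  bin <- round(r) + 1L                      # shifted layout, 1-based
  rho <- (seq_len(max(bin)) - 1L) * grid$ds / grid$pupil_diameter
  keep <- rho <= 1
  binmap <- ifftshift2(bin)                  # align with unshifted fft output
  binmap[binmap > max(which(keep))] <- 0L
  list(bin = binmap, n_bins = max(which(keep)), rho = rho[keep])
}

# differentiable radial MTF of a unit-sum PSF node (DC-normalized by
# construction since the PSF is normalized on the tape)
.ad_mtf_radial <- function(psf_node, bins) {
  m <- ad_fft_mag2(psf_node)
  ad_binmean(m, bins$bin, bins$n_bins)
}

# differentiable mean-L1 deviation of one (z, lambda) MTF from the target
.ad_mtf_err <- function(phase_node, mask, bins, target) {
  q <- ad_psf_intensity(phase_node, mask)
  p <- q / ad_sum(q)
  prof <- .ad_mtf_radial(p, bins)
  ad_mean(abs(prof - target))
}

# per-(depth, wavelength) mean-L1 MTF deviations for a numeric design state
#' MTF deviations from the passband target
#'
#' For each depth and wavelength, the mean absolute deviation of the
#' DC-normalized radial MTF from the target passband — the quantity the
#' pre-optimization aggregates. Useful for inspecting how uniformly a design
#' covers the depth range (its standard deviation across depth shrinks as
#' the MTF becomes depth-stable).
#'
#' @param design A [metaoptic_design()] (or `NULL` for the conventional
#'   zero-modulation system).
#' @param lib Unit-cell library (ignored when `design` is `NULL`).
#' @param config An [optical_config()].
#' @param depths Depth planes in um.
#' @param grid A [make_pupil()] grid.
#' @param cfg An [edof_config()] (for `rho_cut`).
#' @return Matrix of deviations, depths in rows, wavelengths in columns.
#' @export
mtf_deviations <- function(design, lib, config, depths, grid,
                           cfg = edof_config()) {
  bins <- .mtf_bins(grid)
  target <- target_passband(bins$rho, cfg$rho_cut)
  out <- matrix(0, length(depths), length(config$wavelengths))
  for (li in seq_along(config$wavelengths)) {
    lam <- config$wavelengths[li]
    mod <- if (is.null(design)) matrix(0, grid$n, grid$n)
           else metaoptic_phase(design, lib, lam, grid)
    for (zi in seq_along(depths)) {
      psi <- defocus_coefficient(depths[zi], config$nominal_focus, lam,
                                 config$pupil_diameter)
      phase <- defocus_phase(grid, psi) + mod
      err <- .ad_mtf_err(ad_const(phase), grid$mask, bins, target)
      out[zi, li] <- ad_value(err)
    }
  }
  dimnames(out) <- list(paste0("z", signif(depths, 6)),
                        paste0(config$wavelengths, "nm"))
  out
}

#' Pre-optimize the meta-optic for extended depth of field
#'
#' Gradient descent (Adam) on the width perturbation only, minimizing the
#' frequency-domain EDoF objective over the simulated PSF-to-MTF chain at
#' every configured depth and wavelength. Returns the optimized widths as
#' the initialization `gamma_init` for subsequent end-to-end training,
#' together with the per-epoch loss history.
#'
#' @param design Starting [metaoptic_design()] (flat-pi by default).
#' @param lib Unit-cell library.
#' @param config An [optical_config()].
#' @param depths Depth planes in um (typically [sample_depths()]).
#' @param grid A [make_pupil()] grid.
#' @param cfg An [edof_config()].
#' @param seed Integer seed (the objective is deterministic; the seed fixes
#'   any downstream stochastic use of the result).
#' @return An `edof_pretrain` fit: `design` (with `gamma_init` set to the
#'   optimized widths and `delta_gamma` zeroed), `history` (loss per epoch,
#'   including the initial value at epoch 0), `initial_design`, `cfg`.
#' @export
pretrain_metaoptic <- function(design, lib, config, depths, grid,
                               cfg = edof_config(), seed = 1L) {
  stopifnot(inherits(design, "metaoptic_design"),
            inherits(cfg, "edof_config"))
  set.seed(seed)
  bins <- .mtf_bins(grid)
  target <- target_passband(bins$rho, cfg$rho_cut)
  nl <- length(config$wavelengths)
  defoc <- lapply(seq_along(depths), function(zi)
    lapply(seq_len(nl), function(li)
      defocus_phase(grid, defocus_coefficient(
        depths[zi], config$nominal_focus, config$wavelengths[li],
        config$pupil_diameter))))

  objective <- function(delta_node) {
    ch <- vector("list", nl)
    for (li in seq_len(nl)) {
      phi_m <- metaoptic_phase(design, lib, config$wavelengths[li], grid,
                               delta_gamma = delta_node)
      errs <- vector("list", length(depths))
      for (zi in seq_along(depths))
        errs[[zi]] <- .ad_mtf_err(defoc[[zi]][[li]] + phi_m, grid$mask,
                                  bins, target)
      # (1/beta) log sum_z exp(alpha * err_z)
      s <- NULL
      for (zi in seq_along(depths)) {
        e <- exp(cfg$alpha_lse * errs[[zi]])
        s <- if (is.null(s)) e else s + e
      }
      ch[[li]] <- log(s) / cfg$beta_lse
    }
    lmax <- which.max(vapply(ch, ad_value, numeric(1)))
    se <- NULL
    for (li in seq_len(nl)) {
      e <- exp(cfg$eta_lse * ch[[li]])
      se <- if (is.null(se)) e else se + e
    }
    cfg$lambda_focus * ch[[lmax]] +
      (1 - cfg$lambda_focus) * (log(se) / cfg$eta_lse)
  }

  delta <- design$delta_gamma
  opt <- adam_init(list(delta))
  history <- numeric(cfg$epochs + 1)
  loss0 <- objective(ad_const(delta))
  history[1] <- ad_value(loss0)
  for (ep in seq_len(cfg$epochs)) {
    node <- ad_param(delta)
    loss <- objective(node)
    if (!is.finite(ad_value(loss)))
      stop("non-finite EDoF loss at epoch ", ep, call. = FALSE)
    ad_backward(loss)
    g <- node$grad
    if (is.null(g)) g <- delta * 0  # fully clamped: zero gradient
    step <- adam_step(opt, list(g), lr = cfg$learning_rate)
    delta <- delta + step[[1]]
    # clamp so effective widths respect the bounds after every step
    delta <- pmin(pmax(delta, design$width_bounds[1] - design$gamma_init),
                  design$width_bounds[2] - design$gamma_init)
    history[ep + 1] <- ad_value(loss)
  }
  out_design <- design
  out_design$gamma_init <- as.numeric(effective_widths(design, delta))
  out_design$delta_gamma <- numeric(length(delta))
  structure(list(design = out_design, history = history,
                 initial_design = design, cfg = cfg, depths = depths,
                 seed = seed),
            class = "edof_pretrain")
}

#' @export
print.edof_pretrain <- function(x, ...) {
  cat(sprintf(
    "EDoF pre-optimization: %d epochs, loss %.4f -> %.4f (%d depths)\n",
    length(x$history) - 1, x$history[1], x$history[length(x$history)],
    length(x$depths)))
  invisible(x)
}

#' Cubic-phase radial initialization (baseline)
#'
#' Maps a cubic radial phase profile `strength * rho^3` to nanopillar widths
#' by nearest-phase inversion of the library at the reference wavelength.
#' Provided as an untuned baseline; under strong defocus it produces heavily
#' blurred sensor images compared to the flat-pi start.
#'
#' @param lib Unit-cell library.
#' @param n_bins Radial sample count.
#' @param strength Phase at the aperture edge, radians.
#' @param reference_wavelength Wavelength (nm) for the inversion.
#' @return Width vector (nm) usable as `gamma_init`.
#' @export
cubic_init <- function(lib, n_bins, strength = 2 * pi,
                       reference_wavelength = min(lib$wavelengths)) {
  li <- .lib_col(lib, reference_wavelength)
  ph <- lib$phases[, li]
  rho <- seq(0, 1, length.out = n_bins)
  want <- ph[1] + (strength * rho^3) %% (max(ph) - min(ph))
  vapply(want, function(p) lib$widths[which.min(abs(ph - p))], numeric(1))
}
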