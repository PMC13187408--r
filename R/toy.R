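# A desk-scale co-design experiment: small pupil grid, two emission
# channels, three training depths. Mirrors the full pipeline (flat-pi
# initialization, MTF-guided pre-optimization, end-to-end joint training,
# ablation arms) at sizes where every stage runs in seconds to minutes on a
# single CPU. The vignette documents the choices behind these sizes.

#' Toy optical configuration
#'
#' Two emission channels (433 and 681 nm), a 1.4 mm pupil and a 100 um
#' symmetric depth range around a 3 mm nominal focus, chosen so the
#' worst-case defocus coefficient is about 20 rad — the regime of moderate
#' wavefront-coding studies — while PSFs stay well-sampled on a 64 x 64
#' pupil grid.
#'
#' @param dof_halfwidth Half depth range in um (default 50).
#' @return An [optical_config()].
#' @export
toy_optical_config <- function(dof_halfwidth = 50) {
  optical_config(
    numerical_aperture = 1.1,
    wavelengths = c(433, 681),
    pupil_diameter = 1.397,
    nominal_focus = 3000,
    magnification = 60,
    sensor_pitch = 6.5,
    sensor_counts = c(512L, 512L),
    target_dof = 2 * dof_halfwidth
  )
}

#' Build the toy system components
#'
#' The pupil grid (64 x 64, aperture spanning half the grid), a surrogate
#' unit-cell library restricted to the toy wavelengths, a flat-pi meta-optic
#' design with 8 radial bins, and a compact reconstructor
#' (widths 8-16-32).
#'
#' @param channels Channel count (2 for the toy multispectral system).
#' @param n Pupil grid side.
#' @param n_bins Radial width-vector length.
#' @param net_widths Encoder widths of the toy network.
#' @param seed Seed for network initialization.
#' @return List with `config`, `grid`, `lib`, `design`, `net`.
#' @export
toy_system <- function(channels = 2L, n = 64L, n_bins = 8L,
                       net_widths = c(8L, 16L, 32L), seed = 1L) {
  config <- toy_optical_config()
  if (channels == 1L) config$wavelengths <- 601
  D_um <- config$pupil_diameter * 1000
  grid <- make_pupil(n, 2 * D_um / n, D_um)
  lib <- surrogate_library(wavelengths = config$wavelengths)
  design <- metaoptic_design(lib, n_bins)
  net <- build_reconstructor(
    reconstructor_spec(channels = channels, widths = net_widths),
    seed = seed)
  list(config = config, grid = grid, lib = lib, design = design, net = net)
}

#' Toy phantom set
#'
#' Two-channel phantoms (nuclei-like and filament archetypes) sized for a
#' valid 64 x 64 sensor crop after convolution with the 64 x 64 PSF.
#'
#' @param n_patches Number of patches.
#' @param channels Channel count.
#' @param out_size Sensor patch side.
#' @param psf_size PSF support side.
#' @param seed Base seed; patch i uses `seed * 1000 + i`.
#' @return List of `[gt, gt, channels]` arrays.
#' @export
toy_phantoms <- function(n_patches, channels = 2L, out_size = 64L,
                         psf_size = 64L, seed = 1L) {
  size <- gt_size_for(out_size, psf_size)
  lapply(seq_len(n_patches), function(i)
    generate_phantom(phantom_recipe(kind = "mixed", size = size,
                                    channels = channels, density = 1.6,
                                    seed = seed * 1000L + i)))
}

#' Run the scaled-down co-design experiment
#'
#' The full pipeline at desk scale: (1) MTF-guided pre-optimization of the
#' meta-optic from the flat-pi start (30 epochs); (2) end-to-end joint
#' training of meta-optic and network; (3) an ablation arm with the
#' meta-optic removed (conventional optics + its own trained network) and
#' one with the network removed (pre-optimized meta-optic, raw sensor
#' output); (4) evaluation of all three arms on held-out phantoms across a
#' diopter-uniform depth grid spanning the toy depth range.
#'
#' @param seed Master seed; all stages derive from it.
#' @param steps End-to-end training steps per trained arm (<= a few
#'   hundred).
#' @param pretrain_epochs Pre-optimization epochs.
#' @param n_depths Training depth planes.
#' @param n_train,n_test Phantom counts.
#' @param eval_planes Depth planes for evaluation.
#' @param lr_network Network learning rate for the short toy schedule.
#' @param noise_sd Sensor noise level.
#' @return List: `system` (components), `pretrain` (the [pretrain_metaoptic()]
#'   fit), `dev_flat`, `dev_pretrained` ([mtf_deviations()] matrices for the
#'   flat-pi and pre-optimized designs), `fit_full`, `fit_no_meta`
#'   (codesign fits), `arms` (named [evaluate_system()] tables), `summary`
#'   (depth-averaged PSNR per arm and the across-depth PSNR standard
#'   deviations of the full and conventional arms).
#' @export
toy_codesign <- function(seed = 1L, steps = 250L, pretrain_epochs = 30L,
                         n_depths = 3L, n_train = 6L, n_test = 3L,
                         eval_planes = 5L, lr_network = 2e-3,
                         noise_sd = 0.01) {
  sys <- toy_system(seed = seed)
  config <- sys$config; grid <- sys$grid; lib <- sys$lib
  halfwidth <- config$target_dof / 2
  depths <- sample_depths(n_depths, config$nominal_focus, halfwidth, "grid")
  cfg <- edof_config(epochs = pretrain_epochs)

  dev_flat <- mtf_deviations(sys$design, lib, config, depths, grid, cfg)
  pre <- pretrain_metaoptic(sys$design, lib, config, depths, grid, cfg,
                            seed = seed)
  dev_pre <- mtf_deviations(pre$design, lib, config, depths, grid, cfg)

  out_size <- 64L
  train_data <- toy_phantoms(n_train, out_size = out_size,
                             psf_size = grid$n, seed = seed)
  test_data <- toy_phantoms(n_test, out_size = out_size,
                            psf_size = grid$n, seed = seed + 500L)
  tc <- train_config(lr_network = lr_network, noise_sd = noise_sd)

  fit_full <- train_end_to_end(config, grid, pre$design, lib, sys$net,
                               train_data, out_size, n_depths, halfwidth,
                               steps, tc, seed = seed)
  net_conv <- build_reconstructor(
    reconstructor_spec(channels = length(config$wavelengths),
                       widths = sys$net$spec$widths), seed = seed)
  fit_no_meta <- train_end_to_end(config, grid, NULL, lib, net_conv,
                                  train_data, out_size, n_depths, halfwidth,
                                  steps, tc, seed = seed)

  eval_depths <- sample_depths(eval_planes, config$nominal_focus, halfwidth,
                               "grid")
  arms <- list(
    full = evaluate_system(config, grid, fit_full$design, lib, fit_full$net,
                           test_data, eval_depths, out_size, noise_sd,
                           seed = seed),
    no_metaoptic = evaluate_system(config, grid, NULL, lib, fit_no_meta$net,
                                   test_data, eval_depths, out_size,
                                   noise_sd, seed = seed),
    metaoptic_only = evaluate_system(config, grid, pre$design, lib, NULL,
                                     test_data, eval_depths, out_size,
                                     noise_sd, seed = seed)
  )
  depth_mean <- function(df) mean(tapply(df$psnr, df$depth, mean))
  depth_sd <- function(df) stats::sd(tapply(df$psnr, df$depth, mean))
  summary <- list(
    psnr_full = depth_mean(arms$full),
    psnr_no_metaoptic = depth_mean(arms$no_metaoptic),
    psnr_metaoptic_only = depth_mean(arms$metaoptic_only),
    psnr_sd_full = depth_sd(arms$full),
    psnr_sd_conventional = depth_sd(arms$no_metaoptic),
    pretrain_initial = pre$history[1],
    pretrain_final = pre$history[length(pre$history)],
    flatness_flat = mean(apply(dev_flat, 2, stats::sd)),
    flatness_pretrained = mean(apply(dev_pre, 2, stats::sd))
  )
  list(system = sys, pretrain = pre, dev_flat = dev_flat,
       dev_pretrained = dev_pre, fit_full = fit_full,
       fit_no_meta = fit_no_meta, arms = arms, summary = summary,
       depths = depths, eval_depths = eval_depths)
}
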