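# End-to-end co-design: the two-optimizer training loop (optical parameters
# and network parameters, network-only weight regularization), evaluation
# depth sweeps and the ablation harness.

#' Training configuration
#'
#' Two Adam optimizers: one for the optical width perturbation (no weight
#' regularization) and one for the network with an L2 penalty
#' `beta_wd * ||theta||^2` added to the objective (gradient `2 beta_wd
#' theta`); the optical parameters are never regularized.
#'
#' @param lr_optics Optical learning rate (nm per step; default 1e-2).
#' @param lr_network Network learning rate (default 1e-4).
#' @param beta_wd Network weight-decay coefficient (default 1e-3).
#' @param augment Apply random flips/rotations/brightness to each training
#'   patch.
#' @param noise_sd Sensor read-noise standard deviation in normalized units.
#' @param depths_per_step Number of depth planes accumulated per step (the
#'   schedule is sampled without replacement each step).
#' @return A `train_config`.
#' @export
train_config <- function(lr_optics = 1e-2, lr_network = 1e-4,
                         beta_wd = 1e-3, augment = TRUE, noise_sd = 0.01,
                         depths_per_step = 1L) {
  stopifnot(lr_optics > 0, lr_network > 0, beta_wd >= 0,
            depths_per_step >= 1)
  structure(list(lr_optics = lr_optics, lr_network = lr_network,
                 beta_wd = beta_wd, augment = augment, noise_sd = noise_sd,
                 depths_per_step = as.integer(depths_per_step)),
            class = "train_config")
}

# differentiable sensor image for one channel at one depth
.ad_sensor_channel <- function(gt_c, phase, mask, out_size, noise_mat) {
  q <- ad_psf_intensity(phase, mask)
  p <- q / ad_sum(q)
  si <- ad_conv_crop(gt_c, p, out_size)
  if (!is.null(noise_mat)) si <- si + noise_mat
  si
}

# center crop of a [H, W, C] numeric array (alignment of ad_conv_crop)
.center_crop <- function(x, out_size) {
  nx <- dim(x)[1]
  off <- floor((nx - out_size) / 2)
  x[off + seq_len(out_size), off + seq_len(out_size), , drop = FALSE]
}

#' Jointly train the meta-optic and the reconstruction network
#'
#' Each step samples a ground-truth patch, assigns it to depth planes drawn
#' from the diopter-uniform schedule, simulates the per-channel PSFs from
#' the current width perturbation, renders noisy sensor images, reconstructs
#' them, and accumulates the multi-term loss over the sampled depth/channel
#' set. The loss is backpropagated through the network and the full optical
#' chain; both Adam optimizers step, the L2 penalty touching network
#' parameters only. Effective widths are re-clamped to the design bounds
#' after every optical step.
#'
#' @param config An [optical_config()].
#' @param grid A [make_pupil()] grid.
#' @param design A [metaoptic_design()], or `NULL` for the conventional
#'   (zero-modulation) system; with `NULL`, only the network trains.
#' @param lib Unit-cell library (ignored when `design` is `NULL`).
#' @param net A [build_reconstructor()] network (mutated: batch-norm running
#'   statistics update during training).
#' @param data List of ground-truth patches, each
#'   `[gt_size, gt_size, channels]` with
#'   `gt_size = out_size + grid$n - 1` (see [gt_size_for()]).
#' @param out_size Sensor/reconstruction patch side.
#' @param k_depths Number of depth planes in the training schedule.
#' @param dof_halfwidth Half the target depth range in um.
#' @param steps Training steps.
#' @param tc A [train_config()].
#' @param weights A [loss_weights()].
#' @param seed Integer seed (patch/depth sampling, noise, augmentation).
#' @param train_optics Freeze the optical optimizer when `FALSE`
#'   (`delta_gamma` is then bit-identical before and after).
#' @return A `codesign_fit`: updated `design`, `net`, `history`
#'   (data.frame of per-step loss and total objective), `depth_schedule`,
#'   `settings`.
#' @export
train_end_to_end <- function(config, grid, design, lib, net, data, out_size,
                             k_depths, dof_halfwidth, steps,
                             tc = train_config(), weights = loss_weights(),
                             seed = 1L, train_optics = !is.null(design)) {
  stopifnot(inherits(net, "reconstructor"), length(data) >= 1, steps >= 1)
  set.seed(seed)
  C <- net$spec$channels
  stopifnot(length(config$wavelengths) == C)
  schedule <- sample_depths(k_depths, config$nominal_focus, dof_halfwidth,
                            mode = "grid")
  n <- grid$n
  # fixed per-wavelength defocus phases at the schedule depths
  defoc <- lapply(schedule, function(z)
    lapply(config$wavelengths, function(lam)
      defocus_phase(grid, defocus_coefficient(z, config$nominal_focus, lam,
                                              config$pupil_diameter))))
  zero_mod <- matrix(0, n, n)
  opt_optic <- if (train_optics) adam_init(list(design$delta_gamma)) else NULL
  opt_net <- adam_init(net$params)
  history <- data.frame(step = seq_len(steps), loss = NA_real_,
                        objective = NA_real_)
  for (st in seq_len(steps)) {
    gt <- data[[sample.int(length(data), 1)]]
    if (tc$augment) gt <- augment(gt)
    zsel <- sample(seq_along(schedule),
                   min(tc$depths_per_step, length(schedule)))
    delta_node <- if (train_optics) ad_param(design$delta_gamma) else NULL
    params <- lapply(net$params, ad_param)
    loss <- NULL
    for (zi in zsel) {
      chans <- vector("list", C)
      for (ci in seq_len(C)) {
        phi_m <- if (is.null(design)) {
          zero_mod
        } else {
          metaoptic_phase(design, lib, config$wavelengths[ci], grid,
                          delta_gamma = delta_node %||% design$delta_gamma)
        }
        noise_mat <- if (tc$noise_sd > 0)
          matrix(stats::rnorm(out_size^2, 0, tc$noise_sd), out_size)
        else NULL
        chans[[ci]] <- .ad_sensor_channel(gt[, , ci],
                                          defoc[[zi]][[ci]] + phi_m,
                                          grid$mask, out_size, noise_mat)
      }
      si <- ad_stack3(chans)
      oi <- net_forward(net, si, params, training = TRUE)
      l <- recon_loss(oi, .center_crop(gt, out_size), weights)
      loss <- if (is.null(loss)) l else loss + l
    }
    loss <- loss / length(zsel)
    lval <- ad_value(loss)
    if (!is.finite(lval))
      stop("non-finite training loss at step ", st, call. = FALSE)
    ad_backward(loss)
    # network step with L2 penalty gradient (network parameters only)
    grads <- lapply(names(net$params), function(nm) {
      g <- params[[nm]]$grad
      if (is.null(g)) g <- net$params[[nm]] * 0
      g + 2 * tc$beta_wd * net$params[[nm]]
    })
    upd <- adam_step(opt_net, grads, lr = tc$lr_network)
    for (i in seq_along(net$params))
      net$params[[i]] <- net$params[[i]] + upd[[i]]
    # optical step, unregularized
    if (train_optics) {
      g <- delta_node$grad
      if (is.null(g)) g <- design$delta_gamma * 0
      du <- adam_step(opt_optic, list(g), lr = tc$lr_optics)
      delta <- design$delta_gamma + du[[1]]
      design$delta_gamma <- pmin(
        pmax(delta, design$width_bounds[1] - design$gamma_init),
        design$width_bounds[2] - design$gamma_init)
    }
    penalty <- tc$beta_wd *
      sum(vapply(net$params, function(p) sum(p^2), numeric(1)))
    history$loss[st] <- lval
    history$objective[st] <- lval + penalty
  }
  structure(list(design = design, net = net, history = history,
                 depth_schedule = schedule,
                 settings = list(tc = tc, weights = weights, seed = seed,
                                 out_size = out_size, steps = steps,
                                 dof_halfwidth = dof_halfwidth)),
            class = "codesign_fit")
}

#' @export
print.codesign_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "Co-design fit: %d steps, loss %.4f -> %.4f (mean of last 10%%)\n",
    nrow(h), h$loss[1],
    mean(utils::tail(h$loss, max(1, nrow(h) %/% 10)))))
  cat(sprintf("  depth schedule (um): %s\n",
              paste(signif(x$depth_schedule, 6), collapse = ", ")))
  invisible(x)
}

#' Evaluate an imaging system over phantoms and depths
#'
#' Simulates the measurement of each phantom at each depth through the
#' system's PSFs (meta-optic modulation included when a design is given),
#' reconstructs (identity when `net` is `NULL`: the raw sensor image,
#' clamped) and scores PSNR and SSIM per channel against the ground-truth
#' crop.
#'
#' @inheritParams train_end_to_end
#' @param phantoms List of ground-truth patches.
#' @param depths Depth planes in um.
#' @param noise_sd Sensor noise level.
#' @param seed RNG seed for the noise draws.
#' @return Data frame with columns `depth`, `channel`, `psnr`, `ssim`
#'   (averaged over phantoms).
#' @export
evaluate_system <- function(config, grid, design, lib, net, phantoms, depths,
                            out_size, noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  C <- length(config$wavelengths)
  rows <- list()
  mods <- lapply(config$wavelengths, function(lam) {
    if (is.null(design)) matrix(0, grid$n, grid$n)
    else metaoptic_phase(design, lib, lam, grid)
  })
  for (zi in seq_along(depths)) {
    psfs <- lapply(seq_len(C), function(ci) {
      psi <- defocus_coefficient(depths[zi], config$nominal_focus,
                                 config$wavelengths[ci],
                                 config$pupil_diameter)
      pupil_to_psf(grid, defocus_phase(grid, psi) + mods[[ci]])
    })
    acc_psnr <- matrix(NA_real_, length(phantoms), C)
    acc_ssim <- matrix(NA_real_, length(phantoms), C)
    for (pi in seq_along(phantoms)) {
      gt <- phantoms[[pi]]
      si <- render_sensor(gt, psfs, out_size = out_size, noise_sd = noise_sd)
      oi <- if (is.null(net)) pmin(pmax(si, 0), 1) else reconstruct(net, si)
      gtc <- .center_crop(gt, out_size)
      for (ci in seq_len(C)) {
        acc_psnr[pi, ci] <- psnr(oi[, , ci], gtc[, , ci])
        acc_ssim[pi, ci] <- ssim(oi[, , ci], gtc[, , ci])
      }
    }
    for (ci in seq_len(C)) {
      p <- acc_psnr[, ci]
      rows[[length(rows) + 1L]] <- data.frame(
        depth = depths[zi], channel = config$wavelengths[ci],
        psnr = mean(p[is.finite(p)]), ssim = mean(acc_ssim[, ci]))
    }
  }
  do.call(rbind, rows)
}

#' PSNR/SSIM depth sweep
#'
#' Evaluates the system across `n_planes` depth planes spaced uniformly in
#' diopters over the target range (the published protocol uses 41 planes).
#'
#' @inheritParams evaluate_system
#' @param n_planes Number of planes (>= 2).
#' @param dof_halfwidth Half the covered depth range in um.
#' @return A `depth_sweep` data frame (`depth`, `channel`, `psnr`, `ssim`)
#'   with the plane schedule as attribute `depths`.
#' @export
depth_sweep <- function(config, grid, design, lib, net, phantoms, out_size,
                        n_planes = 41L, dof_halfwidth = config$target_dof / 2,
                        noise_sd = 0.01, seed = 1L) {
  stopifnot(n_planes >= 2)
  depths <- sample_depths(n_planes, config$nominal_focus, dof_halfwidth,
                          mode = "grid")
  out <- evaluate_system(config, grid, design, lib, net, phantoms, depths,
                         out_size, noise_sd, seed)
  attr(out, "depths") <- depths
  class(out) <- c("depth_sweep", class(out))
  out
}

#' @export
plot.depth_sweep <- function(x, metric = "psnr", ...) {
  chans <- unique(x$channel)
  cols <- grDevices::hcl.colors(length(chans), "Dark 3")
  graphics::plot(NULL, xlim = range(x$depth), ylim = range(x[[metric]]),
                 xlab = "depth (um)", ylab = toupper(metric), ...)
  for (i in seq_along(chans)) {
    sub <- x[x$channel == chans[i], ]
    graphics::lines(sub$depth, sub[[metric]], col = cols[i])
  }
  graphics::legend("bottomleft", legend = paste(chans, "nm"), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Ablation comparison: full system vs single components
#'
#' Trains and evaluates, on identical data, seeds and depth schedules,
#' three configurations: the full co-designed system (meta-optic + network),
#' the system with the meta-optic removed (conventional optics + trained
#' network), and the system with the network removed (pre-optimized
#' meta-optic, raw sensor output). Returns the per-channel depth-averaged
#' PSNR/SSIM table, full system first.
#'
#' @param arms Named list of three evaluated [evaluate_system()] outputs
#'   `full`, `no_metaoptic`, `metaoptic_only` (as produced by
#'   [toy_codesign()]), or `NULL` to run the default toy experiment.
#' @param seed Seed for the default toy run.
#' @param ... Passed to [toy_codesign()] when `arms` is `NULL`.
#' @return Data frame `arm`, `channel`, `psnr`, `ssim`, ordered full /
#'   no-meta-optic / meta-optic-only.
#' @export
ablation_eval <- function(arms = NULL, seed = 1L, ...) {
  if (is.null(arms)) arms <- toy_codesign(seed = seed, ...)$arms
  stopifnot(all(c("full", "no_metaoptic", "metaoptic_only") %in% names(arms)))
  agg <- function(df, nm) {
    a <- stats::aggregate(df[, c("psnr", "ssim")],
                          by = list(channel = df$channel), FUN = mean)
    cbind(arm = nm, a)
  }
  rbind(agg(arms$full, "full"),
        agg(arms$no_metaoptic, "no_metaoptic"),
        agg(arms$metaoptic_only, "metaoptic_only"))
}
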