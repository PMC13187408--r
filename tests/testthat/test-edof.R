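test_that("target passband is an indicator up to the cutoff", {
  rho <- seq(0, 1, length.out = 101)
  T1 <- target_passband(rho, 0.5)
  expect_equal(T1[1], 1)
  expect_true(all(T1[rho > 0.5] == 0))
  expect_true(all(T1[rho <= 0.5] == 1))
  expect_equal(mean(T1), 0.5, tolerance = 0.02)  # fraction of unity bins
})

test_that("depth aggregation interpolates between mean and max", {
  cfg <- edof_config()
  nb <- 20
  target <- target_passband(seq(0, 1, length.out = nb), 0.5)
  # M = T at every depth: exp(0) summed over N_z
  m_perfect <- matrix(rep(target, 4), 4, byrow = TRUE)
  expect_equal(edof_channel_loss(m_perfect, target, cfg),
               log(4) / cfg$beta_lse)
  # single depth with alpha = beta: exactly the L1 deviation
  m1 <- matrix(runif(nb), 1)
  cfg1 <- edof_config(alpha_lse = 3, beta_lse = 3)
  expect_equal(edof_channel_loss(m1, target, cfg1),
               mean(abs(m1 - target)), tolerance = 1e-12)
  # alpha = beta = 50 approaches the worst depth: errors {0.1, 0.5, 0.9}
  mk <- do.call(rbind, lapply(c(0.1, 0.5, 0.9), function(e) target + e))
  got <- edof_channel_loss(mk, target, edof_config(alpha_lse = 50))
  expect_equal(got, 0.9, tolerance = 1e-3)
  # beta -> 0+ (alpha = beta) approaches mean + constant
  cfg_small <- edof_config(alpha_lse = 1e-3, beta_lse = 1e-3)
  got_small <- edof_channel_loss(mk, target, cfg_small)
  expect_equal(got_small - log(3) / 1e-3, mean(c(0.1, 0.5, 0.9)),
               tolerance = 1e-3)
  # permutation invariance in depth order
  expect_equal(edof_channel_loss(mk[c(3, 1, 2), ], target, cfg),
               edof_channel_loss(mk, target, cfg))
  # monotone: increasing any single per-depth error never decreases it
  mk2 <- mk; mk2[2, ] <- mk2[2, ] + 0.05
  expect_gte(edof_channel_loss(mk2, target, cfg),
             edof_channel_loss(mk, target, cfg))
  expect_error(edof_channel_loss(matrix(numeric(0), 0, nb), target, cfg),
               "empty")
})

test_that("channel aggregation weights the limiting wavelength", {
  L <- c(0.3, 0.8, 0.5)
  # lambda_focus = 1: pure max
  expect_equal(edof_total_loss(L, edof_config(lambda_focus = 1)), 0.8)
  # equal channels: closed form L + (1 - lf) ln C / eta
  cfg <- edof_config(lambda_focus = 0.4, eta_lse = 10)
  expect_equal(edof_total_loss(rep(0.6, 5), cfg),
               0.4 * 0.6 + 0.6 * (0.6 + log(5) / 10), tolerance = 1e-12)
  # large eta: the log-sum-exp term approaches the max
  cfg_big <- edof_config(lambda_focus = 0, eta_lse = 500)
  expect_equal(edof_total_loss(L, cfg_big), 0.8, tolerance = 1e-3)
  # permutation invariance in channel order
  expect_equal(edof_total_loss(L[c(2, 3, 1)], cfg), edof_total_loss(L, cfg))
})

test_that("differentiable channel loss matches the numeric formula", {
  sys <- toy_system(seed = 1)
  cfg <- edof_config()
  depths <- sample_depths(3, sys$config$nominal_focus, 50, "grid")
  bins <- edofco:::.mtf_bins(sys$grid)
  target <- target_passband(bins$rho, cfg$rho_cut)
  profs <- lapply(depths, function(z) {
    psi <- defocus_coefficient(z, sys$config$nominal_focus, 433,
                               sys$config$pupil_diameter)
    p <- pupil_to_psf(sys$grid, defocus_phase(sys$grid, psi))
    prof <- mtf_radial(p, rho_max = 1)
    prof$value[seq_len(bins$n_bins)]
  })
  numeric_loss <- edof_channel_loss(do.call(rbind, profs), target, cfg)
  dev <- mtf_deviations(NULL, NULL, sys$config, depths, sys$grid, cfg)
  taped_loss <- edofco:::.lse(cfg$alpha_lse * dev[, 1]) / cfg$beta_lse
  # the taped magnitude uses a 1e-12 epsilon guard; agreement to 1e-6
  expect_equal(taped_loss, numeric_loss, tolerance = 1e-6)
})

test_that("short pre-optimization runs are finite, seeded and improving", {
  sys <- toy_system(seed = 1)
  depths <- sample_depths(3, sys$config$nominal_focus, 50, "grid")
  cfg <- edof_config(epochs = 6)
  pre <- pretrain_metaoptic(sys$design, sys$lib, sys$config, depths,
                            sys$grid, cfg, seed = 1)
  expect_true(all(is.finite(pre$history)))
  expect_lt(pre$history[length(pre$history)], pre$history[1])
  pre2 <- pretrain_metaoptic(sys$design, sys$lib, sys$config, depths,
                             sys$grid, cfg, seed = 1)
  expect_identical(pre$design$gamma_init, pre2$design$gamma_init)
  # widths respect the design bounds after optimization
  expect_true(all(pre$design$gamma_init >= sys$design$width_bounds[1] &
                    pre$design$gamma_init <= sys$design$width_bounds[2]))
})
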