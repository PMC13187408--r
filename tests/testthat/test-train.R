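test_that("training contracts: frozen optics, penalty bookkeeping", {
  sys <- toy_system(seed = 1)
  data <- toy_phantoms(2, seed = 3)
  tc <- train_config(lr_network = 1e-3, noise_sd = 0.01)
  delta0 <- sys$design$delta_gamma
  fit <- train_end_to_end(sys$config, sys$grid, sys$design, sys$lib,
                          sys$net, data, 64L, 3, 50, steps = 3, tc,
                          seed = 5, train_optics = FALSE)
  # freezing the optical optimizer leaves delta_gamma bit-unchanged
  expect_identical(fit$design$delta_gamma, delta0)
  expect_true(all(is.finite(fit$history$loss)))
  # beta_wd = 0 removes the penalty: objective equals the loss exactly
  net2 <- build_reconstructor(reconstructor_spec(channels = 2,
                                                 widths = c(4, 8, 16)),
                              seed = 1)
  fit0 <- train_end_to_end(sys$config, sys$grid, sys$design, sys$lib, net2,
                           data, 64L, 3, 50, steps = 2,
                           train_config(beta_wd = 0, lr_network = 1e-3),
                           seed = 5)
  expect_identical(fit0$history$objective, fit0$history$loss)
  # with beta_wd > 0 the penalty is exactly beta * ||theta_net||^2 —
  # the optical parameters contribute nothing to the regularizer
  net3 <- build_reconstructor(reconstructor_spec(channels = 2,
                                                 widths = c(4, 8, 16)),
                              seed = 1)
  fit1 <- train_end_to_end(sys$config, sys$grid, sys$design, sys$lib, net3,
                           data, 64L, 3, 50, steps = 1,
                           train_config(beta_wd = 1e-3, lr_network = 1e-3),
                           seed = 5)
  pen <- fit1$history$objective[1] - fit1$history$loss[1]
  expect_equal(pen, 1e-3 * sum(vapply(fit1$net$params,
                                      function(p) sum(p^2), numeric(1))),
               tolerance = 1e-9)
})

test_that("joint training moves the widths and keeps them in bounds", {
  sys <- toy_system(seed = 2)
  data <- toy_phantoms(2, seed = 4)
  fit <- train_end_to_end(sys$config, sys$grid, sys$design, sys$lib,
                          sys$net, data, 64L, 3, 50, steps = 4,
                          train_config(lr_optics = 0.05, lr_network = 1e-3),
                          seed = 6)
  expect_gt(max(abs(fit$design$delta_gamma)), 0)
  w <- fit$design$gamma_init + fit$design$delta_gamma
  expect_true(all(w >= fit$design$width_bounds[1] - 1e-9 &
                    w <= fit$design$width_bounds[2] + 1e-9))
})

test_that("training and evaluation share the depth schedule", {
  sys <- toy_system(seed = 1)
  data <- toy_phantoms(1, seed = 1)
  fit <- train_end_to_end(sys$config, sys$grid, sys$design, sys$lib,
                          sys$net, data, 64L, 5, 40, steps = 1,
                          train_config(lr_network = 1e-3), seed = 1)
  expect_equal(fit$depth_schedule,
               sample_depths(5, sys$config$nominal_focus, 40, "grid"))
})

test_that("depth sweeps produce one row per plane and channel", {
  sys <- toy_system(seed = 1)
  phs <- toy_phantoms(1, seed = 30)
  sw <- depth_sweep(sys$config, sys$grid, NULL, sys$lib, NULL, phs, 64L,
                    n_planes = 5, dof_halfwidth = 50, noise_sd = 0,
                    seed = 1)
  expect_equal(nrow(sw), 5 * 2)
  expect_length(attr(sw, "depths"), 5)
  # planes are uniform in diopters
  expect_equal(diff(range(diff(1 / attr(sw, "depths")))), 0,
               tolerance = 1e-12)
  # the default protocol uses 41 planes
  expect_equal(eval(formals(depth_sweep)$n_planes), 41L)
  # conventional system: PSNR at best focus exceeds the DoF edge
  at_focus <- sw$psnr[abs(sw$depth - 3000) == min(abs(sw$depth - 3000))]
  at_edge <- sw$psnr[sw$depth == min(sw$depth)]
  expect_gt(mean(at_focus), mean(at_edge))
})

test_that("ablation tables list the full system first with all channels", {
  df <- data.frame(depth = rep(c(1, 2), each = 2),
                   channel = rep(c(433, 681), 2),
                   psnr = c(20, 21, 19, 20), ssim = c(0.8, 0.8, 0.7, 0.7))
  arms <- list(full = df, no_metaoptic = df, metaoptic_only = df)
  tab <- ablation_eval(arms)
  expect_equal(nrow(tab), 3 * 2)
  expect_equal(unique(tab$arm),
               c("full", "no_metaoptic", "metaoptic_only"))
  expect_equal(tab$psnr[tab$arm == "full"], c(19.5, 20.5))
})
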