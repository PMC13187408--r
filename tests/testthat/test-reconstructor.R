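test_that("network obeys its shape, bound and identity contracts", {
  net <- build_reconstructor(reconstructor_spec(), seed = 1)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  out <- reconstruct(net, x)
  expect_equal(dim(out), c(64, 64, 4))
  expect_true(min(out) >= 0 && max(out) <= 1)
  # zero-initialized residual head: output = clamp(input) at initialization
  expect_equal(out, pmin(pmax(x, 0), 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # evaluation mode is bit-deterministic
  expect_identical(out, reconstruct(net, x))
  expect_error(reconstructor_spec(widths = c(64, 32, 128)), "increase")
})

test_that("residual head keeps the pre-clamp residual below one", {
  net <- build_reconstructor(reconstructor_spec(channels = 2,
                                                widths = c(4, 8, 16)),
                             seed = 3)
  set.seed(3)
  for (nm in names(net$params))
    net$params[[nm]] <- net$params[[nm]] +
      array(rnorm(length(net$params[[nm]]), 0, 0.2),
            dim(net$params[[nm]]) %||% length(net$params[[nm]]))
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  out <- reconstruct(net, x)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(abs(out - x) < 1 + 1e-12))  # |tanh| < 1
})

test_that("single-channel variant omits the attention block", {
  net1 <- build_reconstructor(reconstructor_spec(channels = 1), seed = 1)
  expect_false(net1$spec$attention)
  expect_false(any(grepl("^attn_", names(net1$params))))
  net4 <- build_reconstructor(reconstructor_spec(channels = 4), seed = 1)
  expect_true(any(grepl("^attn_", names(net4$params))))
})

test_that("parameter count is a pure function of the spec", {
  expect_identical(n_parameters(build_reconstructor(reconstructor_spec(),
                                                    seed = 7)), 473247L)
  expect_identical(
    n_parameters(build_reconstructor(reconstructor_spec(channels = 1),
                                     seed = 7)), 472259L)
})

test_that("Fourier channel attention gates are symmetric, bounded, guarded", {
  set.seed(5)
  C <- 3; h <- 2
  w1 <- matrix(rnorm(h, 0, 0.5), 1, h); b1 <- rnorm(h)
  w2 <- matrix(rnorm(h, 0, 0.5), h, 1); b2 <- rnorm(1)
  one <- matrix(runif(64), 8)
  x_same <- edofco:::ad_stack3(lapply(1:C, function(i) ad_const(one)))
  out <- fourier_channel_attention(x_same, w1, b1, w2, b2)
  gates <- ad_value(out)[1, 1, ] / one[1, 1]
  expect_equal(gates[1], gates[2], tolerance = 1e-12)
  expect_equal(gates[2], gates[3], tolerance = 1e-12)
  expect_true(all(gates > 0 & gates < 1))
  # all-zero input stays finite (epsilon guard inside the magnitude)
  xz <- array(0, c(8, 8, C))
  outz <- ad_value(fourier_channel_attention(ad_const(xz), w1, b1, w2, b2))
  expect_true(all(is.finite(outz)))
})

test_that("padding policy handles indivisible input sizes", {
  net <- build_reconstructor(reconstructor_spec(channels = 2,
                                                widths = c(4, 8, 16)),
                             seed = 1)
  x <- array(runif(18 * 18 * 2), c(18, 18, 2))
  out <- reconstruct(net, x, pad = TRUE)
  expect_equal(dim(out), c(18, 18, 2))
  expect_error(reconstruct(net, x, pad = FALSE), "divisible")
})

test_that("gradients reach every parameter group once the head is active", {
  net <- build_reconstructor(reconstructor_spec(channels = 2,
                                                widths = c(4, 8, 16)),
                             seed = 2)
  set.seed(2)
  net$params$head_w <- matrix(rnorm(4 * 2, 0, 0.3), 4, 2)
  x <- array(runif(16 * 16 * 2, 0.1, 0.9), c(16, 16, 2))
  gt <- array(runif(16 * 16 * 2), c(16, 16, 2))
  params <- lapply(net$params, ad_param)
  loss <- recon_loss(net_forward(net, x, params, training = TRUE), gt)
  ad_backward(loss)
  for (nm in names(params)) {
    expect_false(is.null(params[[nm]]$grad), info = nm)
    expect_true(all(is.finite(params[[nm]]$grad)), info = nm)
  }
  # spot-check a handful of deep weights against finite differences
  idx <- cbind(c(1, 9, 30, 55), c(1, 2, 8, 16))
  w0 <- net$params$enc3a_w[idx]
  h <- 1e-5
  for (k in seq_len(nrow(idx))) {
    num <- vapply(c(h, -h), function(d) {
      p <- net$params
      p$enc3a_w[idx[k, , drop = FALSE]] <- w0[k] + d
      loss_node <- recon_loss(net_forward(net, x, p, training = TRUE), gt)
      loss_node$value
    }, numeric(1))
    fd <- (num[1] - num[2]) / (2 * h)
    expect_equal(params$enc3a_w$grad[idx[k, , drop = FALSE]], fd,
                 tolerance = 1e-3)
  }
})

test_that("weights round-trip through the text checkpoint format", {
  net <- build_reconstructor(reconstructor_spec(channels = 2,
                                                widths = c(4, 8, 16)),
                             seed = 4)
  set.seed(4)
  net$params$head_w <- matrix(rnorm(8, 0, 0.1), 4, 2)
  path <- tempfile()
  save_weights(net, path)
  back <- load_weights(path)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_equal(reconstruct(back, x), reconstruct(net, x), tolerance = 1e-12)
})
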