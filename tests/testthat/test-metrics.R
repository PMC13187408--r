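test_that("PSNR follows its closed form and the infinity sentinel", {
  a <- matrix(0.5, 10, 10)
  b <- a + 0.1            # MSE = 0.01 -> 20 dB at peak 1
  expect_equal(psnr(a, b), 20)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, b, peak = 2), 20 + 10 * log10(4))
})

test_that("SSIM is 1 on identical images and symmetric", {
  set.seed(1)
  a <- matrix(runif(32 * 32), 32)
  b <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_lt(ssim(a, b), 1)
})

test_that("PSNR and SSIM agree with the scikit-image reference", {
  set.seed(42)
  pairs <- lapply(1:20, function(i)
    list(a = matrix(runif(48 * 48), 48), b = matrix(runif(48 * 48), 48)))
  td <- tempfile(); dir.create(td)
  for (i in seq_along(pairs)) {
    utils::write.table(pairs[[i]]$a, file.path(td, paste0("a", i, ".csv")),
                       row.names = FALSE, col.names = FALSE, sep = ",")
    utils::write.table(pairs[[i]]$b, file.path(td, paste0("b", i, ".csv")),
                       row.names = FALSE, col.names = FALSE, sep = ",")
  }
  script <- file.path(td, "ref.py")
  writeLines(c(
    "import numpy as np, sys",
    "from skimage.metrics import peak_signal_noise_ratio, structural_similarity",
    "td = sys.argv[1]; out = []",
    "for i in range(1, 21):",
    "    a = np.loadtxt(f'{td}/a{i}.csv', delimiter=',')",
    "    b = np.loadtxt(f'{td}/b{i}.csv', delimiter=',')",
    "    p = peak_signal_noise_ratio(a, b, data_range=1)",
    "    s = structural_similarity(a, b, data_range=1, gaussian_weights=True,",
    "        sigma=1.5, use_sample_covariance=False)",
    "    out.append(f'{p:.12f} {s:.12f}')",
    "print('\\n'.join(out))"), script)
  ref <- system2("python", c(script, td), stdout = TRUE)
  ref <- do.call(rbind, lapply(strsplit(ref, " "), as.numeric))
  for (i in seq_along(pairs)) {
    expect_equal(psnr(pairs[[i]]$a, pairs[[i]]$b), ref[i, 1],
                 tolerance = 1e-6)
    expect_equal(ssim(pairs[[i]]$a, pairs[[i]]$b), ref[i, 2],
                 tolerance = 1e-6)
  }
  unlink(td, recursive = TRUE)
})

test_that("reconstruction loss vanishes iff images match", {
  set.seed(2)
  x <- array(runif(24 * 24 * 2), c(24, 24, 2))
  expect_equal(recon_loss(x, x), 0)
  y <- x; y[5, 5, 1] <- y[5, 5, 1] + 0.2
  expect_gt(recon_loss(y, x), 0)
})

test_that("individual loss terms follow their closed forms", {
  a <- array(0.3, c(24, 24, 1))
  b <- array(0.3 + 0.12, c(24, 24, 1))
  # RMSE-only: plain RMSE = d for constant offset
  expect_equal(recon_loss(b, a, loss_weights(1, 0, 0, 0)), 0.12,
               tolerance = 1e-9)
  # gradient term: constant images have zero finite differences
  expect_equal(recon_loss(b, a, loss_weights(0, 0, 1, 0)), 0,
               tolerance = 1e-12)
  # low-pass MSE term: matches an independent naive convolution oracle
  lp <- recon_loss(b, a, loss_weights(0, 0, 0, 1))
  naive_blur <- function(m, k) {
    r <- (nrow(k) - 1) / 2
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      acc <- 0
      for (u in -r:r) for (v in -r:r) {
        ii <- i + u; jj <- j + v
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
          acc <- acc + m[ii, jj] * k[u + r + 1, v + r + 1]
      }
      out[i, j] <- acc
    }
    out
  }
  k9 <- gaussian_kernel(9L, 1.5)
  oracle <- mean((naive_blur(b[, , 1], k9) - naive_blur(a[, , 1], k9))^2)
  expect_equal(lp, oracle, tolerance = 1e-9)
  set.seed(3)
  x <- array(runif(24 * 24 * 2), c(24, 24, 2))
  y <- array(runif(24 * 24 * 2), c(24, 24, 2))
  # RMSE-only equals the per-channel RMSE average
  rm <- mean(vapply(1:2, function(c) sqrt(mean((x[, , c] - y[, , c])^2)),
                    numeric(1)))
  expect_equal(recon_loss(x, y, loss_weights(1, 0, 0, 0)), rm,
               tolerance = 1e-9)
  # SSIM-only equals 1 - ssim()
  expect_equal(recon_loss(x, y, loss_weights(0, 1, 0, 0)), 1 - ssim(x, y),
               tolerance = 1e-9)
  expect_error(recon_loss(x, y[, , 1, drop = FALSE]), "shape mismatch")
  expect_error(loss_weights(0, 0, 0, 0), "positive")
})

test_that("Gaussian-fit FWHM recovers sigma exactly and under noise", {
  xs <- 1:41
  gauss2 <- function(sx, sy, A = 1, off = 0, cx = 21, cy = 21)
    A * exp(-(outer((xs - cy)^2 / (2 * sy^2),
                    (xs - cx)^2 / (2 * sx^2), `+`))) + off
  k <- 2 * sqrt(2 * log(2))
  fit <- fwhm_gaussian_fit(gauss2(2, 2), pitch = 0.1)
  expect_equal(fit$fwhm_x, k * 2 * 0.1, tolerance = 1e-6)
  expect_equal(fit$fwhm_y, k * 2 * 0.1, tolerance = 1e-6)
  # anisotropic case: two distinct widths, each matching its closed form
  fit2 <- fwhm_gaussian_fit(gauss2(1.5, 3.2), pitch = 1)
  expect_equal(fit2$fwhm_x, k * 1.5, tolerance = 1e-6)
  expect_equal(fit2$fwhm_y, k * 3.2, tolerance = 1e-6)
  # Monte-Carlo at peak-SNR 20: median FWHM within 5% of truth
  set.seed(6)
  est <- replicate(100, {
    noisy <- gauss2(2, 2) + matrix(rnorm(41^2, 0, 0.05), 41)
    fwhm_gaussian_fit(noisy, pitch = 1)$fwhm_x
  })
  expect_lt(mean(is.na(est)), 0.1)   # non-convergence is rare and flagged
  expect_lt(abs(stats::median(est, na.rm = TRUE) - k * 2) / (k * 2), 0.05)
})
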