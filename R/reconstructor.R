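# The deblurring network: a three-level encoder-decoder with per-channel
# input normalization, identity-initialized 1x1 spectral mixing,
# Fourier-domain channel attention, double-conv blocks (batch norm + ReLU),
# bilinear-upsampling decoder with skip connections, and a residual head
# whose tanh output is added to the input and clamped to [0, 1].

#' Reconstruction network specification
#'
#' @param channels Input/output channel count (4 for the multispectral
#'   system, 1 for the single-wavelength variant).
#' @param widths Encoder feature widths, strictly increasing, one per level
#'   (default `c(32, 64, 128)`); the decoder mirrors them.
#' @param attention Use the Fourier-domain channel-attention block; forced
#'   off for single-channel specs (no cross-channel reweighting is possible).
#' @param residual Use the residual head `clamp(input + tanh(residual))`.
#' @return A `reconstructor_spec`.
#' @export
reconstructor_spec <- function(channels = 4L, widths = c(32L, 64L, 128L),
                               attention = channels > 1L, residual = TRUE) {
  stopifnot(channels >= 1, length(widths) == 3L)
  if (is.unsorted(widths, strictly = TRUE))
    stop("spec error: feature widths must increase strictly down the encoder",
         call. = FALSE)
  if (channels == 1L) attention <- FALSE
  structure(list(channels = as.integer(channels), widths = as.integer(widths),
                 levels = 3L, attention = attention, residual = residual),
            class = "reconstructor_spec")
}

.he_init <- function(d, fan_in) array(stats::rnorm(prod(d), 0,
                                                   sqrt(2 / fan_in)), d)

.conv3_params <- function(cin, cout, prefix) {
  p <- list()
  p[[paste0(prefix, "_w")]] <- .he_init(c(9 * cin, cout), 9 * cin)
  p[[paste0(prefix, "_b")]] <- numeric(cout)
  p[[paste0(prefix, "_bn_g")]] <- rep(1, cout)
  p[[paste0(prefix, "_bn_b")]] <- numeric(cout)
  p
}

#' Build the reconstruction network
#'
#' Assembles the parameter set: per-channel input instance normalization
#' (parameter-free), a 1x1 cross-channel mixing layer initialized to the
#' identity, an optional Fourier-domain channel-attention block, three
#' double-convolution encoder levels (widths `spec$widths`), the mirrored
#' bilinear-upsampling decoder with skip connections, and a zero-initialized
#' 1x1 residual head so the network is the identity map
#' `clamp(input)` at initialization (asserted numerically at build time).
#'
#' @param spec A [reconstructor_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `reconstructor` handle: `spec`, `params` (named list of numeric
#'   arrays), `bn` (running batch-norm statistics environment).
#' @export
build_reconstructor <- function(spec = reconstructor_spec(), seed = 1L) {
  stopifnot(inherits(spec, "reconstructor_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  C <- spec$channels
  f <- spec$widths
  p <- list(mix_w = diag(C), mix_b = numeric(C))
  if (spec$attention) {
    h <- max(2L, C %/% 2L)
    p$attn_w1 <- .he_init(c(1, h), 1)
    p$attn_b1 <- numeric(h)
    p$attn_w2 <- .he_init(c(h, 1), h)
    p$attn_b2 <- numeric(1)
  }
  p <- c(p,
         .conv3_params(C, f[1], "enc1a"), .conv3_params(f[1], f[1], "enc1b"),
         .conv3_params(f[1], f[2], "enc2a"), .conv3_params(f[2], f[2], "enc2b"),
         .conv3_params(f[2], f[3], "enc3a"), .conv3_params(f[3], f[3], "enc3b"),
         .conv3_params(f[3] + f[2], f[2], "dec2a"),
         .conv3_params(f[2], f[2], "dec2b"),
         .conv3_params(f[2] + f[1], f[1], "dec1a"),
         .conv3_params(f[1], f[1], "dec1b"))
  p$head_w <- matrix(0, f[1], C)   # zero init: identity map at start
  p$head_b <- numeric(C)
  bn <- new.env(parent = emptyenv())
  net <- structure(list(spec = spec, params = p, bn = bn),
                   class = "reconstructor")
  # identity-at-initialization contract
  probe <- array(stats::runif(16 * 16 * C), c(16, 16, C))
  out <- reconstruct(net, probe)
  stopifnot(max(abs(out - pmin(pmax(probe, 0), 1))) < 1e-12)
  net
}

#' @export
print.reconstructor <- function(x, ...) {
  cat(sprintf(
    "Reconstructor: %d-channel, widths %s%s, %d parameters\n",
    x$spec$channels, paste(x$spec$widths, collapse = "-"),
    if (x$spec$attention) ", Fourier channel attention" else "",
    n_parameters(x)))
  invisible(x)
}

#' Total number of learnable parameters
#' @param net A `reconstructor`.
#' @return Integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# batch-norm over the spatial extent with learnable scale/shift; running
# statistics (momentum 0.1) are used in evaluation mode.
.bn <- function(x, g, b, net, id, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- ad_cmean(x)
    xc <- ad_cadd(x, -1 * mu)
    v <- ad_cmean(xc * xc)
    st <- net$bn[[id]]
    if (is.null(st)) st <- list(mean = ad_value(mu) * 0,
                                var = ad_value(v) * 0 + 1)
    net$bn[[id]] <- list(
      mean = (1 - momentum) * st$mean + momentum * ad_value(mu),
      var = (1 - momentum) * st$var + momentum * ad_value(v))
    xn <- ad_cscale(xc, 1 / sqrt(v + eps))
  } else {
    st <- net$bn[[id]]
    if (is.null(st)) st <- list(mean = numeric(length(ad_value(g))),
                                var = rep(1, length(ad_value(g))))
    xn <- ad_cscale(ad_cadd(x, -st$mean), 1 / sqrt(st$var + eps))
  }
  ad_cadd(ad_cscale(xn, g), b)
}

.double_conv <- function(x, p, prefix, net, training) {
  for (blk in c("a", "b")) {
    nm <- paste0(prefix, blk)
    x <- ad_conv3(x, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]])
    x <- .bn(x, p[[paste0(nm, "_bn_g")]], p[[paste0(nm, "_bn_b")]],
             net, nm, training)
    x <- ad_relu(x)
  }
  x
}

#' Fourier-domain channel attention
#'
#' Computes one gate per channel from the mean magnitude spectrum of that
#' channel's discrete Fourier transform: the pooled scalar of each channel
#' passes through a shared two-layer bottleneck (so channels with identical
#' content receive identical gates) and a sigmoid, and the gates multiply
#' the channels. Gates are strictly inside (0, 1); an epsilon inside the
#' magnitude keeps all-zero channels finite.
#'
#' @param x `[H, W, C]` features (numeric array or tape node).
#' @param w1,b1,w2,b2 Shared bottleneck parameters (`1 x h`, `h`, `h x 1`,
#'   `1`), applied to every channel's pooled statistic.
#' @return Reweighted features of the same shape (tape node).
#' @export
fourier_channel_attention <- function(x, w1, b1, w2, b2) {
  d <- dim(ad_value(x))
  C <- d[3]
  h <- length(ad_value(b1))
  pooled <- ad_stack_scalars(lapply(seq_len(C), function(c)
    ad_mean(ad_fft_mag2(ad_slice3(x, c)))))
  ones <- matrix(1, C, 1)
  z <- ad_matmul(ad_reshape(pooled, c(C, 1)), w1)        # C x h
  z <- ad_relu(z + ad_matmul(ones, ad_reshape(b1, c(1, h))))
  z <- ad_matmul(z, w2) + ad_matmul(ones, ad_reshape(b2, c(1, 1)))
  gates <- ad_sigmoid(z)                                  # C x 1
  ad_cscale(x, ad_reshape(gates, C))
}

# stack scalar nodes into a vector node
ad_stack_scalars <- function(xs) {
  vals <- vapply(xs, ad_value, numeric(1))
  vjps <- lapply(seq_along(xs), function(i) {
    force(i)
    function(g) g[i]
  })
  ad_op(vals, xs, vjps)
}

# full forward pass; `params` may hold tape nodes (training) or numerics
net_forward <- function(net, x, params = net$params, training = FALSE) {
  spec <- net$spec
  xin <- if (is_ad(x)) x else ad_const(x)
  h <- ad_spatial_norm(xin)                      # per-channel InstanceNorm
  h <- ad_conv1(h, params$mix_w, params$mix_b)   # identity-initialized mixing
  if (spec$attention)
    h <- fourier_channel_attention(h, params$attn_w1, params$attn_b1,
                                   params$attn_w2, params$attn_b2)
  e1 <- .double_conv(h, params, "enc1", net, training)
  e2 <- .double_conv(ad_maxpool2(e1), params, "enc2", net, training)
  e3 <- .double_conv(ad_maxpool2(e2), params, "enc3", net, training)
  d2 <- .double_conv(ad_concat3(ad_upsample2(e3), e2), params, "dec2",
                     net, training)
  d1 <- .double_conv(ad_concat3(ad_upsample2(d2), e1), params, "dec1",
                     net, training)
  res <- ad_conv1(d1, params$head_w, params$head_b)
  if (spec$residual) {
    ad_clamp(xin + tanh(res), 0, 1)
  } else {
    ad_clamp(tanh(res) * 0.5 + 0.5, 0, 1)
  }
}

#' Reconstruct a sensor image
#'
#' Evaluation-mode forward pass: deterministic for fixed weights, output
#' clamped to `[0, 1]`. Inputs whose side is not divisible by
#' `2^(levels - 1)` (= 4) are zero-padded to the next multiple and the
#' output cropped back (or an error is raised with `pad = FALSE`).
#'
#' @param net A [build_reconstructor()] network.
#' @param si Sensor image, `[H, W, C]` array (a single matrix is treated as
#'   one channel).
#' @param pad Apply the padding policy for indivisible sizes.
#' @return `[H, W, C]` array in `[0, 1]`.
#' @export
reconstruct <- function(net, si, pad = TRUE) {
  stopifnot(inherits(net, "reconstructor"))
  if (is.matrix(si)) si <- array(si, c(dim(si), 1L))
  d <- dim(si)
  stopifnot(d[3] == net$spec$channels)
  m <- 2^(net$spec$levels - 1)
  hp <- ceiling(d[1] / m) * m
  wp <- ceiling(d[2] / m) * m
  if ((hp != d[1] || wp != d[2])) {
    if (!pad)
      stop("input size must be divisible by ", m, call. = FALSE)
    xi <- array(0, c(hp, wp, d[3]))
    xi[seq_len(d[1]), seq_len(d[2]), ] <- si
  } else xi <- si
  out <- ad_value(net_forward(net, xi, training = FALSE))
  out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

#' Save / load network weights
#'
#' Weights are stored as a JSON header (the spec and array shapes) plus a
#' flat text array container, portable across platforms.
#'
#' @param net A `reconstructor`.
#' @param path Output path (two files: `path` and `path.json`).
#' @return `save_weights()` the path invisibly; `load_weights()` a
#'   `reconstructor`.
#' @export
save_weights <- function(net, path) {
  shapes <- lapply(net$params, function(a) dim(a) %||% length(a))
  jsonlite::write_json(
    list(spec = unclass(net$spec), shapes = shapes,
         bn = as.list(net$bn)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(net$params))
    writeLines(paste(c(nm, format(c(net$params[[nm]]), digits = 17)),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(reconstructor_spec,
                  meta$spec[c("channels", "widths", "attention", "residual")])
  lines <- readLines(path)
  params <- list()
  for (ln in lines) {
    parts <- strsplit(ln, " +")[[1]]
    nm <- parts[1]
    vals <- as.numeric(parts[-1])
    shp <- unlist(meta$shapes[[nm]])
    params[[nm]] <- if (length(shp) > 1) array(vals, shp) else vals
  }
  bn <- new.env(parent = emptyenv())
  for (nm in names(meta$bn))
    bn[[nm]] <- list(mean = as.numeric(meta$bn[[nm]]$mean),
                     var = as.numeric(meta$bn[[nm]]$var))
  structure(list(spec = spec, params = params, bn = bn),
            class = "reconstructor")
}
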