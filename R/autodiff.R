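# Minimal reverse-mode automatic differentiation on R arrays.
#
# The co-design objective is differentiated end to end: from the multi-term
# reconstruction loss through the network, the sensor-image convolution, the
# wave-optics PSF model and the width-to-phase lookup down to the nanopillar
# width perturbation. Nodes are environments holding a value, the parent
# nodes and one vector-Jacobian product (vjp) closure per parent; backward()
# walks the tape in reverse creation order (a valid topological order, since
# parents are always created before children). FFT-based primitives carry
# hand-derived adjoints, each validated against central finite differences in
# the test suite.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L
.ad$cache <- new.env(parent = emptyenv())  # interpolation matrices etc.

is_ad <- function(x) inherits(x, "advar")

ad_value <- function(x) if (is_ad(x)) x$value else x

new_ad <- function(value, requires = FALSE) {
  nd <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  nd$id <- .ad$counter
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- list()
  nd$vjps <- list()
  nd$requires <- requires
  class(nd) <- "advar"
  nd
}

#' Create a differentiable parameter
#'
#' Wraps a numeric array as a leaf node of the automatic-differentiation
#' tape. After [ad_backward()] on a downstream scalar, the accumulated
#' gradient is in `$grad`.
#'
#' @param value Numeric scalar, vector, matrix or array.
#' @return An `advar` node.
#' @export
ad_param <- function(value) new_ad(value, requires = TRUE)

ad_const <- function(value) new_ad(value, requires = FALSE)

# Build a derived node; `vjps[[i]]` maps the output cotangent to the
# cotangent of `parents[[i]]`. Parents given as plain numerics are constants.
ad_op <- function(value, parents, vjps) {
  keep <- vapply(parents, function(p) is_ad(p) && p$requires, TRUE)
  nd <- new_ad(value, requires = any(keep))
  if (nd$requires) {
    nd$parents <- parents[keep]
    nd$vjps <- vjps[keep]
  }
  nd
}

#' @export
print.advar <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf("<advar id=%d %s%s>\n", x$id,
              if (is.null(d)) paste0("len ", length(x$value))
              else paste(d, collapse = "x"),
              if (x$requires) " grad" else ""))
  invisible(x)
}

# reduce a broadcast gradient back to the shape of the operand
.unbcast <- function(g, target) {
  if (length(target) == 1L && length(g) > 1L) sum(g) else g
}

#' @export
Ops.advar <- function(e1, e2) {
  if (missing(e2)) {  # unary
    if (.Generic == "-") return(ad_op(-ad_value(e1), list(e1),
                                      list(function(g) -g)))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for advar: ", .Generic, call. = FALSE)
  }
  v1 <- ad_value(e1); v2 <- ad_value(e2)
  switch(.Generic,
    "+" = ad_op(v1 + v2, list(e1, e2),
                list(function(g) .unbcast(g, v1), function(g) .unbcast(g, v2))),
    "-" = ad_op(v1 - v2, list(e1, e2),
                list(function(g) .unbcast(g, v1),
                     function(g) .unbcast(-g, v2))),
    "*" = ad_op(v1 * v2, list(e1, e2),
                list(function(g) .unbcast(g * v2, v1),
                     function(g) .unbcast(g * v1, v2))),
    "/" = ad_op(v1 / v2, list(e1, e2),
                list(function(g) .unbcast(g / v2, v1),
                     function(g) .unbcast(-g * v1 / v2^2, v2))),
    "^" = {
      if (is_ad(e2)) stop("advar exponent not supported", call. = FALSE)
      ad_op(v1^v2, list(e1), list(function(g) g * v2 * v1^(v2 - 1)))
    },
    stop("unsupported op for advar: ", .Generic, call. = FALSE)
  )
}

#' @export
Math.advar <- function(x, ...) {
  v <- x$value
  switch(.Generic,
    exp = ad_op(exp(v), list(x), list(function(g) g * exp(v))),
    log = ad_op(log(v), list(x), list(function(g) g / v)),
    sqrt = ad_op(sqrt(v), list(x), list(function(g) g / (2 * sqrt(v)))),
    tanh = {
      t <- tanh(v)
      ad_op(t, list(x), list(function(g) g * (1 - t^2)))
    },
    abs = ad_op(abs(v), list(x), list(function(g) g * sign(v))),
    stop("unsupported Math op for advar: ", .Generic, call. = FALSE)
  )
}

#' Tape reductions and elementwise helpers
#'
#' `ad_sum()`/`ad_mean()` reduce to a scalar node; `ad_sigmoid()`,
#' `ad_relu()` and `ad_clamp()` are the usual elementwise nonlinearities
#' (clamp uses the subgradient that passes gradients inside `[lo, hi]`).
#'
#' @param x An `advar` (or numeric, treated as constant).
#' @return An `advar`.
#' @export
ad_sum <- function(x) {
  v <- ad_value(x)
  ad_op(sum(v), list(x), list(function(g) array(g, dim(v) %||% length(v))))
}

#' @rdname ad_sum
#' @export
ad_mean <- function(x) {
  v <- ad_value(x)
  n <- length(v)
  ad_op(mean(v), list(x),
        list(function(g) array(g / n, dim(v) %||% length(v))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ad_sum
#' @export
ad_sigmoid <- function(x) {
  v <- ad_value(x)
  s <- 1 / (1 + exp(-v))
  ad_op(s, list(x), list(function(g) g * s * (1 - s)))
}

#' @rdname ad_sum
#' @export
ad_relu <- function(x) {
  v <- ad_value(x)
  ad_op(pmax(v, 0), list(x), list(function(g) g * (v > 0)))
}

#' @rdname ad_sum
#' @param lo,hi Clamp bounds.
#' @export
ad_clamp <- function(x, lo = 0, hi = 1) {
  v <- ad_value(x)
  out <- pmin(pmax(v, lo), hi)
  ad_op(out, list(x), list(function(g) g * (v >= lo & v <= hi)))
}

#' Matrix product of tape nodes
#' @param a,b Matrices (`advar` or numeric).
#' @return An `advar` holding `a %*% b`.
#' @export
ad_matmul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  ad_op(va %*% vb, list(a, b),
        list(function(g) g %*% t(vb), function(g) t(va) %*% g))
}

#' @rdname ad_sum
#' @param dims New dimension vector.
#' @export
ad_reshape <- function(x, dims) {
  v <- ad_value(x)
  old <- dim(v) %||% length(v)
  ad_op(array(v, dims), list(x), list(function(g) array(g, old)))
}

# ---- channel helpers on [H, W, C] arrays --------------------------------

# per-channel spatial mean -> length-C vector
ad_cmean <- function(x) {
  v <- ad_value(x)
  d <- dim(v); hw <- d[1] * d[2]
  m <- colMeans(matrix(v, hw, d[3]))
  ad_op(m, list(x),
        list(function(g) array(rep(g / hw, each = hw), d)))
}

.cexpand <- function(s, d) array(rep(s, each = d[1] * d[2]), d)

# multiply each channel of x [H,W,C] by scalar s[C]
ad_cscale <- function(x, s) {
  vx <- ad_value(x); vs <- ad_value(s)
  d <- dim(vx)
  ad_op(vx * .cexpand(vs, d), list(x, s),
        list(function(g) g * .cexpand(vs, d),
             function(g) colSums(matrix(g * vx, d[1] * d[2], d[3]))))
}

# add scalar b[C] to each channel
ad_cadd <- function(x, b) {
  vx <- ad_value(x); vb <- ad_value(b)
  d <- dim(vx)
  ad_op(vx + .cexpand(vb, d), list(x, b),
        list(function(g) g,
             function(g) colSums(matrix(g, d[1] * d[2], d[3]))))
}

# concatenate along the channel axis
ad_concat3 <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  da <- dim(va); db <- dim(vb)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- va
  out[, , da[3] + seq_len(db[3])] <- vb
  ad_op(out, list(a, b),
        list(function(g) g[, , seq_len(da[3]), drop = FALSE],
             function(g) g[, , da[3] + seq_len(db[3]), drop = FALSE]))
}

#' Run backpropagation from a scalar node
#'
#' Accumulates gradients into the `$grad` field of every reachable node that
#' requires gradients (leaves created by [ad_param()] in particular).
#'
#' @param root A scalar `advar`.
#' @return `root`, invisibly.
#' @export
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  # collect reachable sub-tape
  nodes <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (is_ad(p)) stack[[length(stack) + 1L]] <- p
  }
  for (nd in nodes) nd$grad <- NULL
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)),
               decreasing = TRUE)
  root$grad <- 1
  for (k in ord) {
    nd <- nodes[[k]]
    if (is.null(nd$grad) || !nd$requires) next
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      g <- nd$vjps[[i]](nd$grad)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- FFT-based primitives (hand-derived adjoints) -----------------------

# Unaberrated-to-aberrated PSF intensity (unnormalized): q = |F u|^2 with
# u = mask exp(i phase) and F the centered 2-D DFT. The adjoint uses
# F^T = F (the centered DFT matrix is symmetric):
#   dL/dphase = -2 Im( u * F(gbar * conj(A)) ).
ad_psf_intensity <- function(phase, mask) {
  vp <- ad_value(phase)
  u <- mask * exp(1i * vp)
  A <- fftshift2(stats::fft(ifftshift2(u)))
  q <- Re(A * Conj(A))
  ad_op(q, list(phase),
        list(function(g) {
          w <- g * Conj(A)
          -2 * Im(u * fftshift2(stats::fft(ifftshift2(w))))
        }))
}

# magnitude spectrum m = sqrt(|fft2(x)|^2 + eps) of a real matrix; adjoint
# dL/dx = Re( fft2( gbar * conj(X) / m ) ) with the (symmetric) plain DFT.
ad_fft_mag2 <- function(x, eps = 1e-12) {
  vx <- ad_value(x)
  X <- stats::fft(vx)
  m <- sqrt(Re(X * Conj(X)) + eps)
  ad_op(m, list(x),
        list(function(g) Re(stats::fft(g * Conj(X) / m))))
}

# full linear 2-D convolution via zero-padded FFTs (plain numeric helper)
conv_full_fft <- function(a, b) {
  na <- dim(a); nb <- dim(b)
  nf <- na + nb - 1
  ap <- matrix(0, nf[1], nf[2]); ap[seq_len(na[1]), seq_len(na[2])] <- a
  bp <- matrix(0, nf[1], nf[2]); bp[seq_len(nb[1]), seq_len(nb[2])] <- b
  Re(stats::fft(stats::fft(ap) * stats::fft(bp), inverse = TRUE)) /
    prod(nf)
}

.flip2 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

# center-cropped full convolution of image x (nx x nx) with kernel k
# (nk x nk), output out_n x out_n. Aligned so that a kernel that is a delta
# at the kernel center (floor(nk/2)+1) returns the center crop of x.
ad_conv_crop <- function(x, k, out_n) {
  vx <- ad_value(x); vk <- ad_value(k)
  nx <- nrow(vx); nk <- nrow(vk)
  stopifnot(ncol(vx) == nx, ncol(vk) == nk, out_n <= nx)
  full <- conv_full_fft(vx, vk)
  off <- floor(nk / 2) + floor((nx - out_n) / 2)
  rows <- off + seq_len(out_n)
  out <- full[rows, rows, drop = FALSE]
  ad_op(out, list(x, k),
        list(
          function(g) {
            gf <- matrix(0, nx + nk - 1, nx + nk - 1)
            gf[rows, rows] <- g
            cf <- conv_full_fft(gf, .flip2(vk))
            cf[nk - 1 + seq_len(nx), nk - 1 + seq_len(nx), drop = FALSE]
          },
          function(g) {
            gf <- matrix(0, nx + nk - 1, nx + nk - 1)
            gf[rows, rows] <- g
            cf <- conv_full_fft(gf, .flip2(vx))
            cf[nx - 1 + seq_len(nk), nx - 1 + seq_len(nk), drop = FALSE]
          }
        ))
}

# same-size convolution with a fixed (non-learnable) centered kernel,
# applied independently to each channel of x [H, W, C]; used by the SSIM
# window and the low-pass loss term. Gradient flows to x only. The padded
# kernel FFT is cached per (shape, kernel) across calls.
ad_fixed_blur <- function(x, kernel) {
  vx <- ad_value(x)
  d <- dim(vx)
  nk <- nrow(kernel)
  nf <- d[1:2] + nk - 1
  key <- paste0("blur", d[1], "x", d[2], "k", nk, "s",
                format(sum(kernel * seq_along(kernel)), digits = 17))
  plan <- .ad$cache[[key]]
  if (is.null(plan)) {
    kp <- matrix(0, nf[1], nf[2]); kp[seq_len(nk), seq_len(nk)] <- kernel
    kf <- matrix(0, nf[1], nf[2])
    kf[seq_len(nk), seq_len(nk)] <- .flip2(kernel)
    plan <- list(Khat = stats::fft(kp), Khat_flip = stats::fft(kf))
    .ad$cache[[key]] <- plan
  }
  Khat <- plan$Khat
  conv_k <- function(img, Kh) {
    ap <- matrix(0, nf[1], nf[2])
    ap[seq_len(nrow(img)), seq_len(ncol(img))] <- img
    Re(stats::fft(stats::fft(ap) * Kh, inverse = TRUE)) / prod(nf)
  }
  off_f <- floor(nk / 2)
  off_b <- nk - 1 - floor(nk / 2)
  out <- array(0, d)
  for (c in seq_len(d[3]))
    out[, , c] <- conv_k(vx[, , c], Khat)[off_f + seq_len(d[1]),
                                          off_f + seq_len(d[2])]
  ad_op(out, list(x),
        list(function(g) {
          gx <- array(0, d)
          # adjoint of same-size conv = same-size correlation with the kernel
          for (c in seq_len(d[3]))
            gx[, , c] <- conv_k(g[, , c],
                                plan$Khat_flip)[off_b + seq_len(d[1]),
                                                off_b + seq_len(d[2])]
          gx
        }))
}

# horizontal / vertical first differences of [H, W, C] arrays
ad_diff_h <- function(x) {
  vx <- ad_value(x); d <- dim(vx)
  out <- vx[, -1, , drop = FALSE] - vx[, -d[2], , drop = FALSE]
  ad_op(out, list(x),
        list(function(g) {
          gx <- array(0, d)
          gx[, -1, ] <- gx[, -1, , drop = FALSE] + g
          gx[, -d[2], ] <- gx[, -d[2], , drop = FALSE] - g
          gx
        }))
}

ad_diff_v <- function(x) {
  vx <- ad_value(x); d <- dim(vx)
  out <- vx[-1, , , drop = FALSE] - vx[-d[1], , , drop = FALSE]
  ad_op(out, list(x),
        list(function(g) {
          gx <- array(0, d)
          gx[-1, , ] <- gx[-1, , , drop = FALSE] + g
          gx[-d[1], , ] <- gx[-d[1], , , drop = FALSE] - g
          gx
        }))
}

# piecewise-linear table lookup y(gamma) with gradient = local segment slope
ad_interp_lookup <- function(xs, ys, gamma) {
  vg <- ad_value(gamma)
  n <- length(xs)
  i <- findInterval(vg, xs, rightmost.closed = TRUE, all.inside = TRUE)
  slope <- (ys[i + 1] - ys[i]) / (xs[i + 1] - xs[i])
  out <- ys[i] + slope * (vg - xs[i])
  ad_op(out, list(gamma), list(function(g) g * slope))
}

# scatter a radial vector onto a 2-D map: map[px] = gamma[bin[px]] where
# bin is a precomputed index matrix (0 outside the aperture). Linear in
# gamma; the adjoint sums cotangents over each annulus.
ad_scatter_radial <- function(gamma, bin) {
  vg <- ad_value(gamma)
  nb <- length(vg)
  out <- matrix(0, nrow(bin), ncol(bin))
  inside <- bin > 0
  out[inside] <- vg[bin[inside]]
  ad_op(out, list(gamma),
        list(function(g) {
          acc <- tapply(g[inside], bin[inside], sum)
          res <- numeric(nb)
          res[as.integer(names(acc))] <- acc
          res
        }))
}
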