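# Neural-network primitives on [H, W, C] arrays for the autodiff tape:
# 3x3 same-padding convolution (im2col + matrix product), 1x1 channel mixing,
# 2x2 max pooling, factor-2 bilinear upsampling, channel slicing/stacking.

# Flattened index map into the zero-padded [H+2, W+2, C] array for each of
# the 9 neighborhood offsets (columns); cached per shape.
.im2col_idx <- function(H, W, C) {
  key <- paste0("i2c", H, "x", W, "x", C)
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  h <- rep.int(seq_len(H), times = W * C)
  w <- rep.int(rep(seq_len(W), each = H), times = C)
  c <- rep(seq_len(C), each = H * W)
  base <- (c - 1L) * (Hp * Wp)
  idx <- matrix(0L, H * W * C, 9L)
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    o <- o + 1L
    idx[, o] <- (h + dy) + Hp * (w + dx - 1L) + base
  }
  .ad$cache[[key]] <- idx
  idx
}

# im2col for a 3x3 neighborhood with zero padding: [H*W, 9*C] matrix.
.im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  idx <- .im2col_idx(H, W, C)
  col <- matrix(0, H * W, 9 * C)
  for (o in 1:9)
    col[, (o - 1L) * C + seq_len(C)] <- xp[idx[, o]]
  col
}

.col2im3 <- function(gcol, H, W, C) {
  idx <- .im2col_idx(H, W, C)
  gp <- numeric((H + 2) * (W + 2) * C)
  for (o in 1:9) {
    i <- idx[, o]
    gp[i] <- gp[i] + gcol[, (o - 1L) * C + seq_len(C)]
  }
  dim(gp) <- c(H + 2, W + 2, C)
  gp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

# 3x3 same-padding convolution: x [H,W,Cin], w [9*Cin, Cout], b [Cout]
ad_conv3 <- function(x, w, b) {
  vx <- ad_value(x); vw <- ad_value(w); vb <- ad_value(b)
  d <- dim(vx)
  H <- d[1]; W <- d[2]; Cin <- d[3]; Cout <- ncol(vw)
  col <- .im2col3(vx)
  y <- col %*% vw
  y <- sweep(y, 2, vb, `+`)
  ad_op(array(y, c(H, W, Cout)), list(x, w, b),
        list(
          function(g) {
            gm <- matrix(g, H * W, Cout)
            .col2im3(tcrossprod(gm, vw), H, W, Cin)
          },
          function(g) crossprod(col, matrix(g, H * W, Cout)),
          function(g) colSums(matrix(g, H * W, Cout))
        ))
}

# 1x1 convolution (pure channel mixing): w [Cin, Cout], b [Cout]
ad_conv1 <- function(x, w, b) {
  vx <- ad_value(x); vw <- ad_value(w); vb <- ad_value(b)
  d <- dim(vx)
  xm <- matrix(vx, d[1] * d[2], d[3])
  y <- sweep(xm %*% vw, 2, vb, `+`)
  ad_op(array(y, c(d[1], d[2], ncol(vw))), list(x, w, b),
        list(
          function(g) array(tcrossprod(matrix(g, d[1] * d[2], ncol(vw)), vw), d),
          function(g) crossprod(xm, matrix(g, d[1] * d[2], ncol(vw))),
          function(g) colSums(matrix(g, d[1] * d[2], ncol(vw)))
        ))
}

# 2x2 max pooling (H, W even)
ad_maxpool2 <- function(x) {
  vx <- ad_value(x)
  d <- dim(vx)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  s <- list(vx[io, jo, , drop = FALSE], vx[io + 1, jo, , drop = FALSE],
            vx[io, jo + 1, , drop = FALSE], vx[io + 1, jo + 1, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  ad_op(m, list(x),
        list(function(g) {
          gx <- array(0, d)
          taken <- array(FALSE, dim(m))  # first-argmax tie break
          put <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
          for (k in 1:4) {
            hit <- (s[[k]] == m) & !taken
            taken <- taken | hit
            gi <- g * hit
            gx[io + put[[k]][1], jo + put[[k]][2], ] <-
              gx[io + put[[k]][1], jo + put[[k]][2], , drop = FALSE] + gi
          }
          gx
        }))
}

# 1-D bilinear interpolation matrix for factor-2 upsampling (align corners
# false): output pixel centers at (i - 0.5) / 2 in input pixel units.
.upsample_mat <- function(Hin) {
  key <- paste0("up", Hin)
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- 2L * Hin
  R <- matrix(0, Hout, Hin)
  for (i in seq_len(Hout)) {
    cpos <- (i - 0.5) / 2          # in units of input pixels, centers at j-0.5
    j <- floor(cpos + 0.5)          # lower neighbor index
    frac <- cpos - (j - 0.5)
    j0 <- min(max(j, 1L), Hin)
    j1 <- min(max(j + 1L, 1L), Hin)
    R[i, j0] <- R[i, j0] + (1 - frac)
    R[i, j1] <- R[i, j1] + frac
  }
  .ad$cache[[key]] <- R
  R
}

# factor-2 bilinear upsampling of [H, W, C]
ad_upsample2 <- function(x) {
  vx <- ad_value(x)
  d <- dim(vx)
  Ry <- .upsample_mat(d[1]); Rx <- .upsample_mat(d[2])
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- tcrossprod(Ry %*% vx[, , c], Rx)
  ad_op(out, list(x),
        list(function(g) {
          gx <- array(0, d)
          for (c in seq_len(d[3])) gx[, , c] <- crossprod(Ry, g[, , c]) %*% Rx
          gx
        }))
}

# channel slice -> matrix [H, W]
ad_slice3 <- function(x, c_idx) {
  vx <- ad_value(x)
  d <- dim(vx)
  ad_op(vx[, , c_idx], list(x),
        list(function(g) {
          gx <- array(0, d)
          gx[, , c_idx] <- g
          gx
        }))
}

# stack a list of [H, W] nodes into [H, W, C]
ad_stack3 <- function(slices) {
  vals <- lapply(slices, ad_value)
  d <- dim(vals[[1]])
  C <- length(slices)
  out <- array(0, c(d[1], d[2], C))
  for (c in seq_len(C)) out[, , c] <- vals[[c]]
  vjps <- lapply(seq_len(C), function(c) {
    force(c)
    function(g) g[, , c]
  })
  ad_op(out, slices, vjps)
}

# crop rows/cols of an [H, W, C] array (adjoint scatters back)
ad_crop3 <- function(x, rows, cols) {
  vx <- ad_value(x)
  d <- dim(vx)
  ad_op(vx[rows, cols, , drop = FALSE], list(x),
        list(function(g) {
          gx <- array(0, d)
          gx[rows, cols, ] <- g
          gx
        }))
}

# spatial (instance/batch style) normalization over H, W per channel,
# composed from tape ops so gradients flow through the moments.
ad_spatial_norm <- function(x, eps = 1e-5) {
  mu <- ad_cmean(x)
  xc <- ad_cadd(x, -1 * mu)
  v <- ad_cmean(xc * xc)
  ad_cscale(xc, 1 / sqrt(v + eps))
}

# per-bin mean of a matrix given an integer bin map (0 = drop); linear
ad_binmean <- function(x, bin, n_bins) {
  vx <- ad_value(x)
  keep <- bin > 0
  counts <- tabulate(bin[keep], nbins = n_bins)
  sums <- numeric(n_bins)
  acc <- tapply(vx[keep], bin[keep], sum)
  sums[as.integer(names(acc))] <- acc
  ad_op(sums / pmax(counts, 1), list(x),
        list(function(g) {
          gx <- array(0, dim(vx))
          gx[keep] <- (g / pmax(counts, 1))[bin[keep]]
          gx
        }))
}
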