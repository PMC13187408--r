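# Synthetic multispectral fluorescence phantoms: channel-distinct structure
# (nuclei-like blobs, filament networks, membrane rings, sparse puncta) in
# [0, 1], plus dataset plumbing (band selection, splits, augmentation).
# These are structural stand-ins for real stained-cell data, not a
# statistical model of any particular dye or cell line.

#' Phantom recipe
#'
#' @param kind One of `"nuclei"`, `"filaments"`, `"membranes"`, `"puncta"`,
#'   `"mixed"`. `"mixed"` cycles the four archetypes over the channels
#'   (nuclei, filaments, membranes, puncta), emulating four fluorescence
#'   labels with distinct spatial statistics; any other kind uses that
#'   archetype for every channel.
#' @param size Patch side in pixels.
#' @param channels Channel count.
#' @param density Object-density multiplier (1 = default density).
#' @param contrast Peak intensity scale in `(0, 1]`.
#' @param seed Integer seed; the patch is a deterministic function of the
#'   recipe.
#' @return A `phantom_recipe`.
#' @export
phantom_recipe <- function(kind = "mixed", size = 512L, channels = 4L,
                           density = 1, contrast = 1, seed = 1L) {
  kind <- match.arg(kind, c("mixed", "nuclei", "filaments", "membranes",
                            "puncta"))
  stopifnot(size >= 16, channels >= 1, density > 0,
            contrast > 0, contrast <= 1)
  structure(list(kind = kind, size = as.integer(size),
                 channels = as.integer(channels), density = density,
                 contrast = contrast, seed = as.integer(seed)),
            class = "phantom_recipe")
}

.draw_nuclei <- function(S, density, contrast) {
  n <- max(1, round(8 * density * (S / 128)^2))
  xs <- matrix(rep(seq_len(S), each = S), S, S)
  ys <- matrix(rep(seq_len(S), times = S), S, S)
  img <- matrix(0, S, S)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
    r1 <- stats::runif(1, 0.05, 0.11) * S; r2 <- r1 * stats::runif(1, 0.6, 1)
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 0.5, 1) * contrast
    dx <- xs - cx; dy <- ys - cy
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    d <- sqrt((u / r1)^2 + (v / r2)^2)
    img <- pmax(img, amp / (1 + exp((d - 1) * 8)))
  }
  list(img = pmin(img, 1), count = n)
}

.draw_filaments <- function(S, density, contrast) {
  n <- max(1, round(8 * density * S / 128))
  img <- matrix(0, S, S)
  for (i in seq_len(n)) {
    len <- round(stats::runif(1, 0.5, 1.4) * S)
    x <- stats::runif(1, 1, S); y <- stats::runif(1, 1, S)
    th <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1) * contrast
    for (s in seq_len(len)) {
      th <- th + stats::rnorm(1, 0, 0.09)
      x <- x + cos(th); y <- y + sin(th)
      xi <- round(x); yi <- round(y)
      if (xi < 1 || xi > S || yi < 1 || yi > S) break
      img[yi, xi] <- max(img[yi, xi], amp)
    }
  }
  k <- gaussian_kernel(5L, 0.7)
  # FFT-based blur can leave O(1e-16) negatives; clamp to the contract
  list(img = pmin(pmax(.blur2(img, k) * 2.2, 0), 1), count = n)
}

.draw_membranes <- function(S, density, contrast) {
  n <- max(1, round(5 * density * (S / 128)^2))
  xs <- matrix(rep(seq_len(S), each = S), S, S)
  ys <- matrix(rep(seq_len(S), times = S), S, S)
  img <- matrix(0, S, S)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
    r1 <- stats::runif(1, 0.10, 0.20) * S; r2 <- r1 * stats::runif(1, 0.7, 1)
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 0.5, 1) * contrast
    wall <- stats::runif(1, 0.02, 0.05)
    dx <- xs - cx; dy <- ys - cy
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    d <- sqrt((u / r1)^2 + (v / r2)^2)
    img <- pmax(img, amp * exp(-((d - 1) / wall)^2))
  }
  list(img = pmin(img, 1), count = n)
}

.draw_puncta <- function(S, density, contrast) {
  n <- max(1, round(40 * density * (S / 128)^2))
  img <- matrix(0, S, S)
  cx <- stats::runif(n, 3, S - 2); cy <- stats::runif(n, 3, S - 2)
  amp <- stats::runif(n, 0.4, 1) * contrast
  sg <- stats::runif(n, 0.8, 1.8)
  for (i in seq_len(n)) {
    r <- ceiling(3 * sg[i])
    xr <- max(1, round(cx[i]) - r):min(S, round(cx[i]) + r)
    yr <- max(1, round(cy[i]) - r):min(S, round(cy[i]) + r)
    g <- amp[i] * exp(-(outer((yr - cy[i])^2, (xr - cx[i])^2, `+`)) /
                        (2 * sg[i]^2))
    img[yr, xr] <- pmax(img[yr, xr], g)
  }
  list(img = pmin(img, 1), count = n)
}

#' Generate a multispectral fluorescence phantom
#'
#' Renders the recipe's channels in `[0, 1]`: soft-edged elliptical blobs
#' (nuclei-like), curvilinear filament networks, elliptical membrane rings
#' and sparse diffraction-scale puncta. Deterministic given the recipe seed.
#'
#' @param recipe A [phantom_recipe()].
#' @return `[size, size, channels]` array with attribute `stats` (a
#'   data.frame of per-channel archetype, object count and mean intensity).
#' @export
generate_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(recipe$seed)
  archetypes <- c("nuclei", "filaments", "membranes", "puncta")
  kinds <- if (recipe$kind == "mixed") {
    archetypes[((seq_len(recipe$channels) - 1L) %% 4L) + 1L]
  } else rep(recipe$kind, recipe$channels)
  S <- recipe$size
  out <- array(0, c(S, S, recipe$channels))
  stats_df <- data.frame(channel = seq_len(recipe$channels),
                         archetype = kinds, count = NA_real_,
                         mean_intensity = NA_real_)
  for (c in seq_len(recipe$channels)) {
    drawn <- switch(kinds[c],
                    nuclei = .draw_nuclei(S, recipe$density, recipe$contrast),
                    filaments = .draw_filaments(S, recipe$density,
                                                recipe$contrast),
                    membranes = .draw_membranes(S, recipe$density,
                                                recipe$contrast),
                    puncta = .draw_puncta(S, recipe$density, recipe$contrast))
    out[, , c] <- drawn$img
    stats_df$count[c] <- drawn$count
    stats_df$mean_intensity[c] <- mean(drawn$img)
  }
  attr(out, "stats") <- stats_df
  out
}

#' Select spectral bands nearest to target wavelengths
#'
#' For each target wavelength, picks the band of a hyperspectral cube whose
#' center wavelength is closest; equidistant ties resolve toward the shorter
#' wavelength.
#'
#' @param cube `[H, W, B]` array.
#' @param band_centers Length-B wavelengths (nm) of the cube's bands.
#' @param targets Target wavelengths (nm).
#' @return `[H, W, length(targets)]` array with attribute
#'   `selected_bands`.
#' @export
band_select <- function(cube, band_centers, targets) {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[3] == length(band_centers),
            length(band_centers) >= 1)
  sel <- vapply(targets, function(t) {
    d <- abs(band_centers - t)
    cand <- which(d == min(d))
    cand[which.min(band_centers[cand])]
  }, integer(1))
  out <- cube[, , sel, drop = FALSE]
  attr(out, "selected_bands") <- band_centers[sel]
  out
}

#' Seeded train/validation/test splits
#'
#' Shuffles `1:n` with the given seed and partitions by the floor of
#' `n * ratios`, distributing any remainder one item at a time to the splits
#' with the largest fractional part (earlier split on ties). Splits are
#' disjoint and exhaustive.
#'
#' @param n Number of items.
#' @param ratios Split fractions summing to 1 (default 80/10/10).
#' @param seed Integer seed.
#' @return Named list of index vectors (`train`, `validation`, `test` for
#'   three splits).
#' @export
make_splits <- function(n, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, n >= length(ratios))
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * ratios - sizes
    ord <- order(-frac, seq_along(ratios))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  out <- vector("list", length(ratios))
  pos <- 0L
  for (i in seq_along(ratios)) {
    out[[i]] <- sort(idx[pos + seq_len(sizes[i])])
    pos <- pos + sizes[i]
  }
  names(out) <- if (length(ratios) == 3L) c("train", "validation", "test")
                else paste0("split", seq_along(ratios))
  out
}

#' Augment a multichannel patch
#'
#' Random right-angle rotations, horizontal/vertical flips and a
#' multiplicative brightness factor, applied identically across channels and
#' re-clamped to `[0, 1]`. With all flags off the patch is returned
#' unchanged. Uses the current RNG state.
#'
#' @param patch `[H, W, C]` array.
#' @param flip,rotate Enable the geometric transforms.
#' @param brightness Length-2 range of the multiplicative factor, or `NULL`
#'   to disable.
#' @return Augmented patch.
#' @export
augment <- function(patch, flip = TRUE, rotate = TRUE,
                    brightness = c(0.8, 1.25)) {
  d <- dim(patch)
  out <- patch
  if (rotate) {
    k <- sample(0:3, 1)
    if (k > 0) {
      for (r in seq_len(k)) {
        rot <- array(0, c(d[2], d[1], d[3]))
        for (c in seq_len(d[3]))
          rot[, , c] <- t(out[rev(seq_len(dim(out)[1])), , c])
        out <- rot
        d <- dim(out)
      }
    }
  }
  if (flip) {
    if (stats::runif(1) < 0.5) out <- out[rev(seq_len(d[1])), , , drop = FALSE]
    if (stats::runif(1) < 0.5) out <- out[, rev(seq_len(d[2])), , drop = FALSE]
  }
  if (!is.null(brightness)) {
    f <- stats::runif(1, brightness[1], brightness[2])
    out <- out * f
  }
  pmin(pmax(out, 0), 1)
}

#' Write a simulated phantom dataset
#'
#' Generates `n` phantom patches, stores each as a multipage TIFF (one page
#' per channel) and writes a JSON manifest with recipes and the
#' train/validation/test split.
#'
#' @param dir Output directory (created).
#' @param n Number of patches.
#' @param recipe Template [phantom_recipe()]; each patch uses seed
#'   `recipe$seed + i - 1`.
#' @param ratios Split ratios for [make_splits()].
#' @return The manifest, invisibly.
#' @export
simulate_dataset <- function(dir, n, recipe = phantom_recipe(),
                             ratios = c(0.8, 0.1, 0.1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n)
  for (i in seq_len(n)) {
    r <- recipe
    r$seed <- recipe$seed + i - 1L
    ph <- generate_phantom(r)
    files[i] <- file.path(dir, sprintf("phantom_%04d.tif", i))
    tiff::writeTIFF(lapply(seq_len(dim(ph)[3]), function(c) ph[, , c]),
                    files[i], bits.per.sample = 32L)
  }
  manifest <- list(n = n, files = basename(files),
                   recipe = unclass(recipe),
                   splits = make_splits(n, ratios, seed = recipe$seed),
                   page_order = "channel-major")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
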