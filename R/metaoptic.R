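# Meta-optic parameterization: a radial vector of nanopillar widths, a
# width -> per-wavelength phase lookup table (the unit-cell library), and the
# composition of both into the pupil modulation phase.

#' Surrogate nanopillar unit-cell library
#'
#' Stand-in for electromagnetic unit-cell simulations: the phase delay of a
#' square dielectric nanopillar of edge width `w` at wavelength `lambda` is
#' modeled as `phase(w, lambda) = (2 pi / lambda) * height * (n_eff - 1)`
#' with a smooth, monotone fill-factor effective-index model
#' `n_eff = 1 + (n_pillar(lambda) - 1) * (w / period)^2` and a Cauchy pillar
#' index `n_pillar = A + B / lambda_um^2` (TiO2-like defaults). Phases are
#' kept unwrapped so the lookup stays smooth; by construction the default
#' geometry spans more than 2 pi at each default wavelength.
#'
#' @param widths Pillar edge widths in nm, strictly increasing, all less than
#'   `period`.
#' @param height Pillar height in nm.
#' @param wavelengths Wavelengths in nm.
#' @param index_model List with Cauchy coefficients `A`, `B` (um^2) and the
#'   unit-cell `period` (nm).
#' @return A `unit_cell_library`: `widths`, `phases` (matrix, one column per
#'   wavelength, radians), `wavelengths`, `height`, `material`.
#' @examples
#' lib <- surrogate_library()
#' apply(lib$phases, 2, function(p) diff(range(p))) / (2 * pi)  # >= 1
#' @export
surrogate_library <- function(widths = seq(40, 315, by = 5),
                              height = 700,
                              wavelengths = c(433, 521, 601, 681),
                              index_model = list(A = 2.23, B = 0.07,
                                                 period = 350)) {
  stopifnot(height > 0, all(widths >= 0), all(wavelengths > 0))
  if (any(widths >= index_model$period))
    stop("invalid geometry: widths must be below the unit-cell period",
         call. = FALSE)
  if (is.unsorted(widths, strictly = TRUE))
    stop("widths must be strictly increasing", call. = FALSE)
  lam_um <- wavelengths / 1000
  n_pillar <- index_model$A + index_model$B / lam_um^2
  fill <- (widths / index_model$period)^2
  phases <- sapply(seq_along(wavelengths), function(li) {
    n_eff <- 1 + (n_pillar[li] - 1) * fill
    (2 * pi / wavelengths[li]) * height * (n_eff - 1)
  })
  phases <- matrix(phases, nrow = length(widths))
  colnames(phases) <- paste0("phase_", wavelengths)
  structure(
    list(widths = as.numeric(widths), phases = phases,
         wavelengths = as.numeric(wavelengths), height = height,
         material = "TiO2-like surrogate"),
    class = "unit_cell_library"
  )
}

#' @export
print.unit_cell_library <- function(x, ...) {
  cat(sprintf(
    "Unit-cell library: %d widths in [%g, %g] nm, %d wavelength(s); %s\n",
    length(x$widths), min(x$widths), max(x$widths), length(x$wavelengths),
    x$material))
  span <- apply(x$phases, 2, function(p) diff(range(p)))
  cat(sprintf("  phase span / 2pi: %s\n",
              paste(sprintf("%.2f", span / (2 * pi)), collapse = ", ")))
  invisible(x)
}

#' Read / write a unit-cell library as delimited text
#'
#' The file format is comma-separated with header
#' `width_nm, phase_<lambda1>, phase_<lambda2>, ...` (phases in radians),
#' one row per width. `save_library()` followed by `load_library()`
#' round-trips exactly for finite decimal values.
#'
#' @param path File path.
#' @return `load_library()` a `unit_cell_library`; `save_library()` the path,
#'   invisibly.
#' @export
load_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s*,\\s*")[[1]]
  if (header[1] != "width_nm" || length(header) < 2L ||
      !all(grepl("^phase_", header[-1])))
    stop("library header must be `width_nm, phase_<nm>, ...`; missing ",
         "column(s): ",
         paste(setdiff("width_nm", header), collapse = ", "), call. = FALSE)
  wavelengths <- as.numeric(sub("^phase_", "", header[-1]))
  if (anyNA(wavelengths))
    stop("could not parse wavelength from column(s): ",
         paste(header[-1][is.na(wavelengths)], collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_along(lines[-1]), function(i) {
    cells <- strsplit(trimws(lines[i + 1]), "\\s*,\\s*")[[1]]
    if (length(cells) != length(header))
      stop(sprintf("ragged row at line %d: %d cells, expected %d",
                   i + 1, length(cells), length(header)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell at line %d", i + 1), call. = FALSE)
    vals
  })
  tab <- do.call(rbind, rows)
  widths <- tab[, 1]
  if (anyDuplicated(widths))
    stop("duplicate width rows in library", call. = FALSE)
  if (is.unsorted(widths, strictly = TRUE))
    stop("library widths must be strictly increasing", call. = FALSE)
  phases <- tab[, -1, drop = FALSE]
  colnames(phases) <- header[-1]
  structure(
    list(widths = widths, phases = phases, wavelengths = wavelengths,
         height = NA_real_, material = "loaded"),
    class = "unit_cell_library"
  )
}

#' @rdname load_library
#' @param lib A `unit_cell_library`.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "unit_cell_library"))
  header <- paste(c("width_nm", paste0("phase_", lib$wavelengths)),
                  collapse = ", ")
  rows <- apply(cbind(lib$widths, lib$phases), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ", "))
  writeLines(c(header, rows), path)
  invisible(path)
}

.lib_col <- function(lib, wavelength) {
  li <- match(wavelength, lib$wavelengths)
  if (is.na(li))
    stop("wavelength ", wavelength, " nm is not tabulated in the library",
         call. = FALSE)
  li
}

#' Differentiable width-to-phase spectral lookup
#'
#' Piecewise-linear interpolation of the library's per-wavelength phase
#' delays over the width grid. On tape nodes ([ad_param()]) the gradient
#' with respect to the widths is the local segment slope. Inputs are clamped
#' to the tabulated width range.
#'
#' @param lib A [surrogate_library()] / [load_library()] library.
#' @param gamma Widths in nm (numeric or `advar`, any shape).
#' @param wavelength One of the library's wavelengths (nm).
#' @return Phases in radians, same shape/type as `gamma`.
#' @export
width_to_phase <- function(lib, gamma, wavelength) {
  stopifnot(inherits(lib, "unit_cell_library"))
  if (length(lib$widths) == 0L) stop("empty library", call. = FALSE)
  li <- .lib_col(lib, wavelength)
  xs <- lib$widths
  ys <- lib$phases[, li]
  g <- if (is_ad(gamma)) ad_clamp(gamma, min(xs), max(xs))
       else pmin(pmax(gamma, min(xs)), max(xs))
  if (is_ad(g)) return(ad_interp_lookup(xs, ys, g))
  i <- findInterval(g, xs, rightmost.closed = TRUE, all.inside = TRUE)
  slope <- (ys[i + 1] - ys[i]) / (xs[i + 1] - xs[i])
  out <- ys[i] + slope * (g - xs[i])
  if (!is.null(dim(gamma))) dim(out) <- dim(gamma)
  out
}

#' Radial bin index map for a pupil grid
#'
#' Assigns every pixel inside the aperture to its nearest of `n_bins` radial
#' samples with centers uniformly spaced in normalized radius `rho` from 0
#' to 1. Pixels outside the aperture get index 0.
#'
#' @param grid A [make_pupil()] grid.
#' @param n_bins Number of radial samples.
#' @return Integer matrix of bin indices (0 outside the mask).
#' @export
radial_bins <- function(grid, n_bins) {
  stopifnot(inherits(grid, "pupil_grid"), n_bins >= 2)
  bin <- round(grid$rho * (n_bins - 1)) + 1L
  bin[bin > n_bins] <- n_bins
  bin[grid$mask == 0] <- 0L
  storage.mode(bin) <- "integer"
  bin
}

#' Azimuthal replication of a radial width vector
#'
#' Expands the radial width vector onto the full 2-D pupil by nearest
#' radial-bin assignment, producing a rotationally symmetric width map. The
#' operator is fixed and linear in `gamma`.
#'
#' @param gamma Radial width vector (length = number of radial bins).
#' @param grid A [make_pupil()] grid.
#' @param k_rot Azimuthal replication count (kept for interface symmetry;
#'   the radial construction is invariant to it).
#' @return `n x n` width map (0 outside the aperture); an `advar` when
#'   `gamma` is one.
#' @export
radial_map <- function(gamma, grid, k_rot = 8L) {
  n_bins <- length(ad_value(gamma))
  bin <- radial_bins(grid, n_bins)
  if (is_ad(gamma)) return(ad_scatter_radial(gamma, bin))
  out <- matrix(0, grid$n, grid$n)
  inside <- bin > 0
  out[inside] <- ad_value(gamma)[bin[inside]]
  out
}

#' Learnable meta-optic design
#'
#' The meta-optic is parameterized by a radial nanopillar-width vector
#' `gamma = gamma_init + delta_gamma`, clamped to the width bounds before the
#' phase lookup; `gamma_init` is a fixed initialization and `delta_gamma` the
#' learnable perturbation. By default `gamma_init` is the flat-pi
#' initialization: the tabulated width whose phase at the reference
#' wavelength is closest to pi, replicated over all radii (asserted to be
#' within one lookup quantum of pi).
#'
#' @param lib A unit-cell library.
#' @param n_bins Number of radial samples of `gamma`.
#' @param reference_wavelength Wavelength (nm) at which the flat-pi
#'   initialization is taken; defaults to the shortest library wavelength.
#' @param gamma_init Optional explicit initialization (overrides flat-pi).
#' @param width_bounds Length-2 clamp bounds in nm; default the library span.
#' @param k_rot Azimuthal replication count.
#' @return A `metaoptic_design` with `gamma_init`, `delta_gamma` (zeros),
#'   `width_bounds`, `k_rot`, `reference_wavelength`.
#' @export
metaoptic_design <- function(lib, n_bins,
                             reference_wavelength = min(lib$wavelengths),
                             gamma_init = NULL,
                             width_bounds = range(lib$widths),
                             k_rot = 8L) {
  stopifnot(inherits(lib, "unit_cell_library"), n_bins >= 2)
  if (is.null(gamma_init)) {
    li <- .lib_col(lib, reference_wavelength)
    ph <- lib$phases[, li]
    w_pi <- lib$widths[which.min(abs(ph - pi))]
    quantum <- max(abs(diff(ph)))
    if (min(abs(ph - pi)) > quantum)
      stop("library cannot realize a flat-pi initialization at ",
           reference_wavelength, " nm", call. = FALSE)
    gamma_init <- rep(w_pi, n_bins)
  } else {
    stopifnot(length(gamma_init) == n_bins)
  }
  structure(
    list(gamma_init = as.numeric(gamma_init),
         delta_gamma = numeric(n_bins),
         width_bounds = as.numeric(width_bounds),
         k_rot = as.integer(k_rot),
         reference_wavelength = reference_wavelength),
    class = "metaoptic_design"
  )
}

#' @export
print.metaoptic_design <- function(x, ...) {
  cat(sprintf(
    "Meta-optic design: %d radial bins, widths in [%g, %g] nm\n",
    length(x$gamma_init), x$width_bounds[1], x$width_bounds[2]))
  cat(sprintf("  gamma range: [%.1f, %.1f] nm; |delta| max %.2f nm\n",
              min(x$gamma_init + x$delta_gamma),
              max(x$gamma_init + x$delta_gamma),
              max(abs(x$delta_gamma))))
  invisible(x)
}

#' Effective widths of a design
#'
#' `clamp(gamma_init + delta_gamma)` to the width bounds.
#' @param design A [metaoptic_design()].
#' @param delta_gamma Perturbation (numeric or `advar`); defaults to the
#'   design's stored value.
#' @return Widths in nm (numeric or `advar`).
#' @export
effective_widths <- function(design, delta_gamma = design$delta_gamma) {
  g <- if (is_ad(delta_gamma)) {
    ad_clamp(design$gamma_init + delta_gamma,
             design$width_bounds[1], design$width_bounds[2])
  } else {
    pmin(pmax(design$gamma_init + delta_gamma,
              design$width_bounds[1]), design$width_bounds[2])
  }
  g
}

#' Meta-optic modulation phase on a pupil grid
#'
#' Composes clamping, the (linear) azimuthal replication and the
#' piecewise-linear spectral lookup:
#' `phi_M = width_to_phase(lib, radial_map(clamp(gamma_init + delta)), lam)`.
#' Because every pixel of a radial bin shares one width, the lookup is
#' evaluated per bin and scattered, which is pointwise identical. When
#' `delta_gamma` is a tape node, the result is differentiable end to end.
#'
#' @inheritParams effective_widths
#' @param lib A unit-cell library.
#' @param wavelength Wavelength in nm (must be tabulated).
#' @param grid A [make_pupil()] grid.
#' @return `n x n` phase matrix in radians (an `advar` if `delta_gamma` is).
#' @export
metaoptic_phase <- function(design, lib, wavelength, grid,
                            delta_gamma = design$delta_gamma) {
  gamma <- effective_widths(design, delta_gamma)
  phase_per_bin <- width_to_phase(lib, gamma, wavelength)
  radial_map(phase_per_bin, grid, design$k_rot)
}

#' Export a design as a width-map TIFF plus JSON metadata
#'
#' Writes the rotationally replicated width map as a 32-bit float TIFF with
#' widths normalized by the unit-cell period (scale recorded in the JSON
#' sidecar together with grid pitch, replication count and bounds).
#'
#' @param design A [metaoptic_design()].
#' @param grid A [make_pupil()] grid.
#' @param path Output TIFF path.
#' @param period Normalization scale in nm (default: upper width bound).
#' @return `path`, invisibly.
#' @export
export_design <- function(design, grid, path,
                          period = design$width_bounds[2]) {
  wmap <- radial_map(effective_widths(design), grid, design$k_rot)
  tiff::writeTIFF(wmap / period, path, bits.per.sample = 32L)
  meta <- list(grid_pitch_um = grid$ds, n = grid$n,
               pupil_diameter_um = grid$pupil_diameter,
               k_rot = design$k_rot, width_scale_nm = period,
               width_bounds_nm = design$width_bounds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
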