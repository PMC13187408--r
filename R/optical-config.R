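#' Describe the optical system
#'
#' Bundles the physical parameters of a wide-field fluorescence microscope
#' with a pupil-plane phase element: objective numerical aperture, emission
#' wavelengths, entrance-pupil diameter, nominal focus distance, magnification
#' and sensor geometry, plus the targeted extended depth of field.
#'
#' All lengths are given in the units stated below and stored as-is; the
#' planner and simulator convert internally where needed.
#'
#' @param numerical_aperture Objective NA (dimensionless, > 0).
#' @param wavelengths Emission wavelengths in nm, sorted ascending.
#' @param pupil_diameter Entrance-pupil diameter D in mm.
#' @param nominal_focus Nominal focus distance z0 in um (distance from the
#'   pupil principal plane at which the system is focused).
#' @param magnification Total magnification M (dimensionless).
#' @param sensor_pitch Sensor pixel pitch p in um.
#' @param sensor_counts Integer vector of length 2, pixels along x and y.
#' @param immersion_index Refractive index of the immersion medium.
#' @param target_dof Target extended depth of field in um, interpreted as a
#'   symmetric range `nominal_focus` +/- `target_dof/2`.
#'
#' @return An object of class `optical_config` (a validated list).
#' @examples
#' cfg <- optical_config(
#'   numerical_aperture = 1.1, wavelengths = c(433, 521, 601, 681),
#'   pupil_diameter = 6.64, nominal_focus = 3020, magnification = 60,
#'   sensor_pitch = 6.5, sensor_counts = c(2048, 2048), target_dof = 50
#' )
#' cfg
#' @seealso [plan_sampling()], [space_bandwidth()], [demo_config()]
#' @export
optical_config <- function(numerical_aperture,
                           wavelengths,
                           pupil_diameter,
                           nominal_focus,
                           magnification,
                           sensor_pitch,
                           sensor_counts,
                           immersion_index = 1.33,
                           target_dof = 50) {
  stopifnot(
    is.numeric(numerical_aperture), length(numerical_aperture) == 1L,
    numerical_aperture > 0,
    is.numeric(wavelengths), length(wavelengths) >= 1L, all(wavelengths > 0),
    is.numeric(pupil_diameter), pupil_diameter > 0,
    is.numeric(nominal_focus), nominal_focus > 0,
    is.numeric(magnification), magnification > 0,
    is.numeric(sensor_pitch), sensor_pitch > 0,
    length(sensor_counts) == 2L, all(sensor_counts >= 1),
    is.numeric(immersion_index), immersion_index >= 1,
    is.numeric(target_dof), target_dof > 0
  )
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("`wavelengths` must be sorted strictly ascending", call. = FALSE)
  if (nominal_focus <= target_dof / 2)
    stop("`nominal_focus` must exceed target_dof/2 so the defocus ",
         "coefficient stays finite across the target range", call. = FALSE)
  structure(
    list(
      numerical_aperture = numerical_aperture,
      wavelengths = as.numeric(wavelengths),
      pupil_diameter = pupil_diameter,
      nominal_focus = nominal_focus,
      magnification = magnification,
      sensor_pitch = sensor_pitch,
      sensor_counts = as.integer(sensor_counts),
      immersion_index = immersion_index,
      target_dof = target_dof
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  NA %.2f, immersion n = %.2f, M = %gx\n",
              x$numerical_aperture, x$immersion_index, x$magnification))
  cat(sprintf("  wavelengths: %s nm\n", paste(x$wavelengths, collapse = ", ")))
  cat(sprintf("  pupil D = %g mm, nominal focus z0 = %g um\n",
              x$pupil_diameter, x$nominal_focus))
  cat(sprintf("  sensor %d x %d px @ %g um; target DoF %g um\n",
              x$sensor_counts[1], x$sensor_counts[2], x$sensor_pitch,
              x$target_dof))
  invisible(x)
}

#' A representative high-NA multispectral configuration
#'
#' A water-immersion 60x/NA 1.1 wide-field system with a 2048 x 2048 sensor at
#' 6.5 um pitch and four fluorescence emission channels at 433, 521, 601 and
#' 681 nm. The pupil diameter and nominal focus follow from inverting the
#' worst-case defocus model against the published operating points of such a
#' system (see [fit_defocus_model()]).
#'
#' @param target_dof Target depth of field in um (default 50).
#' @return An [optical_config()] object.
#' @export
demo_config <- function(target_dof = 50) {
  optical_config(
    numerical_aperture = 1.1,
    wavelengths = c(433, 521, 601, 681),
    pupil_diameter = 6.643,
    nominal_focus = 3019.6,
    magnification = 60,
    sensor_pitch = 6.5,
    sensor_counts = c(2048L, 2048L),
    immersion_index = 1.33,
    target_dof = target_dof
  )
}

#' Read / write an optical configuration as JSON
#'
#' @param path File path.
#' @return `read_config()` returns an [optical_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("numerical_aperture", "wavelengths", "pupil_diameter",
            "nominal_focus", "magnification", "sensor_pitch", "sensor_counts")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("config file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(optical_config, x[intersect(names(x), c(need, "immersion_index",
                                                  "target_dof"))])
}

#' @rdname read_config
#' @param config An [optical_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "optical_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
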