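#' Camera specification for the synthetic TOF scene
#'
#' Describes a continuous-wave time-of-flight camera of the SR4K class:
#' 176 x 144 pixel sensor, 30 MHz modulation (unambiguous range
#' `c / (2 f)` = 5 m), mounted in top view at a fixed distance above the
#' plate carrying the cow model. Frames are matrices with `height` rows
#' and `width` columns; the model travels along the row (vertical image)
#' axis.
#'
#' @param width Number of image columns (pixels).
#' @param height Number of image rows (pixels).
#' @param hfov Field of view along the row axis (degrees); the wide camera
#'   axis is aligned with the direction of travel.
#' @param vfov Field of view along the column axis (degrees).
#' @param mount_distance Distance between sensor and plate (meters).
#' @param frame_rate Frames per second actually recorded (the sensor
#'   supports up to 54; the effective rate depends on exposure time).
#' @param modulation_frequency Modulation frequency f of the emitted
#'   infrared signal (Hz).
#' @param range_min,range_max Calibrated measurement range (meters).
#' @return An object of class `camera_spec`. Fields `dx`/`dy` give the
#'   metric pixel pitch on the plate along columns/rows.
#' @export
camera_spec <- function(width = 144L, height = 176L,
                        hfov = 43.6, vfov = 34.6,
                        mount_distance = 1.28, frame_rate = 9,
                        modulation_frequency = 3e7,
                        range_min = 0.8, range_max = 5.0) {
  stopifnot(width >= 1, height >= 1, frame_rate > 0, frame_rate <= 54,
            modulation_frequency > 0, mount_distance > 0,
            range_min >= 0, range_max > range_min)
  unambiguous <- .speed_of_light / (2 * modulation_frequency)
  cam <- list(
    width = as.integer(width), height = as.integer(height),
    hfov = hfov, vfov = vfov,
    mount_distance = mount_distance, frame_rate = frame_rate,
    modulation_frequency = modulation_frequency,
    range_min = range_min, range_max = range_max,
    unambiguous_range = unambiguous,
    # orthographic pixel pitch of the plate plane at the mount distance
    dy = 2 * mount_distance * tan(hfov / 2 * pi / 180) / height,
    dx = 2 * mount_distance * tan(vfov / 2 * pi / 180) / width
  )
  class(cam) <- "camera_spec"
  cam
}

# nominal speed of light: gives the camera's stated 5 m unambiguous range
# at 30 MHz exactly (c/(2f) = 5), as in the usual TOF range convention
.speed_of_light <- 3e8

#' Noise specification for the synthetic TOF scene
#'
#' Depth-noise standard deviations per surface class, the elevated noise of
#' the 1-2 pixel boundary band (a proxy for mixed-phase/multipath errors at
#' steep edges), and the velocity-dependent motion-artifact model. Default
#' sigmas follow the per-pixel temporal standard deviations observed on the
#' real recordings (plaster 3 mm, white fur 2 mm, black fur 6 mm, boundary
#' band 20 mm). Default artifact rates are a calibration, not physics: they
#' are chosen so that default simulations land near the recorded
#' high-quality-image ratios of the two arms.
#'
#' @param model_kind `"plaster"` or `"fur"`; selects the default artifact
#'   rate table.
#' @param sigma_plaster,sigma_white,sigma_black Depth noise sd (meters).
#' @param boundary_band_sigma Noise sd in the boundary band (meters).
#' @param boundary_band_width Width of the boundary band (pixels, 1-2).
#' @param artifact_rate Either a named numeric vector mapping velocities
#'   (cm/s) to corruption probabilities, or a function `function(v)`.
#'   Must be monotone non-decreasing in velocity.
#' @param phase_jitter Phase noise sd (radians) applied to demodulated
#'   phases at pixels whose four phase sub-samples saw inconsistent scene
#'   content; large values produce the erratic depth values typical of
#'   motion edges.
#' @param seed Root seed; per-frame random streams are derived
#'   deterministically from `(seed, frame index)`.
#' @return An object of class `noise_spec` with an `artifact_rate(v)`
#'   function field.
#' @export
noise_spec <- function(model_kind = c("plaster", "fur"),
                       sigma_plaster = 0.003, sigma_white = 0.002,
                       sigma_black = 0.006, boundary_band_sigma = 0.02,
                       boundary_band_width = 1L,
                       artifact_rate = NULL, phase_jitter = 2.5,
                       seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(sigma_black >= sigma_white, sigma_plaster >= 0,
            boundary_band_width >= 1, phase_jitter >= 0)
  if (is.null(artifact_rate)) {
    artifact_rate <- if (model_kind == "plaster") {
      c("0" = 0.13, "10" = 0.32, "20" = 0.34, "30" = 0.38)
    } else {
      c("0" = 0.0, "10" = 0.66, "20" = 0.94, "30" = 0.985)
    }
  }
  rate_fun <- if (is.function(artifact_rate)) {
    artifact_rate
  } else {
    v_grid <- as.numeric(names(artifact_rate))
    p_grid <- as.numeric(artifact_rate)
    if (is.unsorted(v_grid)) stop("artifact_rate velocities must ascend")
    if (is.unsorted(p_grid)) stop("artifact_rate must be monotone non-decreasing")
    function(v) stats::approx(v_grid, p_grid, xout = v, rule = 2)$y
  }
  if (rate_fun(0) < 0) stop("artifact_rate(0) must be >= 0")
  ns <- list(model_kind = model_kind,
             sigma_plaster = sigma_plaster, sigma_white = sigma_white,
             sigma_black = sigma_black,
             boundary_band_sigma = boundary_band_sigma,
             boundary_band_width = as.integer(boundary_band_width),
             artifact_rate = rate_fun, phase_jitter = phase_jitter,
             seed = as.integer(seed))
  class(ns) <- "noise_spec"
  ns
}

#' Motion specification
#'
#' Standstill recordings run for a fixed duration at a centred position;
#' moving recordings tow the model through the field of view at a
#' controlled velocity for a number of passes. The defaults are the study
#' conditions: four minutes of standstill and five passes at each of
#' 10, 20 and 30 cm/s.
#'
#' @param velocity Velocity in cm/s (0 = standstill).
#' @param passes Number of passes through the field of view (moving).
#' @param duration Recording duration in seconds (standstill).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(velocity = 0, passes = 5L, duration = 240) {
  stopifnot(velocity >= 0, passes >= 1, duration > 0)
  ms <- list(velocity = velocity, passes = as.integer(passes),
             duration = duration)
  class(ms) <- "motion_spec"
  ms
}

#' Default velocity grid of the experiment (cm/s)
#' @export
default_velocities <- function() c(0, 10, 20, 30)
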