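#' Depth from four phase samples
#'
#' Continuous-wave TOF cameras estimate the phase delay `t_d` of the
#' returning modulated signal from four charge samples Q1..Q4 gated by
#' control signals 90 degrees apart: `t_d = atan2(Q3 - Q4, Q1 - Q2)`,
#' mapped to `[0, 2*pi)`. Distance follows as
#' `d = c/(2 f) * t_d/(2*pi)`, bounded by the unambiguous range `c/(2 f)`.
#'
#' Degenerate charge sets (`Q1 == Q2` and `Q3 == Q4`) carry no phase
#' information; these are flagged invalid (`NA` depth), not raised as
#' errors, matching how a camera reports low-confidence pixels.
#'
#' @param q Numeric vector of length 4 `(Q1, Q2, Q3, Q4)`, or a matrix
#'   with 4 columns for vectorised use. Charges must be non-negative.
#' @param camera A [camera_spec()].
#' @return A list with `depth` (meters, `NA` where invalid), `phase`
#'   (radians in `[0, 2*pi)`) and `valid` (logical).
#' @export
depth_from_phases <- function(q, camera = camera_spec()) {
  if (is.null(dim(q))) {
    if (length(q) %% 4 != 0) stop("q must have 4 charges per measurement")
    q <- matrix(q, ncol = 4, byrow = TRUE)
  }
  stopifnot(ncol(q) == 4)
  if (any(q < 0, na.rm = TRUE)) stop("charges must be non-negative")
  i <- q[, 1] - q[, 2]
  s <- q[, 3] - q[, 4]
  valid <- !(i == 0 & s == 0)
  phase <- atan2(s, i) %% (2 * pi)
  depth <- camera$unambiguous_range * phase / (2 * pi)
  depth[!valid] <- NA_real_
  phase[!valid] <- NA_real_
  list(depth = depth, phase = phase, valid = valid)
}

#' Synthesise four phase samples from a distance
#'
#' Forward model of the four-phase demodulation: for a target at distance
#' `d`, phase `phi = 2*pi*d / (c/(2 f))`, the gated charges are
#' `Q1 = B + A cos(phi)`, `Q2 = B - A cos(phi)`, `Q3 = B + A sin(phi)`,
#' `Q4 = B - A sin(phi)` with signal amplitude `A` and offset `B >= A`
#' (charges are non-negative). [depth_from_phases()] inverts this exactly
#' on `[0, c/(2 f))`.
#'
#' @param depth Distances (meters), in `[0, unambiguous range)`.
#' @param camera A [camera_spec()].
#' @param amplitude Signal amplitude `A` (arbitrary linear units).
#' @param offset Charge offset `B`; defaults to `amplitude` so charges are
#'   non-negative.
#' @return A matrix with columns Q1..Q4, one row per distance.
#' @export
phases_from_depth <- function(depth, camera = camera_spec(),
                              amplitude = 100, offset = amplitude) {
  stopifnot(all(depth >= 0), all(depth < camera$unambiguous_range),
            offset >= amplitude)
  phi <- 2 * pi * depth / camera$unambiguous_range
  cbind(Q1 = offset + amplitude * cos(phi),
        Q2 = offset - amplitude * cos(phi),
        Q3 = offset + amplitude * sin(phi),
        Q4 = offset - amplitude * sin(phi))
}

#' Demodulate phase samples taken at four object sub-positions
#'
#' When the object moves during the acquisition of the four control
#' signals, each charge sample sees the scene at a different position.
#' Given the four per-pixel true depths `d0..d3` and per-pixel amplitudes
#' `a0..a3` at the four sub-sample instants, this mixes
#' `Q1 = B + a0 cos(phi0)`, `Q2 = B - a1 cos(phi1)`,
#' `Q3 = B + a2 sin(phi2)`, `Q4 = B - a3 sin(phi3)` and demodulates. At
#' pixels where all four sub-samples agree the result equals the true
#' depth; where they straddle a depth edge the demodulated depth lies
#' between the two surfaces (a motion smear).
#'
#' @param depths List of four equal-shaped numeric arrays (meters).
#' @param amplitudes List of four equal-shaped arrays, or a single number.
#' @param camera A [camera_spec()].
#' @return Numeric array of demodulated depths with the input shape.
#' @export
demodulate_moving <- function(depths, amplitudes = 100,
                              camera = camera_spec()) {
  stopifnot(length(depths) == 4)
  if (!is.list(amplitudes)) amplitudes <- rep(list(amplitudes), 4)
  rng <- camera$unambiguous_range
  phi <- lapply(depths, function(d) 2 * pi * d / rng)
  i <- amplitudes[[1]] * cos(phi[[1]]) + amplitudes[[2]] * cos(phi[[2]])
  s <- amplitudes[[3]] * sin(phi[[3]]) + amplitudes[[4]] * sin(phi[[4]])
  out <- rng * (atan2(s, i) %% (2 * pi)) / (2 * pi)
  dim(out) <- dim(depths[[1]])
  out
}
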