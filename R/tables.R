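#' Recorded and passing frame counts of the original experiment
#'
#' The frame bookkeeping of the original recordings: for each model
#' (plaster cast, fur-covered) and velocity (0, 10, 20, 30 cm/s), the
#' number of recorded frames `C` and the number `N` that passed all
#' quality tests of the recording software. These counts are the inputs
#' from which the high-quality-image ratios and all velocity fits are
#' recomputed.
#'
#' @return Data frame with columns `model`, `velocity` (cm/s), `C`, `N`.
#' @export
hqi_counts <- function() {
  data.frame(
    model = rep(c("plaster", "fur"), each = 4),
    velocity = rep(c(0, 10, 20, 30), 2),
    C = c(2155, 542, 482, 370, 2138, 411, 356, 267),
    N = c(1882, 371, 321, 231, 2138, 141, 21, 4)
  )
}

#' Landmark imprecision (RpV) of the original experiment
#'
#' Range-per-number-of-values of the automatically determined
#' X-coordinates for the six body parts of each model at the four
#' velocities, as measured on the original recordings, together with the
#' printed quadratic coefficients and goodness-of-fit statistics for
#' cross-checking recomputed fits.
#'
#' @return Data frame with columns `model`, `body_part`, `rpv_0`,
#'   `rpv_10`, `rpv_20`, `rpv_30`, `printed_coeff`, `printed_rmsd`,
#'   `printed_r2`.
#' @export
rpv_table <- function() {
  data.frame(
    model = rep(c("plaster", "fur"), each = 6),
    body_part = rep(c("isc_tub_l", "dish_l", "tail", "dish_r", "isc_tub_r",
                      "bb30"), 2),
    rpv_0  = c(0.008, 0.014, 0.014, 0.013, 0.018, 0.0011,
               0.002, 0.001, 0.002, 0,     0.001, 0.0005),
    rpv_10 = c(0.038, 0.062, 0.062, 0.067, 0.039, 0.0108,
               0.071, 0.106, 0.078, 0.036, 0.029, 0.0142),
    rpv_20 = c(0.044, 0.072, 0.069, 0.069, 0.046, 0.0156,
               0.3,   0.286, 0.191, 0.048, 0.095, 0.0476),
    rpv_30 = c(0.061, 0.1,   0.087, 0.1,   0.065, 0.026,
               2.5,   5.0,   0.75,  1.5,   2,     0.25),
    printed_coeff = c(0, -0.01, -0.01, -0.01, 0, 0,
                      0.53, 1.15, 0.12, 0.35, 0.47, 0.05),
    printed_rmsd = c(0.008, 0.013, 0.012, 0.018, 0.006, 0.001,
                     0.405, 0.998, 0.092, 0.33, 0.40, 0.002),
    printed_r2 = c(0.96, 0.96, 0.95, 0.92, 0.97, 0.98,
                   0.96, 0.94, 0.98, 0.93, 0.94, 0.57)
  )
}
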