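#' Ratio of high-quality images
#'
#' `N / C`: the fraction of recorded frames at one velocity that passed
#' all quality tests.
#'
#' @param n Number of frames passing all quality tests.
#' @param c_total Number of recorded frames (>= 1).
#' @return The ratio in `[0, 1]`.
#' @export
hqi_ratio <- function(n, c_total) {
  if (any(c_total < 1)) stop("hqi_ratio needs at least one recorded frame")
  if (any(n < 0 | n > c_total)) stop("need 0 <= N <= C")
  n / c_total
}

#' Pixel-wise summed absolute consecutive differences (SumDiff)
#'
#' For a standstill stream of `N0` frames, per pixel:
#' `1/(N0-1) * sum_i |frame_{i+1} - frame_i|`.
#'
#' @param frames `height x width x N0` array of segmented depth frames
#'   (meters), `N0 >= 2`.
#' @param mask Optional logical matrix; the criterion is zeroed outside
#'   it (typically the intersection of the stream's foreground masks).
#' @return Matrix of SumDiff values (meters).
#' @export
sum_diff <- function(frames, mask = NULL) {
  n <- dim(frames)[3]
  if (is.null(n) || n < 2) stop("SumDiff needs at least two frames")
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(n - 1)) {
    acc <- acc + abs(frames[, , i + 1] - frames[, , i])
  }
  out <- acc / (n - 1)
  if (!is.null(mask)) out[!mask] <- 0
  out
}

#' Pixel-wise temporal standard deviation (pwStd)
#'
#' Per-pixel sample standard deviation (denominator `N0 - 1`) of depth
#' across the frames of a standstill stream.
#'
#' @inheritParams sum_diff
#' @return Matrix of pwStd values (meters).
#' @export
pw_std <- function(frames, mask = NULL) {
  n <- dim(frames)[3]
  if (is.null(n) || n < 2) stop("pwStd needs at least two frames")
  H <- dim(frames)[1]; W <- dim(frames)[2]
  x <- matrix(frames, H * W, n)
  mu <- rowMeans(x)
  out <- matrix(sqrt(rowSums((x - mu)^2) / (n - 1)), H, W)
  if (!is.null(mask)) out[!mask] <- 0
  out
}

#' Intersection of a stream's foreground masks
#'
#' Pixels that are foreground in every frame of the stream, so that
#' consecutive-frame criteria always compare model surface with model
#' surface (mask jitter pixels fall to the boundary band).
#'
#' @param masks List of logical matrices.
#' @return Logical matrix.
#' @export
common_foreground <- function(masks) {
  Reduce(`&`, masks)
}

#' Range per number of values (RpV)
#'
#' Imprecision of a landmark's detected X-coordinates at one velocity:
#' `(max - min) / N`. Zero iff all coordinates are equal.
#'
#' @param x_coords Detected X (column) coordinates.
#' @param n Number of values `N_velocity`; defaults to `length(x_coords)`.
#' @return The RpV value, or `NA` (flagged undefined) for an empty input.
#' @export
rpv <- function(x_coords, n = length(x_coords)) {
  x_coords <- x_coords[!is.na(x_coords)]
  if (length(x_coords) == 0 || n < 1) return(NA_real_)
  (max(x_coords) - min(x_coords)) / n
}

#' Criterion summaries per region label
#'
#' Medians (the preferred centre for these skewed criteria), plus
#' min/max/mean, of a criterion matrix over each label of a region
#' partition.
#'
#' @param matrix_ A SumDiff or pwStd matrix.
#' @param partition A [partition_regions()] (optionally after
#'   [fur_color_mask()]) result.
#' @return Data frame with one row per label (`interior`, `boundary`,
#'   and when present `interior_white` / `interior_black`): `n`,
#'   `median`, `min`, `max`, `mean`. Empty labels carry `NA` and
#'   `present = FALSE`.
#' @export
medians_by_region <- function(matrix_, partition) {
  labels <- list(interior = partition$interior,
                 boundary = partition$boundary)
  if (!is.null(partition$interior_white)) {
    labels$interior_white <- partition$interior_white
    labels$interior_black <- partition$interior_black
  }
  rows <- lapply(names(labels), function(nm) {
    v <- matrix_[labels[[nm]]]
    if (length(v) == 0) {
      data.frame(label = nm, n = 0L, median = NA_real_, min = NA_real_,
                 max = NA_real_, mean = NA_real_, present = FALSE)
    } else {
      data.frame(label = nm, n = length(v), median = stats::median(v),
                 min = min(v), max = max(v), mean = mean(v), present = TRUE)
    }
  })
  do.call(rbind, rows)
}
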