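#' Average the empty scenery into a background model
#'
#' Per-pixel arithmetic mean depth over a stream of plate-only frames.
#'
#' @param stream A `tof_stream` (or a `height x width x n` array).
#' @return Object of class `background_model`: per-pixel mean depth
#'   (matrix, meters) with the source frame count as attribute `"n"`.
#' @export
average_empty_scenery <- function(stream) {
  depth <- if (inherits(stream, "tof_stream")) stream$depth else stream
  if (length(dim(depth)) == 2) depth <- array(depth, c(dim(depth), 1))
  n <- dim(depth)[3]
  if (is.null(n) || n < 1) stop("empty scenery stream has no frames")
  bg <- apply(depth, c(1, 2), mean)
  if (!all(is.finite(bg))) stop("background model contains non-finite values")
  structure(bg, n = n, class = c("background_model", "matrix", "array"))
}

#' Segmentation configuration
#'
#' @param height_band Elevation band (meters above plate) accepted as
#'   model surface; adapted to the models' maximum height of 0.22 m.
#' @param beam_rects List of beam pixel rectangles `c(r1, r2, c1, c2)`
#'   to remove from the candidate mask (fur model); specified once per
#'   installation, as the beams ride with the model only in world
#'   coordinates, not in the standstill pixel frame. `NULL` for none.
#' @param area_min,area_max Accepted foreground area (pixels).
#' @param range_frac Maximum tolerated fraction of foreground depths
#'   outside the calibrated range / height band.
#' @param min_fragment Secondary candidate components at least this large
#'   (pixels) count as fragmentation.
#' @param required_landmarks Landmarks that must be defined for a frame
#'   to pass.
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(height_band = c(0.02, 0.25), beam_rects = NULL,
                       area_min = 2000, area_max = 20000,
                       range_frac = 0.01, min_fragment = 100,
                       required_landmarks = c("tail", "isc_tub_l",
                                              "isc_tub_r", "dish_l",
                                              "dish_r", "bb30")) {
  stopifnot(length(height_band) == 2, height_band[1] < height_band[2],
            area_min >= 0, area_max > area_min)
  cfg <- list(height_band = height_band, beam_rects = beam_rects,
              area_min = area_min, area_max = area_max,
              range_frac = range_frac, min_fragment = min_fragment,
              required_landmarks = required_landmarks)
  class(cfg) <- "seg_config"
  cfg
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (dr in c(-1, 1)) for (dc in c(-1, 1)) {
    sh <- shift_mat_num(lab, dr, dc)
    sel <- lab > 0 & sh > 0 & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], sh[sel]))
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(nmax), function(i) as.integer(find(i)), integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

shift_mat_num <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Segment a frame against the background model
#'
#' Elevation is `background - frame`; pixels inside the configured height
#' band form the candidate mask. Configured beam rectangles are removed;
#' a rectangle spanning the foreground's column extent down to the lower
#' image edge is temporarily appended so the body-presence rule (cow area
#' reaching the lower border) holds for models that end above it, and
#' removed again after the check. The largest 8-connected component is
#' retained, enclosed holes are filled, and background depths are zeroed.
#'
#' @param frame Depth frame (matrix, meters).
#' @param background A [average_empty_scenery()] background model.
#' @param cfg A [seg_config()].
#' @return Object of class `segmented_frame`: `depth` (background zeroed),
#'   `mask`, `elevation`, `candidate_sizes` (component sizes before
#'   cleanup), `verdict` (`pass`/`fail`) and `reasons`.
#' @export
segment_frame <- function(frame, background, cfg = seg_config()) {
  if (!all(dim(frame) == dim(background))) stop("frame/background shape mismatch")
  elevation <- unclass(background) - frame
  candidate <- elevation >= cfg$height_band[1] & elevation <= cfg$height_band[2]
  if (!is.null(cfg$beam_rects)) {
    for (rect in cfg$beam_rects) {
      candidate[rect[1]:rect[2], rect[3]:rect[4]] <- FALSE
    }
  }
  sf <- list(depth = matrix(0, nrow(frame), ncol(frame)),
             mask = matrix(FALSE, nrow(frame), ncol(frame)),
             elevation = elevation, candidate_sizes = integer(0),
             verdict = "fail", reasons = character(0), raw = frame)
  class(sf) <- "segmented_frame"
  if (!any(candidate)) {
    sf$reasons <- "no foreground"
    return(sf)
  }
  # rectangle augmentation: close the gap to the lower image edge so the
  # body-presence rule holds; it contributes no pixels downstream
  cols <- range(which(colSums(candidate) > 0))
  low_row <- max(which(rowSums(candidate) > 0))
  augmented <- candidate
  if (low_row < nrow(candidate)) {
    augmented[(low_row + 1):nrow(candidate), cols[1]:cols[2]] <- TRUE
  }
  body_present <- any(augmented[nrow(augmented), ])
  if (!body_present) {  # unreachable by construction; kept for ingest data
    sf$reasons <- "no foreground"
    return(sf)
  }
  lab <- label_components8(candidate)   # rectangle removed again: label the
  sizes <- tabulate(lab[lab > 0])       # original candidate, not `augmented`
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) == 1
  sf$mask <- mask
  sf$depth <- frame * mask
  sf$candidate_sizes <- sort(sizes, decreasing = TRUE)
  sf$verdict <- "segmented"
  sf
}

#' Frame quality tests
#'
#' A frame fails if any of: no foreground; foreground area outside
#' `[area_min, area_max]`; foreground touching the left, right or top
#' image border (truncated view — the lower border is covered by the
#' body-presence rectangle rule); fragmentation (a secondary candidate
#' component of at least `min_fragment` px); more than `range_frac` of
#' foreground depths outside the calibrated range or implying elevations
#' outside the height band (erratic demodulation); any required landmark
#' undefined. All failures are enumerated in `reasons`.
#'
#' @param sf A [segment_frame()] result.
#' @param cfg A [seg_config()].
#' @param camera A [camera_spec()] (calibrated range).
#' @return List `pass` (logical), `reasons` (character), `landmarks`
#'   (the [detect_landmarks()] table, when the frame had a foreground).
#' @export
quality_tests <- function(sf, cfg = seg_config(), camera = camera_spec()) {
  reasons <- character(0)
  mask <- sf$mask
  area <- sum(mask)
  if (area == 0) {
    return(list(pass = FALSE, reasons = "no foreground", landmarks = NULL))
  }
  if (area < cfg$area_min || area > cfg$area_max) {
    reasons <- c(reasons, "area out of bounds")
  }
  if (any(mask[, 1]) || any(mask[, ncol(mask)]) || any(mask[1, ])) {
    reasons <- c(reasons, "border contact")
  }
  if (length(sf$candidate_sizes) > 1 &&
      sf$candidate_sizes[2] >= cfg$min_fragment) {
    reasons <- c(reasons, "fragmented foreground")
  }
  depths <- sf$raw[mask]
  elevs <- sf$elevation[mask]
  out_of_range <- depths < camera$range_min | depths > camera$range_max |
    elevs < cfg$height_band[1] | elevs > cfg$height_band[2]
  if (mean(out_of_range) > cfg$range_frac) {
    reasons <- c(reasons, "depth out of range")
  }
  lms <- detect_landmarks(sf)
  need <- cfg$required_landmarks
  undef <- need[!need %in% lms$name[lms$defined]]
  if (length(undef) > 0) {
    reasons <- c(reasons, "landmark undefined")
  }
  list(pass = length(reasons) == 0, reasons = reasons, landmarks = lms)
}

#' Mirror a frame on the vertical midline
#'
#' Reverses the 144 columns, so column j maps to column 145 - j; the
#' mirror axis runs between columns 72 and 73. Applying it twice is the
#' identity.
#'
#' @param frame Matrix with 144 columns (depth or amplitude).
#' @return The mirrored matrix.
#' @export
mirror_frame <- function(frame) {
  if (ncol(frame) != 144) {
    stop("mirror_frame expects the sensor's 144 columns, got ", ncol(frame))
  }
  frame[, rev(seq_len(ncol(frame))), drop = FALSE]
}
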