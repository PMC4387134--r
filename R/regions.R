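#' Partition the foreground into Boundary and Interior
#'
#' A foreground pixel whose radius-1 (Moore, 8-neighbour) neighbourhood
#' intersects the background is "boundary"; a foreground pixel whose
#' neighbourhood is fully foreground is "interior". The image border
#' counts as background, so a region touching the border still has a
#' boundary. Boundary and interior are disjoint and their union is the
#' foreground.
#'
#' @param mask Logical (or 0/1) matrix: foreground mask.
#' @return Object of class `region_partition`: `labels` (matrix of
#'   `"background"`, `"boundary"`, `"interior"`), logical `boundary` and
#'   `interior` masks, and per-label `counts`.
#' @export
partition_regions <- function(mask) {
  mask <- mask > 0
  interior <- mask & erode_shift(mask, 1L)
  boundary <- mask & !interior
  labels <- matrix("background", nrow(mask), ncol(mask))
  labels[boundary] <- "boundary"
  labels[interior] <- "interior"
  part <- list(labels = labels, boundary = boundary, interior = interior,
               counts = c(background = sum(!mask), boundary = sum(boundary),
                          interior = sum(interior)))
  class(part) <- "region_partition"
  part
}

#' Split the interior by fur colour using the amplitude image
#'
#' All interior pixels with gray value at or above the threshold belong
#' to the white spot; the rest of the interior is black. Boundary pixels
#' are never sub-labelled. Amplitude frames from the simulator are
#' already on a 0-255 scale; 16-bit external input should be min-max
#' scaled per stream to 0-255 beforehand (see [scale_amplitude()]).
#'
#' @param amplitude Amplitude frame on a 0-255 gray scale.
#' @param partition A [partition_regions()] result.
#' @param threshold Gray level at or above which a pixel is white.
#' @return The partition, extended with logical `interior_white` /
#'   `interior_black` masks and updated `counts`.
#' @export
fur_color_mask <- function(amplitude, partition, threshold = 25) {
  white <- partition$interior & amplitude >= threshold
  black <- partition$interior & !white
  partition$interior_white <- white
  partition$interior_black <- black
  partition$labels[white] <- "interior_white"
  partition$labels[black] <- "interior_black"
  partition$counts <- c(partition$counts,
                        interior_white = sum(white),
                        interior_black = sum(black))
  partition
}

#' Linearly rescale an amplitude frame to the 0-255 gray scale
#'
#' @param amplitude Numeric matrix (e.g. 16-bit amplitudes).
#' @return Matrix scaled so the stream minimum maps to 0 and the maximum
#'   to 255.
#' @export
scale_amplitude <- function(amplitude) {
  lo <- min(amplitude); hi <- max(amplitude)
  if (hi == lo) return(matrix(0, nrow(amplitude), ncol(amplitude)))
  (amplitude - lo) / (hi - lo) * 255
}

#' Detect the six lower-back landmarks on a segmented frame
#'
#' A deliberately simple geometric detector standing in for the original
#' (unpublished) body-trait software: the backbone trace is the per-row
#' elevation-maximum column within the central third of the model's
#' column extent, median-smoothed over 5 rows; the tail is the posterior
#' (largest-row) end of the trace; the ischeal tuberosities are the
#' elevation maxima of the posterior-lateral quadrants; the rump dishes
#' are the elevation minima between backbone and each tuberosity; BB30 is
#' the trace point at a 30 px Euclidean radius from the tail. Landmarks
#' without a qualifying extremum (flat surface, missing prominence,
#' empty search region) are flagged "undefined" rather than erroring.
#'
#' @param sf A [segment_frame()] result (needs `mask` and `elevation`).
#' @param prominence_tub Minimum prominence (meters) of a tuberosity
#'   maximum over its quadrant median.
#' @param prominence_dish Minimum depression (meters) of a dish minimum
#'   below its search-region median.
#' @param flat_tol Elevation range (meters) below which the surface is
#'   treated as a featureless slab (all landmarks undefined).
#' @return Object of class `landmark_set`: a data frame with `name`,
#'   `row`, `col`, `defined`, plus the backbone `trace` (data frame
#'   `row`, `col`) as an attribute.
#' @export
detect_landmarks <- function(sf, prominence_tub = 0.015,
                             prominence_dish = 0.008, flat_tol = 0.01) {
  empty <- landmark_frame()
  mask <- sf$mask
  if (!any(mask)) return(empty)
  # 3x3 median filter against single-pixel noise spikes (the boundary
  # band carries heavy mixed-phase noise); extrema searches additionally
  # stay off the band itself
  elev <- sf$elevation
  elev[!mask] <- 0
  elev <- median9(elev)
  elev[!mask] <- NA
  core <- mask & erode_shift(mask, 2L)
  rng <- range(elev, na.rm = TRUE)
  if (diff(rng) < flat_tol) return(empty)

  cols <- range(which(colSums(mask) > 0))
  rows <- range(which(rowSums(mask) > 0))
  span <- cols[2] - cols[1] + 1
  c_lo <- cols[1] + floor(span / 3)
  c_hi <- cols[2] - floor(span / 3)

  # backbone trace: per-row argmax in the central third, median-smoothed
  central <- elev[, c_lo:c_hi, drop = FALSE]
  has_px <- rowSums(!is.na(central)) > 0
  trace_rows <- which(has_px)
  if (length(trace_rows) == 0) return(empty)
  raw_col <- max.col(replace(central[trace_rows, , drop = FALSE],
                             is.na(central[trace_rows, , drop = FALSE]),
                             -Inf), ties.method = "first") + c_lo - 1
  sm_col <- if (length(raw_col) >= 5) {
    as.numeric(stats::runmed(raw_col, 5, endrule = "median"))
  } else raw_col
  trace <- data.frame(row = trace_rows, col = round(sm_col))

  # tail: posterior end of the trace; its column from the median of the
  # last trace rows, which sits on the noisy posterior rim otherwise
  k_tail <- min(5, nrow(trace))
  tail_pt <- data.frame(
    row = trace$row[nrow(trace)],
    col = round(stats::median(trace$col[seq(nrow(trace) - k_tail + 1,
                                            nrow(trace))])))

  # posterior-lateral quadrants: posterior 40% of rows, left/right of the
  # central third
  r_post <- rows[1] + 0.6 * (rows[2] - rows[1])
  quad_max <- function(side) {
    sel_cols <- if (side == "l") seq(cols[1], c_lo - 1)
                else seq(c_hi + 1, cols[2])
    if (length(sel_cols) == 0) return(NULL)
    sub <- elev[, sel_cols, drop = FALSE]
    sub[!core[, sel_cols, drop = FALSE]] <- NA
    sub[seq_len(nrow(sub)) < r_post, ] <- NA
    if (all(is.na(sub))) return(NULL)
    med <- stats::median(sub, na.rm = TRUE)
    top <- max(sub, na.rm = TRUE)
    if (top - med < prominence_tub) return(NULL)
    # centroid of the 2 mm summit plateau: stabler than the raw argmax
    idx <- which(sub >= top - 0.002, arr.ind = TRUE)
    c(row = round(mean(idx[, 1])),
      col = round(mean(sel_cols[idx[, 2]])))
  }
  dish_min <- function(tub, side) {
    if (is.null(tub)) return(NULL)
    tr_col <- trace$col[which.min(abs(trace$row - tub["row"]))]
    lo <- if (side == "l") unname(tub["col"]) + 1 else tr_col + 1
    hi <- if (side == "l") tr_col - 1 else unname(tub["col"]) - 1
    if (hi - lo < 1) return(NULL)
    sel_cols <- lo:hi
    rsel <- max(rows[1], unname(tub["row"]) - 8):
      min(rows[2], unname(tub["row"]) + 8)
    sub <- elev[rsel, sel_cols, drop = FALSE]
    sub[!core[rsel, sel_cols, drop = FALSE]] <- NA
    if (all(is.na(sub))) return(NULL)
    med <- stats::median(sub, na.rm = TRUE)
    bottom <- min(sub, na.rm = TRUE)
    if (med - bottom < prominence_dish) return(NULL)
    idx <- which(sub <= bottom + 0.002, arr.ind = TRUE)
    c(row = round(mean(rsel[idx[, 1]])),
      col = round(mean(sel_cols[idx[, 2]])))
  }
  tub_l <- quad_max("l"); tub_r <- quad_max("r")
  dish_l <- dish_min(tub_l, "l"); dish_r <- dish_min(tub_r, "r")
  bb30 <- locate_bb30(trace, c(row = tail_pt$row, col = tail_pt$col))

  as_row <- function(name, pt) {
    if (is.null(pt)) {
      data.frame(name = name, row = NA_real_, col = NA_real_, defined = FALSE)
    } else {
      data.frame(name = name, row = as.numeric(pt["row"]),
                 col = as.numeric(pt["col"]), defined = TRUE)
    }
  }
  out <- rbind(
    as_row("tail", c(row = tail_pt$row, col = tail_pt$col)),
    as_row("isc_tub_l", tub_l), as_row("isc_tub_r", tub_r),
    as_row("dish_l", dish_l), as_row("dish_r", dish_r),
    as_row("bb30", bb30)
  )
  attr(out, "trace") <- trace
  class(out) <- c("landmark_set", "data.frame")
  out
}

# 3x3 median filter via a compare-exchange network (vectorised over the
# whole image; border windows use replicate padding)
median9 <- function(m) {
  p <- vector("list", 9)
  k <- 0
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1
    s <- shift_mat_num(m, dr, dc, fill = 0)
    # replicate padding: out-of-border neighbours take the centre value
    if (dr != 0) {
      rows <- if (dr == 1) 1 else nrow(m)
      s[rows, ] <- m[rows, ]
    }
    if (dc != 0) {
      cols <- if (dc == 1) 1 else ncol(m)
      s[, cols] <- m[, cols]
    }
    p[[k]] <- s
  }
  ex <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network (1-indexed)
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9); ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6); ex(5, 8); ex(5, 3); ex(7, 5); ex(5, 3)
  p[[5]]
}

landmark_frame <- function() {
  out <- data.frame(
    name = c("tail", "isc_tub_l", "isc_tub_r", "dish_l", "dish_r", "bb30"),
    row = NA_real_, col = NA_real_, defined = FALSE
  )
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' Locate BB30: the backbone point at 30 px radius from the tail
#'
#' Among the trace points anterior of the tail, picks the one whose
#' Euclidean distance to the tail is closest to 30 px; ties break toward
#' the anterior (smaller row). A trace of 30 rows or fewer yields
#' "undefined" (`NULL`).
#'
#' @param trace Data frame `row`, `col` (the backbone trace).
#' @param tail Named vector `c(row =, col =)` of the tail point.
#' @param radius Target radius in pixels.
#' @return `c(row =, col =)` or `NULL` when undefined.
#' @export
locate_bb30 <- function(trace, tail, radius = 30) {
  if (nrow(trace) <= radius) return(NULL)
  anterior <- trace[trace$row < tail["row"], , drop = FALSE]
  if (nrow(anterior) == 0) return(NULL)
  d <- sqrt((anterior$row - tail["row"])^2 + (anterior$col - tail["col"])^2)
  err <- abs(d - radius)
  best <- which(err == min(err))
  pick <- best[which.min(anterior$row[best])]   # ties toward the anterior
  c(row = anterior$row[pick], col = anterior$col[pick])
}
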