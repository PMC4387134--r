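# Stream container: a directory holding header.json, depth.bin (float32,
# row-major within each frame, frames concatenated), amplitude.bin (uint8),
# and optional validity.bin (uint8). Depth is stored in meters.

#' Write a TOF stream to a container directory
#'
#' @param stream A `tof_stream`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- stream$meta
  header <- list(width = m$camera$width, height = m$camera$height,
                 frame_count = m$n, frame_rate = m$frame_rate,
                 velocity = m$velocity, model_kind = m$model_kind,
                 seed = m$seed, mount_distance = m$camera$mount_distance)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "depth.bin"), "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(m$n)) {
    # row-major: write the transposed frame column-by-column
    writeBin(as.numeric(t(stream$depth[, , i])), con, size = 4,
             endian = "little")
  }
  cona <- file(file.path(path, "amplitude.bin"), "wb")
  on.exit(close(cona), add = TRUE)
  for (i in seq_len(m$n)) {
    writeBin(as.raw(t(stream_amplitude(stream, i))), cona)
  }
  invisible(path)
}

#' Read a TOF stream from a container directory
#'
#' @param path Container directory written by [write_stream()].
#' @return A `tof_stream`. Depth carries float32 precision.
#' @export
read_stream <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a stream container (missing header.json): ",
                             path)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  required <- c("width", "height", "frame_count", "frame_rate", "velocity",
                "model_kind", "seed")
  missing <- setdiff(required, names(header))
  if (length(missing) > 0) {
    stop("stream header schema violation; missing fields: ",
         paste(missing, collapse = ", "))
  }
  H <- header$height; W <- header$width; n <- header$frame_count
  cam <- camera_spec(width = W, height = H, frame_rate = header$frame_rate,
                     mount_distance = header$mount_distance %||% 1.28)
  npx <- H * W
  con <- file(file.path(path, "depth.bin"), "rb")
  on.exit(close(con), add = TRUE)
  depth <- array(NA_real_, c(H, W, n))
  for (i in seq_len(n)) {
    v <- readBin(con, numeric(), n = npx, size = 4, endian = "little")
    if (length(v) != npx) stop("depth.bin truncated at frame ", i)
    depth[, , i] <- t(matrix(v, W, H))
  }
  cona <- file(file.path(path, "amplitude.bin"), "rb")
  on.exit(close(cona), add = TRUE)
  amaps <- vector("list", n)
  for (i in seq_len(n)) {
    v <- as.integer(readBin(cona, raw(), n = npx))
    if (length(v) != npx) stop("amplitude.bin truncated at frame ", i)
    amaps[[i]] <- t(matrix(v, W, H))
  }
  structure(list(
    depth = depth,
    amplitude = list(maps = amaps, index = seq_len(n)),
    meta = list(camera = cam, velocity = header$velocity,
                frame_rate = header$frame_rate,
                model_kind = header$model_kind, seed = header$seed, n = n)
  ), class = "tof_stream")
}

#' Export one frame as an ASCII PGM image for visual inspection
#'
#' Depth is linearly rescaled to 0-255 over the camera's calibrated range;
#' amplitude frames are written as-is.
#'
#' @param frame Numeric matrix (depth, meters) or integer matrix (0-255).
#' @param path Output file (`.pgm`).
#' @param range Depth range mapped to 0..255 (ignored for 0-255 input).
#' @export
write_pgm <- function(frame, path, range = c(0.8, 5)) {
  if (max(frame, na.rm = TRUE) > 255 || is.double(frame)) {
    g <- round(255 * (pmin(pmax(frame, range[1]), range[2]) - range[1]) /
                 (range[2] - range[1]))
  } else {
    g <- frame
  }
  g[is.na(g)] <- 0
  lines <- c("P2", paste(ncol(g), nrow(g)), "255",
             apply(g, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

# snap doubles to float32 precision (the container's depth storage format)
snap_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), numeric(),
          n = length(x), size = 4)
}
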