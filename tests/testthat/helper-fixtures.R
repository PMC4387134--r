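# shared fixtures, built once per test run and memoised

.fx <- new.env(parent = emptyenv())

fx_camera <- function() camera_spec()

# flat background model at the mount distance
fx_background <- function() {
  if (is.null(.fx$bg)) {
    cam <- fx_camera()
    .fx$bg <- matrix(cam$mount_distance, cam$height, cam$width)
  }
  .fx$bg
}

fx_field <- function(kind = "fur") {
  key <- paste0("field_", kind)
  if (is.null(.fx[[key]])) .fx[[key]] <- build_cow_surface(surface_spec(kind))
  .fx[[key]]
}

# noiseless noise spec (keeps the default artifact table of the arm)
fx_zero_noise <- function(kind = "fur") {
  noise_spec(kind, sigma_plaster = 0, sigma_white = 0, sigma_black = 0,
             boundary_band_sigma = 0)
}

# noiseless centred rendering of a model
fx_frame <- function(kind = "fur") {
  key <- paste0("frame_", kind)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- render_frame(fx_field(kind), fx_camera(),
                               noise = fx_zero_noise(kind))
  }
  .fx[[key]]
}

fx_segmented <- function(kind = "fur") {
  key <- paste0("seg_", kind)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- segment_frame(fx_frame(kind)$depth, fx_background(),
                                seg_config())
  }
  .fx[[key]]
}

# random blob masks for partition property tests
random_blob_mask <- function(h = 28, w = 24) {
  m <- matrix(stats::runif(h * w) < 0.45, h, w)
  # one smoothing vote makes connected blobs out of salt noise
  votes <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    sh <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    votes <- votes + sh
  }
  votes >= 5
}

# brute-force boundary/interior labelling by scanning each pixel's
# radius-1 neighbourhood (image border counts as background)
brute_force_partition <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  boundary <- matrix(FALSE, h, w); interior <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc]) next
    touches_bg <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1 || rr > h || ccc < 1 || ccc > w || !mask[rr, ccc]) {
        touches_bg <- TRUE
      }
    }
    if (touches_bg) boundary[r, cc] <- TRUE else interior[r, cc] <- TRUE
  }
  list(boundary = boundary, interior = interior)
}
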