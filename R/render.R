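# ---- scene sampling -------------------------------------------------------

# Evaluate the scene (plate + model at a given travel offset) at every pixel
# centre under an orthographic top view. Returns noiseless depth, amplitude,
# per-pixel surface class, the ground-truth masks and landmark pixel
# coordinates. Classes: 0 plate, 1 plaster, 2 white fur, 3 black fur, 4 beam.
scene_sample <- function(field, camera, offset) {
  H <- camera$height; W <- camera$width
  spec <- field$spec
  x <- (seq_len(W) - 0.5) * camera$dx
  y <- (seq_len(H) - 0.5) * camera$dy
  x0 <- (W * camera$dx - spec$width) / 2          # centre the model in columns
  u <- matrix(rep(x - x0, each = H), H, W)
  v <- matrix(rep(y - offset, times = W), H, W)

  elev <- field$elev(u, v)
  mask <- !is.na(elev)
  elev[!mask] <- 0

  cls <- matrix(0L, H, W)
  if (spec$model_kind == "plaster") {
    cls[mask] <- 1L
  } else {
    white <- mask & !is.na(spec$fur_pattern(u, v)) & spec$fur_pattern(u, v)
    cls[mask] <- ifelse(white[mask], 2L, 3L)
  }

  beam_mask <- matrix(FALSE, H, W)
  if (isTRUE(spec$beams)) {
    hb <- spec$board_side / 2; hs <- spec$beam_side / 2
    cx <- spec$width / 2; cy <- spec$length / 2
    for (su in c(-1, 1)) for (sv in c(-1, 1)) {
      bm <- abs(u - (cx + su * hb)) <= hs & abs(v - (cy + sv * hb)) <= hs
      beam_mask <- beam_mask | bm
    }
    beam_mask <- beam_mask & !mask
    elev[beam_mask] <- spec$beam_height
    cls[beam_mask] <- 4L
  }

  depth <- camera$mount_distance - elev
  amp <- matrix(120L, H, W)                        # wooden plate
  amp[cls == 1L | cls == 2L | cls == 4L] <- 200L   # plaster, white fur, beams
  amp[cls == 3L] <- 10L                            # black fur

  lm <- field$landmarks[field$landmarks$name != "backbone", ]
  landmarks <- data.frame(
    name = lm$name,
    row = (offset + lm$v) / camera$dy + 0.5,
    col = (x0 + lm$u) / camera$dx + 0.5,
    defined = lm$defined
  )
  # the backbone runs straight along the rows, so BB30 ground truth sits
  # 30 px anterior of the tail at the tail's column
  tail_i <- landmarks$name == "tail"
  landmarks <- rbind(landmarks, data.frame(
    name = "bb30", row = landmarks$row[tail_i] - 30,
    col = landmarks$col[tail_i], defined = landmarks$defined[tail_i]
  ))
  in_view <- landmarks$row >= 0.5 & landmarks$row <= H + 0.5
  landmarks$defined <- landmarks$defined & in_view

  list(depth = depth, amplitude = amp, class = cls, mask = mask,
       beam_mask = beam_mask, white_mask = cls == 2L,
       landmarks = landmarks, offset = offset)
}

# per-pixel noise sd map: surface-class sigma, boundary-band sigma in the
# 1-2 px band along steep edges (cow outline and beam outline)
noise_sigma_map <- function(scene, noise) {
  cls <- scene$class
  sig <- matrix(noise$sigma_plaster, nrow(cls), ncol(cls))
  sig[cls == 2L] <- noise$sigma_white
  sig[cls == 3L] <- noise$sigma_black
  fg <- scene$mask | scene$beam_mask
  band <- fg & !erode_shift(fg, noise$boundary_band_width)
  sig[band] <- noise$boundary_band_sigma
  sig
}

# erosion by k steps of the 8-neighbourhood, image border treated as background
erode_shift <- function(m, k = 1L) {
  for (i in seq_len(k)) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out & shift_mat(m, dr, dc, fill = FALSE)
    }
    m <- out
  }
  m
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# ---- frame rendering ------------------------------------------------------

#' Render one synthetic TOF frame
#'
#' Places the model at a travel offset and renders depth and amplitude
#' under an orthographic top view: plate pixels measure the mount
#' distance, model pixels `mount_distance - elevation`. Additive Gaussian
#' depth noise uses the per-surface-class sigmas of the [noise_spec()];
#' pixels in the 1-2 px boundary band along steep edges receive the
#' elevated band sigma (a proxy for mixed-phase errors). Amplitude is high
#' on plaster/white fur and low on black fur, so a gray threshold of 25
#' separates the fur colours.
#'
#' @param field A [build_cow_surface()] height field.
#' @param camera A [camera_spec()].
#' @param offset Travel offset of the model's anterior edge (meters along
#'   the row axis); may place the model partly or fully out of view.
#' @param noise A [noise_spec()]; set all sigmas to zero for a noiseless
#'   frame.
#' @param seed Optional integer seed for the noise draw.
#' @return List with `depth` (meters), `amplitude` (0-255 integer),
#'   `scene` (ground truth: masks, classes, landmark pixel coordinates).
#' @export
render_frame <- function(field, camera = camera_spec(), offset = NULL,
                         noise = noise_spec(field$spec$model_kind),
                         seed = NULL) {
  if (is.null(offset)) {
    offset <- (camera$height * camera$dy - field$spec$length) / 2
  }
  scene <- scene_sample(field, camera, offset)
  if (!is.null(seed)) set.seed(seed)
  sig <- noise_sigma_map(scene, noise)
  depth <- scene$depth
  noisy <- sig > 0
  if (any(noisy)) {
    depth[noisy] <- depth[noisy] + stats::rnorm(sum(noisy), 0, sig[noisy])
  }
  list(depth = depth, amplitude = scene$amplitude, scene = scene)
}

# ---- motion artifacts -----------------------------------------------------

# scramble the phase of selected pixels: wrap-around demodulation noise
phase_scramble <- function(depth, idx, jitter, range) {
  phi <- 2 * pi * depth[idx] / range + stats::rnorm(length(idx), 0, jitter)
  depth[idx] <- range * (phi %% (2 * pi)) / (2 * pi)
  depth
}

#' Corrupt a frame with motion artifacts
#'
#' With probability `artifact_rate(velocity)` the frame is corrupted.
#' For a moving model every pixel is re-demodulated from phase samples
#' taken at four sub-frame object positions (the model advances by
#' `velocity / (4 * frame_rate)` between control signals): pixels whose
#' four sub-positions straddle a depth edge get demodulated depths
#' between the two surfaces, and — because the inconsistent charge
#' samples leave the phase estimate unstable — additional phase jitter
#' that produces erratic, possibly wrapped depth values along motion
#' edges. In standstill a corruption event (non-zero `artifact_rate(0)`
#' models sporadic interference on the real recordings) scrambles the
#' phase in a random patch of the model area instead, since a motionless
#' four-phase resample is a no-op.
#'
#' @param frame Noiseless depth frame (matrix, meters) at `scene$offset`.
#' @param velocity Velocity in cm/s.
#' @param noise A [noise_spec()] (artifact rate, phase jitter).
#' @param scene Scene context: list with the height `field` and `offset`
#'   used to render `frame` (needed to resample the four sub-positions).
#' @param camera A [camera_spec()].
#' @return The (possibly) corrupted depth frame; attribute `"corrupted"`
#'   records whether a corruption event occurred.
#' @export
corrupt_with_motion_artifacts <- function(frame, velocity, noise, scene,
                                          camera = camera_spec(),
                                          cache = NULL) {
  stopifnot(velocity >= 0)
  rate <- noise$artifact_rate(velocity)
  if (stats::runif(1) >= rate) {
    attr(frame, "corrupted") <- FALSE
    return(frame)
  }
  rng <- camera$unambiguous_range
  if (velocity > 0) {
    if (is.null(cache)) {
      cache <- motion_smear_cache(scene$field, camera, scene$offset, velocity)
    }
    out <- cache$demod
    if (noise$phase_jitter > 0 && length(cache$straddle) > 0) {
      out <- phase_scramble(out, cache$straddle, noise$phase_jitter, rng)
    }
  } else {
    out <- frame
    mask <- if (!is.null(cache$mask)) cache$mask
            else scene_sample(scene$field, camera, scene$offset)$mask
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    half <- 12L
    rc <- round(stats::runif(1, rows[1] + half, rows[2] - half))
    cc <- round(stats::runif(1, cols[1] + half, cols[2] - half))
    patch <- matrix(FALSE, nrow(out), ncol(out))
    patch[(rc - half):(rc + half), (cc - half):(cc + half)] <- TRUE
    idx <- which(patch & mask)
    out <- phase_scramble(out, idx, max(noise$phase_jitter, 2.5), rng)
  }
  attr(out, "corrupted") <- TRUE
  out
}

# deterministic part of the motion smear at one offset: the four-phase
# re-demodulation with the object advancing by velocity/(4*frame_rate)
# between control signals, and the pixels whose sub-samples disagree
motion_smear_cache <- function(field, camera, offset, velocity) {
  dt <- 1 / (4 * camera$frame_rate)               # sub-frame interval
  sub <- lapply(0:3, function(k) {
    scene_sample(field, camera, offset + velocity / 100 * k * dt)
  })
  depths <- lapply(sub, `[[`, "depth")
  amps <- lapply(sub, function(s) as.numeric(s$amplitude))
  demod <- demodulate_moving(depths, amps, camera)
  # demodulation destabilises where the four sub-samples disagree by
  # more than the depth noise floor (~1 mm) or saw different albedo
  tol <- 0.001
  straddle <- abs(depths[[2]] - depths[[1]]) > tol |
    abs(depths[[3]] - depths[[1]]) > tol |
    abs(depths[[4]] - depths[[1]]) > tol |
    sub[[2]]$amplitude != sub[[1]]$amplitude |
    sub[[3]]$amplitude != sub[[1]]$amplitude |
    sub[[4]]$amplitude != sub[[1]]$amplitude
  list(demod = demod, straddle = which(straddle))
}

# ---- stream simulation ----------------------------------------------------

frame_seed <- function(root, i) {
  as.integer((as.numeric(root) + i * 48271) %% 2147483647) + 1L
}

#' Simulate a TOF depth/amplitude stream of a moving or standing model
#'
#' Standstill recordings produce `duration * frame_rate` frames at a
#' centred position; moving recordings produce, per pass, one frame at
#' each travel offset for which the model is fully in view (the offset
#' advances by `velocity / frame_rate` between frames). Each frame is
#' rendered, possibly corrupted by motion artifacts, and overlaid with
#' the class-dependent Gaussian depth noise. Per-frame random streams are
#' derived deterministically from `(noise$seed, frame index)`, so a fixed
#' configuration is bit-reproducible.
#'
#' @param surface A [surface_spec()] or a prebuilt [build_cow_surface()].
#' @param camera A [camera_spec()].
#' @param motion A [motion_spec()].
#' @param noise A [noise_spec()].
#' @return List with `stream` (class `tof_stream`: depth array
#'   `height x width x n`, per-offset amplitude maps, metadata) and
#'   `truth` (class `scene_truth`: per-frame masks, fur masks, beam
#'   masks, landmark pixel coordinates, corruption flags).
#' @export
simulate_stream <- function(surface = surface_spec(),
                            camera = camera_spec(),
                            motion = motion_spec(),
                            noise = noise_spec(surface$model_kind %||%
                                                 surface$spec$model_kind)) {
  field <- if (inherits(surface, "height_field")) surface
           else build_cow_surface(surface, grid_step = camera$dy)
  spec <- field$spec
  H <- camera$height
  span <- H * camera$dy - spec$length  # offsets with the model fully in view
  if (span <= 2 * camera$dy) stop("model does not fit the field of view")

  if (motion$velocity == 0) {
    n <- round(motion$duration * camera$frame_rate)
    offsets <- rep(span / 2, n)
  } else {
    if (motion$passes < 1) stop("moving recordings need passes >= 1")
    step <- motion$velocity / 100 / camera$frame_rate
    pass_offsets <- seq(camera$dy, span - camera$dy, by = step)
    offsets <- unlist(lapply(seq_len(motion$passes), function(p) {
      if (p %% 2 == 1) pass_offsets else rev(pass_offsets)
    }))
    n <- length(offsets)
  }

  uo <- unique(offsets)
  scene_cache <- lapply(uo, function(o) scene_sample(field, camera, o))
  sigma_cache <- lapply(scene_cache, function(s) noise_sigma_map(s, noise))
  o_index <- match(offsets, uo)
  smear_cache <- vector("list", length(uo))  # filled lazily per offset

  depth <- array(NA_real_, c(H, camera$width, n))
  corrupted <- logical(n)
  lm_list <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- scene_cache[[o_index[i]]]
    set.seed(frame_seed(noise$seed, i))
    # every moving frame carries the deterministic four-phase smear (the
    # object advances between control signals in every acquisition); a
    # corruption event additionally scrambles the inconsistent pixels
    if (motion$velocity > 0 && is.null(smear_cache[[o_index[i]]])) {
      smear_cache[[o_index[i]]] <- motion_smear_cache(field, camera,
                                                      sc$offset,
                                                      motion$velocity)
    }
    base <- if (motion$velocity > 0) smear_cache[[o_index[i]]]$demod
            else sc$depth
    fr <- corrupt_with_motion_artifacts(
      base, motion$velocity, noise,
      scene = list(field = field, offset = sc$offset), camera = camera,
      cache = if (motion$velocity > 0) smear_cache[[o_index[i]]]
              else list(mask = sc$mask))
    corrupted[i] <- isTRUE(attr(fr, "corrupted"))
    attr(fr, "corrupted") <- NULL
    sig <- sigma_cache[[o_index[i]]]
    noisy <- sig > 0
    if (any(noisy)) {
      fr[noisy] <- fr[noisy] + stats::rnorm(sum(noisy), 0, sig[noisy])
    }
    depth[, , i] <- fr
    lm <- sc$landmarks
    lm$frame <- i
    lm_list[[i]] <- lm
  }

  stream <- structure(list(
    depth = depth,
    amplitude = list(maps = lapply(scene_cache, `[[`, "amplitude"),
                     index = o_index),
    meta = list(camera = camera, velocity = motion$velocity,
                frame_rate = camera$frame_rate, model_kind = spec$model_kind,
                seed = noise$seed, n = n)
  ), class = "tof_stream")

  truth <- structure(list(
    masks = lapply(scene_cache, `[[`, "mask"),
    white_masks = lapply(scene_cache, `[[`, "white_mask"),
    beam_masks = lapply(scene_cache, `[[`, "beam_mask"),
    mask_index = o_index,
    offsets = offsets,
    landmarks = do.call(rbind, lm_list),
    corrupted = corrupted
  ), class = "scene_truth")

  list(stream = stream, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in a stream
#' @param stream A `tof_stream`.
#' @export
n_frames <- function(stream) stream$meta$n

#' Extract one depth frame / amplitude frame from a stream
#' @param stream A `tof_stream`.
#' @param i Frame index.
#' @export
stream_depth <- function(stream, i) stream$depth[, , i]

#' @rdname stream_depth
#' @export
stream_amplitude <- function(stream, i) {
  stream$amplitude$maps[[stream$amplitude$index[i]]]
}

#' Ground-truth foreground mask of frame i
#' @param truth A `scene_truth`.
#' @param i Frame index.
#' @export
truth_mask <- function(truth, i) truth$masks[[truth$mask_index[i]]]

#' Simulate frames of the empty scenery (plate only)
#'
#' @param camera A [camera_spec()].
#' @param noise A [noise_spec()]; plate pixels use `sigma_plaster`.
#' @param n Number of frames (>= 1).
#' @return A `tof_stream` of plate-only frames at the mount distance.
#' @export
simulate_empty_scenery <- function(camera = camera_spec(),
                                   noise = noise_spec("plaster"), n = 100) {
  stopifnot(n >= 1)
  H <- camera$height; W <- camera$width
  depth <- array(camera$mount_distance, c(H, W, n))
  if (noise$sigma_plaster > 0) {
    for (i in seq_len(n)) {
      set.seed(frame_seed(noise$seed, i))
      depth[, , i] <- depth[, , i] + stats::rnorm(H * W, 0, noise$sigma_plaster)
    }
  }
  structure(list(
    depth = depth,
    amplitude = list(maps = list(matrix(120L, H, W)), index = rep(1L, n)),
    meta = list(camera = camera, velocity = 0, frame_rate = camera$frame_rate,
                model_kind = "empty", seed = noise$seed, n = n)
  ), class = "tof_stream")
}
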