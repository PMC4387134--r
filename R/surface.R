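#' Surface specification of a cow-back model
#'
#' Parametric lower-back geometry shared by both models: a smooth slab
#' (superellipse footprint) carrying a backbone ridge along the direction
#' of travel, a tail bump at the posterior end, two ischeal-tuberosity
#' bumps in the posterior-lateral quadrants and two rump-dish depressions
#' between backbone and tuberosities. Elevations stay within the models'
#' measured 0.15-0.22 m (plaster: 0.16-0.22 m) above the plate.
#'
#' Model-local coordinates: `u` runs along image columns, `v` along image
#' rows (direction of travel); the posterior end (tail) is at large `v`.
#' All positions and lengths are meters.
#'
#' @param model_kind `"plaster"` or `"fur"`. The fur model carries a
#'   black/white fur pattern and four corner beams (0.05 x 0.05 m posts,
#'   0.25 m high) on its mounting board; the plaster cast is homogeneous.
#' @param length,width Footprint extent along `v` (travel) and `u`.
#' @param base_height Slab elevation away from all bumps (meters).
#' @param bumps Data frame with columns `name`, `u`, `v`, `amp`, `sigma`
#'   describing the point landmarks (amp < 0 for depressions).
#' @param ridge List `amp`, `sigma` of the backbone ridge (Gaussian in
#'   `u`, constant along `v`).
#' @param fur_pattern `NULL`, or `function(u, v)` returning `TRUE` for
#'   white fur; defaults for the fur model to two elliptical white spots
#'   covering roughly a fifth of the footprint.
#' @param beams Logical: render corner beams (fur model default `TRUE`).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(model_kind = c("fur", "plaster"),
                         length = NULL, width = NULL,
                         base_height = 0.18,
                         bumps = NULL, ridge = list(amp = 0.03, sigma = 0.015),
                         fur_pattern = NULL, beams = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(length)) length <- if (model_kind == "fur") 0.5 else 0.56
  if (is.null(width))  width  <- if (model_kind == "fur") 0.5 else 0.55
  cx <- width / 2; cy <- length / 2
  if (is.null(bumps)) {
    dish_amp <- if (model_kind == "fur") -0.03 else -0.02
    bumps <- data.frame(
      name  = c("tail", "isc_tub_l", "isc_tub_r", "dish_l", "dish_r"),
      u     = cx + c(0, -0.3, 0.3, -0.15, 0.15) * width,
      v     = cy + c(0.5, 0.3, 0.3, 0.3, 0.3) * length,
      amp   = c(0.01, 0.04, 0.04, dish_amp, dish_amp),
      sigma = c(0.02, 0.015, 0.015, 0.012, 0.012)
    )
  }
  if (is.null(beams)) beams <- model_kind == "fur"
  if (is.null(fur_pattern) && model_kind == "fur") {
    fur_pattern <- default_fur_pattern(width, length)
  }
  spec <- list(model_kind = model_kind, length = length, width = width,
               base_height = base_height, bumps = bumps, ridge = ridge,
               fur_pattern = fur_pattern, beams = beams,
               beam_side = 0.05, beam_height = 0.25,
               board_side = 0.64)
  class(spec) <- "surface_spec"
  .check_bump_overlap(spec)
  spec
}

# two elliptical white spots on black ground, ~20% white interior
default_fur_pattern <- function(width, length) {
  force(width); force(length)
  function(u, v) {
    e1 <- ((u - 0.64 * width) / (0.20 * width))^2 +
          ((v - 0.36 * length) / (0.24 * length))^2 <= 1
    e2 <- ((u - 0.30 * width) / (0.14 * width))^2 +
          ((v - 0.64 * length) / (0.18 * length))^2 <= 1
    e1 | e2
  }
}

# landmark bumps must not interact: pairwise centre distance at least
# 2*(sigma_i + sigma_j); the ridge is a line in u, checked in u only
.check_bump_overlap <- function(spec) {
  b <- spec$bumps
  if (nrow(b) >= 2) {
    for (i in seq_len(nrow(b) - 1)) for (j in seq(i + 1, nrow(b))) {
      d <- sqrt((b$u[i] - b$u[j])^2 + (b$v[i] - b$v[j])^2)
      if (d < 2 * (b$sigma[i] + b$sigma[j]))
        stop("landmark bumps '", b$name[i], "' and '", b$name[j],
             "' overlap beyond tolerance")
    }
  }
  ridge_u <- spec$width / 2
  off_ridge <- b$name != "tail"
  du <- abs(b$u[off_ridge] - ridge_u)
  bad <- du < 2 * (spec$ridge$sigma + b$sigma[off_ridge])
  if (any(bad))
    stop("landmark bump(s) ", paste(b$name[off_ridge][bad], collapse = ", "),
         " overlap the backbone ridge beyond tolerance")
  invisible(spec)
}

#' Build the height field of a cow-back model
#'
#' Evaluates the parametric geometry of a [surface_spec()] into a height
#' field: an analytic elevation evaluator, a sampled elevation map on a
#' metric grid, and the ground-truth landmark coordinates (the analytic
#' extrema of the parametric bumps). With all bump and ridge amplitudes
#' zero the model is a constant-height slab and every landmark is
#' reported "undefined".
#'
#' @param spec A [surface_spec()].
#' @param grid_step Grid spacing of the sampled map (meters); defaults to
#'   the camera pixel pitch along rows at the default mount distance.
#' @return An object of class `height_field` with fields `elev(u, v)`
#'   (vectorised evaluator, `NA` outside the footprint), `inside(u, v)`,
#'   `grid` (sampled matrix), `landmarks` (data frame `name`, `u`, `v`,
#'   `defined`) and the spec.
#' @export
build_cow_surface <- function(spec = surface_spec(),
                              grid_step = camera_spec()$dy) {
  b <- spec$bumps; ridge <- spec$ridge
  cx <- spec$width / 2
  inside <- function(u, v) {
    (2 * (u - spec$width / 2) / spec$width)^4 +
      (2 * (v - spec$length / 2) / spec$length)^4 <= 1
  }
  elev_raw <- function(u, v) {
    z <- spec$base_height +
      ridge$amp * exp(-(u - cx)^2 / (2 * ridge$sigma^2))
    for (k in seq_len(nrow(b))) {
      z <- z + b$amp[k] *
        exp(-((u - b$u[k])^2 + (v - b$v[k])^2) / (2 * b$sigma[k]^2))
    }
    z
  }
  elev <- function(u, v) {
    z <- elev_raw(u, v)
    z[!inside(u, v)] <- NA_real_
    z
  }
  us <- seq(grid_step / 2, spec$width, by = grid_step)
  vs <- seq(grid_step / 2, spec$length, by = grid_step)
  grid <- outer(vs, us, function(v, u) elev(u, v))  # rows follow v
  flat <- abs(ridge$amp) < 1e-9 && all(abs(b$amp) < 1e-9)
  landmarks <- data.frame(
    name = c(b$name, "backbone"),
    u = c(b$u, cx),
    v = c(b$v, NA_real_),
    defined = !flat
  )
  hf <- list(elev = elev, inside = inside, grid = grid,
             grid_step = grid_step, landmarks = landmarks, spec = spec)
  class(hf) <- "height_field"
  hf
}
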