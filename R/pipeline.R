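# ---- fixtures mode --------------------------------------------------------

#' Recompute the experiment's headline numbers from the embedded tables
#'
#' Fixtures mode of the pipeline: runs entirely on the embedded frame
#' counts ([hqi_counts()]) and landmark imprecision values
#' ([rpv_table()]) — no simulation, no random state. Computes the
#' high-quality-image ratios, the quadratic and Gaussian-exponential
#' fits of the ratio-versus-velocity vectors (on ordinal abscissae
#' x = 1..4), the quotient of the quadratic coefficients quantifying how
#' much faster quality decays with fur, the per-body-part quadratic fits
#' of the RpV vectors, the model-wise medians of their quadratic
#' coefficients (medians taken over coefficients rounded to the
#' two-decimal tabulation precision), and the rank-sum test of the
#' coefficients between models with rank-based eta-squared.
#'
#' @param alpha_coeff Significance level for the coefficient comparison.
#' @return A list of class `fixture_report`; see the README for a worked
#'   example of its fields.
#' @export
fixture_report <- function(alpha_coeff = 0.05) {
  counts <- hqi_counts()
  counts$hqi <- hqi_ratio(counts$N, counts$C)
  x <- 1:4
  fits <- list()
  for (m in c("plaster", "fur")) {
    y <- counts$hqi[counts$model == m]
    fits[[m]] <- list(quadratic = fit_quadratic(y, x),
                      gaussian = fit_gaussian_exp(y, x))
  }
  alpha_ratio <- fits$fur$quadratic$coefficients["alpha"] /
    fits$plaster$quadratic$coefficients["alpha"]

  rt <- rpv_table()
  rpv_fits <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    yv <- as.numeric(rt[i, c("rpv_0", "rpv_10", "rpv_20", "rpv_30")])
    rpv_fits[[i]] <- fit_quadratic(yv, x)
  }
  rt$coeff <- vapply(rpv_fits, function(f) unname(f$coefficients["alpha"]),
                     numeric(1))
  rt$rmsd <- vapply(rpv_fits, function(f) f$rmsd, numeric(1))
  rt$r_squared <- vapply(rpv_fits, function(f) f$r_squared, numeric(1))
  coeff_rounded <- round_half_away(rt$coeff, 2)
  medians <- tapply(coeff_rounded, rt$model, stats::median)
  coeff_test <- rank_sum_test(rt$coeff[rt$model == "plaster"],
                              rt$coeff[rt$model == "fur"],
                              alpha = alpha_coeff)

  out <- list(table1 = counts, hqi_fits = fits,
              alpha_ratio = unname(alpha_ratio),
              table4 = rt, coeff_medians = medians,
              coeff_test = coeff_test)
  class(out) <- "fixture_report"
  out
}

# ---- simulate / analyze mode ----------------------------------------------

#' Experiment configuration
#'
#' Bundles the per-arm specifications and analysis settings of the
#' end-to-end experiment. The defaults are the study conditions (both
#' models, velocities 0/10/20/30 cm/s, 240 s standstill, five passes);
#' `standstill_duration` may be lowered to scale the simulation.
#'
#' @param models Model arms to simulate.
#' @param velocities Velocity grid (cm/s).
#' @param camera A [camera_spec()].
#' @param seed Root seed.
#' @param standstill_duration Standstill recording length (seconds).
#' @param passes Passes per moving recording.
#' @param alpha_regions,alpha_fur,alpha_coeff Significance levels for the
#'   region, fur-colour and coefficient comparisons.
#' @param mask_mode `"intersection"` (criteria on pixels foreground in
#'   every standstill frame) or `"per_frame"`.
#' @param mirror Re-run the analysis on mirrored frames and attach the
#'   mirrored report (robustness control).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(models = c("plaster", "fur"),
                              velocities = default_velocities(),
                              camera = camera_spec(), seed = 1L,
                              standstill_duration = 240, passes = 5L,
                              alpha_regions = 0.02, alpha_fur = 0.001,
                              alpha_coeff = 0.05,
                              mask_mode = c("intersection", "per_frame"),
                              mirror = FALSE) {
  cfg <- list(models = models, velocities = velocities, camera = camera,
              seed = as.integer(seed),
              standstill_duration = standstill_duration,
              passes = as.integer(passes),
              alpha_regions = alpha_regions, alpha_fur = alpha_fur,
              alpha_coeff = alpha_coeff, mask_mode = match.arg(mask_mode),
              mirror = mirror)
  class(cfg) <- "experiment_config"
  cfg
}

#' Segment a stream and run the quality tests on every frame
#'
#' @param stream A `tof_stream`.
#' @param background A [average_empty_scenery()] background model.
#' @param cfg A [seg_config()].
#' @param mirror Mirror every frame before analysis (control transform).
#' @return List: `verdicts` (data frame `frame`, `pass`, `reasons`),
#'   `landmarks` (per-frame landmark table of passing frames), `frames`
#'   (segmented depth array of passing frames), `masks` (their masks).
#' @export
analyze_stream <- function(stream, background, cfg = seg_config(),
                           mirror = FALSE) {
  n <- n_frames(stream)
  camera <- stream$meta$camera
  verdicts <- data.frame(frame = seq_len(n), pass = FALSE,
                         reasons = character(n))
  lm_list <- list()
  seg_frames <- list()
  seg_masks <- list()
  bg <- if (mirror) mirror_frame(unclass(background)) else unclass(background)
  for (i in seq_len(n)) {
    fr <- stream_depth(stream, i)
    if (mirror) fr <- mirror_frame(fr)
    sf <- segment_frame(fr, bg, cfg)
    qt <- quality_tests(sf, cfg, camera)
    verdicts$pass[i] <- qt$pass
    verdicts$reasons[i] <- paste(qt$reasons, collapse = "; ")
    if (qt$pass) {
      lms <- qt$landmarks
      lms$frame <- i
      lm_list[[length(lm_list) + 1]] <- lms
      seg_frames[[length(seg_frames) + 1]] <- sf$depth
      seg_masks[[length(seg_masks) + 1]] <- sf$mask
    }
  }
  list(verdicts = verdicts,
       landmarks = if (length(lm_list)) do.call(rbind, lm_list) else NULL,
       frames = seg_frames, masks = seg_masks)
}

#' Run the end-to-end simulated experiment
#'
#' Simulates both model arms over the velocity grid, segments every
#' frame, applies the quality tests, and computes the four criteria:
#' the high-quality-image ratio per arm and velocity (with quadratic and
#' Gaussian-exponential fits over ordinal velocity indices), SumDiff and
#' pwStd on the passing standstill frames with region medians and
#' rank-sum tests (regions; fur colours on the fur arm), and RpV of the
#' landmark X-coordinates per velocity with quadratic fits and the
#' between-model coefficient test. Deterministic given the seed; arms
#' with zero passing frames are recorded, not fatal.
#'
#' @param cfg An [experiment_config()].
#' @return List of class `report_bundle` with elements `table1`,
#'   `hqi_fits`, `alpha_ratio`, `pixelwise`, `region_tests`, `rpv`,
#'   `coeff_test`, `config`, and optionally `mirrored`.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  camera <- cfg$camera
  empty <- simulate_empty_scenery(camera,
                                  noise_spec("plaster", seed = cfg$seed),
                                  n = 200)
  background <- average_empty_scenery(empty)
  bundle <- run_experiment_arms(cfg, background, mirror = FALSE)
  if (isTRUE(cfg$mirror)) {
    bundle$mirrored <- run_experiment_arms(cfg, background, mirror = TRUE)
  }
  bundle$config <- cfg
  class(bundle) <- "report_bundle"
  bundle
}

run_experiment_arms <- function(cfg, background, mirror = FALSE) {
  camera <- cfg$camera
  x <- seq_along(cfg$velocities)
  table1 <- NULL
  pixelwise <- list(); region_tests <- list()
  rpv_rows <- list(); hqi_fits <- list()
  lm_names <- c("isc_tub_l", "dish_l", "tail", "dish_r", "isc_tub_r", "bb30")

  for (m in cfg$models) {
    surface <- surface_spec(m)
    field <- build_cow_surface(surface, grid_step = camera$dy)
    noise <- noise_spec(m, seed = cfg$seed)
    arm_rpv <- matrix(NA_real_, length(lm_names), length(cfg$velocities),
                      dimnames = list(lm_names, cfg$velocities))
    for (vi in seq_along(cfg$velocities)) {
      v <- cfg$velocities[vi]
      motion <- if (v == 0) {
        motion_spec(0, duration = cfg$standstill_duration)
      } else {
        motion_spec(v, passes = cfg$passes)
      }
      sim <- simulate_stream(field, camera, motion, noise)
      res <- analyze_stream(sim$stream, background, seg_config(),
                            mirror = mirror)
      C <- n_frames(sim$stream)
      N <- sum(res$verdicts$pass)
      table1 <- rbind(table1, data.frame(model = m, velocity = v,
                                         C = C, N = N,
                                         hqi = hqi_ratio(N, C)))
      if (!is.null(res$landmarks)) {
        for (nm in lm_names) {
          xs <- res$landmarks$col[res$landmarks$name == nm &
                                    res$landmarks$defined]
          arm_rpv[nm, vi] <- rpv(xs)   # N = frames with determined X
        }
      }
      if (v == 0 && N >= 2) {
        frames <- array(unlist(res$frames),
                        c(camera$height, camera$width, N))
        cmask <- if (cfg$mask_mode == "intersection") {
          common_foreground(res$masks)
        } else res$masks[[1]]
        sd_mat <- sum_diff(frames, cmask)
        std_mat <- pw_std(frames, cmask)
        part <- partition_regions(cmask)
        if (m == "fur") {
          amp <- stream_amplitude(sim$stream, 1)
          if (mirror) amp <- mirror_frame(amp)
          part <- fur_color_mask(amp, part)
        }
        pixelwise[[m]] <- list(
          sum_diff = medians_by_region(sd_mat, part),
          pw_std = medians_by_region(std_mat, part),
          n_frames = N, partition_counts = part$counts)
        region_tests[[m]] <- list(
          sum_diff = rank_sum_test(sd_mat[part$interior],
                                   sd_mat[part$boundary],
                                   alpha = cfg$alpha_regions),
          pw_std = rank_sum_test(std_mat[part$interior],
                                 std_mat[part$boundary],
                                 alpha = cfg$alpha_regions))
        if (m == "fur") {
          region_tests$fur_color <- list(
            sum_diff = rank_sum_test(sd_mat[part$interior_white],
                                     sd_mat[part$interior_black],
                                     alpha = cfg$alpha_fur),
            pw_std = rank_sum_test(std_mat[part$interior_white],
                                   std_mat[part$interior_black],
                                   alpha = cfg$alpha_fur))
        }
      }
    }
    y <- table1$hqi[table1$model == m]
    hqi_fits[[m]] <- if (length(y) >= 4) {
      list(quadratic = fit_quadratic(y, x), gaussian = fit_gaussian_exp(y, x))
    } else NULL
    for (nm in lm_names) {
      yv <- arm_rpv[nm, ]
      fit <- if (length(yv) >= 4 && all(is.finite(yv))) {
        fit_quadratic(yv, x)
      } else NULL
      rpv_rows[[paste(m, nm)]] <- data.frame(
        model = m, body_part = nm,
        t(stats::setNames(yv, paste0("rpv_", cfg$velocities))),
        coeff = if (is.null(fit)) NA_real_ else
          unname(fit$coefficients["alpha"]),
        rmsd = if (is.null(fit)) NA_real_ else fit$rmsd,
        r_squared = if (is.null(fit)) NA_real_ else fit$r_squared)
    }
  }

  rpv_df <- do.call(rbind, rpv_rows)
  rownames(rpv_df) <- NULL
  coeff_test <- NULL
  cp <- rpv_df$coeff[rpv_df$model == "plaster"]
  cf <- rpv_df$coeff[rpv_df$model == "fur"]
  if (sum(is.finite(cp)) >= 2 && sum(is.finite(cf)) >= 2) {
    coeff_test <- rank_sum_test(cp[is.finite(cp)], cf[is.finite(cf)],
                                alpha = cfg$alpha_coeff)
  }
  alpha_ratio <- if (all(c("plaster", "fur") %in% names(hqi_fits))) {
    unname(hqi_fits$fur$quadratic$coefficients["alpha"] /
             hqi_fits$plaster$quadratic$coefficients["alpha"])
  } else NA_real_

  list(table1 = table1, hqi_fits = hqi_fits, alpha_ratio = alpha_ratio,
       pixelwise = pixelwise, region_tests = region_tests,
       rpv = rpv_df, coeff_test = coeff_test)
}

# ---- report output --------------------------------------------------------

#' Write a report bundle to CSV/JSON files
#'
#' @param bundle A `report_bundle` or `fixture_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$table1)) {
    utils::write.csv(bundle$table1, file.path(dir, "table1_hqi.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$table4 %||% bundle$rpv)) {
    utils::write.csv(bundle$table4 %||% bundle$rpv,
                     file.path(dir, "table4_rpv.csv"), row.names = FALSE)
  }
  fits <- bundle$hqi_fits
  fit_json <- lapply(fits, function(f) {
    lapply(f, function(g) list(kind = g$kind,
                               coefficients = as.list(g$coefficients),
                               sse = g$sse, rmsd = g$rmsd,
                               r_squared = g$r_squared, dof = g$dof))
  })
  summary <- list(
    hqi_fits = fit_json,
    alpha_ratio = bundle$alpha_ratio,
    coeff_medians = as.list(bundle$coeff_medians),
    coeff_test = if (!is.null(bundle$coeff_test)) list(
      median_plaster = bundle$coeff_test$median_a,
      median_fur = bundle$coeff_test$median_b,
      p_value = bundle$coeff_test$p_value,
      eta_squared = bundle$coeff_test$eta_squared) else NULL)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
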