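test_that("empty-scenery averaging is the per-pixel mean", {
  cam <- fx_camera()
  a <- array(1.2, c(4, 5, 3))
  expect_true(all(average_empty_scenery(a) == 1.2))
  b <- array(c(rep(1.2, 20), rep(1.22, 20)), c(4, 5, 2))
  expect_true(all(abs(average_empty_scenery(b) - 1.21) < 1e-12))
  expect_error(average_empty_scenery(array(1, c(4, 5, 0))), "no frames")

  ns <- noise_spec("plaster", sigma_plaster = 0.003, seed = 2)
  s <- simulate_empty_scenery(cam, ns, n = 500)
  bg <- average_empty_scenery(s)
  expect_equal(attr(bg, "n"), 500)
  dev <- abs(unclass(bg) - cam$mount_distance)
  expect_gt(mean(dev <= 3 * 0.003 / sqrt(500)), 0.995)
})

test_that("noiseless frames segment to the exact ground-truth mask", {
  for (kind in c("plaster", "fur")) {
    fr <- fx_frame(kind)
    sf <- segment_frame(fr$depth, fx_background(), seg_config())
    expect_identical(sf$mask, fr$scene$mask)
    # background zeroed, foreground depths preserved
    expect_true(all(sf$depth[!sf$mask] == 0))
    expect_identical(sf$depth[sf$mask], fr$depth[sf$mask])
  }
})

test_that("beam pixels never survive into the final mask", {
  fr <- fx_frame("fur")
  expect_gt(sum(fr$scene$beam_mask), 200)
  # without configured rectangles: dropped as secondary components
  sf <- segment_frame(fr$depth, fx_background(), seg_config())
  expect_true(all(!sf$mask[fr$scene$beam_mask]))
  # with configured rectangles: removed from the candidate itself
  rects <- list()
  lab <- tofcow:::label_components8(fr$scene$beam_mask)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    rects[[k]] <- c(range(idx[, 1]), range(idx[, 2]))[c(1, 2, 3, 4)]
  }
  cfg <- seg_config(beam_rects = rects)
  sf2 <- segment_frame(fr$depth, fx_background(), cfg)
  expect_true(all(!sf2$mask[fr$scene$beam_mask]))
  expect_identical(sf2$mask, fr$scene$mask)
})

test_that("a frame identical to the background yields a clean failure", {
  bg <- fx_background()
  sf <- segment_frame(bg, bg, seg_config())
  expect_equal(sf$verdict, "fail")
  expect_equal(sf$reasons, "no foreground")
  qt <- quality_tests(sf, seg_config(), fx_camera())
  expect_false(qt$pass)
  expect_equal(qt$reasons, "no foreground")
})

test_that("segmentation is idempotent", {
  cam <- fx_camera()
  fr <- render_frame(fx_field("fur"), cam, noise = noise_spec("fur"),
                     seed = 31)
  sf1 <- segment_frame(fr$depth, fx_background(), seg_config())
  sf2 <- segment_frame(sf1$depth, fx_background(), seg_config())
  expect_identical(sf2$mask, sf1$mask)
  expect_identical(sf2$depth, sf1$depth)
})

test_that("quality verdicts follow the frame's content", {
  cam <- fx_camera()
  cfg <- seg_config()
  # default noiseless standstill frame passes
  qt <- quality_tests(fx_segmented("fur"), cfg, cam)
  expect_true(qt$pass)
  expect_length(qt$reasons, 0)
  # half out of view at the stream start: border contact
  fr <- render_frame(fx_field("fur"), cam, offset = -0.25,
                     noise = fx_zero_noise("fur"))
  sf <- segment_frame(fr$depth, fx_background(), cfg)
  qt <- quality_tests(sf, cfg, cam)
  expect_false(qt$pass)
  expect_true("border contact" %in% qt$reasons)
})

test_that("mirroring is an involution that swaps columns", {
  fr <- fx_frame("fur")$depth
  expect_identical(mirror_frame(mirror_frame(fr)), fr)
  expect_identical(mirror_frame(fr)[, 144], fr[, 1])
  expect_identical(mirror_frame(fr)[, 1], fr[, 144])
  expect_error(mirror_frame(fr[, 1:100]), "144")
})

test_that("SumDiff commutes with mirroring on a short stream", {
  cam <- fx_camera()
  sim <- simulate_stream(fx_field("fur"), cam,
                         motion_spec(0, duration = 10 / cam$frame_rate),
                         noise_spec("fur", seed = 9))
  sd1 <- sum_diff(sim$stream$depth)
  mir <- sim$stream$depth
  for (i in seq_len(dim(mir)[3])) mir[, , i] <- mirror_frame(mir[, , i])
  sd2 <- sum_diff(mir)
  expect_lt(max(abs(mirror_frame(sd1) - sd2)), 1e-12)
})
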