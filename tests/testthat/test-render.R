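test_that("noiseless rendering puts plate and model at their exact depths", {
  cam <- fx_camera()
  fr <- fx_frame("plaster")
  plate <- fr$depth[!fr$scene$mask & !fr$scene$beam_mask]
  expect_true(all(plate == cam$mount_distance))
  model <- fr$depth[fr$scene$mask]
  expect_true(all(model >= 1.28 - 0.22 - 1e-12))
  expect_true(all(model <= 1.28 - 0.15 + 1e-12))
})

test_that("rendering is seed-deterministic and noise is class-confined", {
  cam <- fx_camera()
  field <- fx_field("fur")
  noise <- noise_spec("fur")
  f1 <- render_frame(field, cam, noise = noise, seed = 7)
  f2 <- render_frame(field, cam, noise = noise, seed = 7)
  expect_identical(f1$depth, f2$depth)
  f3 <- render_frame(field, cam, noise = noise, seed = 8)
  expect_false(identical(f1$depth, f3$depth))
  # a zero-noise surface class stays exact while others fluctuate
  quiet <- noise_spec("fur", sigma_plaster = 0, boundary_band_sigma = 0.02)
  g1 <- render_frame(field, cam, noise = quiet, seed = 1)
  g2 <- render_frame(field, cam, noise = quiet, seed = 2)
  plate <- !fx_frame("fur")$scene$mask & !fx_frame("fur")$scene$beam_mask
  # plate pixels away from any edge band are noise-free
  core_plate <- plate & g1$depth == cam$mount_distance
  expect_gt(sum(core_plate), 10000)
  expect_true(all(g2$depth[core_plate] == cam$mount_distance))
})

test_that("empirical interior noise matches the configured sigmas", {
  cam <- fx_camera()
  field <- fx_field("fur")
  ns <- noise_spec("fur", sigma_white = 0.002, sigma_black = 0.006,
                   seed = 13)
  sim <- simulate_stream(field, cam, motion_spec(0, duration = 800 / 9), ns)
  std <- pw_std(sim$stream$depth)
  mask <- truth_mask(sim$truth, 1)
  part <- partition_regions(mask)
  part <- fur_color_mask(stream_amplitude(sim$stream, 1), part)
  # stay off the boundary band: the elevated-noise band is 1 px wide, and
  # landmark bumps sit well inside, so erode the interior further
  core <- part$interior & tofcow:::erode_shift(part$interior, 2)
  w <- std[core & part$interior_white]
  b <- std[core & part$interior_black]
  expect_lt(abs(stats::median(w) / 0.002 - 1), 0.05)
  expect_lt(abs(stats::median(b) / 0.006 - 1), 0.05)
  # boundary band noise strictly exceeds interior noise
  expect_gt(stats::median(std[part$boundary]), stats::median(std[core]))
})

test_that("empty scenery frames average to the mount distance", {
  cam <- fx_camera()
  s0 <- simulate_empty_scenery(cam, fx_zero_noise("plaster"), n = 1)
  expect_equal(n_frames(s0), 1)
  expect_true(all(stream_depth(s0, 1) == cam$mount_distance))

  ns <- noise_spec("plaster", sigma_plaster = 0.003, seed = 5)
  s <- simulate_empty_scenery(cam, ns, n = 1000)
  m <- apply(s$depth, c(1, 2), mean)
  dev <- abs(m - cam$mount_distance)
  bound <- 3 * 0.003 / sqrt(1000)
  # per-pixel CLT bound holds at its nominal coverage, and the grand
  # mean is far tighter
  expect_gt(mean(dev <= bound), 0.995)
  expect_lt(abs(mean(m) - cam$mount_distance), 1e-4)
})
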