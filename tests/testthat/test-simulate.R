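test_that("standstill streams have duration x frame-rate frames", {
  cam <- fx_camera()
  field <- fx_field("plaster")
  sim <- simulate_stream(field, cam, motion_spec(0, duration = 20),
                         fx_zero_noise("plaster"))
  expect_lte(abs(n_frames(sim$stream) - 20 * cam$frame_rate), 1)
  # landmark positions constant without motion
  lt <- sim$truth$landmarks
  for (nm in unique(lt$name)) {
    expect_equal(length(unique(lt$col[lt$name == nm])), 1)
    expect_equal(length(unique(lt$row[lt$name == nm])), 1)
  }
})

test_that("doubling the velocity halves the in-view frames per pass", {
  cam <- fx_camera()
  field <- fx_field("plaster")
  nz <- fx_zero_noise("plaster")
  n10 <- n_frames(simulate_stream(field, cam,
                                  motion_spec(10, passes = 1), nz)$stream)
  n20 <- n_frames(simulate_stream(field, cam,
                                  motion_spec(20, passes = 1), nz)$stream)
  expect_lte(abs(n20 - n10 / 2), 1)
})

test_that("a fixed seed makes streams bit-reproducible", {
  cam <- fx_camera()
  field <- fx_field("fur")
  ns <- noise_spec("fur", seed = 99)
  s1 <- simulate_stream(field, cam, motion_spec(20, passes = 1), ns)
  s2 <- simulate_stream(field, cam, motion_spec(20, passes = 1), ns)
  expect_identical(s1$stream$depth, s2$stream$depth)
  expect_identical(s1$truth$corrupted, s2$truth$corrupted)
})

test_that("zero velocity leaves frames untouched when the rate is zero", {
  cam <- fx_camera()
  field <- fx_field("fur")
  sc <- tofcow:::scene_sample(field, cam, 0.2)
  ns <- noise_spec("fur")  # artifact_rate(0) = 0 for the fur arm
  set.seed(4)
  out <- corrupt_with_motion_artifacts(sc$depth, 0, ns,
                                       list(field = field, offset = 0.2),
                                       cam)
  expect_false(attr(out, "corrupted"))
  attr(out, "corrupted") <- NULL
  expect_identical(out, sc$depth)
})

test_that("a corrupted moving frame fails the quality tests", {
  cam <- fx_camera()
  field <- fx_field("plaster")
  always <- noise_spec("plaster", artifact_rate = function(v) 1)
  sc <- tofcow:::scene_sample(field, cam, 0.2)
  set.seed(11)
  fr <- corrupt_with_motion_artifacts(sc$depth, 20, always,
                                      list(field = field, offset = 0.2),
                                      cam)
  expect_true(attr(fr, "corrupted"))
  sf <- segment_frame(fr, fx_background(), seg_config())
  qt <- quality_tests(sf, seg_config(), cam)
  expect_false(qt$pass)
})
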