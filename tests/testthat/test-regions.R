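test_that("canonical masks partition as expected", {
  # 3x3 block: ring of 8 boundary pixels around 1 interior pixel
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  p <- partition_regions(m)
  expect_equal(unname(p$counts["boundary"]), 8)
  expect_equal(unname(p$counts["interior"]), 1)
  expect_true(p$interior[4, 4])

  # full-frame foreground: the image border counts as background
  f <- matrix(TRUE, 6, 9)
  pf <- partition_regions(f)
  ring <- matrix(FALSE, 6, 9)
  ring[c(1, 6), ] <- TRUE; ring[, c(1, 9)] <- TRUE
  expect_identical(pf$boundary, ring)

  # empty mask: empty partition
  pe <- partition_regions(matrix(FALSE, 4, 4))
  expect_equal(unname(pe$counts["boundary"] + pe$counts["interior"]), 0)
})

test_that("partition agrees with a brute-force neighbourhood scan", {
  set.seed(77)
  for (i in 1:60) {
    m <- random_blob_mask()
    p <- partition_regions(m)
    bf <- brute_force_partition(m)
    expect_identical(p$boundary, bf$boundary)
    expect_identical(p$interior, bf$interior)
    # conservation: boundary and interior tile the foreground
    expect_equal(sum(p$boundary) + sum(p$interior), sum(m))
    expect_false(any(p$boundary & p$interior))
  }
})

test_that("the gray threshold splits interior fur colours like the truth", {
  p <- partition_regions(matrix(TRUE, 5, 5))
  all_white <- fur_color_mask(matrix(255, 5, 5), p)
  expect_equal(sum(all_white$interior_white), sum(p$interior))
  all_black <- fur_color_mask(matrix(0, 5, 5), p)
  expect_equal(sum(all_black$interior_black), sum(p$interior))
  # boundary pixels are never sub-labelled
  expect_false(any(all_white$interior_white & all_white$boundary))

  fr <- fx_frame("fur")
  part <- partition_regions(fr$scene$mask)
  part <- fur_color_mask(fr$amplitude, part)
  truth_white <- fr$scene$white_mask & part$interior
  expect_identical(part$interior_white, truth_white)
})

test_that("the elevated-noise band hugs the mask edge", {
  fr <- fx_frame("fur")
  sc <- fr$scene
  sig <- tofcow:::noise_sigma_map(sc, noise_spec("fur"))
  band <- sig == noise_spec("fur")$boundary_band_sigma
  fg <- sc$mask | sc$beam_mask
  # the band is foreground and vanishes after eroding twice: 1-2 px wide
  expect_true(all(fg[band]))
  expect_false(any(band & tofcow:::erode_shift(fg, 2)))
  # it covers the partition's boundary ring of the cow area
  p <- partition_regions(sc$mask)
  expect_true(all(band[p$boundary & !sc$beam_mask] |
                    !fg[p$boundary & !sc$beam_mask]))
})

test_that("noiseless landmarks sit within 2 px of the ground truth", {
  for (kind in c("plaster", "fur")) {
    sf <- fx_segmented(kind)
    lm <- detect_landmarks(sf)
    truth <- fx_frame(kind)$scene$landmarks
    both <- merge(lm, truth, by = "name")
    expect_true(all(both$defined.x))
    expect_lte(max(abs(both$row.x - both$row.y)), 2)
    expect_lte(max(abs(both$col.x - both$col.y)), 2)
  }
})

test_that("a flat slab yields only undefined landmarks", {
  spec <- surface_spec("plaster", ridge = list(amp = 0, sigma = 0.015))
  spec$bumps$amp <- 0
  field <- build_cow_surface(spec)
  fr <- render_frame(field, fx_camera(), noise = fx_zero_noise("plaster"))
  sf <- segment_frame(fr$depth, fx_background(), seg_config())
  lm <- detect_landmarks(sf)
  expect_true(all(!lm$defined))
})

test_that("mirroring swaps left/right landmarks across the midline", {
  sf <- fx_segmented("fur")
  lm1 <- detect_landmarks(sf)
  sf2 <- segment_frame(mirror_frame(fx_frame("fur")$depth),
                       fx_background(), seg_config())
  lm2 <- detect_landmarks(sf2)
  swap <- c(tail = "tail", isc_tub_l = "isc_tub_r", isc_tub_r = "isc_tub_l",
            dish_l = "dish_r", dish_r = "dish_l", bb30 = "bb30")
  for (nm in lm1$name) {
    a <- lm1[lm1$name == nm, ]
    b <- lm2[lm2$name == unname(swap[nm]), ]
    expect_lte(abs(b$col - (145 - a$col)), 1)
    expect_lte(abs(b$row - a$row), 1)
  }
})

test_that("standstill landmark X-coordinates fluctuate by at most 2 px", {
  cam <- fx_camera()
  bg <- fx_background()
  for (kind in c("plaster", "fur")) {
    sim <- simulate_stream(fx_field(kind), cam,
                           motion_spec(0, duration = 40 / cam$frame_rate),
                           noise_spec(kind, seed = 3))
    res <- analyze_stream(sim$stream, average_empty_scenery(
      array(bg, c(nrow(bg), ncol(bg), 1))))
    lt <- res$landmarks
    for (nm in unique(lt$name)) {
      xs <- lt$col[lt$name == nm & lt$defined]
      expect_lte(diff(range(xs)), 2)
    }
  }
})

test_that("BB30 matches an exhaustive distance scan on synthetic traces", {
  # straight vertical trace
  tr <- data.frame(row = 1:60, col = 40)
  bb <- locate_bb30(tr, c(row = 60, col = 40))
  expect_equal(unname(bb["row"]), 30)
  expect_equal(unname(bb["col"]), 40)
  # 45-degree diagonal: 30/sqrt(2) ~ 21.2 rows anterior
  trd <- data.frame(row = 1:60, col = 1:60)
  bbd <- locate_bb30(trd, c(row = 60, col = 60))
  expect_equal(unname(bbd["row"]), 60 - 21)
  # too-short trace is undefined
  expect_null(locate_bb30(tr[1:25, ], c(row = 25, col = 40)))

  set.seed(5)
  for (i in 1:25) {
    n <- sample(35:90, 1)
    cols <- cumsum(sample(-1:1, n, replace = TRUE)) + 50
    tr <- data.frame(row = seq_len(n), col = cols)
    tail <- c(row = n, col = cols[n])
    got <- locate_bb30(tr, tail)
    # oracle: scan all anterior points for the distance closest to 30,
    # ties toward the anterior
    d <- sqrt((tr$row - n)^2 + (tr$col - cols[n])^2)
    cand <- which(tr$row < n)
    err <- abs(d[cand] - 30)
    best <- cand[err == min(err)]
    pick <- best[which.min(tr$row[best])]
    expect_equal(unname(got["row"]), tr$row[pick])
    expect_equal(unname(got["col"]), tr$col[pick])
  }
})
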