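test_that("specification constructors enforce their invariants", {
  expect_error(tassel_spec(main_spike_length = 2), "shorter than 3")
  expect_error(tassel_spec(n_branches = 2, branch_attach_fractions = c(0.5, 0.2)),
               "strictly increasing")
  expect_error(tassel_spec(n_branches = 1, branch_attach_fractions = 1.2),
               "inside \\(0,1\\)")
  expect_error(tassel_spec(n_branches = 1, branch_attach_fractions = 0.5,
                           branch_lengths = -3), "positive")
  expect_error(anthesis_model(onset_fraction = 1.4), "probability")
  expect_error(anthesis_model(up_rate = -0.1), ">= 0")
  expect_error(anthesis_model(amplitude = 0), "> 0")
  expect_error(anthesis_model(duration_frames = 0), ">= 1")
  expect_error(scene_spec(n_days = 0), ">= 1")
  expect_error(scene_spec(jitter = list(sigma = 2, missing_prob = 1.5)),
               "probability")
})

test_that("width profile follows the two-sided swelling front", {
  sp <- tassel_spec(main_spike_length = 100, n_branches = 0, curvature = 0)
  ## before start: constant base width
  an <- anthesis_model(onset_fraction = 0.5, up_rate = 0.05, down_rate = 0.05,
                       amplitude = 6, duration_frames = 20, start_frame = 10)
  pr <- true_width_profile(sp, an, frame = 3)
  expect_true(all(pr$width == sp$base_width))
  ## zero spread: a single widened position at the onset
  an0 <- anthesis_model(onset_fraction = 0.5, up_rate = 0, down_rate = 0,
                        amplitude = 6, duration_frames = 20, start_frame = 0)
  pr0 <- true_width_profile(sp, an0, frame = 5)
  wide <- pr0$position[pr0$width > sp$base_width]
  expect_lte(length(wide), 2)
  expect_gte(length(wide), 1)
  expect_lt(abs(mean(wide) - 0.5 * max(pr0$position)), 2)
  ## after the duration elapses the spike relaxes to base width
  pr_end <- true_width_profile(sp, an0, frame = 25)
  expect_true(all(pr_end$width == sp$base_width))
  ## symmetric rates 0.05/frame, 5 frames in: band covers fractions [.25,.75]
  an5 <- anthesis_model(onset_fraction = 0.5, up_rate = 0.05, down_rate = 0.05,
                        amplitude = 6, duration_frames = 20, start_frame = 0)
  pr5 <- true_width_profile(sp, an5, frame = 5)
  frac <- pr5$position / 100
  expect_true(all(pr5$width[frac > 0.26 & frac < 0.74] == sp$base_width + 6))
  expect_true(all(pr5$width[frac < 0.24 | frac > 0.76] == sp$base_width))
})

test_that("rendered swelling band matches a column-count oracle", {
  ## straight vertical spike: perpendicular slices are image rows
  sp <- tassel_spec(main_spike_length = 100, n_branches = 0, curvature = 0,
                    base_width = 5)
  an <- anthesis_model(onset_fraction = 0.5, up_rate = 0.05, down_rate = 0.05,
                       amplitude = 6, duration_frames = 20, start_frame = 0)
  tg <- generate_tassel(sp, an, frame = 5)
  counts <- rowSums(tg$mask)
  wide_rows <- which(counts >= 9)           # swollen width 11 vs base 5
  tip_y <- tg$truth$tip["y"]
  band_lo <- (min(wide_rows) - 1 - tip_y)   # px from tip
  band_hi <- (max(wide_rows) - 1 - tip_y)
  ## true band [0.25, 0.75] of the spike, blurred by the disc radius (5 px)
  expect_lt(abs(band_lo - 25), 7)
  expect_lt(abs(band_hi - 75), 7)
  ## mask is a single 8-connected component
  lab <- EBImage::bwlabel(tg$mask)
  expect_equal(max(lab), 1)
})

test_that("scene rendering is deterministic with full mask/box consistency", {
  sc <- scene_spec(seed = 42L)
  a <- render_scene(sc, 3)
  b <- render_scene(sc, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  for (id in c("left", "right")) {
    tr <- a$truth[[id]]
    if (!isTRUE(tr$present)) next
    px <- which(tr$mask > 0, arr.ind = TRUE)
    expect_gte(min(px[, 2]) - 1, tr$box$x_min)
    expect_lte(max(px[, 2]), tr$box$x_max)
    expect_gte(min(px[, 1]) - 1, tr$box$y_min)
    expect_lte(max(px[, 1]), tr$box$y_max)
  }
})

test_that("presence controls produce the expected number of ground-truth boxes", {
  sc0 <- scene_spec(clutter = list(n_leaves = 0L, background_tassel_prob = 0),
                    jitter = list(sigma = 0, missing_prob = 0))
  fr <- render_scene(sc0, 0)
  expect_equal(sum(vapply(fr$truth, function(t) isTRUE(t$present), TRUE)), 2)
  sc1 <- scene_spec(jitter = list(sigma = 0, missing_prob = 1))
  for (f in 0:2)
    expect_equal(sum(vapply(render_scene(sc1, f)$truth,
                            function(t) isTRUE(t$present), TRUE)), 0)
})

test_that("clutter-free scenes have >= 50 grey levels of sky/tassel separation", {
  sc <- scene_spec(clutter = list(n_leaves = 0L, background_tassel_prob = 0),
                   jitter = list(sigma = 0, missing_prob = 0))
  fr <- render_scene(sc, 0)
  g <- to_gray(fr$image) * 255
  fg <- fr$truth$left$mask + fr$truth$right$mask > 0
  expect_gte(mean(g[!fg]) - mean(g[fg]), 50)
})

test_that("sequences are written with the daylight capture cadence", {
  dir <- tempfile("seq")
  sc <- scene_spec(height = 64L, width = 96L,
                   left = tassel_spec(main_spike_length = 40, n_branches = 1,
                                      branch_attach_fractions = 0.1),
                   right = tassel_spec(main_spike_length = 35, n_branches = 0),
                   frames_per_day = 6L, n_days = 2L, seed = 5L)
  res <- generate_sequence(sc, dir)
  mf <- read_manifest(dir)
  expect_equal(nrow(mf), 12)
  ts <- as.POSIXct(mf$timestamp, tz = "UTC")
  within_day <- diff(ts)[1:5]
  expect_true(all(as.numeric(within_day, units = "mins") == 120))  # 720/6 min
  ## overnight gap: 7 pm back to 7 am
  expect_gt(as.numeric(ts[7] - ts[6], units = "hours"), 12)
  expect_true(all(format(ts[c(1, 7)], "%H:%M") == "07:00"))
  expect_true(all(file.exists(file.path(dir, mf$filename))))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ## determinism: regenerating yields identical frame bytes
  dir2 <- tempfile("seq2")
  generate_sequence(sc, dir2)
  h1 <- tools::md5sum(file.path(dir, mf$filename))
  h2 <- tools::md5sum(file.path(dir2, mf$filename))
  expect_identical(unname(h1), unname(h2))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("single-frame sequences are valid", {
  dir <- tempfile("seq1")
  sc <- scene_spec(height = 64L, width = 96L,
                   left = tassel_spec(main_spike_length = 40, n_branches = 0),
                   right = tassel_spec(main_spike_length = 35, n_branches = 0),
                   frames_per_day = 1L, n_days = 1L)
  res <- generate_sequence(sc, dir)
  expect_equal(nrow(res$manifest), 1)
  unlink(dir, recursive = TRUE)
})
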