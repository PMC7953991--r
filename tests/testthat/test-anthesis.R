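make_profile <- function(len, width = 5) {
  structure(data.frame(position = 0:(len - 1), width = width),
            class = c("width_profile", "data.frame"))
}

test_that("profiles align tip-anchored with invalid padding beyond each length", {
  profs <- list(make_profile(80), make_profile(100), make_profile(90))
  surf <- align_profiles(profs, frames = 0:2)
  expect_equal(dim(surf$widths), c(3, 100))
  expect_equal(rowSums(surf$valid), c(80, 100, 90))
  expect_true(all(surf$valid[2, ]))
  expect_false(any(surf$valid[1, 81:100]))
  ## identical profiles give a constant surface
  surf2 <- align_profiles(list(make_profile(50), make_profile(50)), frames = 0:1)
  expect_true(all(surf2$widths[surf2$valid] == 5))
  ## permuted input frames sort to the identical surface
  surf3 <- align_profiles(profs[c(3, 1, 2)], frames = c(2, 0, 1))
  expect_identical(surf3$widths, surf$widths)
  expect_identical(surf3$valid, surf$valid)
  expect_error(align_profiles(list(make_profile(10))), "at least 2")
  expect_error(align_profiles(list(NULL, NULL), frames = 0:1), "empty")
})

test_that("outlier removal flags spikes but preserves flowering steps", {
  ## constant surface with one cell spiked to 10x the median
  W <- matrix(5, 40, 6)
  W[20, 3] <- 50
  surf <- make_surface(W)
  cleaned <- remove_outliers(surf)
  expect_false(cleaned$valid[20, 3])
  expect_equal(sum(surf$valid) - sum(cleaned$valid), 1)
  ## a clean stepped surface (a genuine flowering plateau) loses nothing
  Ws <- matrix(5, 60, 6)
  Ws[25:45, 2:4] <- 11
  surfs <- make_surface(Ws)
  cleaneds <- remove_outliers(surfs)
  expect_equal(sum(cleaneds$valid), sum(surfs$valid))
  ## idempotence and monotone valid-cell count
  again <- remove_outliers(cleaned)
  expect_identical(again$valid, cleaned$valid)
  expect_lte(sum(cleaned$valid), sum(surf$valid))
})

test_that("flowering summary detects onset, duration and spread directions", {
  ## construct a surface with a two-sided front: baseline 5, amplitude 6,
  ## onset at column 50 of 100, spreading 1 px/frame each way, frames 30..90
  T_ <- 120L; P <- 100L
  W <- matrix(5, T_, P)
  for (t in 30:90) {
    e <- t - 30
    cols <- max(1, 51 - e):min(P, 51 + e)
    W[t + 1, cols] <- 11
  }
  surf <- make_surface(W, frames_per_day = 24L)
  sm <- summarize_flowering(surf, baseline_frames = 20L)
  expect_true(sm$detected)
  expect_equal(sm$onset_position_px, 50, tolerance = 2)
  expect_equal(sm$onset_frame, 30)
  expect_equal(sm$end_frame, 90)
  expect_equal(sm$duration_days, 60 / 24)
  expect_setequal(sm$directions, c("upward", "downward"))
  ## flat surface: nothing detected
  flat <- make_surface(matrix(5, 60, 50))
  smf <- summarize_flowering(flat, baseline_frames = 20L)
  expect_false(smf$detected)
  expect_equal(smf$duration_days, 0)
  ## one-sided spread reports a single direction
  W1 <- matrix(5, T_, P)
  for (t in 30:90) W1[t + 1, 51:min(P, 51 + (t - 30))] <- 11
  sm1 <- summarize_flowering(make_surface(W1, frames_per_day = 24L),
                             baseline_frames = 20L)
  expect_equal(sm1$directions, "downward")
  expect_error(summarize_flowering(surf, baseline_frames = 200L), "leave frames")
})

test_that("raising the swell threshold never lengthens the detected duration", {
  set.seed(12)
  T_ <- 100L; P <- 80L
  W <- matrix(5 + rnorm(T_ * P, 0, 0.2), T_, P)
  for (t in 40:80) {
    e <- t - 40
    cols <- max(1, 41 - e):min(P, 41 + e)
    ## amplitude fades toward the edges of the window so thresholds bite
    W[t + 1, cols] <- W[t + 1, cols] + 6 * (1 - abs(t - 60) / 25)
  }
  surf <- make_surface(W, frames_per_day = 24L)
  durs <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    summarize_flowering(surf, baseline_frames = 30L,
                        swell_threshold = th)$duration_days, 0)
  expect_true(all(diff(durs) <= 1e-9))
})

test_that("the full chain recovers generator anthesis parameters", {
  rec <- anthesis_recovery_study(n_sequences = 2, seed = 5,
                                 onset_fractions = c(0.45, 0.65),
                                 durations_days = c(1, 2))
  means <- attr(rec, "means")
  expect_true(means$all_detected)
  expect_lte(means$onset_mae, 0.05)
  expect_lte(means$duration_mae, 0.25)
  expect_true(all(rec$both_directions))
})

test_that("surfaces and summaries serialize to CSV/JSON", {
  surf <- make_surface(matrix(5, 10, 8))
  f <- tempfile(fileext = ".csv")
  write_surface_csv(surf, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 10)
  expect_equal(ncol(back), 9)   # frame_index + 8 positions
  sm <- summarize_flowering(surf, baseline_frames = 4L)
  j <- tempfile(fileext = ".json")
  write_summary_json(sm, j)
  expect_false(jsonlite::read_json(j)$detected)
  unlink(c(f, j))
})
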