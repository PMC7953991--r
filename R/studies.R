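## Desk-scale recovery studies against generator ground truth.
##
## These functions run a pipeline stage end-to-end on seeded synthetic data
## and measure how well the stage recovers the generator's known truth:
## tracking identity agreement, width-profile fidelity, anthesis parameter
## recovery, and learning sanity for the two trainable models. They are
## used both interactively and by the package's acceptance checks.

#' Tracking identity recovery on synthetic sequences
#'
#' Generates seeded scenes whose horizontal tassel separation is at least
#' four times the wind-jitter sigma, pools the ground-truth boxes of all
#' frames, runs [collect_centers()] + [cluster_tracks()], and measures the
#' fraction of boxes whose recovered identity agrees with the generator's.
#'
#' @param n_sequences number of independent sequences.
#' @param n_frames frames per sequence.
#' @param seed master seed.
#' @param jitter_sigma wind jitter sd in pixels (separation is ~128 px).
#' @return list with per-sequence `agreement` (fractions) and `mean_agreement`.
#' @export
tracking_recovery_study <- function(n_sequences = 20L, n_frames = 20L, seed = 1L,
                                    jitter_sigma = 2) {
  agreement <- numeric(n_sequences)
  for (s in seq_len(n_sequences)) {
    sc <- scene_spec(height = 160L, width = 320L,
                     left = tassel_spec(main_spike_length = 100, seed = s),
                     right = tassel_spec(main_spike_length = 95, curvature = -0.1,
                                         seed = s + 100L),
                     clutter = list(n_leaves = 0L, background_tassel_prob = 0),
                     jitter = list(sigma = jitter_sigma, missing_prob = 0.05),
                     frames_per_day = n_frames, n_days = 1L,
                     seed = substream_seed(seed, "trackseq", s))
    boxes <- NULL; truth_id <- character(0)
    for (f in seq_len(n_frames) - 1L) {
      tr <- render_scene(sc, f)$truth
      for (id in c("left", "right")) {
        t1 <- tr[[id]]
        if (isTRUE(t1$present)) {
          boxes <- rbind(boxes, bounding_box(t1$box$x_min, t1$box$y_min,
                                             t1$box$x_max, t1$box$y_max,
                                             score = 1, frame = f, source = "truth"))
          truth_id <- c(truth_id, id)
        }
      }
    }
    centers <- collect_centers(boxes)
    tracks <- cluster_tracks(centers, seed = substream_seed(seed, "km", s))
    asg <- attr(tracks, "assignment")
    rec_id <- asg$identity[order(asg$box_row)]
    agreement[s] <- mean(rec_id == truth_id[sort(asg$box_row)])
  }
  list(agreement = agreement, mean_agreement = mean(agreement))
}

#' Width-profile fidelity on clutter-free synthetic spikes
#'
#' Renders single tassels over a range of shapes (with and without active
#' swelling), runs the full skeleton/crop/width chain, and reports the mean
#' absolute error between measured and true tip-anchored width profiles.
#'
#' @param n_tassels number of tassels.
#' @param seed master seed.
#' @return list with per-tassel `mae` (pixels) and `mean_mae`.
#' @export
width_recovery_study <- function(n_tassels = 25L, seed = 1L) {
  mae <- numeric(n_tassels)
  for (i in seq_len(n_tassels)) {
    prm <- with_seed(substream_seed(seed, "widthspec", i), {
      list(L = stats::runif(1, 110, 150), curv = stats::runif(1, -0.2, 0.2),
           nb = sample(2:4, 1), swell = stats::runif(1) < 0.5)
    })
    sp <- tassel_spec(main_spike_length = prm$L, n_branches = prm$nb,
                      curvature = prm$curv, base_width = 5,
                      seed = substream_seed(seed, "shape", i))
    an <- anthesis_model(onset_fraction = 0.6, up_rate = 0.004, down_rate = 0.004,
                         amplitude = 6, duration_frames = 144L, start_frame = 0L)
    frame <- if (prm$swell) 60L else 200L   # mid-swelling or fully quiescent
    tg <- generate_tassel(sp, an, frame)
    res <- analyze_mask(tg$mask)
    truth <- tg$truth$width_profile
    pos <- round(res$profile$position)
    ok <- pos >= 0 & pos <= max(truth$position)
    w_true <- truth$width[match(pos[ok], truth$position)]
    mae[i] <- mean(abs(res$profile$width[ok] - w_true))
  }
  list(mae = mae, mean_mae = mean(mae))
}

#' Anthesis parameter recovery on synthetic mask sequences
#'
#' For seeded sequences spanning onset fractions and durations, renders the
#' tassel mask at every frame, measures width profiles through the full
#' morphometry chain, assembles and cleans the surface, summarizes
#' flowering, and compares the recovered onset position (as a fraction of
#' the spike length from the tip) and duration (capture days) with the
#' generator's parameters.
#'
#' @param n_sequences number of sequences.
#' @param seed master seed.
#' @param onset_fractions vector of true onset fractions (recycled).
#' @param durations_days vector of true durations in capture days (recycled).
#' @param frames_per_day frames per capture day (default 72: 10-minute
#'   cadence over 12 daylight hours).
#' @param up_rate,down_rate spread rates in spike fractions per frame.
#' @return data.frame with one row per sequence (`onset_true`, `onset_rec`,
#'   `onset_err`, `duration_true`, `duration_rec`, `duration_err`,
#'   `both_directions`) plus attribute `means`.
#' @export
anthesis_recovery_study <- function(n_sequences = 20L, seed = 1L,
                                    onset_fractions = seq(0.3, 0.8, length.out = n_sequences),
                                    durations_days = rep(1:3, length.out = n_sequences),
                                    frames_per_day = 72L,
                                    up_rate = 0.004, down_rate = 0.004) {
  onset_fractions <- rep_len(onset_fractions, n_sequences)
  durations_days <- rep_len(durations_days, n_sequences)
  out <- data.frame(onset_true = onset_fractions, onset_rec = NA_real_,
                    onset_err = NA_real_, duration_true = durations_days,
                    duration_rec = NA_real_, duration_err = NA_real_,
                    both_directions = NA)
  for (s in seq_len(n_sequences)) {
    ## Architecture chosen so the swelling front stays observable over the
    ## whole swept onset range: a low branch whorl (so the profiled crop
    ## reaches 0.8 of the spike from the tip with room below), short
    ## opposite-side branches and mild curvature (so the swollen spike never
    ## fuses with a branch, which would truncate the visible crop - the
    ## branch-occlusion failure mode this measurement inherits by design).
    sp <- tassel_spec(main_spike_length = 140, n_branches = 2,
                      branch_attach_fractions = c(0.04, 0.07),
                      branch_lengths = 21, base_width = 5,
                      curvature = with_seed(substream_seed(seed, "curv", s),
                                            stats::runif(1, -0.08, 0.08)),
                      seed = substream_seed(seed, "shape", s))
    dur_frames <- durations_days[s] * frames_per_day
    an <- anthesis_model(onset_fraction = onset_fractions[s],
                         up_rate = up_rate, down_rate = down_rate,
                         amplitude = 6, duration_frames = dur_frames,
                         start_frame = frames_per_day)
    n_frames <- frames_per_day + dur_frames + frames_per_day %/% 3L
    profiles <- vector("list", n_frames)
    S <- NA_real_
    ## frames sharing a swelling interval render bit-identical masks, so the
    ## measured profile is computed once per distinct interval
    memo <- new.env(parent = emptyenv())
    for (f in seq_len(n_frames) - 1L) {
      iv <- swollen_interval(an, f)
      key <- if (is.null(iv)) "quiescent" else sprintf("%.6f_%.6f", iv[1], iv[2])
      if (is.null(memo[[key]])) {
        tg <- generate_tassel(sp, an, f)
        S <- tg$truth$spike_length
        memo[[key]] <- analyze_mask(tg$mask)$profile
      }
      profiles[[f + 1L]] <- memo[[key]]
    }
    surf <- align_profiles(profiles, frames = seq_len(n_frames) - 1L,
                           frames_per_day = frames_per_day)
    surf <- remove_outliers(surf)
    sm <- summarize_flowering(surf, baseline_frames = (2L * frames_per_day) %/% 3L)
    if (sm$detected) {
      out$onset_rec[s] <- sm$onset_position_px / S
      out$onset_err[s] <- abs(out$onset_rec[s] - onset_fractions[s])
      out$duration_rec[s] <- sm$duration_days
      out$duration_err[s] <- abs(sm$duration_days - durations_days[s])
      out$both_directions[s] <- all(c("upward", "downward") %in% sm$directions)
    }
  }
  attr(out, "means") <- list(onset_mae = mean(out$onset_err),
                             duration_mae = mean(out$duration_err),
                             all_detected = !anyNA(out$onset_rec),
                             frac_both_directions = mean(out$both_directions))
  out
}

#' Synthetic crop/mask pairs for segmenter studies
#'
#' Each pair is a sky-backed tassel render and its exact foreground mask.
#'
#' @param n number of pairs.
#' @param seed master seed.
#' @return list with `crops` and `masks` (parallel lists).
#' @export
synth_segmentation_pairs <- function(n = 100L, seed = 1L) {
  crops <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    si <- substream_seed(seed, "segpair", i)
    pr <- with_seed(si, list(L = stats::runif(1, 80, 105),
                             nb = sample(2:4, 1),
                             curv = stats::runif(1, -0.2, 0.2),
                             bright = stats::runif(1, 0.7, 0.9)))
    sp <- tassel_spec(main_spike_length = pr$L, n_branches = pr$nb,
                      curvature = pr$curv, base_width = 5, seed = si)
    H <- 130L; W <- 90L
    tg <- generate_tassel(sp, anthesis_model(start_frame = 10000L), 0,
                          canvas = c(H, W), origin = c(W / 2, 0.95 * H))
    img <- array(0, c(H, W, 3))
    sky <- c(0.80, 0.88, 1.0) * pr$bright
    cloud <- with_seed(substream_seed(si, "cloud"),
                       bilinear_upsample(matrix(stats::rnorm(30), 5, 6), H, W) * 0.06)
    for (k in 1:3) {
      ch <- pmin(1, pmax(0, sky[k] * (1 + cloud)))
      ch[tg$mask > 0] <- c(0.33, 0.24, 0.14)[k]
      img[, , k] <- ch
    }
    crops[[i]] <- img; masks[[i]] <- tg$mask
  }
  list(crops = crops, masks = masks)
}

#' Learning sanity study for the crop classifier
#'
#' Trains the convolutional tassel/non-tassel classifier from scratch on a
#' separable synthetic crop set for several seeds and records the held-out
#' validation accuracy of each run.
#'
#' @param n_seeds number of independent seeded runs.
#' @param n_crops crops per run.
#' @param size square input side in pixels.
#' @param epochs maximum training epochs.
#' @param seed master seed.
#' @param pass_acc validation accuracy counted as a pass (default 0.9).
#' @return list with `val_acc` (per-seed), `n_pass` and `pass_rate`.
#' @export
classifier_learning_study <- function(n_seeds = 10L, n_crops = 200L, size = 64L,
                                      epochs = 20L, seed = 1L, pass_acc = 0.9) {
  val_acc <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- substream_seed(seed, "clsrun", k)
    ds <- synth_crop_dataset(n_crops, size = size, seed = sk)
    model <- build_classifier(classifier_config(input_size = c(size, size)),
                              seed = sk)
    model <- train_classifier(model, ds$x, ds$y,
                              hyperparams = list(epochs = epochs,
                                                 early_stop_acc = 0.95),
                              seed = sk)
    val_acc[k] <- utils::tail(model$history$val_acc, 1L)
  }
  list(val_acc = val_acc, n_pass = sum(val_acc >= pass_acc),
       pass_rate = mean(val_acc >= pass_acc))
}

#' Learning sanity study for the encoder-decoder segmenter
#'
#' Trains the tiny encoder-decoder on easy synthetic crop/mask pairs and
#' reports held-out pixel accuracy and foreground IOU.
#'
#' @param n_pairs training pairs.
#' @param size square input side in pixels.
#' @param epochs maximum training epochs.
#' @param seed master seed.
#' @return list with `pixel_accuracy`, `iou_fg` and the trained model.
#' @export
segmenter_learning_study <- function(n_pairs = 100L, size = 64L, epochs = 30L,
                                     seed = 1L) {
  ds <- synth_segmentation_pairs(n_pairs + 20L, seed = seed)
  test_i <- seq_len(20L)
  train_i <- 20L + seq_len(n_pairs)
  model <- build_segmenter(segmenter_config(input_size = size), seed = seed)
  model <- train_segmenter(model, ds$crops[train_i], ds$masks[train_i],
                           hyperparams = list(epochs = epochs,
                                              early_stop_acc = 0.97),
                           seed = seed)
  accs <- numeric(length(test_i)); ious <- numeric(length(test_i))
  for (j in seq_along(test_i)) {
    pred <- predict_segmenter(model, ds$crops[[test_i[j]]])
    ev <- evaluate_segmentation(pred$mask, ds$masks[[test_i[j]]])
    accs[j] <- ev$pixel_accuracy; ious[j] <- ev$iou_fg
  }
  list(pixel_accuracy = mean(accs), iou_fg = mean(ious), model = model)
}
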