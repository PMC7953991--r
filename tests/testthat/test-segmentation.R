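test_that("classical segmenters recover the synthetic mask in each colour space", {
  pair <- make_tassel_crop(seed = 2)
  for (m in c("otsu", "rgb", "hsv", "lab")) {
    cand <- segment_classical(pair$crop, m)
    expect_s3_class(cand, "mask_candidate")
    expect_equal(dim(cand$mask), dim(pair$mask))
    expect_true(all(cand$mask %in% c(0L, 1L)))
    iou_m <- sum(cand$mask & pair$mask) / sum(cand$mask | pair$mask)
    expect_gte(iou_m, 0.9)
  }
  ## otsu is essentially exact on these hard-edged, bimodal renders
  ot <- segment_classical(pair$crop, "otsu")
  expect_gte(sum(ot$mask & pair$mask) / sum(ot$mask | pair$mask), 0.99)
  ## determinism
  expect_identical(segment_classical(pair$crop, "hsv")$mask,
                   segment_classical(pair$crop, "hsv")$mask)
})

test_that("degenerate crops are handled gracefully", {
  white <- array(1, c(20, 20, 3))
  expect_warning(cand <- segment_classical(white, "otsu"), "constant")
  expect_equal(sum(cand$mask), 0)
  expect_equal(sum(segment_classical(white, "rgb")$mask), 0)
})

test_that("consensus annotation selects the argmax candidate or rejects all", {
  pair <- make_tassel_crop(seed = 4)
  res <- consensus_annotate(pair$crop, reference_mask = pair$mask)
  expect_false(res$rejected)
  expect_equal(unname(res$scores[res$selected$method]), max(res$scores))
  expect_gte(res$selected$score, 0.9)
  ## all-background candidates against a non-empty truth: rejection
  white <- array(1, c(30, 30, 3))
  truth <- matrix(0L, 30, 30); truth[10:20, 10:20] <- 1L
  res2 <- suppressWarnings(consensus_annotate(white, reference_mask = truth))
  expect_true(res2$rejected)
  expect_null(res2$selected)
  ## no-reference mode writes the review layout
  rd <- tempfile("review")
  res3 <- consensus_annotate(pair$crop, review_dir = rd)
  expect_true(all(file.exists(file.path(rd, c("crop.png", "otsu.png", "rgb.png",
                                              "hsv.png", "lab.png",
                                              "selection.json")))))
  unlink(rd, recursive = TRUE)
})

test_that("segmentation evaluation reproduces hand-counted toy cases", {
  a <- matrix(1L, 4, 4)
  expect_equal(evaluate_segmentation(a, a)$miou, 1)
  expect_equal(evaluate_segmentation(a, a)$pixel_accuracy, 1)
  b <- 1L - a
  expect_equal(evaluate_segmentation(a, b)$pixel_accuracy, 0)
  expect_equal(evaluate_segmentation(a, b)$miou, 0)
  ## 4x4 worked case: truth 4 fg px; prediction hits 2, adds 2 fp
  truth <- matrix(0L, 4, 4); truth[1, 1:4] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 1:2] <- 1L; pred[2, 1:2] <- 1L
  ev <- evaluate_segmentation(pred, truth)
  expect_equal(ev$pixel_accuracy, 12 / 16)
  expect_equal(ev$iou_fg, 2 / 6)
  expect_equal(ev$iou_bg, 10 / 14)
  expect_equal(ev$miou, (2 / 6 + 10 / 14) / 2)
  ## empty-union convention: all-background pair scores 1
  z <- matrix(0L, 3, 3)
  expect_equal(evaluate_segmentation(z, z)$miou, 1)
  expect_error(evaluate_segmentation(matrix(0, 2, 2), z), "differ")
})

test_that("segmentation evaluation matches per-pixel brute force on random masks", {
  set.seed(55)
  for (i in 1:300) {
    pred <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    truth <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    ev <- evaluate_segmentation(pred, truth)
    o <- seg_eval_oracle(pred, truth)
    expect_equal(ev$pixel_accuracy, o$pixel_accuracy)
    expect_equal(ev$iou_fg, o$iou_fg)
    expect_equal(ev$iou_bg, o$iou_bg)
    expect_equal(ev$miou, o$miou)
    ## accuracy is symmetric under swapping prediction and truth
    expect_equal(ev$pixel_accuracy,
                 evaluate_segmentation(truth, pred)$pixel_accuracy)
  }
})

test_that("the encoder-decoder builds, validates and trains reproducibly", {
  expect_error(segmenter_config(input_size = 30), "divisible")
  m1 <- build_segmenter(segmenter_config(input_size = 32), seed = 7)
  m2 <- build_segmenter(segmenter_config(input_size = 32), seed = 7)
  expect_identical(m1$net$layers[[1]]$W, m2$net$layers[[1]]$W)
  ds <- synth_segmentation_pairs(12, seed = 5)
  expect_error(train_segmenter(m1, ds$crops[1:3], ds$masks[1:3]), "10 training")
  expect_error(train_segmenter(m1, ds$crops, ds$masks[c(2:12, 1)][1:11]),
               "differ in length")
  ## zero-epoch training is defined and leaves the model unchanged
  t0 <- train_segmenter(m1, ds$crops, ds$masks,
                        hyperparams = list(epochs = 0, val_fraction = 0), seed = 2)
  expect_identical(t0$net$layers[[1]]$W, m1$net$layers[[1]]$W)
  pred <- predict_segmenter(t0, ds$crops[[1]])
  expect_equal(dim(pred$mask), dim(ds$masks[[1]]))
})

test_that("duplicating training pairs leaves the full-batch loss unchanged", {
  ds <- synth_segmentation_pairs(5, seed = 9)
  model <- build_segmenter(segmenter_config(input_size = 32), seed = 1)
  pb <- tasseltrack:::as_pair_batch(ds$crops, ds$masks, 32)
  out1 <- tasseltrack:::nn_forward(model$net, pb$x)$out
  l1 <- tasseltrack:::bce_pixel_loss(out1, pb$y)$loss
  xd <- array(c(pb$x, pb$x), c(32, 32, 3, 10))
  yd <- array(c(pb$y, pb$y), c(32, 32, 1, 10))
  out2 <- tasseltrack:::nn_forward(model$net, xd)$out
  l2 <- tasseltrack:::bce_pixel_loss(out2, yd)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})
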