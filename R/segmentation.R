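## Tassel segmentation: binary masks from RGB crops.
##
## Four classical segmenters (Otsu on grey, fixed-channel thresholds in RGB,
## HSV and LAB colour spaces), a consensus-annotation workflow that selects
## the best candidate against a reference (or emits candidates for human
## review), a small trainable encoder-decoder, and pixel-accuracy / mIOU
## evaluation.

## configured (channel, cutoff, polarity) triples for the colour-space
## thresholds; the tassel silhouette is dark against bright sky, so the
## defaults select the dark/low side of each channel
default_seg_options <- function() {
  list(rgb = list(channel = "red", cutoff = 0.45, below = TRUE),
       hsv = list(channel = "v", cutoff = 0.55, below = TRUE),
       lab = list(channel = "L", cutoff = 55, below = TRUE))
}

#' Classical segmentation of an RGB crop
#'
#' Methods: `otsu` applies the global threshold maximizing between-class
#' variance on the grey image (darker side = tassel foreground); `rgb`,
#' `hsv`, `lab` threshold one configured channel in that colour space.
#'
#' @param crop RGB array `H x W x 3`.
#' @param method one of `"otsu"`, `"rgb"`, `"hsv"`, `"lab"`.
#' @param options per-method `(channel, cutoff, below)` settings; see
#'   `default_seg_options()` in the sources for the defaults.
#' @return object of class `mask_candidate`: `method`, binary `mask`, and an
#'   optional quality `score`.
#' @export
segment_classical <- function(crop, method = c("otsu", "rgb", "hsv", "lab"),
                              options = default_seg_options()) {
  method <- match.arg(method)
  if (length(dim(crop)) != 3L) stopf("segment_classical() expects an RGB crop")
  h <- dim(crop)[1]; w <- dim(crop)[2]
  if (method == "otsu") {
    g <- to_gray(crop)
    if (max(g) - min(g) < 1e-6) {
      warnf("constant-intensity crop; otsu returns all-background")
      mask <- matrix(0L, h, w)
    } else {
      thr <- EBImage::otsu(g, range = c(0, 1), levels = 256)
      mask <- matrix(as.integer(g < thr), h, w)
    }
  } else {
    opt <- options[[method]]
    ch <- switch(method,
      rgb = crop[, , match(opt$channel, c("red", "green", "blue"))],
      hsv = {
        m <- grDevices::rgb2hsv(matrix(aperm(crop, c(3, 1, 2)), nrow = 3), maxColorValue = 1)
        matrix(m[match(opt$channel, c("h", "s", "v")), ], h, w)
      },
      lab = {
        m <- grDevices::convertColor(matrix(crop, ncol = 3), from = "sRGB", to = "Lab")
        matrix(m[, match(opt$channel, c("L", "a", "b"))], h, w)
      })
    mask <- if (isTRUE(opt$below)) matrix(as.integer(ch < opt$cutoff), h, w)
            else matrix(as.integer(ch > opt$cutoff), h, w)
  }
  structure(list(method = method, mask = mask, score = NULL),
            class = "mask_candidate")
}

## foreground IOU of two binary masks (empty union -> 1)
fg_iou <- function(a, b) {
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0L) 1 else inter / uni
}

#' Consensus annotation: select the best classical mask
#'
#' With a reference mask (synthetic ground truth), all four classical
#' candidates are scored by foreground IOU and the argmax is selected; if
#' even the best candidate scores below `reject_threshold`, all candidates
#' are rejected (the crop is discarded from the annotation set). Without a
#' reference, the crop and the four candidate masks are written to a review
#' directory for human selection, recorded in a `selection.json` sidecar.
#'
#' @param crop RGB crop.
#' @param reference_mask optional binary reference mask.
#' @param reject_threshold minimum acceptable foreground IOU (default 0.5).
#' @param review_dir directory for the human-review layout (no-reference mode).
#' @param options classical segmenter options.
#' @return list with `selected` (a `mask_candidate` or `NULL`), `scores`
#'   (named IOUs, reference mode), `rejected` flag and `review_dir`.
#' @export
consensus_annotate <- function(crop, reference_mask = NULL, reject_threshold = 0.5,
                               review_dir = NULL, options = default_seg_options()) {
  methods <- c("otsu", "rgb", "hsv", "lab")
  cands <- lapply(methods, function(m)
    suppressWarnings(segment_classical(crop, m, options)))
  names(cands) <- methods
  if (is.null(reference_mask)) {
    if (is.null(review_dir)) stopf("need a reference_mask or a review_dir")
    dir.create(review_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(crop, file.path(review_dir, "crop.png"))
    for (m in methods) write_mask(cands[[m]]$mask, file.path(review_dir, paste0(m, ".png")))
    jsonlite::write_json(list(selection = NULL, candidates = methods),
                         file.path(review_dir, "selection.json"),
                         auto_unbox = TRUE, null = "null")
    return(list(selected = NULL, scores = NULL, rejected = NA, review_dir = review_dir))
  }
  if (!all(dim(reference_mask) == dim(crop)[1:2])) stopf("reference mask size mismatch")
  scores <- vapply(cands, function(cd) fg_iou(cd$mask, reference_mask), 0)
  best <- which.max(scores)
  if (scores[best] < reject_threshold)
    return(list(selected = NULL, scores = scores, rejected = TRUE, review_dir = NULL))
  sel <- cands[[best]]
  sel$score <- unname(scores[best])
  list(selected = sel, scores = scores, rejected = FALSE, review_dir = NULL)
}

#' Evaluate a predicted mask against a reference
#'
#' Pixel accuracy is the fraction of matching pixels; per-class IOU is
#' intersection over union for foreground and background separately (a class
#' with empty union contributes IOU 1, so all-background crops remain
#' scoreable); mIOU is the mean of the two class IOUs.
#'
#' @param predicted,truth binary masks of identical size.
#' @return object of class `seg_eval`: `pixel_accuracy`, `iou_fg`, `iou_bg`,
#'   `miou`.
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) stopf("mask dimensions differ")
  p <- predicted > 0; t_ <- truth > 0
  acc <- mean(p == t_)
  iou_class <- function(pp, tt) {
    uni <- sum(pp | tt)
    if (uni == 0L) 1 else sum(pp & tt) / uni
  }
  fg <- iou_class(p, t_)
  bg <- iou_class(!p, !t_)
  structure(list(pixel_accuracy = acc, iou_fg = fg, iou_bg = bg,
                 miou = (fg + bg) / 2),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("pixel accuracy %.4f  IOU(fg) %.4f  IOU(bg) %.4f  mIOU %.4f\n",
              x$pixel_accuracy, x$iou_fg, x$iou_bg, x$miou))
  invisible(x)
}

#' Encoder-decoder segmenter configuration
#'
#' A symmetric fully-convolutional model: `depth` encoder levels
#' (conv + ReLU + 2x2 max pool, channel width doubling from `base_filters`),
#' a bottleneck conv, `depth` decoder levels (nearest-neighbour upsample +
#' conv + ReLU), and a 1x1 conv with per-pixel sigmoid output.
#'
#' @param input_size square input side in pixels (divisible by `2^depth`).
#' @param depth number of down/up-sampling levels (default 2).
#' @param base_filters channels of the first encoder level (default 8).
#' @return object of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size = 64L, depth = 2L, base_filters = 8L) {
  if (input_size %% (2^depth) != 0) stopf("input_size must be divisible by 2^depth")
  if (input_size < 2^depth * 4) stopf("input too small for %d pooling levels", depth)
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters)),
            class = "segmenter_config")
}

#' Build the encoder-decoder segmenter
#' @param config a `segmenter_config`.
#' @param seed seed for weight initialization.
#' @return object of class `tassel_segmenter`.
#' @export
build_segmenter <- function(config = segmenter_config(), seed = 1L) {
  stopifnot(inherits(config, "segmenter_config"))
  layers <- list(); in_ch <- 3L; f <- config$base_filters
  widths <- f * 2^(seq_len(config$depth) - 1L)
  for (i in seq_len(config$depth)) {            # encoder
    layers <- c(layers, list(nn_conv(in_ch, widths[i], 3L,
                                     seed = substream_seed(seed, "enc", i)),
                             nn_relu(), nn_pool()))
    in_ch <- widths[i]
  }
  layers <- c(layers, list(nn_conv(in_ch, in_ch, 3L,                # bottleneck
                                   seed = substream_seed(seed, "mid")),
                           nn_relu()))
  for (i in rev(seq_len(config$depth))) {       # decoder
    out_ch <- if (i > 1L) widths[i - 1L] else f
    layers <- c(layers, list(nn_upsample(),
                             nn_conv(in_ch, out_ch, 3L,
                                     seed = substream_seed(seed, "dec", i)),
                             nn_relu()))
    in_ch <- out_ch
  }
  layers <- c(layers, list(nn_conv(in_ch, 1L, 1L, seed = substream_seed(seed, "head"))))
  structure(list(net = nn_network(layers, head = "pixel_sigmoid"),
                 config = config, seed = as.integer(seed)),
            class = "tassel_segmenter")
}

## resize crops+masks to the square model input
as_pair_batch <- function(crops, masks, size) {
  n <- length(crops)
  x <- array(0, c(size, size, 3L, n))
  y <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    if (!all(dim(crops[[i]])[1:2] == dim(masks[[i]])))
      stopf("crop/mask size mismatch in pair %d", i)
    x[, , , i] <- letterbox(crops[[i]], size, pad = 0.5)
    y[, , 1L, i] <- letterbox(matrix(as.numeric(masks[[i]] > 0), nrow(masks[[i]])),
                              size, pad = 0)
  }
  list(x = x, y = round(y))
}

#' Train the encoder-decoder segmenter
#'
#' Per-pixel binary cross-entropy loss; probability-to-mask cutoff 0.5.
#'
#' @param model a `tassel_segmenter`.
#' @param crops list of RGB crops.
#' @param masks list of binary masks matching `crops` sizes.
#' @param hyperparams list: `epochs` (30), `batch_size` (16), `lr` (1e-3),
#'   `optimizer` ("adam"), `shuffle` (TRUE), `val_fraction` (0.15),
#'   `early_stop_acc` (optional pixel accuracy for early stopping),
#'   `pos_weight` (foreground-pixel loss weight; `"auto"`, the default,
#'   uses the inverse foreground fraction of the training masks, capped
#'   at 20 — tassel silhouettes cover only a few percent of a crop and
#'   unweighted loss stalls in the all-background solution).
#' @param seed seed for split/shuffle/initial state.
#' @return the model with trained weights and `history`.
#' @export
train_segmenter <- function(model, crops, masks, hyperparams = list(), seed = 1L) {
  stopifnot(inherits(model, "tassel_segmenter"))
  if (length(crops) != length(masks)) stopf("crops and masks differ in length")
  if (length(crops) < 10L) stopf("need at least 10 training pairs")
  hp <- utils::modifyList(list(epochs = 30L, batch_size = 16L, lr = 1e-3,
                               optimizer = "adam", shuffle = TRUE,
                               val_fraction = 0.15, early_stop_acc = NULL,
                               pos_weight = "auto"),
                          hyperparams)
  pb <- as_pair_batch(crops, masks, model$config$input_size)
  n <- dim(pb$x)[4]
  if (identical(hp$pos_weight, "auto")) {
    fg <- mean(pb$y)
    hp$pos_weight <- if (fg <= 0) 1 else min(20, max(1, (1 - fg) / fg))
  }
  x_val <- NULL; y_val <- NULL
  if (hp$val_fraction > 0 && n >= 10L) {
    n_val <- max(2L, round(hp$val_fraction * n))
    vi <- with_seed(substream_seed(seed, "valsplit"), sample.int(n, n_val))
    x_val <- pb$x[, , , vi, drop = FALSE]; y_val <- pb$y[, , , vi, drop = FALSE]
    pb$x <- pb$x[, , , -vi, drop = FALSE]; pb$y <- pb$y[, , , -vi, drop = FALSE]
  }
  tr <- nn_train(model$net, pb$x, pb$y, epochs = hp$epochs,
                 batch_size = hp$batch_size, lr = hp$lr, optimizer = hp$optimizer,
                 shuffle = hp$shuffle, seed = seed,
                 x_val = x_val, y_val = y_val, early_stop_acc = hp$early_stop_acc,
                 pos_weight = hp$pos_weight)
  model$net <- tr$net
  model$history <- tr$history
  model
}

#' Apply the trained segmenter to a crop
#'
#' The crop is letterboxed to the model input, the per-pixel foreground
#' probability is predicted, and the thresholded mask is mapped back to the
#' original crop geometry.
#'
#' @param model a trained `tassel_segmenter`.
#' @param crop RGB crop.
#' @param cutoff probability cutoff (default 0.5).
#' @return a `mask_candidate` with `method = "model"`.
#' @export
predict_segmenter <- function(model, crop, cutoff = 0.5) {
  stopifnot(inherits(model, "tassel_segmenter"))
  size <- model$config$input_size
  h <- dim(crop)[1]; w <- dim(crop)[2]
  x <- array(letterbox(crop, size, pad = 0.5), c(size, size, 3L, 1L))
  logits <- nn_forward(model$net, x)$out
  p <- 1 / (1 + exp(-logits[, , 1L, 1L]))
  ## undo the letterbox: crop the content window, then resize back
  s <- min(size / h, size / w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  y0 <- (size - nh) %/% 2L; x0 <- (size - nw) %/% 2L
  pc <- p[y0 + seq_len(nh), x0 + seq_len(nw), drop = FALSE]
  mask <- matrix(as.integer(resize_nearest(pc, h, w) > cutoff), h, w)
  structure(list(method = "model", mask = mask, score = NULL),
            class = "mask_candidate")
}
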