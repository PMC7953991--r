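## CNN tassel/non-tassel classifier: a stack of conv blocks (28 3x3 filters
## each, ReLU, 2x2 max pooling), flatten, dropout, and a 2-way softmax.
## Crops are letterboxed (aspect-preserving resize + padding) to the
## configured input size.

#' Classifier configuration
#'
#' @param input_size `c(H, W)` input size in pixels (both >= 16).
#' @param n_conv_blocks number of conv+ReLU+maxpool blocks (default 3).
#' @param filters filters per convolutional layer (default 28).
#' @param kernel convolution kernel side (default 3).
#' @param dropout dropout rate before the dense layer, in `[0, 1)`.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(input_size = c(64L, 64L), n_conv_blocks = 3L,
                              filters = 28L, kernel = 3L, dropout = 0.25) {
  if (any(input_size < 16)) stopf("input dimensions must be >= 16")
  if (filters < 1) stopf("'filters' must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("'dropout' must lie in [0, 1)")
  h <- input_size[1]; w <- input_size[2]
  for (i in seq_len(n_conv_blocks)) { h <- h %/% 2L; w <- w %/% 2L }
  if (h < 1 || w < 1)
    stopf("input collapses below 1 pixel after %d pooling stages", n_conv_blocks)
  structure(list(input_size = as.integer(input_size),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 dropout = dropout, final_hw = c(h, w)),
            class = "classifier_config")
}

#' Build the tassel/non-tassel classifier
#'
#' The model maps `(H, W, 3)` crops to two normalized class scores summing
#' to one. Two builds from the same configuration and seed have identical
#' initial parameters; the parameter count is a pure function of the
#' configuration.
#'
#' @param config a `classifier_config`.
#' @param seed integer seed for weight initialization.
#' @return object of class `tassel_classifier`.
#' @export
build_classifier <- function(config = classifier_config(), seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  layers <- list()
  in_ch <- 3L
  for (i in seq_len(config$n_conv_blocks)) {
    layers <- c(layers, list(nn_conv(in_ch, config$filters, config$kernel,
                                     seed = substream_seed(seed, "conv", i)),
                             nn_relu(), nn_pool()))
    in_ch <- config$filters
  }
  d <- prod(config$final_hw) * config$filters
  layers <- c(layers, list(nn_dropout(config$dropout),
                           nn_dense(d, 2L, seed = substream_seed(seed, "dense"))))
  structure(list(net = nn_network(layers, head = "softmax"),
                 config = config, seed = as.integer(seed),
                 classes = c("nontassel", "tassel")),
            class = "tassel_classifier")
}

## crops: list of HxWx3 arrays or an (H,W,3,N) array -> letterboxed batch
as_crop_batch <- function(crops, size) {
  if (is.array(crops) && length(dim(crops)) == 4L) {
    if (all(dim(crops)[1:2] == size)) return(crops)
    crops <- lapply(seq_len(dim(crops)[4]), function(i) crops[, , , i])
  }
  if (is.array(crops) && length(dim(crops)) == 3L) crops <- list(crops)
  n <- length(crops)
  x <- array(0, c(size[1], size[2], 3L, n))
  for (i in seq_len(n)) x[, , , i] <- letterbox(crops[[i]], size[1], pad = 0.5)
  x
}

#' Train the classifier
#'
#' @param model a `tassel_classifier`.
#' @param crops list of RGB crops (any sizes; letterboxed to the configured
#'   input) or an `(H, W, 3, N)` array.
#' @param labels binary labels: 1/"tassel" = tassel, 0/"nontassel" = not.
#' @param hyperparams list: `epochs` (default 20), `batch_size` (32),
#'   `lr` (1e-3), `optimizer` ("adam" or "sgd"), `shuffle` (TRUE),
#'   `val_fraction` (0.15), `early_stop_acc` (optional accuracy at which
#'   training stops early).
#' @param seed seed controlling the split, shuffling and dropout.
#' @return the model with trained weights and a per-epoch `history`
#'   data.frame (`epoch`, `loss`, `acc`, `val_acc`).
#' @export
train_classifier <- function(model, crops, labels, hyperparams = list(), seed = 1L) {
  stopifnot(inherits(model, "tassel_classifier"))
  hp <- utils::modifyList(list(epochs = 20L, batch_size = 32L, lr = 1e-3,
                               optimizer = "adam", shuffle = TRUE,
                               val_fraction = 0.15, early_stop_acc = NULL),
                          hyperparams)
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "tassel") else as.integer(labels)
  if (length(unique(y)) < 2L)
    stopf("training requires both classes; got a single-class dataset")
  if (min(table(y)) < 2L) stopf("need at least 2 examples per class")
  x <- as_crop_batch(crops, model$config$input_size)
  if (dim(x)[4] != length(y)) stopf("number of crops and labels differ")
  n <- length(y)
  x_val <- NULL; y_val <- NULL
  if (hp$val_fraction > 0 && n >= 10L) {
    n_val <- max(2L, round(hp$val_fraction * n))
    vi <- with_seed(substream_seed(seed, "valsplit"), sample.int(n, n_val))
    x_val <- x[, , , vi, drop = FALSE]; y_val <- y[vi]
    x <- x[, , , -vi, drop = FALSE]; y <- y[-vi]
  }
  tr <- nn_train(model$net, x, y, epochs = hp$epochs, batch_size = hp$batch_size,
                 lr = hp$lr, optimizer = hp$optimizer, shuffle = hp$shuffle,
                 seed = seed, x_val = x_val, y_val = y_val,
                 early_stop_acc = hp$early_stop_acc)
  model$net <- tr$net
  model$history <- tr$history
  model
}

#' Classify box crops of frames
#'
#' @param model a trained `tassel_classifier`.
#' @param frames list of RGB frames, indexed by 0-based frame index + 1, or a
#'   single frame.
#' @param boxes box data.frame whose `frame` column indexes `frames`.
#' @return data.frame: the boxes plus `label` ("tassel"/"nontassel") and
#'   `tassel_score` (softmax probability of the tassel class).
#' @export
classify_crops <- function(model, frames, boxes) {
  stopifnot(inherits(model, "tassel_classifier"))
  if (is.array(frames)) frames <- list(frames)
  if (nrow(boxes) == 0L)
    return(cbind(boxes, data.frame(label = character(0), tassel_score = numeric(0))))
  crops <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    fi <- if (is.na(boxes$frame[i])) 1L else boxes$frame[i] + 1L
    if (fi < 1L || fi > length(frames)) stopf("box %d references missing frame %s", i, boxes$frame[i])
    fr <- frames[[fi]]
    if (boxes$x_min[i] < 0 || boxes$y_min[i] < 0 ||
        boxes$x_max[i] > dim(fr)[2] || boxes$y_max[i] > dim(fr)[1])
      stopf("box %d lies outside frame %s", i, boxes$frame[i])
    crops[[i]] <- crop_box(fr, boxes[i, ])
  }
  x <- as_crop_batch(crops, model$config$input_size)
  out <- nn_forward(model$net, x)$out
  z <- sweep(out, 2L, apply(out, 2L, max), "-")
  p <- sweep(exp(z), 2L, colSums(exp(z)), "/")
  boxes$label <- ifelse(p[2L, ] >= 0.5, "tassel", "nontassel")
  boxes$tassel_score <- p[2L, ]
  boxes
}

#' Remove boxes labelled non-tassel
#'
#' @param boxes box data.frame.
#' @param labels character labels parallel to `boxes` (or taken from a
#'   `label` column). Idempotent.
#' @return list with `kept` (tassel boxes) and `removed` (logged with scores).
#' @export
filter_false_positives <- function(boxes, labels = boxes$label) {
  if (nrow(boxes) == 0L) return(list(kept = boxes, removed = boxes))
  keep <- labels == "tassel"
  list(kept = boxes[keep, , drop = FALSE], removed = boxes[!keep, , drop = FALSE])
}

#' Classical dark-fraction crop classifier
#'
#' A deterministic rule-based backend for the classification stage: a crop is
#' labelled a tassel when the fraction of markedly-dark pixels (tassel
#' silhouette against sky) exceeds `min_dark_frac`. Useful when no trained
#' checkpoint is available; the CNN backend replaces it via configuration.
#'
#' @param frames list of RGB frames (see [classify_crops()]).
#' @param boxes box data.frame.
#' @param dark_threshold grey level below which a pixel counts as dark.
#' @param min_dark_frac minimum dark-pixel fraction for a tassel label.
#' @return boxes with `label` and `tassel_score` (the dark fraction).
#' @export
rule_classify_crops <- function(frames, boxes, dark_threshold = 0.45,
                                min_dark_frac = 0.05) {
  if (is.array(frames)) frames <- list(frames)
  if (nrow(boxes) == 0L)
    return(cbind(boxes, data.frame(label = character(0), tassel_score = numeric(0))))
  score <- numeric(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    fi <- if (is.na(boxes$frame[i])) 1L else boxes$frame[i] + 1L
    g <- to_gray(crop_box(frames[[fi]], boxes[i, ]))
    score[i] <- mean(g < dark_threshold)
  }
  boxes$label <- ifelse(score >= min_dark_frac, "tassel", "nontassel")
  boxes$tassel_score <- score
  boxes
}

#' Save / load a classifier checkpoint
#'
#' Weights go into a single serialized file with a JSON configuration
#' sidecar (`<path>.json`).
#'
#' @param model a `tassel_classifier`.
#' @param path checkpoint path.
#' @return the path (`save_classifier`) or the restored model
#'   (`load_classifier`).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "tassel_classifier"))
  m
}
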