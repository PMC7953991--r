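## Tassel detection: bounding boxes, annotation quality control, a classical
## reference detector for sky-backed scenes, a file-import adapter for boxes
## produced by any external detector, and IOU/mAP evaluation.
##
## Boxes are rows of a data.frame with columns
##   x_min, y_min, x_max, y_max, score, frame, source
## in 0-based half-open pixel coordinates: column x belongs to the box iff
## x_min <= x < x_max. Areas are continuous (width * height), which equals
## the pixel count under the half-open convention.

#' Construct a bounding-box data.frame
#'
#' @param x_min,y_min,x_max,y_max box edges (0-based, half-open); vectors are
#'   recycled to a common length.
#' @param score detection confidence in `[0, 1]` (`NA` for ground truth).
#' @param frame 0-based frame index.
#' @param source backend identifier.
#' @return data.frame of validated boxes.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max, score = NA_real_,
                         frame = NA_integer_, source = "") {
  n <- length(x_min)
  if (n == 0L)
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0), frame = integer(0),
                      source = character(0), stringsAsFactors = FALSE))
  df <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                   score = rep_len(score, n), frame = rep_len(frame, n),
                   source = rep_len(source, n), stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

validate_boxes <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$x_min >= df$x_max) || any(df$y_min >= df$y_max))
    stopf("degenerate box: require x_min < x_max and y_min < y_max")
  ok_score <- is.na(df$score) | (df$score >= 0 & df$score <= 1)
  if (!all(ok_score)) stopf("box scores must lie in [0,1] (or be NA)")
  invisible(df)
}

box_area <- function(df) (df$x_max - df$x_min) * (df$y_max - df$y_min)

#' Intersection over union of two boxes
#'
#' The overlap criterion used to judge a predicted box against an annotated
#' one: area of overlap divided by area of union. Predictions with IOU above
#' 0.5 count as true in the detection evaluation.
#'
#' @param a,b single boxes (one-row data.frames or lists with
#'   `x_min`/`y_min`/`x_max`/`y_max`).
#' @return ratio in `[0, 1]`; symmetric, 0 iff disjoint, 1 iff identical.
#' @export
iou <- function(a, b) {
  if ((a$x_max - a$x_min) <= 0 || (a$y_max - a$y_min) <= 0 ||
      (b$x_max - b$x_min) <= 0 || (b$y_max - b$y_min) <= 0)
    stopf("degenerate (zero-area) box")
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  inter <- max(0, iw) * max(0, ih)
  areas <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (areas - inter)
}

#' Quality-control rule for annotated/detected boxes
#'
#' Mirrors annotation quality control: removal of very small boxes by pixel
#' area plus a check that width and height lie within a priori bounds, and a
#' cap on how many boxes per frame survive (largest area first).
#'
#' @param min_area minimum box area in pixels^2.
#' @param width_range,height_range `c(min, max)` bounds in pixels.
#' @param max_boxes_kept cap on surviving boxes per frame.
#' @return object of class `qc_rule`.
#' @export
qc_rule <- function(min_area = 1, width_range = c(1, Inf),
                    height_range = c(1, Inf), max_boxes_kept = Inf) {
  if (min_area < 1) stopf("'min_area' must be >= 1")
  if (width_range[1] > width_range[2] || height_range[1] > height_range[2])
    stopf("bounds must satisfy min <= max")
  structure(list(min_area = min_area, width_range = width_range,
                 height_range = height_range, max_boxes_kept = max_boxes_kept),
            class = "qc_rule")
}

#' Default QC rule as fractions of the image size
#'
#' The exact a priori bounds used for field annotations are configuration;
#' these defaults scale with the frame: minimum area `0.0004 * H * W`, width
#' and height within `[0.01, 0.9]` of the image dimensions, at most two boxes
#' kept (two tassels per camera).
#'
#' @param height,width frame size in pixels.
#' @param max_boxes_kept cap on surviving boxes.
#' @return a `qc_rule`.
#' @export
qc_rule_default <- function(height, width, max_boxes_kept = 2L) {
  qc_rule(min_area = 0.0004 * height * width,
          width_range = c(0.01, 0.9) * width,
          height_range = c(0.01, 0.9) * height,
          max_boxes_kept = max_boxes_kept)
}

#' Filter boxes by a QC rule
#'
#' Kept boxes satisfy all bounds; at most `max_boxes_kept` survive, largest
#' area first, ties broken by smaller `x_min`. Applied per frame when the
#' boxes span several frames. Idempotent.
#'
#' @param boxes box data.frame.
#' @param rule a `qc_rule`.
#' @return list with `kept` and `discarded` data.frames.
#' @export
qc_filter <- function(boxes, rule) {
  stopifnot(inherits(rule, "qc_rule"))
  if (nrow(boxes) == 0L) return(list(kept = boxes, discarded = boxes))
  w <- boxes$x_max - boxes$x_min
  h <- boxes$y_max - boxes$y_min
  ok <- (w * h) >= rule$min_area &
    w >= rule$width_range[1] & w <= rule$width_range[2] &
    h >= rule$height_range[1] & h <= rule$height_range[2]
  kept <- boxes[ok, , drop = FALSE]
  disc <- boxes[!ok, , drop = FALSE]
  if (is.finite(rule$max_boxes_kept) && nrow(kept) > 0L) {
    pieces <- split(kept, if (all(is.na(kept$frame))) rep(1L, nrow(kept)) else kept$frame)
    trimmed <- lapply(pieces, function(p) {
      p <- p[order(-box_area(p), p$x_min), , drop = FALSE]
      utils::head(p, rule$max_boxes_kept)
    })
    extra <- lapply(pieces, function(p) {
      p <- p[order(-box_area(p), p$x_min), , drop = FALSE]
      p[-seq_len(min(nrow(p), rule$max_boxes_kept)), , drop = FALSE]
    })
    kept <- do.call(rbind, c(trimmed, list(make.row.names = FALSE)))
    disc <- do.call(rbind, c(list(disc), extra, list(make.row.names = FALSE)))
  }
  rownames(kept) <- rownames(disc) <- NULL
  list(kept = kept, discarded = disc)
}

#' Classical reference detector for sky-backed frames
#'
#' A threshold-and-label detector that stands in for a trained detector on
#' synthetic scenes (bright, near-uniform sky background): the grey image is
#' split by Otsu's threshold, components markedly darker than the sky are
#' labelled, and the two largest yield boxes. Scores are each component's
#' share of the total foreground.
#'
#' @param image RGB array `H x W x 3`.
#' @param frame frame index recorded on the boxes.
#' @param min_area_frac smallest component kept, as a fraction of the frame.
#' @param min_contrast minimum grey-level gap between a component and the sky.
#' @param max_boxes maximum number of boxes returned.
#' @return box data.frame (possibly empty).
#' @export
reference_detect <- function(image, frame = NA_integer_, min_area_frac = 5e-4,
                             min_contrast = 0.2, max_boxes = 2L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("reference_detect() expects an RGB image")
  g <- to_gray(image)
  thr <- EBImage::otsu(g, range = c(0, 1), levels = 256)
  fg <- g < thr
  empty <- bounding_box(numeric(0), numeric(0), numeric(0), numeric(0))
  if (!any(fg) || mean(fg) > 0.5) return(empty)
  bg_mean <- mean(g[!fg])
  lab <- EBImage::bwlabel(matrix(as.integer(fg), nrow(g), ncol(g)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_frac * length(g))
  keep <- keep[vapply(keep, function(k) bg_mean - mean(g[lab == k]) >= min_contrast, TRUE)]
  if (length(keep) == 0L) return(empty)
  keep <- keep[order(-sizes[keep])]
  keep <- utils::head(keep, max_boxes)
  total <- sum(sizes[keep])
  boxes <- lapply(keep, function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    bounding_box(x_min = min(px[, 2]) - 1L, y_min = min(px[, 1]) - 1L,
                 x_max = max(px[, 2]), y_max = max(px[, 1]),
                 score = sizes[k] / total, frame = frame, source = "reference")
  })
  do.call(rbind, boxes)
}

#' Write boxes to the box CSV schema
#'
#' Schema: `frame_index,filename,x_min,y_min,x_max,y_max,score,label`, one
#' row per box, header mandatory.
#'
#' @param boxes box data.frame.
#' @param path output CSV path.
#' @param filenames optional per-box frame filenames.
#' @param label class label column value.
#' @export
write_boxes_csv <- function(boxes, path, filenames = "", label = "tassel") {
  n <- nrow(boxes)
  df <- data.frame(frame_index = boxes$frame,
                   filename = rep_len(filenames, n),
                   x_min = boxes$x_min, y_min = boxes$y_min,
                   x_max = boxes$x_max, y_max = boxes$y_max,
                   score = boxes$score, label = rep_len(label, n))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load externally produced boxes from CSV
#'
#' Adapter for boxes produced by any external detector. Invalid rows
#' (degenerate geometry, out-of-range scores, non-numeric fields) are
#' collected into an error report with their line numbers rather than
#' aborting the load.
#'
#' @param path CSV path following the box schema (see [write_boxes_csv()]).
#' @return list with `boxes` (validated data.frame) and `errors`
#'   (data.frame of `line`, `reason`).
#' @export
load_external_boxes <- function(path) {
  if (!file.exists(path)) stopf("box CSV not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "x_min", "y_min", "x_max", "y_max", "score")
  if (!all(need %in% names(raw)))
    stopf("box CSV must contain columns: %s", paste(need, collapse = ", "))
  errors <- data.frame(line = integer(0), reason = character(0))
  ok <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    reason <- NULL
    nums <- suppressWarnings(vapply(r[need], as.numeric, 0))
    if (any(is.na(nums[c("x_min", "y_min", "x_max", "y_max")])))
      reason <- "non-numeric coordinates"
    else if (nums["x_max"] <= nums["x_min"] || nums["y_max"] <= nums["y_min"])
      reason <- "degenerate box (x_max <= x_min or y_max <= y_min)"
    else if (!is.na(nums["score"]) && (nums["score"] < 0 || nums["score"] > 1))
      reason <- "score outside [0,1]"
    if (!is.null(reason)) {
      ok[i] <- FALSE
      errors <- rbind(errors, data.frame(line = i + 1L, reason = reason))
    }
  }
  good <- raw[ok, , drop = FALSE]
  boxes <- if (nrow(good) == 0L)
    bounding_box(numeric(0), numeric(0), numeric(0), numeric(0))
  else bounding_box(as.numeric(good$x_min), as.numeric(good$y_min),
                    as.numeric(good$x_max), as.numeric(good$y_max),
                    score = as.numeric(good$score),
                    frame = as.integer(good$frame_index), source = "external")
  list(boxes = boxes, errors = errors)
}

#' Evaluate detections against ground truth (IOU matching, AP/mAP)
#'
#' Predictions are matched greedily in descending score order; each
#' prediction takes the unmatched ground-truth box of the same frame with
#' the highest IOU, and counts true only if that IOU exceeds the threshold
#' (default 0.5). Average precision is the area under the interpolated
#' precision envelope over all recall points (`interpolation = "all"`) or
#' the 11-point convention. With a single class, mAP equals AP.
#'
#' @param predictions box data.frame with scores.
#' @param ground_truth box data.frame (scores ignored).
#' @param iou_threshold match threshold, strictly inside (0, 1).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return object of class `detection_eval`: match table, PR points, `ap`,
#'   `map`, and TP/FP/FN counts.
#' @export
evaluate_detections <- function(predictions, ground_truth, iou_threshold = 0.5,
                                interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (!is_number(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1)
    stopf("'iou_threshold' must lie strictly inside (0, 1)")
  n_gt <- nrow(ground_truth)
  if (nrow(predictions) > 0L && all(is.na(predictions$score)))
    stopf("predictions must carry scores")
  ord <- if (nrow(predictions) > 0L) order(-predictions$score) else integer(0)
  gt_used <- rep(FALSE, n_gt)
  tp <- fp <- numeric(length(ord))
  match_gt <- rep(NA_integer_, length(ord))
  for (j in seq_along(ord)) {
    p <- predictions[ord[j], ]
    cand <- which(!gt_used &
                    (is.na(ground_truth$frame) | is.na(p$frame) |
                       ground_truth$frame == p$frame))
    best <- 0; best_i <- NA_integer_
    for (i in cand) {
      v <- iou(p, ground_truth[i, ])
      if (v > best) { best <- v; best_i <- i }
    }
    if (!is.na(best_i) && best > iou_threshold) {
      tp[j] <- 1; gt_used[best_i] <- TRUE; match_gt[j] <- best_i
    } else fp[j] <- 1
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  precision <- if (length(ord)) ctp / (ctp + cfp) else numeric(0)
  recall <- if (length(ord)) { if (n_gt > 0) ctp / n_gt else rep(0, length(ord)) } else numeric(0)
  ap <- average_precision(precision, recall, interpolation)
  structure(list(
    matches = data.frame(rank = seq_along(ord),
                         pred_row = ord,
                         score = predictions$score[ord],
                         tp = as.logical(tp), matched_gt = match_gt),
    precision = precision, recall = recall,
    ap = ap, map = ap, iou_threshold = iou_threshold,
    n_tp = sum(tp), n_fp = sum(fp), n_fn = n_gt - sum(tp)),
    class = "detection_eval")
}

## AP from ranked precision/recall points
average_precision <- function(precision, recall, interpolation = "all") {
  if (length(recall) == 0L || max(recall) == 0) return(0)
  ## interpolated precision: max precision at any recall >= r
  r <- c(0, recall); p <- c(0, precision)
  p_interp <- rev(cummax(rev(p)))
  if (interpolation == "11point") {
    grid <- seq(0, 1, by = 0.1)
    pr <- vapply(grid, function(g) {
      idx <- which(r >= g)
      if (length(idx) == 0L) 0 else max(p[idx[1]:length(p)])
    }, 0)
    return(mean(pr))
  }
  sum(diff(r) * p_interp[-1])
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IOU > %.2f): AP = %.4f, mAP = %.4f\n",
              x$iou_threshold, x$ap, x$map))
  cat(sprintf("  TP = %d, FP = %d, FN = %d\n", x$n_tp, x$n_fp, x$n_fn))
  invisible(x)
}

#' Write a detection evaluation report as JSON
#' @param eval a `detection_eval`.
#' @param path output JSON path.
#' @export
write_detection_report <- function(eval, path) {
  jsonlite::write_json(
    list(summary = list(AP = eval$ap, mAP = eval$map, n_tp = eval$n_tp,
                        n_fp = eval$n_fp, n_fn = eval$n_fn,
                        iou_threshold = eval$iou_threshold),
         matches = eval$matches),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
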