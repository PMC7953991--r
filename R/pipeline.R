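## End-to-end orchestration: detect -> classify -> track -> segment ->
## analyze, with per-stage file artifacts, content-hash caching and a JSON
## run report. Stage artifacts are files (box CSVs, track CSVs, mask PNGs,
## surface CSVs, summary JSONs) so any stage can be swapped for an external
## tool's output — e.g. boxes from a trained detector slot in via the box
## CSV schema.

#' Pipeline configuration
#'
#' @param input_dir sequence directory (manifest + frames, e.g. from
#'   [generate_sequence()]).
#' @param output_dir output root; stage subdirectories are created inside.
#' @param seed global seed propagated to all stochastic stages.
#' @param stages character vector of enabled stages, a subset of
#'   `c("detect", "classify", "track", "segment", "analyze")`.
#' @param detection list: `backend` ("reference" or "external"),
#'   `external_csv` (box CSV path for the external backend), `qc` (apply the
#'   default QC rule), `score_threshold` (minimum detector score kept;
#'   deliberately low because classification does the real screening).
#' @param classification list: `backend` ("rule", "cnn" or "none"),
#'   `model_path` (classifier checkpoint for "cnn"), `dark_threshold`,
#'   `min_dark_frac` (rule backend settings).
#' @param tracking list: `padding` (crop padding in pixels).
#' @param segmentation list: `method` ("otsu", "rgb", "hsv", "lab" or
#'   "model"), `model_path` (segmenter checkpoint for "model").
#' @param analysis list: `baseline_frames` (default two thirds of a capture
#'   day), `swell_threshold`, `window`, `z_cutoff`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1L,
                            stages = c("detect", "classify", "track",
                                       "segment", "analyze"),
                            detection = list(), classification = list(),
                            tracking = list(), segmentation = list(),
                            analysis = list()) {
  structure(list(
    input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
    stages = stages,
    detection = utils::modifyList(list(backend = "reference", external_csv = NULL,
                                       qc = TRUE, score_threshold = 0.05),
                                  detection),
    classification = utils::modifyList(list(backend = "rule", model_path = NULL,
                                            dark_threshold = 0.45,
                                            min_dark_frac = 0.05),
                                       classification),
    tracking = utils::modifyList(list(padding = 6), tracking),
    segmentation = utils::modifyList(list(method = "otsu", model_path = NULL),
                                     segmentation),
    analysis = utils::modifyList(list(baseline_frames = NULL, swell_threshold = 0.5,
                                      window = 9L, z_cutoff = 3.5),
                                 analysis)),
    class = "pipeline_config")
}

## md5 of a set of files plus a parameter object
stage_hash <- function(files, params) {
  files <- files[file.exists(files)]
  fh <- unname(tools::md5sum(sort(files)))
  tmp <- tempfile()
  writeLines(c(fh, jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

stage_is_cached <- function(dir, hash, outputs) {
  hf <- file.path(dir, ".stage_hash")
  file.exists(hf) && identical(readLines(hf, warn = FALSE)[1], unname(hash)) &&
    all(file.exists(outputs))
}

mark_stage <- function(dir, hash) {
  writeLines(unname(hash), file.path(dir, ".stage_hash"))
}

#' Run the pipeline
#'
#' Executes the enabled stages in order, writing artifacts under
#' stage-named subdirectories of the output root. A stage is recomputed
#' only when its inputs (upstream artifact files and its own parameters)
#' changed, tracked by content hash. The run report
#' (`report.json`) records per-stage counts and all effective parameters.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) the run report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$input_dir)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  frame_paths <- file.path(config$input_dir, manifest$filename)
  frames_env <- new.env(parent = emptyenv())
  get_frame <- function(i) {   # lazy, cached frame loader (0-based index)
    k <- as.character(i)
    if (is.null(frames_env[[k]]))
      frames_env[[k]] <- read_image(frame_paths[match(i, manifest$frame_index)])
    frames_env[[k]]
  }
  fpd <- infer_frames_per_day(manifest)

  ## ---- detect ----
  boxes_csv <- file.path(out, "detect", "boxes.csv")
  if ("detect" %in% config$stages) {
    ddir <- file.path(out, "detect")
    dir.create(ddir, showWarnings = FALSE)
    src <- if (config$detection$backend == "external") config$detection$external_csv
           else frame_paths
    h <- stage_hash(c(file.path(config$input_dir, "manifest.csv"), src),
                    config$detection)
    if (stage_is_cached(ddir, h, boxes_csv)) {
      report$stages$detect <- list(cached = TRUE)
    } else {
      if (config$detection$backend == "external") {
        if (is.null(config$detection$external_csv) ||
            !file.exists(config$detection$external_csv))
          stopf("stage 'detect': external backend needs an existing box CSV")
        loaded <- load_external_boxes(config$detection$external_csv)
        boxes <- loaded$boxes
      } else {
        boxes <- NULL
        for (i in manifest$frame_index) {
          b <- reference_detect(get_frame(i), frame = i)
          if (nrow(b)) boxes <- rbind(boxes, b)
        }
        boxes <- boxes %||% bounding_box(numeric(0), numeric(0), numeric(0), numeric(0))
      }
      boxes <- boxes[is.na(boxes$score) | boxes$score >= config$detection$score_threshold, ,
                     drop = FALSE]
      if (isTRUE(config$detection$qc) && nrow(boxes)) {
        fr0 <- get_frame(manifest$frame_index[1])
        boxes <- qc_filter(boxes, qc_rule_default(dim(fr0)[1], dim(fr0)[2]))$kept
      }
      write_boxes_csv(boxes, boxes_csv,
                      filenames = manifest$filename[match(boxes$frame, manifest$frame_index)])
      mark_stage(ddir, h)
      report$stages$detect <- list(cached = FALSE, n_frames = nrow(manifest),
                                   n_boxes = nrow(boxes),
                                   params = config$detection)
    }
  }

  ## ---- classify ----
  kept_csv <- file.path(out, "classify", "kept.csv")
  if ("classify" %in% config$stages) {
    if (!file.exists(boxes_csv)) stopf("stage 'classify': missing upstream artifact %s", boxes_csv)
    cdir <- file.path(out, "classify")
    dir.create(cdir, showWarnings = FALSE)
    h <- stage_hash(boxes_csv, config$classification)
    if (stage_is_cached(cdir, h, kept_csv)) {
      report$stages$classify <- list(cached = TRUE)
    } else {
      boxes <- load_external_boxes(boxes_csv)$boxes
      cl <- config$classification
      labelled <- if (nrow(boxes) == 0L || cl$backend == "none") {
        boxes$label <- rep("tassel", nrow(boxes))
        boxes$tassel_score <- rep(NA_real_, nrow(boxes))
        boxes
      } else if (cl$backend == "cnn") {
        model <- load_classifier(cl$model_path)
        frames <- lapply(seq_len(max(boxes$frame) + 1L) - 1L, get_frame)
        classify_crops(model, frames, boxes)
      } else {
        frames <- lapply(seq_len(max(boxes$frame) + 1L) - 1L, get_frame)
        rule_classify_crops(frames, boxes, cl$dark_threshold, cl$min_dark_frac)
      }
      fl <- filter_false_positives(labelled)
      write_boxes_csv(fl$kept, kept_csv)
      write_boxes_csv(fl$removed, file.path(cdir, "removed.csv"))
      mark_stage(cdir, h)
      report$stages$classify <- list(cached = FALSE, n_in = nrow(boxes),
                                     n_kept = nrow(fl$kept),
                                     n_removed = nrow(fl$removed),
                                     params = cl)
    }
  }

  ## ---- track ----
  tracks_csv <- file.path(out, "track", "tracks.csv")
  if ("track" %in% config$stages) {
    if (!file.exists(kept_csv)) stopf("stage 'track': missing upstream artifact %s", kept_csv)
    tdir <- file.path(out, "track")
    dir.create(tdir, showWarnings = FALSE)
    h <- stage_hash(kept_csv, c(config$tracking, seed = config$seed))
    if (stage_is_cached(tdir, h, tracks_csv)) {
      report$stages$track <- list(cached = TRUE)
    } else {
      boxes <- load_external_boxes(kept_csv)$boxes
      centers <- collect_centers(boxes)
      if (nrow(centers) < 2L) stopf("stage 'track': fewer than 2 box centres to cluster")
      tracks <- cluster_tracks(centers, seed = config$seed)
      write_tracks_csv(tracks, boxes, tracks_csv, all_frames = manifest$frame_index)
      mark_stage(tdir, h)
      report$stages$track <- list(
        cached = FALSE, n_points = nrow(centers),
        n_left = nrow(tracks$left$entries), n_right = nrow(tracks$right$entries),
        n_reassigned = sum(attr(tracks, "assignment")$reassigned),
        params = config$tracking)
    }
  }

  ## ---- segment ----
  crops_csv <- file.path(out, "segment", "crops.csv")
  if ("segment" %in% config$stages) {
    if (!file.exists(tracks_csv)) stopf("stage 'segment': missing upstream artifact %s", tracks_csv)
    sdir <- file.path(out, "segment")
    dir.create(file.path(sdir, "masks"), recursive = TRUE, showWarnings = FALSE)
    h <- stage_hash(c(tracks_csv, frame_paths), config$segmentation)
    if (stage_is_cached(sdir, h, crops_csv)) {
      report$stages$segment <- list(cached = TRUE)
    } else {
      tr <- utils::read.csv(tracks_csv)
      tr <- tr[tr$present_flag == 1L, , drop = FALSE]
      seg_model <- if (config$segmentation$method == "model")
        readRDS(config$segmentation$model_path) else NULL
      rows <- list(); n_masks <- 0L
      pad <- config$tracking$padding
      for (k in seq_len(nrow(tr))) {
        fr <- get_frame(tr$frame_index[k])
        hgt <- dim(fr)[1]; wdt <- dim(fr)[2]
        cb <- list(x_min = max(0, floor(tr$x_min[k] - pad)),
                   y_min = max(0, floor(tr$y_min[k] - pad)),
                   x_max = min(wdt, ceiling(tr$x_max[k] + pad)),
                   y_max = min(hgt, ceiling(tr$y_max[k] + pad)))
        crop <- crop_box(fr, cb)
        cand <- if (is.null(seg_model))
          suppressWarnings(segment_classical(crop, config$segmentation$method))
        else predict_segmenter(seg_model, crop)
        mp <- file.path("masks", sprintf("frame%04d_%s.png",
                                         tr$frame_index[k], tr$identity[k]))
        write_mask(cand$mask, file.path(sdir, mp))
        n_masks <- n_masks + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(identity = tr$identity[k], frame_index = tr$frame_index[k],
                     x_min = cb$x_min, y_min = cb$y_min,
                     x_max = cb$x_max, y_max = cb$y_max, mask = mp)
      }
      utils::write.csv(do.call(rbind, rows), crops_csv, row.names = FALSE)
      mark_stage(sdir, h)
      report$stages$segment <- list(cached = FALSE, n_masks = n_masks,
                                    params = config$segmentation)
    }
  }

  ## ---- analyze ----
  if ("analyze" %in% config$stages) {
    if (!file.exists(crops_csv)) stopf("stage 'analyze': missing upstream artifact %s", crops_csv)
    adir <- file.path(out, "analyze")
    dir.create(adir, showWarnings = FALSE)
    outputs <- file.path(adir, c("left_summary.json", "right_summary.json"))
    h <- stage_hash(c(crops_csv, file.path(config$input_dir, "manifest.csv")),
                    config$analysis)
    if (stage_is_cached(adir, h, outputs)) {
      report$stages$analyze <- list(cached = TRUE)
    } else {
      cr <- utils::read.csv(crops_csv)
      baseline <- config$analysis$baseline_frames %||% max(2L, (2L * fpd) %/% 3L)
      n_profiles <- 0L
      for (id in c("left", "right")) {
        sub <- cr[cr$identity == id, , drop = FALSE]
        profs <- list(); frames <- integer(0)
        for (k in seq_len(nrow(sub))) {
          m <- read_mask(file.path(out, "segment", sub$mask[k]))
          p <- if (any(m > 0)) try(analyze_mask(m)$profile, silent = TRUE) else NULL
          if (inherits(p, "try-error")) p <- NULL
          profs[[length(profs) + 1L]] <- p
          frames <- c(frames, sub$frame_index[k])
        }
        n_profiles <- n_profiles + sum(!vapply(profs, is.null, TRUE))
        if (length(profs) >= 2L && !all(vapply(profs, is.null, TRUE))) {
          ts <- manifest$timestamp[match(frames, manifest$frame_index)]
          surf <- align_profiles(profs, frames = frames, timestamps = ts,
                                 frames_per_day = fpd)
          surf <- remove_outliers(surf, window = config$analysis$window,
                                  z_cutoff = config$analysis$z_cutoff)
          write_surface_csv(surf, file.path(adir, paste0(id, "_surface.csv")))
          sm <- summarize_flowering(surf, baseline_frames = min(baseline, nrow(surf$widths) - 1L),
                                    swell_threshold = config$analysis$swell_threshold)
          write_summary_json(sm, file.path(adir, paste0(id, "_summary.json")))
        } else {
          write_summary_json(structure(list(detected = FALSE, reason = "no profiles"),
                                       class = "flowering_summary"),
                             file.path(adir, paste0(id, "_summary.json")))
        }
      }
      mark_stage(adir, h)
      report$stages$analyze <- list(cached = FALSE, n_profiles = n_profiles,
                                    params = c(config$analysis[
                                      !vapply(config$analysis, is.null, TRUE)],
                                      baseline_frames_effective = baseline))
    }
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

## frames per capture day from the manifest (frames sharing the first date)
infer_frames_per_day <- function(manifest) {
  dates <- substr(manifest$timestamp, 1, 10)
  max(1L, sum(dates == dates[1]))
}

#' Evaluate a pipeline run against synthetic ground truth
#'
#' Produces a single JSON evaluation: detection AP/mAP, classification
#' metrics of the kept boxes, tracking identity agreement, segmentation
#' pixel accuracy and mIOU aggregates, and anthesis recovery errors.
#' Metrics whose ground truth or artifacts are missing are marked absent.
#' The evaluation is a pure function of the files on disk.
#'
#' @param output_dir pipeline output root.
#' @param input_dir sequence directory with `ground_truth.json` and mask PNGs.
#' @param iou_threshold detection match threshold.
#' @return (invisibly) the evaluation list, also written to
#'   `evaluation.json` in `output_dir`.
#' @export
evaluate_run <- function(output_dir, input_dir, iou_threshold = 0.5) {
  gt <- read_ground_truth(input_dir)
  ev <- list()
  gt_boxes <- NULL; gt_ids <- character(0)
  frames_list <- gt$frames
  for (k in seq_along(frames_list$frame_index %||% seq_along(frames_list))) {
    fi <- if (!is.null(frames_list$frame_index)) frames_list$frame_index[k] else k - 1L
    for (id in c("left", "right")) {
      e <- if (!is.null(frames_list[[id]])) {
        lapply(frames_list[[id]], function(col) if (is.data.frame(col)) col[k, ] else col[[k]])
      } else NULL
      if (!is.null(e) && isTRUE(e$present)) {
        b <- e$box
        gt_boxes <- rbind(gt_boxes, bounding_box(b$x_min, b$y_min, b$x_max, b$y_max,
                                                 frame = fi, source = "truth"))
        gt_ids <- c(gt_ids, id)
      }
    }
  }
  boxes_csv <- file.path(output_dir, "detect", "boxes.csv")
  if (file.exists(boxes_csv) && !is.null(gt_boxes)) {
    det <- load_external_boxes(boxes_csv)$boxes
    de <- evaluate_detections(det, gt_boxes, iou_threshold)
    ev$detection <- list(AP = de$ap, mAP = de$map, n_tp = de$n_tp,
                         n_fp = de$n_fp, n_fn = de$n_fn)
  } else ev$detection <- NULL
  kept_csv <- file.path(output_dir, "classify", "kept.csv")
  if (file.exists(kept_csv) && !is.null(gt_boxes)) {
    kept <- load_external_boxes(kept_csv)$boxes
    de <- evaluate_detections(kept, gt_boxes, iou_threshold)
    cm <- confusion_matrix(tp = de$n_tp, fp = de$n_fp, fn = de$n_fn)
    ev$classification <- unclass(compute_metrics(cm))
  } else ev$classification <- NULL
  tracks_csv <- file.path(output_dir, "track", "tracks.csv")
  if (file.exists(tracks_csv) && !is.null(gt_boxes)) {
    tr <- utils::read.csv(tracks_csv)
    tr <- tr[tr$present_flag == 1L, , drop = FALSE]
    agree <- 0L; total <- 0L
    for (k in seq_len(nrow(tr))) {
      cand <- which(gt_boxes$frame == tr$frame_index[k])
      if (!length(cand)) next
      ious <- vapply(cand, function(i) iou(tr[k, ], gt_boxes[i, ]), 0)
      if (max(ious) > iou_threshold) {
        total <- total + 1L
        if (gt_ids[cand[which.max(ious)]] == tr$identity[k]) agree <- agree + 1L
      }
    }
    ev$tracking <- list(identity_agreement = if (total) agree / total else NA,
                        n_matched = total)
  } else ev$tracking <- NULL
  crops_csv <- file.path(output_dir, "segment", "crops.csv")
  if (file.exists(crops_csv) && dir.exists(file.path(input_dir, "masks"))) {
    cr <- utils::read.csv(crops_csv)
    accs <- c(); mious <- c()
    for (k in seq_len(nrow(cr))) {
      gt_mask_path <- file.path(input_dir, "masks",
                                sprintf("frame%04d_%s.png", cr$frame_index[k],
                                        cr$identity[k]))
      if (!file.exists(gt_mask_path)) next
      gm <- read_mask(gt_mask_path)
      pm <- read_mask(file.path(output_dir, "segment", cr$mask[k]))
      gmc <- gm[(cr$y_min[k] + 1):cr$y_max[k], (cr$x_min[k] + 1):cr$x_max[k]]
      se <- evaluate_segmentation(pm, gmc)
      accs <- c(accs, se$pixel_accuracy); mious <- c(mious, se$miou)
    }
    ev$segmentation <- if (length(accs))
      list(pixel_accuracy = mean(accs), miou = mean(mious), n_frames = length(accs))
    else NULL
  } else ev$segmentation <- NULL
  ev$anthesis <- list()
  for (id in c("left", "right")) {
    sp <- file.path(output_dir, "analyze", paste0(id, "_summary.json"))
    if (!file.exists(sp) || is.null(gt$anthesis[[id]])) next
    sm <- jsonlite::read_json(sp, simplifyVector = TRUE)
    tru <- gt$anthesis[[id]]
    fpd <- gt$frames_per_day %||% 72L
    spike_len <- NULL
    if (!is.null(frames_list[[id]]$spike_length))
      spike_len <- frames_list[[id]]$spike_length[!is.na(frames_list[[id]]$spike_length)][1]
    if (isTRUE(sm$detected) && !is.null(spike_len)) {
      ev$anthesis[[id]] <- list(
        onset_fraction_true = tru$onset_fraction,
        onset_fraction_rec = sm$onset_position_px / spike_len,
        onset_error = abs(sm$onset_position_px / spike_len - tru$onset_fraction),
        duration_days_true = tru$duration_frames / fpd,
        duration_days_rec = sm$duration_days,
        duration_error = abs(sm$duration_days - tru$duration_frames / fpd))
    } else ev$anthesis[[id]] <- list(detected = isTRUE(sm$detected))
  }
  jsonlite::write_json(ev, file.path(output_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(ev)
}
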