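## Temporal association of detected boxes to the two physical tassels of a
## camera: k-means (k = 2) on the box centres pooled over the whole
## sequence, identities named left/right by ascending cluster-centre x.

#' Collect box centres per frame
#'
#' Per frame, the centres of at most `max_per_frame` largest-area boxes
#' (the two tassels of interest sit closest to the camera and are the
#' biggest) contribute points `((x_min + x_max)/2, (y_min + y_max)/2)`.
#'
#' @param boxes QC'd and classified box data.frame with a `frame` column.
#' @param max_per_frame boxes retained per frame (default 2).
#' @return data.frame with `frame`, `x`, `y` and `box_row` (row index into
#'   `boxes`).
#' @export
collect_centers <- function(boxes, max_per_frame = 2L) {
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      box_row = integer(0))
  if (nrow(boxes) == 0L) return(empty)
  boxes$..row <- seq_len(nrow(boxes))
  pieces <- split(boxes, boxes$frame)
  out <- lapply(pieces, function(p) {
    p <- p[order(-box_area(p), p$x_min), , drop = FALSE]
    p <- utils::head(p, max_per_frame)
    data.frame(frame = p$frame, x = (p$x_min + p$x_max) / 2,
               y = (p$y_min + p$y_max) / 2, box_row = p$..row)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$frame, res$box_row), , drop = FALSE]
}

#' Cluster box centres into two tassel tracks
#'
#' k-means with k = 2 (10 restarts, squared Euclidean on raw pixel
#' coordinates) on all centres of the sequence. Identities are named
#' `left`/`right` by ascending cluster-centre x. If one frame contributed
#' two boxes that land in the same cluster, the box nearer the other
#' cluster's centre is reassigned so that each identity holds at most one
#' box per frame (logged via the `reassigned` column).
#'
#' @param centers data.frame from [collect_centers()] (>= 2 points).
#' @param seed seed for the k-means restarts.
#' @return list of two objects of class `tassel_track` (`identity`,
#'   `center`, `entries` data.frame), plus an `assignment` data.frame
#'   attribute mapping every input point to an identity.
#' @export
cluster_tracks <- function(centers, seed = 1L) {
  if (nrow(centers) < 2L) stopf("clustering requires at least 2 points")
  pts <- as.matrix(centers[, c("x", "y")])
  if (nrow(unique(pts)) < 2L) {
    warnf("all centres identical; both clusters collapse, returning one populated track")
    asg <- rep(1L, nrow(centers))
    cent <- rbind(colMeans(pts), c(NA, NA))
  } else {
    km <- with_seed(seed, stats::kmeans(pts, centers = 2L, nstart = 10L))
    asg <- km$cluster
    cent <- km$centers
  }
  ## left/right by ascending cluster-centre x
  ord <- order(cent[, 1])
  ident <- c("left", "right")[match(asg, ord)]
  reassigned <- rep(FALSE, nrow(centers))
  ## same-cluster collision: one box per identity per frame
  for (f in unique(centers$frame)) {
    ii <- which(centers$frame == f)
    if (length(ii) == 2L && ident[ii[1]] == ident[ii[2]]) {
      cur <- ident[ii[1]]
      other <- setdiff(c("left", "right"), cur)
      oc <- cent[ord[match(other, c("left", "right"))], ]
      d <- sqrt((pts[ii, 1] - oc[1])^2 + (pts[ii, 2] - oc[2])^2)
      move <- ii[which.min(d)]
      ident[move] <- other
      reassigned[move] <- TRUE
    }
  }
  assignment <- cbind(centers, identity = ident, reassigned = reassigned)
  tracks <- lapply(c("left", "right"), function(id) {
    e <- assignment[assignment$identity == id, , drop = FALSE]
    e <- e[order(e$frame), , drop = FALSE]
    rownames(e) <- NULL
    structure(list(identity = id,
                   center = if (nrow(e)) c(x = mean(e$x), y = mean(e$y)) else c(x = NA_real_, y = NA_real_),
                   entries = e),
              class = "tassel_track")
  })
  names(tracks) <- c("left", "right")
  attr(tracks, "assignment") <- assignment
  tracks
}

#' Crop the frames of one track
#'
#' One crop per frame in which the track has a box; boxes are padded by
#' `padding` pixels and clamped to the frame bounds. Frames without a box
#' for this identity are skipped and listed in `skipped`.
#'
#' @param frames list of RGB frames indexed by 0-based frame index + 1.
#' @param track a `tassel_track`.
#' @param boxes the box data.frame that `track$entries$box_row` indexes.
#' @param padding pixels added around each box before clamping.
#' @return list with `crops` (named by frame index), `boxes` (clamped
#'   crop geometry) and `skipped` frame indices.
#' @export
crop_track <- function(frames, track, boxes, padding = 0) {
  stopifnot(inherits(track, "tassel_track"))
  if (is.array(frames)) frames <- list(frames)
  crops <- list(); geom <- list(); skipped <- integer(0)
  all_frames <- sort(unique(boxes$frame))
  for (f in all_frames) {
    e <- track$entries[track$entries$frame == f, , drop = FALSE]
    if (nrow(e) == 0L) { skipped <- c(skipped, f); next }
    b <- boxes[e$box_row[1], ]
    fr <- frames[[f + 1L]]
    h <- dim(fr)[1]; w <- dim(fr)[2]
    cb <- list(x_min = max(0, floor(b$x_min - padding)),
               y_min = max(0, floor(b$y_min - padding)),
               x_max = min(w, ceiling(b$x_max + padding)),
               y_max = min(h, ceiling(b$y_max + padding)))
    crops[[as.character(f)]] <- crop_box(fr, cb, pad = 0)
    geom[[as.character(f)]] <- cb
  }
  list(crops = crops, boxes = geom, skipped = skipped)
}

#' Write tracks to CSV
#'
#' Schema: `identity, frame_index, x_min, y_min, x_max, y_max, present_flag`.
#'
#' @param tracks list returned by [cluster_tracks()].
#' @param boxes the underlying box data.frame.
#' @param path output CSV path.
#' @param all_frames optional vector of all frame indices (absent frames get
#'   `present_flag = 0`).
#' @export
write_tracks_csv <- function(tracks, boxes, path, all_frames = NULL) {
  if (is.null(all_frames))
    all_frames <- sort(unique(unlist(lapply(tracks, function(t) t$entries$frame))))
  rows <- list()
  for (t in tracks) {
    for (f in all_frames) {
      e <- t$entries[t$entries$frame == f, , drop = FALSE]
      if (nrow(e) > 0L) {
        b <- boxes[e$box_row[1], ]
        rows[[length(rows) + 1L]] <-
          data.frame(identity = t$identity, frame_index = f,
                     x_min = b$x_min, y_min = b$y_min,
                     x_max = b$x_max, y_max = b$y_max, present_flag = 1L)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(identity = t$identity, frame_index = f,
                     x_min = NA_real_, y_min = NA_real_,
                     x_max = NA_real_, y_max = NA_real_, present_flag = 0L)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
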