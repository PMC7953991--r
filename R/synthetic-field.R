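## Procedural time-lapse scene generator.
##
## Emulates the statistical structure of a field camera pointed north at two
## maize tassels against a bright sky: 10-minute frame cadence over daylight
## hours, wind jitter, occasional missing tassels, leaf/camera clutter, and a
## main-spike width-swelling anthesis process with controllable onset
## position, spread rates and duration. Every frame carries full ground truth
## (boxes, masks, skeleton path, branch points, width profile), so the
## generator is the oracle for every downstream stage.

#' Tassel shape specification
#'
#' Describes one procedurally grown tassel: a curved main spike with lateral
#' branches attached on its lower portion (maize tassel branches emerge from
#' the lower spike; the upper spike is the unbranched central spike whose
#' width encodes anthesis).
#'
#' @param main_spike_length spike length in pixels (base to tip along the path).
#' @param n_branches number of lateral branches (>= 0).
#' @param branch_attach_fractions fractions in (0,1) of along-path distance
#'   from the base where branches attach; strictly increasing.
#' @param branch_lengths branch lengths in pixels (recycled to `n_branches`).
#' @param base_width resting width of the main spike in pixels (odd values
#'   render exactly).
#' @param curvature dimensionless bend of the spike (horizontal deflection at
#'   the tip as a fraction of length).
#' @param seed integer seed controlling branch angles.
#' @return an object of class `tassel_spec`.
#' @export
tassel_spec <- function(main_spike_length = 140, n_branches = 4,
                        branch_attach_fractions = NULL,
                        branch_lengths = NULL,
                        base_width = 5, curvature = 0.15, seed = 1L) {
  if (!is_number(main_spike_length) || main_spike_length < 3)
    stopf("main spike shorter than 3 pixels is not a tassel")
  if (!is_number(n_branches) || n_branches < 0) stopf("'n_branches' must be >= 0")
  n_branches <- as.integer(n_branches)
  if (is.null(branch_attach_fractions))
    branch_attach_fractions <- if (n_branches > 0)
      seq(0.06, 0.20, length.out = n_branches) else numeric(0)
  if (length(branch_attach_fractions) != n_branches)
    stopf("need one attach fraction per branch")
  if (n_branches > 0) {
    if (any(branch_attach_fractions <= 0) || any(branch_attach_fractions >= 1))
      stopf("attach fractions must lie strictly inside (0,1)")
    if (is.unsorted(branch_attach_fractions, strictly = TRUE))
      stopf("attach fractions must be strictly increasing")
  }
  if (is.null(branch_lengths)) branch_lengths <- rep(0.25 * main_spike_length, n_branches)
  branch_lengths <- rep_len(branch_lengths, n_branches)
  if (n_branches > 0 && any(branch_lengths <= 0)) stopf("branch lengths must be positive")
  if (!is_number(base_width) || base_width < 1) stopf("'base_width' must be >= 1 pixel")
  structure(list(main_spike_length = main_spike_length, n_branches = n_branches,
                 branch_attach_fractions = branch_attach_fractions,
                 branch_lengths = branch_lengths, base_width = base_width,
                 curvature = curvature, seed = as.integer(seed)),
            class = "tassel_spec")
}

#' Anthesis (flowering) process model
#'
#' Flowering is rendered as a local width increase of the main spike. The
#' swollen front starts at `onset_fraction` of the spike length from the tip
#' at `start_frame` and expands as a piecewise-linear two-sided front: after
#' `e` frames it covers spike fractions
#' `[onset_fraction - up_rate * e, onset_fraction + down_rate * e]`
#' (clipped to `[0, 1]`), for `duration_frames` frames, after which the spike
#' returns to its resting width.
#'
#' @param onset_fraction fraction of spike length from the tip where swelling
#'   starts (maize anthesis typically starts about 2/3 of the way down).
#' @param up_rate,down_rate spread rates toward the tip / base, in spike
#'   fractions per frame (>= 0).
#' @param amplitude added width in pixels while swollen (> 0).
#' @param duration_frames number of frames the swelling lasts (>= 1).
#' @param start_frame 0-based frame index at which swelling begins.
#' @return an object of class `anthesis_model`.
#' @export
anthesis_model <- function(onset_fraction = 0.65, up_rate = 0.004,
                           down_rate = 0.004, amplitude = 6,
                           duration_frames = 144L, start_frame = 72L) {
  assert_prob(onset_fraction, "onset_fraction")
  if (!is_number(up_rate) || up_rate < 0 || !is_number(down_rate) || down_rate < 0)
    stopf("spread rates must be >= 0")
  if (!is_number(amplitude) || amplitude <= 0) stopf("'amplitude' must be > 0")
  if (!is_number(duration_frames) || duration_frames < 1)
    stopf("'duration_frames' must be >= 1")
  structure(list(onset_fraction = onset_fraction, up_rate = up_rate,
                 down_rate = down_rate, amplitude = amplitude,
                 duration_frames = as.integer(duration_frames),
                 start_frame = as.integer(start_frame)),
            class = "anthesis_model")
}

#' Time-lapse scene specification
#'
#' Two tassels (left and right of the frame) in front of a bright sky, imaged
#' at a fixed cadence over daylight hours across several days. With
#' `frames_per_day = 72` the manifest timestamps emulate 10-minute intervals
#' from 7 am to 7 pm.
#'
#' @param left,right `tassel_spec` for the two foreground tassels.
#' @param left_anthesis,right_anthesis `anthesis_model` per tassel.
#' @param height,width scene size in pixels.
#' @param frames_per_day frames captured per daylight window.
#' @param n_days number of capture days.
#' @param sky list: `brightness` (mean sky level), `cloud_amp` (texture
#'   contrast), `cloud_scale` (texture coarseness, cells per image).
#' @param clutter list: `n_leaves`, `leaf_size` (px), `background_tassel_prob`.
#' @param jitter list: `sigma` (per-frame wind translation sd in px),
#'   `missing_prob` (probability a tassel is absent from a frame).
#' @param seed master seed; all sub-streams derive from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(left = tassel_spec(seed = 11L),
                       right = tassel_spec(seed = 22L, curvature = -0.12),
                       left_anthesis = anthesis_model(),
                       right_anthesis = anthesis_model(onset_fraction = 0.6),
                       height = 240L, width = 320L,
                       frames_per_day = 72L, n_days = 3L,
                       sky = list(brightness = 0.82, cloud_amp = 0.06, cloud_scale = 7),
                       clutter = list(n_leaves = 2L, leaf_size = 20,
                                      background_tassel_prob = 0.1),
                       jitter = list(sigma = 2, missing_prob = 0.03),
                       seed = 1L) {
  stopifnot(inherits(left, "tassel_spec"), inherits(right, "tassel_spec"),
            inherits(left_anthesis, "anthesis_model"),
            inherits(right_anthesis, "anthesis_model"))
  if (!is_number(height) || !is_number(width) || height < 32 || width < 32)
    stopf("scene must be at least 32 x 32 pixels")
  if (!is_number(frames_per_day) || frames_per_day < 1) stopf("'frames_per_day' must be >= 1")
  if (!is_number(n_days) || n_days < 1) stopf("'n_days' must be >= 1")
  assert_prob(clutter$background_tassel_prob %||% 0, "background_tassel_prob")
  assert_prob(jitter$missing_prob %||% 0, "missing_prob")
  if ((jitter$sigma %||% 0) < 0) stopf("jitter sigma must be >= 0")
  structure(list(left = left, right = right,
                 left_anthesis = left_anthesis, right_anthesis = right_anthesis,
                 height = as.integer(height), width = as.integer(width),
                 frames_per_day = as.integer(frames_per_day),
                 n_days = as.integer(n_days),
                 sky = sky, clutter = clutter, jitter = jitter,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## ---- geometry ---------------------------------------------------------------

## Sampled centreline geometry of a tassel, in a local frame with the spike
## base at (0, 0), x rightward, y downward (tip at negative y).
tassel_geometry <- function(spec) {
  L <- spec$main_spike_length
  n <- max(8L, ceiling(2.5 * L))
  t <- seq(0, 1, length.out = n)
  px <- spec$curvature * L * t^2
  py <- -L * t
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  S <- arc[n]
  branches <- list()
  if (spec$n_branches > 0) {
    angles <- with_seed(substream_seed(spec$seed, "branch-angles"),
                        stats::runif(spec$n_branches, 25, 50) * pi / 180)
    for (j in seq_len(spec$n_branches)) {
      s_j <- spec$branch_attach_fractions[j] * S
      i_j <- which.min(abs(arc - s_j))
      side <- if (j %% 2L == 1L) 1 else -1
      ## direction: up, rotated outward by the branch angle
      dir <- c(side * sin(angles[j]), -cos(angles[j]))
      len <- spec$branch_lengths[j]
      m <- max(4L, ceiling(2.5 * len))
      u <- seq(0, 1, length.out = m)
      branches[[j]] <- list(
        x = px[i_j] + dir[1] * len * u,
        y = py[i_j] + dir[2] * len * u,
        attach = c(px[i_j], py[i_j]), attach_arc = arc[i_j],
        attach_fraction = spec$branch_attach_fractions[j])
    }
  }
  list(x = px, y = py, arc = arc, length = S, branches = branches)
}

## Spike-fraction interval (measured from the tip) covered by the swelling
## front at `frame`, or NULL if no swelling is active.
swollen_interval <- function(anthesis, frame) {
  e <- frame - anthesis$start_frame
  if (e < 0 || e >= anthesis$duration_frames) return(NULL)
  lo <- max(0, anthesis$onset_fraction - anthesis$up_rate * e)
  hi <- min(1, anthesis$onset_fraction + anthesis$down_rate * e)
  c(lo, hi)
}

#' True tip-anchored width profile of the main spike at one frame
#'
#' @param spec a `tassel_spec`.
#' @param anthesis an `anthesis_model`.
#' @param frame 0-based frame index.
#' @return data.frame with `position` (pixels from the tip, 0 = tip) and
#'   `width` (pixels).
#' @export
true_width_profile <- function(spec, anthesis, frame) {
  S <- tassel_geometry(spec)$length
  pos <- 0:floor(S - 1)
  frac <- pos / S
  w <- rep(spec$base_width, length(pos))
  iv <- swollen_interval(anthesis, frame)
  eps <- 0.5 / S   # half-pixel tolerance so a zero-spread front still covers
  if (!is.null(iv))                                    # its onset position
    w[frac >= iv[1] - eps & frac <= iv[2] + eps] <- spec$base_width + anthesis$amplitude
  data.frame(position = pos, width = w)
}

## stamp discs of given radii at real-valued centres into a H x W 0/1 matrix;
## centres closer than ~0.9 px are deduplicated per radius group since their
## discs overlap anyway
stamp_discs <- function(mask, cx, cy, r) {
  h <- nrow(mask); w <- ncol(mask)
  cx <- round(cx); cy <- round(cy)
  for (rad in unique(r)) {
    sel <- which(r == rad)
    keyu <- !duplicated(cy[sel] * (w + 2) + cx[sel])
    gx <- cx[sel][keyu]; gy <- cy[sel][keyu]
    ir <- floor(rad + 1e-9)
    off <- expand.grid(dx = -ir:ir, dy = -ir:ir)
    off <- off[off$dx^2 + off$dy^2 <= rad^2 + 1e-9, , drop = FALSE]
    if (nrow(off) == 0L) off <- data.frame(dx = 0L, dy = 0L)
    X <- outer(gx, off$dx, "+")
    Y <- outer(gy, off$dy, "+")
    ok <- X >= 0 & X < w & Y >= 0 & Y < h
    mask[Y[ok] + 1 + X[ok] * h] <- 1L   # column-major: row y+1, col x+1
  }
  mask
}

#' Render one tassel mask with ground truth
#'
#' Draws the tassel into a canvas with the spike base at `origin` (0-based
#' pixel coordinates, x rightward, y downward; the tip is rendered at smaller
#' y than the base). Swelling is rendered as a hard width step on the main
#' spike per the `anthesis_model`.
#'
#' @param spec a `tassel_spec`.
#' @param anthesis an `anthesis_model`.
#' @param frame 0-based frame index (>= 0).
#' @param canvas `c(H, W)` canvas size; if `NULL`, a tight canvas is chosen.
#' @param origin `c(x, y)` base position; if `NULL`, placed automatically.
#' @return list with `mask` (integer H x W matrix) and `truth` (box, presence,
#'   path pixels, branch points, spike length, true width profile, anthesis
#'   parameters).
#' @export
generate_tassel <- function(spec, anthesis, frame, canvas = NULL, origin = NULL) {
  stopifnot(inherits(spec, "tassel_spec"), inherits(anthesis, "anthesis_model"))
  if (frame < 0) stopf("'frame' must be >= 0")
  geo <- tassel_geometry(spec)
  S <- geo$length
  r_spike <- (spec$base_width - 1) / 2
  r_swollen <- (spec$base_width + anthesis$amplitude - 1) / 2
  r_branch <- (max(1, spec$base_width - 2) - 1) / 2
  if (is.null(canvas)) {
    allx <- c(geo$x, unlist(lapply(geo$branches, `[[`, "x")))
    ally <- c(geo$y, unlist(lapply(geo$branches, `[[`, "y")))
    m <- ceiling(r_swollen) + 3
    origin <- c(-min(allx) + m, -min(ally) + m)
    canvas <- c(ceiling(diff(range(ally))) + 2 * m + 1,
                ceiling(diff(range(allx))) + 2 * m + 1)
  }
  if (is.null(origin)) origin <- c(round(canvas[2] / 2), round(canvas[1] * 0.95))
  mask <- matrix(0L, canvas[1], canvas[2])

  iv <- swollen_interval(anthesis, frame)
  frac_from_tip <- (S - geo$arc) / S
  eps <- 0.5 / S
  swollen <- if (is.null(iv)) rep(FALSE, length(geo$x)) else
    frac_from_tip >= iv[1] - eps & frac_from_tip <= iv[2] + eps
  r <- ifelse(swollen, r_swollen, r_spike)
  mask <- stamp_discs(mask, origin[1] + geo$x, origin[2] + geo$y, r)
  for (br in geo$branches)
    mask <- stamp_discs(mask, origin[1] + br$x, origin[2] + br$y,
                        rep(r_branch, length(br$x)))

  present <- any(mask > 0)
  box <- NULL
  if (present) {
    rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
    box <- list(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
                x_max = max(cols), y_max = max(rows))
  }
  bp <- if (length(geo$branches) > 0)
    data.frame(x = origin[1] + vapply(geo$branches, function(b) b$attach[1], 0),
               y = origin[2] + vapply(geo$branches, function(b) b$attach[2], 0),
               arc_from_base = vapply(geo$branches, `[[`, 0, "attach_arc"),
               attach_fraction = vapply(geo$branches, `[[`, 0, "attach_fraction"))
  else data.frame(x = numeric(0), y = numeric(0), arc_from_base = numeric(0),
                  attach_fraction = numeric(0))
  list(mask = mask,
       truth = list(present = present, box = box,
                    base = c(x = origin[1] + geo$x[1], y = origin[2] + geo$y[1]),
                    tip = c(x = origin[1] + geo$x[length(geo$x)],
                            y = origin[2] + geo$y[length(geo$y)]),
                    path = cbind(x = origin[1] + geo$x, y = origin[2] + geo$y),
                    arc_from_base = geo$arc,
                    branch_points = bp, spike_length = S,
                    width_profile = true_width_profile(spec, anthesis, frame),
                    anthesis = unclass(anthesis)))
}

## bilinear upsample of a coarse matrix to H x W
bilinear_upsample <- function(m, H, W) {
  ry <- seq(1, nrow(m), length.out = H); rx <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(ry), nrow(m) - 1L); x0 <- pmin(floor(rx), ncol(m) - 1L)
  fy <- ry - y0; fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
  c_ <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  wa <- outer(1 - fy, 1 - fx); wb <- outer(fy, 1 - fx)
  wc <- outer(1 - fy, fx); wd <- outer(fy, fx)
  a * wa + b * wb + c_ * wc + d * wd
}

## paint an ellipse blob into an RGB image (used for leaf clutter)
paint_ellipse <- function(img, cx, cy, a, b, theta, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ext <- ceiling(max(a, b))
  xs <- max(0, floor(cx - ext)):min(w - 1, ceiling(cx + ext))
  ys <- max(0, floor(cy - ext)):min(h - 1, ceiling(cy + ext))
  if (length(xs) == 0L || length(ys) == 0L) return(img)
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (k in 1:3) {
    ch <- img[ys + 1, xs + 1, k]
    ch[inside] <- color[k]
    img[ys + 1, xs + 1, k] <- ch
  }
  img
}

#' Render one scene frame with ground truth
#'
#' Produces the RGB frame (bright sky, darker tassel foreground, optional
#' leaf/background-tassel clutter) and the per-frame ground truth: a tight
#' bounding box and binary mask per present tassel, the spike path, branch
#' points and the true width profile. With the jitter model's
#' `missing_prob`, a tassel is omitted and marked absent; a tassel rendered
#' fully outside the frame is likewise recorded absent.
#'
#' @param scene a `scene_spec`.
#' @param frame 0-based frame index.
#' @return list with `image` (`H x W x 3`) and `truth` (list with one entry
#'   per identity `left`/`right`).
#' @export
render_scene <- function(scene, frame) {
  stopifnot(inherits(scene, "scene_spec"))
  H <- scene$height; W <- scene$width
  sky_col <- c(0.80, 0.88, 1.0) * (scene$sky$brightness %||% 0.82)
  amp <- scene$sky$cloud_amp %||% 0.06
  ncell <- max(2L, round(scene$sky$cloud_scale %||% 7))
  noise <- with_seed(substream_seed(scene$seed, "sky", frame),
                     matrix(stats::rnorm(ncell * (ncell + 2), 0, 1), ncell, ncell + 2))
  cloud <- bilinear_upsample(noise, H, W) * amp
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- pmin(1, pmax(0, sky_col[k] * (1 + cloud)))

  ## clutter behind the foreground tassels
  cl <- scene$clutter
  n_leaves <- cl$n_leaves %||% 0L
  if (n_leaves > 0) {
    leaf_rng <- with_seed(substream_seed(scene$seed, "clutter", frame), {
      data.frame(cx = stats::runif(n_leaves, 0, W),
                 cy = stats::runif(n_leaves, 0.55 * H, H),
                 a = stats::runif(n_leaves, 0.6, 1.3) * (cl$leaf_size %||% 20),
                 b = stats::runif(n_leaves, 0.25, 0.5) * (cl$leaf_size %||% 20),
                 th = stats::runif(n_leaves, 0, pi))
    })
    for (i in seq_len(n_leaves))
      img <- paint_ellipse(img, leaf_rng$cx[i], leaf_rng$cy[i], leaf_rng$a[i],
                           leaf_rng$b[i], leaf_rng$th[i], c(0.18, 0.32, 0.12))
  }
  if (with_seed(substream_seed(scene$seed, "bg-tassel", frame),
                stats::runif(1)) < (cl$background_tassel_prob %||% 0)) {
    bg_spec <- tassel_spec(main_spike_length = 0.35 * scene$left$main_spike_length,
                           n_branches = 2, base_width = 3,
                           seed = substream_seed(scene$seed, "bg-shape", frame))
    bg_x <- with_seed(substream_seed(scene$seed, "bg-x", frame),
                      stats::runif(1, 0.1 * W, 0.9 * W))
    bg <- generate_tassel(bg_spec, anthesis_model(start_frame = .Machine$integer.max),
                          0, canvas = c(H, W), origin = c(bg_x, 0.5 * H))
    ## far row: faint, partially washed out by sky
    for (k in 1:3) {
      ch <- img[, , k]
      ch[bg$mask > 0] <- 0.6 * ch[bg$mask > 0] + 0.4 * c(0.35, 0.30, 0.22)[k]
      img[, , k] <- ch
    }
  }

  tassel_col <- c(0.33, 0.24, 0.14)
  anchors <- list(left = c(0.30 * W, 0.95 * H), right = c(0.70 * W, 0.95 * H))
  specs <- list(left = scene$left, right = scene$right)
  models <- list(left = scene$left_anthesis, right = scene$right_anthesis)
  truth <- list()
  for (id in c("left", "right")) {
    jit <- with_seed(substream_seed(scene$seed, paste0("jitter-", id), frame), {
      list(dxy = stats::rnorm(2, 0, scene$jitter$sigma %||% 0),
           miss = stats::runif(1))
    })
    if (jit$miss < (scene$jitter$missing_prob %||% 0)) {
      truth[[id]] <- list(present = FALSE, identity = id)
      next
    }
    org <- anchors[[id]] + jit$dxy
    tg <- generate_tassel(specs[[id]], models[[id]], frame,
                          canvas = c(H, W), origin = org)
    if (!tg$truth$present) {
      truth[[id]] <- list(present = FALSE, identity = id)
      next
    }
    tex <- with_seed(substream_seed(scene$seed, paste0("texture-", id), frame),
                     stats::rnorm(sum(tg$mask > 0), 0, 0.02))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[tg$mask > 0] <- pmin(1, pmax(0, tassel_col[k] + tex))
      img[, , k] <- ch
    }
    truth[[id]] <- c(tg$truth, list(identity = id, mask = tg$mask))
  }
  list(image = img, truth = truth)
}

## capture timestamps: `frames_per_day` evenly spaced frames from 7 am over a
## 12 h daylight window; timestamps jump from 7 pm to 7 am the next day
frame_timestamp <- function(frame, frames_per_day, start_date = "2016-08-01") {
  day <- frame %/% frames_per_day
  k <- frame %% frames_per_day
  step_min <- 720 / frames_per_day
  t0 <- as.POSIXct(paste(start_date, "07:00:00"), tz = "UTC")
  t0 + day * 86400 + k * step_min * 60
}

#' Generate a time-lapse sequence on disk
#'
#' Writes `n_days * frames_per_day` PNG frames named
#' `cam<ID>_<YYYYMMDD>_<HHMM>.png`, a CSV manifest
#' (`frame_index, timestamp, filename`), per-frame ground-truth mask PNGs and
#' a ground-truth JSON (boxes, absent flags, anthesis parameters, spike
#' lengths, true width profiles).
#'
#' @param scene a `scene_spec`.
#' @param dir output directory (created if needed).
#' @param camera_id integer camera identifier used in filenames.
#' @param start_date first capture date (`YYYY-MM-DD`).
#' @param write_masks write per-frame per-tassel ground-truth masks.
#' @return (invisibly) list with `dir`, the manifest data.frame and the
#'   ground-truth file path.
#' @export
generate_sequence <- function(scene, dir, camera_id = 1L,
                              start_date = "2016-08-01", write_masks = TRUE) {
  n_frames <- scene$n_days * scene$frames_per_day
  if (n_frames < 1) stopf("sequence must contain at least one frame")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (write_masks) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  manifest <- data.frame(frame_index = integer(0), timestamp = character(0),
                         filename = character(0))
  gt <- list(frames_per_day = scene$frames_per_day, n_days = scene$n_days,
             anthesis = list(left = unclass(scene$left_anthesis),
                             right = unclass(scene$right_anthesis)),
             frames = vector("list", n_frames))
  for (i in seq_len(n_frames) - 1L) {
    ts <- frame_timestamp(i, scene$frames_per_day, start_date)
    fn <- sprintf("cam%02d_%s_%s.png", camera_id,
                  format(ts, "%Y%m%d"), format(ts, "%H%M"))
    fr <- render_scene(scene, i)
    write_image(fr$image, file.path(dir, fn))
    entry <- list(frame_index = i)
    for (id in c("left", "right")) {
      tr <- fr$truth[[id]]
      if (isTRUE(tr$present)) {
        entry[[id]] <- list(present = TRUE, box = tr$box,
                            spike_length = tr$spike_length,
                            branch_points = tr$branch_points,
                            width_profile = tr$width_profile)
        if (write_masks)
          write_mask(tr$mask, file.path(dir, "masks",
                                        sprintf("frame%04d_%s.png", i, id)))
      } else entry[[id]] <- list(present = FALSE)
    }
    gt$frames[[i + 1L]] <- entry
    manifest <- rbind(manifest,
                      data.frame(frame_index = i,
                                 timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                                 filename = fn))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(dir = dir, manifest = manifest, ground_truth = gt_path))
}

#' Read a sequence manifest
#' @param dir sequence directory containing `manifest.csv`.
#' @return data.frame with `frame_index`, `timestamp`, `filename`.
#' @export
read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.csv")
  if (!file.exists(p)) stopf("no manifest.csv in %s", dir)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Read sequence ground truth written by [generate_sequence()]
#' @param dir sequence directory.
#' @return nested list as written.
#' @export
read_ground_truth <- function(dir) {
  p <- file.path(dir, "ground_truth.json")
  if (!file.exists(p)) stopf("no ground_truth.json in %s", dir)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Synthetic crop dataset for classifier studies
#'
#' Generates letterboxed square crops of two classes: `tassel` (a rendered
#' tassel against sky) and `nontassel` (sky/cloud texture, optionally with a
#' leaf blob), mirroring the false-positive content a detector produces
#' before tassel emergence.
#'
#' @param n total number of crops.
#' @param size square crop side in pixels.
#' @param seed integer seed.
#' @return list with `x` (array `size x size x 3 x n`), `y` (integer 0/1,
#'   1 = tassel) and `labels` (character).
#' @export
synth_crop_dataset <- function(n = 200L, size = 64L, seed = 1L) {
  x <- array(0, c(size, size, 3, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    si <- substream_seed(seed, "crop", i)
    is_tassel <- i %% 2L == 1L
    ch <- with_seed(si, {
      H <- 130L; W <- 90L
      sky <- c(0.80, 0.88, 1.0) * stats::runif(1, 0.7, 0.9)
      img <- array(0, c(H, W, 3))
      cloud <- bilinear_upsample(matrix(stats::rnorm(30), 5, 6), H, W) * 0.06
      for (k in 1:3) img[, , k] <- pmin(1, pmax(0, sky[k] * (1 + cloud)))
      if (is_tassel) {
        sp <- tassel_spec(main_spike_length = stats::runif(1, 80, 105),
                          n_branches = sample(2:4, 1), base_width = 5,
                          curvature = stats::runif(1, -0.2, 0.2),
                          seed = si)
        tg <- generate_tassel(sp, anthesis_model(start_frame = 10000L), 0,
                              canvas = c(H, W),
                              origin = c(W / 2 + stats::rnorm(1, 0, 4), 0.95 * H))
        col <- c(0.33, 0.24, 0.14) * stats::runif(1, 0.8, 1.2)
        for (k in 1:3) {
          m <- img[, , k]; m[tg$mask > 0] <- min(1, col[k]); img[, , k] <- m
        }
      } else if (stats::runif(1) < 0.5) {
        img <- paint_ellipse(img, stats::runif(1, 0, W), stats::runif(1, 0.5 * H, H),
                             stats::runif(1, 12, 26), stats::runif(1, 5, 12),
                             stats::runif(1, 0, pi), c(0.18, 0.32, 0.12))
      }
      img
    })
    x[, , , i] <- letterbox(ch, size, pad = 0.5)
    y[i] <- as.integer(is_tassel)
  }
  list(x = x, y = y, labels = ifelse(y == 1L, "tassel", "nontassel"))
}
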