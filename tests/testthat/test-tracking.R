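test_that("collect_centers keeps the two largest boxes per frame", {
  boxes <- rbind(
    bounding_box(0, 0, 10, 10, frame = 0),     # area 100
    bounding_box(50, 0, 80, 30, frame = 0),    # area 900
    bounding_box(90, 0, 95, 5, frame = 0),     # area 25 (dropped)
    bounding_box(0, 0, 10, 10, frame = 2))
  ct <- collect_centers(boxes)
  expect_equal(nrow(ct), 3)
  expect_equal(sum(ct$frame == 0), 2)
  expect_false(3 %in% ct$box_row)
  ## centre arithmetic
  expect_equal(unlist(ct[ct$box_row == 1, c("x", "y")]), c(x = 5, y = 5))
  ## frames with no boxes contribute nothing
  expect_equal(nrow(collect_centers(boxes[0, ])), 0)
})

test_that("k-means tracking recovers well-separated identities", {
  set.seed(20)
  n <- 40
  pts <- rbind(data.frame(frame = 0:(n - 1), x = rnorm(n, 100, 5), y = rnorm(n, 200, 5),
                          box_row = 1:n, true = "left"),
               data.frame(frame = 0:(n - 1), x = rnorm(n, 300, 5), y = rnorm(n, 210, 5),
                          box_row = n + 1:n, true = "right"))
  tracks <- cluster_tracks(pts[, 1:4], seed = 1)
  asg <- attr(tracks, "assignment")
  expect_equal(asg$identity, pts$true)
  ## mirroring the x axis swaps the identities exactly
  mirrored <- pts[, 1:4]; mirrored$x <- 400 - mirrored$x
  masg <- attr(cluster_tracks(mirrored, seed = 1), "assignment")
  expect_equal(masg$identity, ifelse(pts$true == "left", "right", "left"))
  ## assignment is invariant to the ordering of the input points
  perm <- sample(nrow(pts))
  pasg <- attr(cluster_tracks(pts[perm, 1:4], seed = 1), "assignment")
  expect_equal(pasg$identity[order(pasg$box_row)],
               asg$identity[order(asg$box_row)])
})

test_that("a lone box lands in the nearer track", {
  pts <- rbind(data.frame(frame = 0:9, x = rnorm(10, 100, 2), y = 200,
                          box_row = 1:10),
               data.frame(frame = 0:9, x = rnorm(10, 300, 2), y = 210,
                          box_row = 11:20),
               data.frame(frame = 10, x = 298, y = 211, box_row = 21))
  set.seed(4)
  asg <- attr(cluster_tracks(pts, seed = 2), "assignment")
  expect_equal(asg$identity[asg$box_row == 21], "right")
})

test_that("same-cluster collisions are resolved to one box per identity per frame", {
  ## frame 5 contributes two boxes that both sit near the left cluster
  set.seed(8)
  pts <- rbind(data.frame(frame = 0:9, x = rnorm(10, 100, 2), y = 200, box_row = 1:10),
               data.frame(frame = c(0:4, 6:9), x = rnorm(9, 300, 2), y = 210,
                          box_row = 11:19),
               data.frame(frame = 5, x = 110, y = 201, box_row = 20))
  tracks <- cluster_tracks(pts, seed = 3)
  asg <- attr(tracks, "assignment")
  f5 <- asg[asg$frame == 5, ]
  expect_setequal(f5$identity, c("left", "right"))
  expect_true(any(asg$reassigned))
  for (t in tracks) expect_false(any(duplicated(t$entries$frame)))
})

test_that("identical points collapse to a single populated track with a warning", {
  pts <- data.frame(frame = 0:3, x = 50, y = 60, box_row = 1:4)
  expect_warning(tracks <- cluster_tracks(pts, seed = 1), "collapse")
  expect_equal(nrow(tracks$left$entries) + nrow(tracks$right$entries), 4)
  expect_true(nrow(tracks$left$entries) == 0 || nrow(tracks$right$entries) == 0)
  expect_error(cluster_tracks(pts[1, ]), "at least 2")
})

test_that("track crops respect padding, clamping and ground-truth containment", {
  sc <- scene_spec(clutter = list(n_leaves = 0L, background_tassel_prob = 0),
                   jitter = list(sigma = 1, missing_prob = 0), seed = 9)
  boxes <- NULL; frames <- list()
  for (f in 0:3) {
    fr <- render_scene(sc, f)
    frames[[f + 1]] <- fr$image
    for (id in c("left", "right")) {
      b <- fr$truth[[id]]$box
      boxes <- rbind(boxes, bounding_box(b$x_min, b$y_min, b$x_max, b$y_max,
                                         score = 1, frame = f))
    }
  }
  tracks <- cluster_tracks(collect_centers(boxes), seed = 1)
  ## padding 0: crop dims equal box dims
  cr0 <- crop_track(frames, tracks$left, boxes, padding = 0)
  e1 <- tracks$left$entries[1, ]
  b1 <- boxes[e1$box_row, ]
  expect_equal(dim(cr0$crops[[as.character(e1$frame)]])[1:2],
               c(b1$y_max - b1$y_min, b1$x_max - b1$x_min))
  ## generous padding is clamped to the frame
  cr <- crop_track(frames, tracks$left, boxes, padding = 500)
  expect_equal(dim(cr$crops[[1]])[1:2], dim(frames[[1]])[1:2])
  ## every crop contains the tassel's ground-truth foreground
  fr0 <- render_scene(sc, 0)
  g0 <- cr0$boxes[["0"]]
  m <- fr0$truth[[tracks$left$identity]]$mask
  px <- which(m > 0, arr.ind = TRUE)
  expect_true(min(px[, 2]) - 1 >= g0$x_min && max(px[, 2]) <= g0$x_max)
  expect_true(min(px[, 1]) - 1 >= g0$y_min && max(px[, 1]) <= g0$y_max)
})
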