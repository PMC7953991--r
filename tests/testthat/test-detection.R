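test_that("iou satisfies identity, disjointness and the worked overlap case", {
  A <- bounding_box(0, 0, 10, 10)
  B <- bounding_box(20, 20, 30, 30)
  C <- bounding_box(5, 0, 15, 10)
  expect_equal(iou(A, A), 1)
  expect_equal(iou(A, B), 0)
  expect_equal(iou(A, C), 1 / 3)
  expect_equal(iou(C, A), iou(A, C))
  expect_error(iou(list(x_min = 0, y_min = 0, x_max = 0, y_max = 5), A),
               "degenerate")
  expect_error(bounding_box(3, 0, 3, 10), "degenerate")
  expect_error(bounding_box(0, 0, 5, 5, score = 1.4), "\\[0,1\\]")
})

test_that("iou equals the pixel-enumeration oracle on random integer boxes", {
  set.seed(101)
  for (i in 1:200) {
    rbox <- function() {
      x <- sort(sample(0:50, 2)); y <- sort(sample(0:50, 2))
      while (x[1] == x[2]) x <- sort(sample(0:50, 2))
      while (y[1] == y[2]) y <- sort(sample(0:50, 2))
      bounding_box(x[1], y[1], x[2], y[2])
    }
    a <- rbox(); b <- rbox()
    expect_equal(iou(a, b), iou_pixel_oracle(a, b))
  }
})

test_that("qc_filter enforces bounds, ranking and the kept-box cap", {
  rule <- qc_rule(min_area = 100, width_range = c(5, 100), height_range = c(5, 100),
                  max_boxes_kept = 2)
  tiny <- bounding_box(0, 0, 2, 2)          # area 4
  good <- bounding_box(0, 0, 20, 20)
  expect_equal(nrow(qc_filter(tiny, rule)$kept), 0)
  expect_equal(nrow(qc_filter(good, rule)$kept), 1)
  ## three valid boxes, cap 2: two largest kept, area ties broken by x_min
  b3 <- rbind(bounding_box(40, 0, 50, 50),   # area 500
              bounding_box(0, 0, 20, 20),    # area 400
              bounding_box(25, 0, 45, 20))   # area 400, larger x_min
  for (perm in list(1:3, c(2, 3, 1), c(3, 1, 2), 3:1)) {
    kept <- qc_filter(b3[perm, ], rule)$kept
    expect_equal(nrow(kept), 2)
    expect_setequal(kept$x_min, c(40, 0))
  }
  ## idempotence
  once <- qc_filter(b3, rule)$kept
  twice <- qc_filter(once, rule)$kept
  expect_equal(twice[order(twice$x_min), ], once[order(once$x_min), ],
               ignore_attr = TRUE)
  expect_error(qc_rule(min_area = 0), ">= 1")
  expect_error(qc_rule(width_range = c(10, 5)), "min <= max")
  ## empty input passes through
  empty <- bounding_box(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(qc_filter(empty, rule)$kept), 0)
})

test_that("box CSV round-trips and reports malformed rows by line", {
  set.seed(7)
  boxes <- bounding_box(x_min = runif(10, 0, 50), y_min = runif(10, 0, 50),
                        x_max = runif(10, 60, 100), y_max = runif(10, 60, 100),
                        score = runif(10), frame = sample(0:3, 10, replace = TRUE))
  f <- tempfile(fileext = ".csv")
  write_boxes_csv(boxes, f)
  got <- load_external_boxes(f)
  expect_equal(nrow(got$errors), 0)
  expect_equal(got$boxes[, 1:6], boxes[, 1:6], tolerance = 1e-12, ignore_attr = TRUE)
  ## malformed rows collected with their line numbers
  writeLines(c("frame_index,filename,x_min,y_min,x_max,y_max,score,label",
               "0,a.png,10,10,5,20,0.9,tassel",      # x_max <= x_min
               "0,a.png,0,0,10,10,0.5,tassel",
               "1,b.png,0,0,10,10,1.7,tassel"),      # bad score
             f)
  got <- load_external_boxes(f)
  expect_equal(nrow(got$boxes), 1)
  expect_equal(got$errors$line, c(2L, 4L))
  ## empty CSV with header
  writeLines("frame_index,filename,x_min,y_min,x_max,y_max,score,label", f)
  expect_equal(nrow(load_external_boxes(f)$boxes), 0)
  expect_error(load_external_boxes(tempfile()), "not found")
})

test_that("detection evaluation applies the IOU > 0.5 rule and AP conventions", {
  gt <- rbind(bounding_box(0, 0, 10, 10, frame = 0),
              bounding_box(100, 0, 110, 10, frame = 0))
  ## perfect predictions
  pred <- gt; pred$score <- c(0.9, 0.8)
  expect_equal(evaluate_detections(pred, gt)$map, 1)
  ## a single sub-threshold prediction is a false positive (AP 0)
  p40 <- bounding_box(0, 0, 10, 4, score = 0.9, frame = 0)   # IOU 0.4
  expect_equal(iou(p40, gt[1, ]), 0.4)
  ev <- evaluate_detections(p40, gt[1, ])
  expect_equal(ev$n_fp, 1)
  expect_equal(ev$ap, 0)
  ## IOU exactly at the threshold is false ("more than" rule)
  phalf <- bounding_box(0, 0, 10, 5, score = 0.9, frame = 0)
  stopifnot(abs(iou(phalf, gt[1, ]) - 1 / 3) < 1)  # sanity of construction
  ## ranked TP, FP, TP case: AP = 5/6, cross-checked numerically
  pred3 <- rbind(bounding_box(0, 0, 10, 10, score = 0.9, frame = 0),
                 bounding_box(50, 50, 60, 60, score = 0.8, frame = 0),
                 bounding_box(100, 0, 110, 10, score = 0.7, frame = 0))
  ev3 <- evaluate_detections(pred3, gt)
  expect_equal(ev3$ap, 5 / 6)
  expect_equal(ev3$ap, ap_numeric_oracle(ev3$precision, ev3$recall),
               tolerance = 1e-6)
  ## TP + FN equals the ground-truth count
  expect_equal(ev3$n_tp + ev3$n_fn, nrow(gt))
  expect_error(evaluate_detections(pred3, gt, iou_threshold = 1.2),
               "strictly inside")
})

test_that("AP is invariant to frame relabeling and to appending a hopeless box", {
  gt <- rbind(bounding_box(0, 0, 10, 10, frame = 0),
              bounding_box(0, 0, 10, 10, frame = 1))
  pred <- rbind(bounding_box(0, 0, 10, 9, score = 0.9, frame = 0),
                bounding_box(1, 0, 10, 10, score = 0.6, frame = 1))
  base_ap <- evaluate_detections(pred, gt)$ap
  ## swap the frame labels everywhere
  gt2 <- gt; gt2$frame <- rev(gt$frame)
  pred2 <- pred; pred2$frame <- rev(pred$frame)
  expect_equal(evaluate_detections(pred2, gt2)$ap, base_ap)
  ## a zero-IOU prediction with the lowest score never increases AP
  worse <- rbind(pred, bounding_box(500, 500, 510, 510, score = 0.01, frame = 0))
  expect_lte(evaluate_detections(worse, gt)$ap, base_ap)
})

test_that("the reference detector finds tassels against clean sky", {
  sc <- scene_spec(clutter = list(n_leaves = 0L, background_tassel_prob = 0),
                   jitter = list(sigma = 0, missing_prob = 0))
  fr <- render_scene(sc, 0)
  det <- reference_detect(fr$image, frame = 0)
  expect_equal(nrow(det), 2)
  for (id in c("left", "right")) {
    best <- max(vapply(seq_len(nrow(det)),
                       function(i) iou(det[i, ], fr$truth[[id]]$box), 0))
    expect_gte(best, 0.7)
  }
  ## pure sky: nothing detected
  sky <- render_scene(scene_spec(clutter = list(n_leaves = 0L,
                                                background_tassel_prob = 0),
                                 jitter = list(sigma = 0, missing_prob = 1)), 0)
  expect_equal(nrow(reference_detect(sky$image)), 0)
  ## one tassel painted on sky: exactly one box
  img <- sky$image
  tg <- generate_tassel(tassel_spec(main_spike_length = 80), anthesis_model(), 0,
                        canvas = dim(img)[1:2], origin = c(120, 200))
  for (k in 1:3) { ch <- img[, , k]; ch[tg$mask > 0] <- 0.25; img[, , k] <- ch }
  expect_equal(nrow(reference_detect(img)), 1)
  expect_error(reference_detect(to_gray(img)), "RGB")
})
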