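# helpers to draw simple shapes ------------------------------------------

draw_bar <- function(h = 50, w = 5, H = 60, W = 15) {
  m <- matrix(0L, H, W)
  x0 <- (W - w) %/% 2
  m[6:(5 + h), (x0 + 1):(x0 + w)] <- 1L
  m
}

# a Y: vertical stem up from the bottom, two arms continuing up-left/up-right
draw_y <- function(stem = 30, left_arm = 25, right_arm = 40, width = 3) {
  H <- 90L; W <- 81L; m <- matrix(0L, H, W)
  cx <- 41L
  stamp <- function(x, y) {
    r <- (width - 1) / 2
    for (dx in -r:r) for (dy in -r:r)
      if (dx^2 + dy^2 <= r^2 + 1e-9) {
        yy <- round(y + dy) + 1; xx <- round(x + dx) + 1
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) m[yy, xx] <<- 1L
      }
  }
  for (t in seq(0, stem)) stamp(cx - 1, H - 2 - t)
  jy <- H - 2 - stem
  for (t in seq(0, left_arm)) stamp(cx - 1 - t * 0.7, jy - t * 0.7)
  for (t in seq(0, right_arm)) stamp(cx - 1 + t * 0.7, jy - t * 0.7)
  m
}

test_that("a vertical bar skeletonizes to a single branchless path", {
  m <- draw_bar()
  g <- skeletonize_mask(m)
  expect_equal(length(g$endpoints), 2)
  expect_equal(length(g$junctions), 0)
  base <- find_base(g)
  expect_equal(base, g$base)
  expect_equal(g$nodes$y[base], max(g$nodes$y))          # bottom endpoint
  sp <- longest_path_from_base(g)
  expect_equal(length(sp$path), nrow(g$nodes))           # path = whole skeleton
  expect_equal(g$nodes$y[sp$tip], min(g$nodes$y))        # tip at the top
  ## branchless: no branch points, crop equals the input mask
  bp <- branch_points_on_path(g, sp)
  expect_equal(nrow(bp), 0)
  expect_null(topmost_branch_point(sp, bp))
  crop <- crop_main_spike(m, g, sp, NULL)
  expect_identical(crop, m)
  ## widths approximately 5 along the interior
  prof <- measure_width(crop, g, sp)
  interior <- prof$width[prof$position > 3 & prof$position < max(prof$position) - 3]
  expect_true(all(abs(interior - 5) <= 1))
})

test_that("a Y-shaped mask yields 3 endpoints, 1 junction and the longer arm", {
  m <- draw_y()
  g <- skeletonize_mask(m)
  expect_equal(length(g$endpoints), 3)
  expect_gte(length(g$junctions), 1)
  sp <- longest_path_from_base(g)
  ## tip is the end of the longer (right) arm: x > centre
  expect_gt(g$nodes$x[sp$tip], 45)
  expect_equal(sp$length, longest_path_oracle(g), tolerance = 1e-9)
  bp <- branch_points_on_path(g, sp)
  expect_equal(nrow(bp), 1)
  top <- topmost_branch_point(sp, bp)
  ## the junction sits strictly between base and tip
  expect_gt(top$arc_from_base, 0)
  expect_lt(top$arc_from_base, sp$length)
  ## crop keeps the tip arm only: subset of mask, nothing below the junction
  crop <- crop_main_spike(m, g, sp, top)
  expect_true(all(m[crop > 0] == 1))
  px <- which(crop > 0, arr.ind = TRUE)
  expect_lte(max(px[, 1]) - 1, top$y + 3)
  ## re-running the chain on the crop gives a branchless spike at least as
  ## long as the tip-to-junction distance
  g2 <- skeletonize_mask(crop)
  sp2 <- longest_path_from_base(g2)
  expect_null(topmost_branch_point(sp2, branch_points_on_path(g2, sp2)))
  expect_gte(sp2$length + 3, sp$length - top$arc_from_base)
})

test_that("degenerate small blobs skeletonize without error", {
  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L
  g <- skeletonize_mask(m)
  expect_gte(nrow(g$nodes), 1)
  sp <- longest_path_from_base(g)
  expect_true(sp$length >= 0)
  expect_error(skeletonize_mask(matrix(0L, 5, 5)), "empty")
})

test_that("base selection breaks ties toward smaller x", {
  ## V-shape graph: two bottom endpoints at equal max y
  nodes <- data.frame(x = c(0, 1, 2, 3, 4), y = c(5, 4, 3, 4, 5))
  edges <- cbind(1:4, 2:5)
  g <- skeleton_graph(nodes, edges)
  expect_equal(find_base(g), 1L)
})

test_that("longest-path ties are broken by smaller tip y then smaller tip x", {
  ## comb: horizontal spine y=10, five equal upward teeth
  spine_n <- 21L
  nodes <- data.frame(x = 0:(spine_n - 1), y = rep(10, spine_n))
  edges <- cbind(1:(spine_n - 1), 2:spine_n)
  for (tx in c(0, 5, 10, 15, 20)) {
    s <- which(nodes$x == tx & nodes$y == 10)
    for (k in 1:4) {
      nodes <- rbind(nodes, data.frame(x = tx, y = 10 - k))
      from <- if (k == 1) s else nrow(nodes) - 1
      edges <- rbind(edges, c(from, nrow(nodes)))
    }
  }
  ## base: unique bottom endpoint; add a short tail below the spine middle
  nodes <- rbind(nodes, data.frame(x = 10, y = 11))
  edges <- rbind(edges, c(which(nodes$x == 10 & nodes$y == 10)[1], nrow(nodes)))
  g <- skeleton_graph(nodes, edges)
  expect_equal(g$nodes$y[g$base], 11)
  sp <- longest_path_from_base(g)
  ## teeth at x = 0,5,10,15,20: distances from base differ; the maximum is
  ## attained at both x=0 and x=20 (spine 10 + tooth 4 + tail 1) -> tie on
  ## length, tip y equal (6), so smaller tip x = 0 wins
  expect_equal(g$nodes$x[sp$tip], 0)
  expect_equal(g$nodes$y[sp$tip], 6)
  expect_equal(sp$length, longest_path_oracle(g), tolerance = 1e-9)
})

test_that("longest path agrees with exhaustive enumeration on random trees", {
  set.seed(77)
  for (i in 1:60) {
    g <- random_tree_graph()
    sp <- longest_path_from_base(g)
    expect_equal(sp$length, longest_path_oracle(g), tolerance = 1e-9)
    ## returned path is a valid simple walk from base ending at an endpoint
    expect_equal(sp$path[1], g$base)
    expect_true(sp$tip %in% g$endpoints)
    expect_false(any(duplicated(sp$path)))
    for (k in seq_along(sp$path)[-1])
      expect_true(sp$path[k] %in% g$adj[[sp$path[k - 1]]])
  }
})

test_that("branch points are path-ordered, merged and exclude the base", {
  ## straight vertical path with side branches at arcs 30 and 55
  n <- 81L
  nodes <- data.frame(x = rep(10, n), y = (n - 1):0)
  edges <- cbind(1:(n - 1), 2:n)
  add_branch <- function(at_arc, side) {
    s <- which(nodes$x == 10 & nodes$y == n - 1 - at_arc)[1]
    for (k in 1:5) {
      nodes <<- rbind(nodes, data.frame(x = 10 + side * k, y = n - 1 - at_arc - k))
      from <- if (k == 1) s else nrow(nodes) - 1
      edges <<- rbind(edges, c(from, nrow(nodes)))
    }
  }
  add_branch(30, 1)
  add_branch(55, -1)
  g <- skeleton_graph(nodes, edges)
  sp <- longest_path_from_base(g)
  bp <- branch_points_on_path(g, sp)
  expect_equal(nrow(bp), 2)
  expect_equal(bp$arc_from_base, c(30, 55))
  top <- topmost_branch_point(sp, bp)
  expect_equal(top$arc_from_base, 55)
  ## two junctions within 3 px merge into one branch point
  add_branch(56, 1)
  g2 <- skeleton_graph(nodes, edges)
  sp2 <- longest_path_from_base(g2)
  bp2 <- branch_points_on_path(g2, sp2)
  expect_equal(nrow(bp2), 2)
  ## a junction exactly at the base is excluded from topmost candidacy
  nodes2 <- data.frame(x = c(0, 0, 0, 1), y = c(2, 1, 0, 2))
  edges2 <- rbind(c(1, 2), c(2, 3), c(1, 4))
  g3 <- skeleton_graph(nodes2, edges2)
  sp3 <- longest_path_from_base(g3)
  expect_null(topmost_branch_point(sp3, branch_points_on_path(g3, sp3)))
})

test_that("width measurement matches analytic shapes", {
  ## rectangle of width 5 handled in the bar test; taper 10 -> 2 over 100 px
  H <- 110L; W <- 21L
  m <- matrix(0L, H, W)
  for (t in 0:99) {
    w <- 10 - 8 * t / 99
    half <- (w - 1) / 2
    cols <- (11 - floor(half)):(11 + floor(half))
    m[H - 4 - t, cols] <- 1L
  }
  g <- skeletonize_mask(m)
  sp <- longest_path_from_base(g)
  prof <- measure_width(m, g, sp)
  interior <- prof[prof$position > 5 & prof$position < 92, ]
  ## monotone decreasing from base to tip: width grows with position-from-tip
  fit <- stats::coef(stats::lm(width ~ position, data = interior))[2]
  expect_gt(fit, 0.05)
  expect_lt(abs(interior$width[which.max(interior$position)] - 10), 2)
  expect_lt(abs(interior$width[which.min(interior$position)] - 2.5), 2)
  ## single-pixel line: width 1 everywhere
  line <- matrix(0L, 30, 5); line[3:28, 3] <- 1L
  gl <- skeletonize_mask(line)
  spl <- longest_path_from_base(gl)
  profl <- measure_width(line, gl, spl)
  expect_true(all(abs(profl$width - 1) <= 1))
})

test_that("measured profiles track generator truth on synthetic tassels", {
  ws <- width_recovery_study(n_tassels = 6, seed = 21)
  expect_lte(ws$mean_mae, 1.5)
})
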