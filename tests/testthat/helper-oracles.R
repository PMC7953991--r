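# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (enumeration, per-pixel loops, numeric integration) and
# never call the code paths they verify.

# IOU by enumerating integer pixels of half-open boxes
iou_pixel_oracle <- function(a, b) {
  pa <- expand.grid(x = seq(a$x_min, a$x_max - 1), y = seq(a$y_min, a$y_max - 1))
  pb <- expand.grid(x = seq(b$x_min, b$x_max - 1), y = seq(b$y_min, b$y_max - 1))
  ka <- paste(pa$x, pa$y); kb <- paste(pb$x, pb$y)
  inter <- length(intersect(ka, kb))
  inter / length(union(ka, kb))
}

# classification metrics by recounting raw (prediction, label) pairs
metric_recount_oracle <- function(tp, fp, fn, tn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  p_den <- sum(pred == 1)
  r_den <- sum(truth == 1)
  a_den <- sum(pred == 1 | truth == 1)
  precision <- if (p_den == 0) 0 else sum(pred == 1 & truth == 1) / p_den
  recall <- if (r_den == 0) 0 else sum(pred == 1 & truth == 1) / r_den
  accuracy <- if (a_den == 0) 0 else sum(pred == 1 & truth == 1) / a_den
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

# segmentation metrics by a per-pixel loop
seg_eval_oracle <- function(pred, truth) {
  match_n <- 0; i_fg <- 0; u_fg <- 0; i_bg <- 0; u_bg <- 0
  for (k in seq_along(pred)) {
    p <- pred[k] > 0; t_ <- truth[k] > 0
    if (p == t_) match_n <- match_n + 1
    if (p && t_) i_fg <- i_fg + 1
    if (p || t_) u_fg <- u_fg + 1
    if (!p && !t_) i_bg <- i_bg + 1
    if (!p || !t_) u_bg <- u_bg + 1
  }
  fg <- if (u_fg == 0) 1 else i_fg / u_fg
  bg <- if (u_bg == 0) 1 else i_bg / u_bg
  list(pixel_accuracy = match_n / length(pred), iou_fg = fg, iou_bg = bg,
       miou = (fg + bg) / 2)
}

# all-point AP by numerically integrating the interpolated precision
# envelope over a fine recall grid
ap_numeric_oracle <- function(precision, recall, step = 1e-6) {
  ord <- order(recall)
  rec <- recall[ord]; prec <- precision[ord]
  suffmax <- rev(cummax(rev(prec)))
  grid <- seq(step / 2, 1 - step / 2, by = step)
  j <- findInterval(grid, rec, left.open = TRUE) + 1L
  env <- ifelse(j > length(rec), 0, suffmax[pmin(j, length(rec))])
  mean(env)
}

# random geometric tree with <= max_endpoints leaves, as a skeleton_graph
random_tree_graph <- function(max_endpoints = 8, max_nodes = 30) {
  repeat {
    n <- sample(6:max_nodes, 1)
    nodes <- data.frame(x = sample.int(50, n, replace = TRUE) - 1,
                        y = sample.int(50, n, replace = TRUE) - 1)
    nodes <- unique(nodes)
    n <- nrow(nodes)
    if (n < 6) next
    parent <- integer(n)
    for (i in 2:n)
      parent[i] <- if (runif(1) < 0.7) i - 1L else sample.int(i - 1L, 1)
    edges <- cbind(parent[-1], 2:n)
    g <- skeleton_graph(nodes, edges)
    if (length(g$endpoints) <= max_endpoints && length(g$endpoints) >= 2) return(g)
  }
}

# exhaustive longest base-to-endpoint path via igraph simple-path enumeration
longest_path_oracle <- function(g) {
  eg <- matrix(unlist(lapply(seq_along(g$adj), function(v) {
    nb <- g$adj[[v]]; nb <- nb[nb > v]
    if (length(nb)) rbind(v, nb) else NULL
  })), nrow = 2)
  ig <- igraph::graph_from_edgelist(t(eg), directed = FALSE)
  best <- -Inf
  for (e in setdiff(g$endpoints, g$base)) {
    paths <- igraph::all_simple_paths(ig, from = g$base, to = e)
    for (p in paths) {
      v <- as.integer(p)
      len <- sum(sqrt(diff(g$nodes$x[v])^2 + diff(g$nodes$y[v])^2))
      if (len > best) best <- len
    }
  }
  best
}

# small helpers used across test files -----------------------------------

# a clean sky + single dark tassel crop with its exact mask
make_tassel_crop <- function(seed = 1, H = 120L, W = 80L) {
  pairs <- synth_segmentation_pairs(1, seed = seed)
  list(crop = pairs$crops[[1]], mask = pairs$masks[[1]])
}

# flat anthesis surface constructed directly
make_surface <- function(widths, frames = seq_len(nrow(widths)) - 1L,
                         frames_per_day = 72L) {
  structure(list(widths = widths, valid = !is.na(widths), frames = frames,
                 timestamps = NULL, frames_per_day = frames_per_day),
            class = "anthesis_surface")
}
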