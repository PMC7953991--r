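## Main-spike morphometry from a binary tassel mask.
##
## The mask is thinned to a one-pixel-wide 8-connected skeleton (Zhang-Suen)
## and converted to a pixel graph. The bottom endpoint is taken as the
## tassel base; the longest base-to-endpoint path contains the main spike
## and its far end is the tassel tip. Branch points are the junctions on
## that path; the spike is cropped between the topmost branch point
## (along-path nearest to the tip) and the tip, and its width is measured at
## every path pixel from the Euclidean distance transform.

## Zhang-Suen thinning of a 0/1 matrix; returns a 1-px-wide skeleton.
## Neighbour tests run on the foreground pixel vector of a zero-padded
## copy, so each pass costs O(foreground), not O(image).
thin_mask <- function(mask) {
  h0 <- nrow(mask); w0 <- ncol(mask)
  H <- h0 + 2L
  m <- matrix(0L, H, w0 + 2L)
  m[2:(h0 + 1L), 2:(w0 + 1L)] <- as.integer(mask > 0)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      idx <- which(m == 1L)
      if (!length(idx)) break
      ## neighbours clockwise from north (y decreasing is up)
      p2 <- m[idx - 1L];     p3 <- m[idx - 1L + H]
      p4 <- m[idx + H];      p5 <- m[idx + 1L + H]
      p6 <- m[idx + 1L];     p7 <- m[idx + 1L - H]
      p8 <- m[idx - H];      p9 <- m[idx - 1L - H]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      del <- if (step == 1L)
        B >= 2L & B <= 6L & A == 1L & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      else
        B >= 2L & B <= 6L & A == 1L & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      if (any(del)) { m[idx[del]] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(h0 + 1L), 2:(w0 + 1L), drop = FALSE]
}

#' Construct a skeleton graph from explicit nodes and edges
#'
#' Used by [skeletonize_mask()] and directly in tests to build synthetic
#' skeleton topologies. Edge weights are Euclidean distances between the
#' node coordinates (1 for axial, sqrt(2) for diagonal pixel steps).
#'
#' @param nodes data.frame with 0-based pixel coordinates `x`, `y`.
#' @param edges two-column matrix of node indices (1-based).
#' @param dim `c(H, W)` of the source mask (optional).
#' @return object of class `skeleton_graph` with adjacency lists, per-node
#'   degrees, `endpoints` (degree <= 1), `junctions` (degree >= 3) and
#'   `base` (bottom endpoint, see [find_base()]).
#' @export
skeleton_graph <- function(nodes, edges, dim = NULL) {
  n <- nrow(nodes)
  adj <- vector("list", n)
  wts <- vector("list", n)
  if (length(edges)) {
    w <- sqrt((nodes$x[edges[, 1]] - nodes$x[edges[, 2]])^2 +
              (nodes$y[edges[, 1]] - nodes$y[edges[, 2]])^2)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
      adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
    }
  }
  degree <- vapply(adj, length, 0L)
  g <- structure(list(nodes = nodes, adj = adj, wts = wts, degree = degree,
                      endpoints = which(degree <= 1L),
                      junctions = which(degree >= 3L),
                      n_edges = if (length(edges)) nrow(edges) else 0L,
                      dim = dim, base = NA_integer_),
                 class = "skeleton_graph")
  g$base <- if (length(g$endpoints)) find_base(g) else NA_integer_
  g
}

#' Skeletonize a binary mask into a pixel graph
#'
#' The largest 8-connected foreground component is thinned to a
#' single-pixel-wide skeleton and converted to a graph over the skeleton
#' pixels. Diagonal adjacencies that are shortcut by a shared axial
#' neighbour are dropped so the graph is free of trivial triangles, and
#' short dead-end chains (`< min_spur` pixels) are pruned: thinning sprouts
#' such spurs wherever the outline has a corner — e.g. at the shoulders of
#' a swelling width step — and their junctions would masquerade as branch
#' points. Real tassel branches are an order of magnitude longer.
#'
#' @param mask binary matrix (non-empty).
#' @param min_spur prune dead-end chains shorter than this many pixels
#'   (default 8; 0 disables pruning).
#' @return a `skeleton_graph`.
#' @export
skeletonize_mask <- function(mask, min_spur = 8) {
  if (!any(mask > 0)) stopf("cannot skeletonize an empty mask")
  lab <- EBImage::bwlabel(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  comp <- matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
  ## thin only the component's bounding box, then restore offsets
  rows <- range(which(rowSums(comp) > 0)); cols <- range(which(colSums(comp) > 0))
  sk <- thin_mask(comp[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
  H <- nrow(sk); W <- ncol(sk)
  px <- which(sk == 1L, arr.ind = TRUE)
  ## local bbox coordinates during graph construction; offsets restored below
  loc <- data.frame(x = px[, 2] - 1L, y = px[, 1] - 1L)
  key <- px[, 1] + (px[, 2] - 1L) * H
  id_of <- integer(H * W); id_of[key] <- seq_len(nrow(loc))
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    ny <- px[, 1] + offs[k, 1]; nx <- px[, 2] + offs[k, 2]
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    nk <- ny[ok] + (nx[ok] - 1L) * H
    hit <- id_of[nk] > 0L
    a <- which(ok)[hit]; b <- id_of[nk[hit]]
    keep <- a < b
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  ## drop diagonal edges shortcut by a shared axial neighbour
  if (nrow(edges)) {
    diag_e <- abs(loc$x[edges[, 1]] - loc$x[edges[, 2]]) == 1L &
              abs(loc$y[edges[, 1]] - loc$y[edges[, 2]]) == 1L
    drop <- rep(FALSE, nrow(edges))
    for (k in which(diag_e)) {
      a <- edges[k, 1]; b <- edges[k, 2]
      c1 <- c(loc$x[a], loc$y[b]); c2 <- c(loc$x[b], loc$y[a])
      for (cc in list(c1, c2)) {
        kk <- (cc[2] + 1L) + cc[1] * H
        if (kk >= 1L && kk <= H * W && id_of[kk] > 0L) { drop[k] <- TRUE; break }
      }
    }
    edges <- edges[!drop, , drop = FALSE]
  }
  nodes <- data.frame(x = loc$x + (cols[1] - 1L), y = loc$y + (rows[1] - 1L))
  g <- skeleton_graph(nodes, edges, dim = dim(mask))
  ## keep the largest connected component of the graph
  comp_id <- graph_components(g)
  main <- which.max(tabulate(comp_id))
  if (any(comp_id != main)) {
    keep <- which(comp_id == main)
    remap <- integer(nrow(nodes)); remap[keep] <- seq_along(keep)
    e2 <- edges[comp_id[edges[, 1]] == main & comp_id[edges[, 2]] == main, , drop = FALSE]
    e2 <- cbind(remap[e2[, 1]], remap[e2[, 2]])
    g <- skeleton_graph(nodes[keep, , drop = FALSE], e2, dim = dim(mask))
  }
  if (min_spur > 0) g <- prune_spurs(g, min_spur)
  g
}

## remove dead-end chains shorter than min_len pixels that terminate at a
## junction; repeated until stable so cascades of spurs collapse
prune_spurs <- function(g, min_len) {
  repeat {
    drop <- rep(FALSE, nrow(g$nodes))
    for (e in g$endpoints) {
      chain <- e; len <- 0; prev <- 0L; cur <- e
      repeat {
        nb <- g$adj[[cur]]; w <- g$wts[[cur]]
        nxt <- which(nb != prev)
        if (g$degree[cur] >= 3L || length(nxt) == 0L) break
        j <- nxt[1L]
        len <- len + w[j]
        prev <- cur; cur <- nb[j]
        if (g$degree[cur] < 3L) chain <- c(chain, cur)
        if (len >= min_len) break
      }
      ## prune only spurs that end at a junction (never a free-standing path)
      if (len < min_len && g$degree[cur] >= 3L) drop[chain] <- TRUE
    }
    if (!any(drop) || all(drop)) break
    keep <- which(!drop)
    remap <- integer(nrow(g$nodes)); remap[keep] <- seq_along(keep)
    edges <- NULL
    for (v in keep) for (j in seq_along(g$adj[[v]])) {
      u <- g$adj[[v]][j]
      if (!drop[u] && v < u) edges <- rbind(edges, c(remap[v], remap[u]))
    }
    g <- skeleton_graph(g$nodes[keep, , drop = FALSE],
                        edges %||% matrix(integer(0), 0, 2), dim = g$dim)
  }
  g
}

## connected components by BFS
graph_components <- function(g) {
  n <- nrow(g$nodes)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- g$adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Find the tassel base endpoint
#'
#' The bottom tip of the skeleton is assumed to be the lower end of the
#' tassel: the endpoint with maximum y (image-down convention), ties broken
#' by smaller x.
#'
#' @param graph a `skeleton_graph` with at least one endpoint.
#' @return node index of the base.
#' @export
find_base <- function(graph) {
  ep <- graph$endpoints
  if (!length(ep)) stopf("skeleton has no endpoints")
  ord <- order(-graph$nodes$y[ep], graph$nodes$x[ep])
  ep[ord[1L]]
}

#' Longest base-to-endpoint path (the main spike)
#'
#' Among simple paths from the base to each endpoint, returns the one with
#' maximum along-path length (8-connected step weights: 1 axial, sqrt(2)
#' diagonal). The far end of that path is the tassel tip. Ties are broken by
#' smaller tip y, then smaller tip x.
#'
#' @param graph a `skeleton_graph`.
#' @param base base node index (defaults to `graph$base`).
#' @return list of class `spike_path`: `path` (node indices base to tip),
#'   `tip`, `length` (pixels) and `arc` (cumulative along-path distance from
#'   the base at every path node).
#' @export
longest_path_from_base <- function(graph, base = graph$base) {
  n <- nrow(graph$nodes)
  if (is.na(base)) stopf("graph has no base endpoint")
  if (n == 1L || length(graph$adj[[base]]) == 0L)
    return(structure(list(path = base, tip = base, length = 0, arc = 0),
                     class = "spike_path"))
  ## Collapse degree-2 pixel chains into weighted segments between "special"
  ## nodes (endpoints/junctions plus the base). A simple pixel path visits a
  ## junction at most once, so simple pixel paths correspond one-to-one to
  ## simple paths in the segment multigraph, which is small enough to
  ## enumerate exactly even when thinning leaves tiny loops.
  is_special <- graph$degree != 2L
  is_special[base] <- TRUE
  used <- lapply(graph$adj, function(a) rep(FALSE, length(a)))
  chains <- list()
  for (s in which(is_special)) {
    for (j in seq_along(graph$adj[[s]])) {
      if (used[[s]][j]) next
      used[[s]][j] <- TRUE
      pixels <- s
      w <- graph$wts[[s]][j]
      prev <- s; cur <- graph$adj[[s]][j]
      used[[cur]][which(graph$adj[[cur]] == prev)[1L]] <- TRUE
      while (!is_special[cur]) {
        pixels <- c(pixels, cur)
        jj <- which(!used[[cur]])[1L]
        if (is.na(jj)) { cur <- NA_integer_; break }   # closed degree-2 loop
        used[[cur]][jj] <- TRUE
        nxt <- graph$adj[[cur]][jj]
        w <- w + graph$wts[[cur]][jj]
        used[[nxt]][which(graph$adj[[nxt]] == cur)[1L]] <- TRUE
        cur <- nxt
      }
      if (is.na(cur) || cur == s) next   # self-loops never lie on a simple path
      chains[[length(chains) + 1L]] <- list(a = s, b = cur, w = w,
                                            pixels = c(pixels, cur))
    }
  }
  special <- which(is_special)
  sid <- integer(n); sid[special] <- seq_along(special)
  incident <- vector("list", length(special))
  for (k in seq_along(chains)) {
    incident[[sid[chains[[k]]$a]]] <- c(incident[[sid[chains[[k]]$a]]], k)
    incident[[sid[chains[[k]]$b]]] <- c(incident[[sid[chains[[k]]$b]]], k)
  }
  xs <- graph$nodes$x; ys <- graph$nodes$y
  best <- new.env(parent = emptyenv())
  best$len <- -Inf; best$tip <- NA_integer_; best$chains <- NULL
  visited_node <- rep(FALSE, length(special))
  visited_chain <- rep(FALSE, length(chains))
  walk <- function(v, len, seq_chains) {    # v: node index (pixel id)
    if (v != base && graph$degree[v] <= 1L) {
      better <- is.na(best$tip) || len > best$len + 1e-9 ||
        (abs(len - best$len) <= 1e-9 &&
           (ys[v] < ys[best$tip] ||
              (ys[v] == ys[best$tip] && xs[v] < xs[best$tip])))
      if (better) { best$len <- len; best$tip <- v; best$chains <- seq_chains }
    }
    for (k in incident[[sid[v]]]) {
      if (visited_chain[k]) next
      ch <- chains[[k]]
      u <- if (ch$a == v) ch$b else ch$a
      if (visited_node[sid[u]]) next
      visited_chain[k] <<- TRUE; visited_node[sid[u]] <<- TRUE
      walk(u, len + ch$w, c(seq_chains, k))
      visited_chain[k] <<- FALSE; visited_node[sid[u]] <<- FALSE
    }
  }
  visited_node[sid[base]] <- TRUE
  walk(base, 0, integer(0))
  if (is.na(best$tip))
    return(structure(list(path = base, tip = base, length = 0, arc = 0),
                     class = "spike_path"))
  ## expand the chain sequence back to the pixel path
  path <- base
  v <- base
  for (k in best$chains) {
    ch <- chains[[k]]
    px <- if (ch$a == v) ch$pixels else rev(ch$pixels)
    path <- c(path, px[-1L])
    v <- if (ch$a == v) ch$b else ch$a
  }
  arc <- numeric(length(path))
  for (i in seq_along(path)[-1L]) {
    j <- match(path[i], graph$adj[[path[i - 1L]]])
    arc[i] <- arc[i - 1L] + graph$wts[[path[i - 1L]]][j]
  }
  structure(list(path = path, tip = best$tip, length = arc[length(arc)], arc = arc),
            class = "spike_path")
}

#' Branch points on the main-spike path
#'
#' Junctions of the skeleton restricted to the path nodes, ordered by
#' along-path distance from the base. Junctions within `merge_dist` pixels
#' of each other along the path are merged into one branch point (skeleton
#' spur artifacts); the merged representative is the middle member.
#'
#' @param graph a `skeleton_graph`.
#' @param spike a `spike_path` from [longest_path_from_base()].
#' @param merge_dist merge radius along the path in pixels (default 3).
#' @return data.frame with `node`, `x`, `y`, `arc_from_base`.
#' @export
branch_points_on_path <- function(graph, spike, merge_dist = 3) {
  on_path <- spike$path %in% graph$junctions
  idx <- which(on_path)
  if (!length(idx))
    return(data.frame(node = integer(0), x = numeric(0), y = numeric(0),
                      arc_from_base = numeric(0)))
  arcs <- spike$arc[idx]
  ## merge runs of junctions closer than merge_dist along the path
  grp <- cumsum(c(1, diff(arcs) > merge_dist))
  reps <- vapply(split(seq_along(idx), grp), function(ii) ii[ceiling(length(ii) / 2)], 0L)
  sel <- idx[reps]
  data.frame(node = spike$path[sel],
             x = graph$nodes$x[spike$path[sel]],
             y = graph$nodes$y[spike$path[sel]],
             arc_from_base = spike$arc[sel])
}

#' Topmost branch point (nearest the tip along the path)
#'
#' The junction with the greatest along-path distance from the base, i.e.
#' the branch point closest to the tip. A junction exactly at the base is
#' excluded; returns `NULL` for a branchless path.
#'
#' @param spike a `spike_path`.
#' @param branch_points data.frame from [branch_points_on_path()].
#' @return one-row data.frame or `NULL`.
#' @export
topmost_branch_point <- function(spike, branch_points) {
  if (nrow(branch_points) == 0L) return(NULL)
  bp <- branch_points[branch_points$arc_from_base > 1e-9 &
                        branch_points$arc_from_base < spike$length - 1e-9, ,
                      drop = FALSE]
  if (nrow(bp) == 0L) return(NULL)
  bp[which.max(bp$arc_from_base), , drop = FALSE]
}

## assign every foreground pixel to its nearest path node (ties to the tip
## side); returns the along-path arc of the assigned node per pixel
nearest_path_arc <- function(mask, graph, spike) {
  fg <- which(mask > 0, arr.ind = TRUE)
  ## path nodes ordered tip first so which.min resolves ties tipward
  ord <- rev(seq_along(spike$path))
  pxx <- graph$nodes$x[spike$path[ord]]
  pyy <- graph$nodes$y[spike$path[ord]]
  arcs <- spike$arc[ord]
  fx <- fg[, 2] - 1L; fy <- fg[, 1] - 1L
  n <- nrow(fg)
  out <- numeric(n)
  chunk <- max(1L, 200000L %/% max(1L, length(pxx)))
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(n, s + chunk - 1L)
    d2 <- outer(fx[ii], pxx, "-")^2 + outer(fy[ii], pyy, "-")^2
    out[ii] <- arcs[max.col(-d2, ties.method = "first")]
  }
  list(fg = fg, arc = out)
}

#' Crop the main spike between the topmost branch point and the tip
#'
#' Foreground is restricted to pixels whose nearest path node lies strictly
#' beyond the topmost branch point toward the tip (ties in the nearest-node
#' assignment resolve to the tip side). For a branchless tassel the whole
#' path's region (the full mask component) is returned.
#'
#' @param mask binary mask the skeleton was computed from.
#' @param graph a `skeleton_graph`.
#' @param spike a `spike_path`.
#' @param topmost one-row data.frame from [topmost_branch_point()] or `NULL`.
#' @return binary mask of the spike crop (same size; subset of `mask`).
#' @export
crop_main_spike <- function(mask, graph, spike, topmost = NULL) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  np <- nearest_path_arc(mask, graph, spike)
  keep <- if (is.null(topmost)) rep(TRUE, nrow(np$fg))
          else np$arc > topmost$arc_from_base + 1e-9
  out[np$fg[keep, , drop = FALSE]] <- 1L
  out
}

## Arc length along a pixel path measured on 5-point moving-average smoothed
## coordinates: the raw 8-connected chain zigzags and overstates arc length
## by 1-2%, which would bias tip-anchored positions toward the base.
smoothed_arc <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2))))
  k <- min(5L, n - (1 - n %% 2L))
  half <- (k - 1L) %/% 2L
  smooth1 <- function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  xs <- smooth1(x); ys <- smooth1(y)
  c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
}

#' Per-pixel width profile of the spike crop
#'
#' Width at each path node inside the crop is `2 d - 1`, where `d` is the
#' Euclidean distance-transform value of the crop foreground at that node
#' (so a one-pixel line has width 1 and a five-pixel bar width 5).
#' Positions are indexed in pixels from the tip (0 = tip).
#'
#' @param spike_mask binary spike-crop mask.
#' @param graph a `skeleton_graph`.
#' @param spike a `spike_path`.
#' @return object of class `width_profile`: data.frame with `position`
#'   (pixels from the tip) and `width` (pixels), tip first.
#' @export
measure_width <- function(spike_mask, graph, spike) {
  d <- EBImage::distmap(matrix(as.numeric(spike_mask > 0), nrow(spike_mask)))
  px <- cbind(graph$nodes$y[spike$path] + 1L, graph$nodes$x[spike$path] + 1L)
  dv <- d[px]
  inside <- dv > 0
  arc_s <- smoothed_arc(graph$nodes$x[spike$path], graph$nodes$y[spike$path])
  pos <- arc_s[length(arc_s)] - arc_s
  prof <- data.frame(position = pos[inside], width = 2 * dv[inside] - 1)
  prof <- prof[order(prof$position), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("width_profile", "data.frame")
  prof
}

#' Full main-spike analysis of one mask
#'
#' Chains [skeletonize_mask()], [longest_path_from_base()],
#' [branch_points_on_path()], [topmost_branch_point()],
#' [crop_main_spike()] and [measure_width()].
#'
#' @param mask binary tassel mask.
#' @return list with `graph`, `spike`, `branch_points`, `topmost`,
#'   `crop` (spike mask) and `profile` (a `width_profile`).
#' @export
analyze_mask <- function(mask) {
  graph <- skeletonize_mask(mask)
  spike <- longest_path_from_base(graph)
  bp <- branch_points_on_path(graph, spike)
  top <- topmost_branch_point(spike, bp)
  crop <- crop_main_spike(mask, graph, spike, top)
  prof <- measure_width(crop, graph, spike)
  list(graph = graph, spike = spike, branch_points = bp, topmost = top,
       crop = crop, profile = prof)
}

#' Write a width profile to CSV
#' @param profile a `width_profile`.
#' @param path output CSV path.
#' @param frame_index frame index column value.
#' @export
write_profile_csv <- function(profile, path, frame_index = NA_integer_) {
  utils::write.csv(data.frame(frame_index = frame_index,
                              position_from_tip_px = profile$position,
                              width_px = profile$width),
                   path, row.names = FALSE)
  invisible(path)
}
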