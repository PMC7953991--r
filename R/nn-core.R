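## Minimal convolutional-network engine.
##
## The classifier and encoder-decoder segmenter in this package are small
## (tens of thousands of parameters, 64x64 inputs), so training is done with
## plain BLAS matrix algebra: im2col convolution, 2x2 max pooling,
## nearest-neighbour upsampling, ReLU, dropout, a dense softmax head or a
## per-pixel sigmoid head, and Adam/SGD optimizers. Batches are arrays of
## shape (H, W, C, N). All gradients are verified against numerical
## differentiation in the test suite.

## ---- layer constructors -----------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = 3L, seed = 1L) {
  fan_in <- k * k * in_ch
  W <- with_seed(seed, matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                              fan_in, out_ch))
  list(type = "conv", k = k, in_ch = in_ch, out_ch = out_ch,
       W = W, b = numeric(out_ch), cache_env = new.env(parent = emptyenv()))
}
nn_relu <- function() list(type = "relu")
nn_pool <- function() list(type = "pool")
nn_upsample <- function() list(type = "upsample")
nn_dropout <- function(rate) list(type = "dropout", rate = rate)
nn_dense <- function(in_dim, out_dim, seed = 1L) {
  W <- with_seed(seed, matrix(stats::rnorm(out_dim * in_dim, 0, sqrt(2 / in_dim)),
                              out_dim, in_dim))
  list(type = "dense", W = W, b = numeric(out_dim))
}

## im2col gather index for one image: (H*W) x (k^2 * C) linear indices into
## the zero-padded (Hp x Wp x C) array; column order is (dy, dx, c) with dy
## fastest, matching the row order of the conv weight matrix.
conv_gather_index <- function(H, W, C, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  base <- rep(seq_len(H), times = W) + (rep(seq_len(W), each = H) - 1L) * Hp
  offs <- as.vector(outer(0:(k - 1L),
                          as.vector(outer((0:(k - 1L)) * Hp, (0:(C - 1L)) * Hp * Wp, "+")),
                          "+"))
  list(idx = outer(base, offs, "+"), Hp = Hp, Wp = Wp, p = p)
}

conv_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k
  key <- paste(H, W, C, N, sep = "x")
  ce <- layer$cache_env
  if (is.null(ce$key) || ce$key != key) {
    gi <- conv_gather_index(H, W, C, k)
    ce$key <- key; ce$gi <- gi
    ce$M <- gi$Hp * gi$Wp * C
    ce$off <- rep((seq_len(N) - 1L) * ce$M, each = H * W)
  }
  gi <- ce$gi
  xp <- array(0, c(gi$Hp, gi$Wp, C, N))
  xp[gi$p + seq_len(H), gi$p + seq_len(W), , ] <- x
  xpv <- as.vector(xp)
  K <- k * k * C; HWN <- H * W * N
  cols <- matrix(0, HWN, K)
  for (j in seq_len(K)) cols[, j] <- xpv[rep(gi$idx[, j], N) + ce$off]
  out <- cols %*% layer$W
  out <- sweep(out, 2L, layer$b, "+")
  out_arr <- aperm(array(out, c(H, W, N, layer$out_ch)), c(1, 2, 4, 3))
  list(out = out_arr, cache = list(cols = cols, dims = d))
}

conv_backward <- function(layer, cache, dout) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), H * W * N, layer$out_ch)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(layer$W)
  ce <- layer$cache_env; gi <- ce$gi
  dxp <- numeric(ce$M * N)
  K <- ncol(dcols)
  for (j in seq_len(K)) {
    ii <- rep(gi$idx[, j], N) + ce$off
    dxp[ii] <- dxp[ii] + dcols[, j]
  }
  dxp <- array(dxp, c(gi$Hp, gi$Wp, C, N))
  dx <- dxp[gi$p + seq_len(H), gi$p + seq_len(W), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x); Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq_len(2L * Ho); ci <- seq_len(2L * Wo)
  a <- x[ri[c(TRUE, FALSE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
  b <- x[ri[c(FALSE, TRUE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
  cc <- x[ri[c(TRUE, FALSE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
  dd <- x[ri[c(FALSE, TRUE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  m1 <- a == out
  m2 <- b == out & !m1
  m3 <- cc == out & !m1 & !m2
  m4 <- dd == out & !m1 & !m2 & !m3
  list(out = out, cache = list(masks = list(m1, m2, m3, m4), dims = d))
}

pool_backward <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]
  rs <- list(seq(1L, 2L * Ho, 2L), seq(2L, 2L * Ho, 2L))
  cs <- list(seq(1L, 2L * Wo, 2L), seq(2L, 2L * Wo, 2L))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (q in 1:4) {
    s <- sel[[q]]
    dx[rs[[s[1]]], cs[[s[2]]], , ] <- dx[rs[[s[1]]], cs[[s[2]]], , , drop = FALSE] +
      dout * cache$masks[[q]]
  }
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  list(out = out, cache = list(dims = d))
}

upsample_backward <- function(cache, dout) {
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  o <- c(TRUE, FALSE); e <- c(FALSE, TRUE)
  dout[seq_len(H2)[o], seq_len(W2)[o], , , drop = FALSE] +
    dout[seq_len(H2)[e], seq_len(W2)[o], , , drop = FALSE] +
    dout[seq_len(H2)[o], seq_len(W2)[e], , , drop = FALSE] +
    dout[seq_len(H2)[e], seq_len(W2)[e], , , drop = FALSE]
}

## ---- network ----------------------------------------------------------------

nn_network <- function(layers, head = c("softmax", "pixel_sigmoid")) {
  structure(list(layers = layers, head = match.arg(head)), class = "nn_network")
}

#' Number of trainable parameters of a model
#' @param net a model handle (classifier, segmenter, or raw network).
#' @return integer parameter count (a pure function of the configuration).
#' @export
param_count <- function(net) {
  if (!inherits(net, "nn_network")) net <- net$net
  sum(vapply(net$layers, function(l)
    if (l$type %in% c("conv", "dense")) length(l$W) + length(l$b) else 0L, 0))
}

nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, x),
      relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
      pool = pool_forward(x),
      upsample = upsample_forward(x),
      dropout = if (train && l$rate > 0) {
        m <- array(stats::runif(length(x)) >= l$rate, dim(x))
        list(out = x * m / (1 - l$rate), cache = list(mask = m, rate = l$rate))
      } else list(out = x, cache = list(mask = NULL)),
      dense = {
        xm <- matrix(x, ncol = dim(x)[4])
        list(out = sweep(l$W %*% xm, 1L, l$b, "+"),
             cache = list(xm = xm, dims = dim(x)))
      },
      stopf("unknown layer type %s", l$type))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]; cache <- caches[[i]]
    if (l$type == "conv") {
      g <- conv_backward(l, cache, dout)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dout <- g$dx
    } else if (l$type == "relu") {
      dout <- dout * cache$mask
    } else if (l$type == "pool") {
      dout <- pool_backward(cache, dout)
    } else if (l$type == "upsample") {
      dout <- upsample_backward(cache, dout)
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) dout <- dout * cache$mask / (1 - cache$rate)
    } else if (l$type == "dense") {
      dm <- if (is.matrix(dout)) dout else matrix(dout, ncol = cache$dims[4])
      grads[[i]] <- list(dW = dm %*% t(cache$xm), db = rowSums(dm))
      dout <- array(t(l$W) %*% dm, cache$dims)
    }
  }
  grads
}

## softmax cross-entropy head: logits (classes x N), y integer 0-based labels
softmax_loss <- function(logits, y) {
  N <- ncol(logits)
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  p <- sweep(exp(z), 2L, colSums(exp(z)), "/")
  idx <- cbind(y + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, dlogits = dlog / N, prob = p)
}

## per-pixel sigmoid binary cross-entropy: logits (H,W,1,N), y same shape 0/1.
## pos_weight > 1 upweights foreground pixels (class imbalance: a tassel
## silhouette occupies a few percent of a letterboxed crop, and unweighted
## BCE stalls in the all-background solution)
bce_pixel_loss <- function(logits, y, pos_weight = 1) {
  p <- 1 / (1 + exp(-logits))
  w <- ifelse(y > 0, pos_weight, 1)
  sw <- sum(w)
  loss <- -sum(w * (y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))) / sw
  list(loss = loss, dlogits = w * (p - y) / sw, prob = p)
}

## ---- optimizers -------------------------------------------------------------

opt_init <- function(net) {
  lapply(net$layers, function(l)
    if (l$type %in% c("conv", "dense"))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL)
}

opt_step <- function(net, grads, state, lr, optimizer, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    l <- net$layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (optimizer == "sgd") {
      l$W <- l$W - lr * g$dW
      l$b <- l$b - lr * g$db
    } else {
      s$mW <- b1 * s$mW + (1 - b1) * g$dW
      s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
      s$mb <- b1 * s$mb + (1 - b1) * g$db
      s$vb <- b2 * s$vb + (1 - b2) * g$db^2
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      l$W <- l$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
      l$b <- l$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
      state[[i]] <- s
    }
    net$layers[[i]] <- l
  }
  list(net = net, state = state)
}

## ---- training loop ----------------------------------------------------------

## x: (H,W,C,N); y: integer labels (softmax head) or (H,W,1,N) masks (pixel
## head). Returns list(net, history). Reproducible given `seed`.
nn_train <- function(net, x, y, epochs, batch_size = 32L, lr = 1e-3,
                     optimizer = c("adam", "sgd"), shuffle = TRUE, seed = 1L,
                     x_val = NULL, y_val = NULL, early_stop_acc = NULL,
                     pos_weight = 1) {
  optimizer <- match.arg(optimizer)
  N <- dim(x)[4]
  pixel <- net$head == "pixel_sigmoid"
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0), val_acc = numeric(0))
  if (epochs == 0L) return(list(net = net, history = history))
  state <- opt_init(net)
  t <- 0L
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(N) else seq_len(N)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1L, N, by = batch_size)) {
      bi <- ord[b0:min(N, b0 + batch_size - 1L)]
      xb <- x[, , , bi, drop = FALSE]
      fw <- nn_forward(net, xb, train = TRUE)
      if (pixel) {
        yb <- y[, , , bi, drop = FALSE]
        ls <- bce_pixel_loss(fw$out, yb, pos_weight)
        ep_correct <- ep_correct + sum((ls$prob > 0.5) == (yb > 0.5)) / length(yb) * length(bi)
      } else {
        yb <- y[bi]
        ls <- softmax_loss(fw$out, yb)
        ep_correct <- ep_correct + sum(max.col(t(ls$prob)) - 1L == yb)
      }
      grads <- nn_backward(net, fw$caches, ls$dlogits)
      t <- t + 1L
      st <- opt_step(net, grads, state, lr, optimizer, t)
      net <- st$net; state <- st$state
      ep_loss <- ep_loss + ls$loss * length(bi)
    }
    val_acc <- NA_real_
    if (!is.null(x_val))
      val_acc <- nn_accuracy(net, x_val, y_val)
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / N,
                                         acc = ep_correct / N, val_acc = val_acc))
    if (!is.null(early_stop_acc)) {
      watch <- if (!is.na(val_acc)) val_acc else ep_correct / N
      if (watch >= early_stop_acc) break
    }
  }
  list(net = net, history = history)
}

nn_accuracy <- function(net, x, y, batch_size = 64L) {
  N <- dim(x)[4]
  correct <- 0; total <- 0
  for (b0 in seq(1L, N, by = batch_size)) {
    bi <- b0:min(N, b0 + batch_size - 1L)
    out <- nn_forward(net, x[, , , bi, drop = FALSE])$out
    if (net$head == "pixel_sigmoid") {
      yb <- y[, , , bi, drop = FALSE]
      p <- 1 / (1 + exp(-out))
      correct <- correct + sum((p > 0.5) == (yb > 0.5)); total <- total + length(yb)
    } else {
      z <- sweep(out, 2L, apply(out, 2L, max), "-")
      p <- sweep(exp(z), 2L, colSums(exp(z)), "/")
      correct <- correct + sum(max.col(t(p)) - 1L == y[bi]); total <- total + length(bi)
    }
  }
  correct / total
}
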