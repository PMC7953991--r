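## Image containers are plain base-R objects:
##   * RGB image: numeric array H x W x 3 with values in [0, 1]
##   * mask:      integer matrix H x W with values in {0, 1}
## Pixel coordinates are 0-based, x rightward (columns), y downward (rows),
## so pixel (x, y) lives at mat[y + 1, x + 1].

#' Read an RGB image from a PNG file
#'
#' Greyscale and RGBA inputs are promoted/stripped to plain RGB.
#'
#' @param path PNG file path.
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  img
}

#' Write an RGB image to a PNG file
#' @param img numeric array `H x W x 3` in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a binary mask PNG (0 = background, 255 = foreground)
#' @param path PNG file path.
#' @return integer matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a binary mask as a PNG (0/255)
#' @param mask integer/logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Luminance of an RGB image
#' @param img `H x W x 3` array.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

## nearest-neighbour resample of an image or mask to out_h x out_w
resize_nearest <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(h, pmax(1L, ceiling(seq_len(out_h) * h / out_h)))
  ci <- pmin(w, pmax(1L, ceiling(seq_len(out_w) * w / out_w)))
  if (length(dim(img)) == 3L) img[ri, ci, , drop = FALSE] else img[ri, ci, drop = FALSE]
}

## aspect-preserving resize into size x size canvas, padded with pad value
letterbox <- function(img, size, pad = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- min(size / h, size / w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  small <- resize_nearest(img, nh, nw)
  if (length(dim(img)) == 3L) {
    out <- array(pad, c(size, size, dim(img)[3]))
    y0 <- (size - nh) %/% 2L; x0 <- (size - nw) %/% 2L
    out[y0 + seq_len(nh), x0 + seq_len(nw), ] <- small
  } else {
    out <- matrix(pad, size, size)
    y0 <- (size - nh) %/% 2L; x0 <- (size - nw) %/% 2L
    out[y0 + seq_len(nh), x0 + seq_len(nw)] <- small
  }
  out
}

## extract the image region covered by a half-open box, clamped to the frame,
## optionally padded outward by `pad` pixels before clamping
crop_box <- function(img, box, pad = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(0L, floor(box$x_min - pad)); x1 <- min(w, ceiling(box$x_max + pad))
  y0 <- max(0L, floor(box$y_min - pad)); y1 <- min(h, ceiling(box$y_max + pad))
  if (x1 <= x0 || y1 <= y0) stopf("box lies outside the frame")
  if (length(dim(img)) == 3L) img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  else img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}
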