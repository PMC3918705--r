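# Grayscale image utilities.
#
# Images are numeric matrices in [0, 1], indexed [row = y, col = x] with
# pixel centres at integer coordinates (x = 1..ncol, y = 1..nrow).  No
# installed R package provides Gaussian filtering of plain matrices, so the
# separable convolution below is implemented directly.

#' Read / write grayscale image frames
#'
#' PNG I/O for frames; colour PNGs are collapsed to grayscale by channel
#' averaging.
#'
#' @param path file path.
#' @return `read_frame()` returns a numeric matrix in `[0, 1]`
#'   (rows = y, columns = x).
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img
}

#' @rdname read_frame
#' @param image numeric matrix in `[0, 1]`.
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmax(pmin(image, 1), 0), path)
  invisible(path)
}

#' Load a directory of PNG frames
#' @param dir directory containing `*.png` frames; lexicographic order.
#' @return list of image matrices.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  lapply(files, read_frame)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {              # along rows (dim 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      idx <- pmin(n, pmax(1, seq_len(n) + o))
      out <- out + k[o + r + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(image))))
}

# central-difference gradients; one-sided at the borders
image_gradient <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  up <- pmax(1, seq_len(nr) - 1); dn <- pmin(nr, seq_len(nr) + 1)
  lf <- pmax(1, seq_len(nc) - 1); rt <- pmin(nc, seq_len(nc) + 1)
  span_y <- matrix(dn - up, nr, nc)
  span_x <- matrix(rt - lf, nr, nc, byrow = TRUE)
  gy <- (image[dn, , drop = FALSE] - image[up, , drop = FALSE]) / span_y
  gx <- (image[, rt, drop = FALSE] - image[, lf, drop = FALSE]) / span_x
  list(gx = gx, gy = gy)
}

# bilinear sampling of a matrix at (x, y) pixel coordinates (vectorised),
# clamped to the image domain
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(nc, pmax(1, x))
  y <- pmin(nr, pmax(1, y))
  x0 <- pmin(nc - 1L, floor(x)); y0 <- pmin(nr - 1L, floor(y))
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}
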