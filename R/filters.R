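# Low-level grid filters shared by the pre-processing chain.
# All of them use symmetric (edge-repeating) reflection at the borders, the
# convention of ImageJ's rank and convolution filters.

# Row/column index vectors for symmetric reflection padding by (ra, rb).
reflect_index <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (r > n) stop("reflection pad larger than image extent")
  c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
}

reflect_pad <- function(m, ra, rb = ra) {
  m[reflect_index(nrow(m), ra), reflect_index(ncol(m), rb), drop = FALSE]
}

# 2D convolution with an odd-sized kernel, reflection padding.
conv2_reflect <- function(m, kernel) {
  ka <- nrow(kernel); kb <- ncol(kernel)
  if (ka %% 2L != 1L || kb %% 2L != 1L) stop("kernel must be odd-sized")
  ra <- (ka - 1L) %/% 2L; rb <- (kb - 1L) %/% 2L
  p <- reflect_pad(m, ra, rb)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (u in seq_len(ka)) {
    for (v in seq_len(kb)) {
      w <- kernel[u, v]
      if (w == 0) next
      out <- out + w * p[(2L * ra + 1L - u) + seq_len(nr),
                         (2L * rb + 1L - v) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

# Separable Gaussian blur, reflection padding, kernel truncated at 3 sigma.
gauss_blur_reflect <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  nr <- nrow(m); nc <- ncol(m)
  # columns (x direction)
  p <- m[, reflect_index(nc, r), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in seq_along(w)) out <- out + w[t] * p[, (t - 1L) + seq_len(nc), drop = FALSE]
  # rows (y direction)
  p <- out[reflect_index(nr, r), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in seq_along(w)) out <- out + w[t] * p[(t - 1L) + seq_len(nr), , drop = FALSE]
  out
}

# Median filter over an odd k x k window, reflection padding. The k^2 shifted
# copies of the image are sorted element-wise by a vectorised exchange network,
# and the middle layer is the per-pixel median.
median_filter_reflect <- function(m, k) {
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 3L) stop("median window must be odd and >= 3")
  r <- (k - 1L) %/% 2L
  p <- reflect_pad(m, r)
  nr <- nrow(m); nc <- ncol(m)
  n <- k * k
  stack <- vector("list", n)
  s <- 1L
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      stack[[s]] <- p[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
      s <- s + 1L
    }
  }
  for (pass in seq_len(n - 1L)) {
    for (i in seq_len(n - pass)) {
      lo <- pmin(stack[[i]], stack[[i + 1L]])
      hi <- pmax(stack[[i]], stack[[i + 1L]])
      stack[[i]] <- lo
      stack[[i + 1L]] <- hi
    }
  }
  stack[[(n + 1L) %/% 2L]]
}

# Grayscale opening with a flat disc structuring element (the rolling-ball
# background estimate). EBImage's grayscale morphology operates on [0, 1]
# intensities, so values are rescaled around it; erosion/dilation commute
# with positive scaling, making the rescale exact.
grey_opening_disc <- function(m, radius_px) {
  radius_px <- as.integer(round(radius_px))
  if (radius_px < 1L) stop("structuring-element radius must be >= 1 px")
  if (radius_px >= min(dim(m))) stop("structuring-element radius >= smallest image dimension")
  scale <- max(m, 1)
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  er <- EBImage::erode(m / scale, brush)
  op <- EBImage::dilate(er, brush)
  matrix(op * scale, nrow(m), ncol(m))
}
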