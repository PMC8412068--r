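# Independent brute-force oracles used to pin the image operators.
# These deliberately share no code with the package implementations:
# plain nested loops, explicit index mirroring, queue-based flood fill.

# mirror an out-of-range index back into 1..n (symmetric reflection with
# edge repetition)
mirror_idx <- function(i, n) {
  if (i < 1L) return(1L - i)
  if (i > n) return(2L * n + 1L - i)
  i
}

# nested-loop 2D convolution with symmetric reflection padding
oracle_conv2 <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  ka <- nrow(kernel); kb <- ncol(kernel)
  cr <- (ka + 1L) %/% 2L; cc <- (kb + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (u in seq_len(ka)) {
        for (v in seq_len(kb)) {
          ii <- mirror_idx(i - (u - cr), nr)
          jj <- mirror_idx(j - (v - cc), nc)
          acc <- acc + kernel[u, v] * m[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# per-pixel sorted-median oracle, reflected edges
oracle_median <- function(m, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- numeric(k * k)
      s <- 1L
      for (di in -r:r) {
        for (dj in -r:r) {
          vals[s] <- m[mirror_idx(i + di, nr), mirror_idx(j + dj, nc)]
          s <- s + 1L
        }
      }
      out[i, j] <- sort(vals)[(k * k + 1L) %/% 2L]
    }
  }
  out
}

# grey opening (erosion then dilation) with a disc of the given radius,
# ignoring out-of-image neighbourhood parts
oracle_grey_opening <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2 + radius / 6 + 0.5, ]
  eroded <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + offs$di; jj <- j + offs$dj
    keep <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    eroded[i, j] <- min(m[cbind(ii[keep], jj[keep])])
  }
  opened <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + offs$di; jj <- j + offs$dj
    keep <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    opened[i, j] <- max(eroded[cbind(ii[keep], jj[keep])])
  }
  opened
}

# queue-based flood-fill labelling with 8-connectivity
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pi <- ((p - 1L) %% nr) + 1L
      pj <- ((p - 1L) %/% nr) + 1L
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          qi <- pi + di; qj <- pj + dj
          if (qi < 1L || qi > nr || qj < 1L || qj > nc) next
          q <- (qj - 1L) * nr + qi
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# exhaustive Yen criterion search over the same binned histogram the
# implementation uses; criterion computed by direct sums per candidate
oracle_yen <- function(values, bins = 256L, clamp_quantile = 0.999) {
  rng <- range(values)
  hi <- if (clamp_quantile >= 1) rng[2]
        else as.numeric(stats::quantile(values, clamp_quantile, names = FALSE))
  if (hi <= rng[1]) hi <- rng[2]
  vn <- pmin((values - rng[1]) / (hi - rng[1]), 1)
  edges <- seq(0, 1, length.out = bins + 1L)
  bi <- pmin(pmax(findInterval(vn, edges, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(bi, bins)
  p <- counts / sum(counts)
  best_t <- NA_integer_
  best_crit <- -Inf
  for (t in seq_len(bins - 1L)) {
    p1 <- sum(p[1:t]); p1sq <- sum(p[1:t]^2)
    p2sq <- sum(p[(t + 1L):bins]^2)
    if (p1sq <= 0 || p2sq <= 0 || p1 <= 0 || p1 >= 1) next
    crit <- log((p1 * (1 - p1))^2 / (p1sq * p2sq))
    if (crit > best_crit) {
      best_crit <- crit
      best_t <- t
    }
  }
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  rng[1] + centers[best_t] * (hi - rng[1])
}

# small helper: clean two-channel scene config used across test files
test_scene_config <- function(seed, field = 20, px = 0.1, pre = 0.4, post = 0.2,
                              coloc = 0, jitter = 0.08, noise = TRUE) {
  scene_config(
    field_size_um = field, pixel_size_um = px,
    channels = list(channel_spec("pre", pre), channel_spec("post", post)),
    coloc_fraction = coloc, coloc_jitter_um = jitter,
    background_level = if (noise) 800 else 0,
    noise_sd = if (noise) 250 else 0,
    blob_density_per_um2 = if (noise) 5e-4 else 0,
    seed = seed)
}

# preprocessing settings scaled to the small test fields
test_preprocess <- function() {
  preprocess_params(background_radius_px = 20, bandpass_small_px = 3,
                    bandpass_large_px = 20, despeckle_kernel_px = 3)
}

test_field_params <- function(...) {
  field_params(preprocess = test_preprocess(), ...)
}
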