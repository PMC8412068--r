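#' Pre-processing parameters
#'
#' Settings of the puncta pre-processing chain applied, in order:
#' rolling-ball background subtraction, difference-of-Gaussians bandpass,
#' despeckling (median), sharpening, Yen thresholding. Defaults follow
#' ImageJ conventions for puncta work at ~0.05 um/px and are deliberately
#' all configurable; every pipeline run logs the values in force.
#'
#' @param background_radius_px Rolling-ball (disc structuring element) radius.
#' @param bandpass_small_px,bandpass_large_px Structure-size pass band: the
#'   DoG uses `sigma_low = small/2` and `sigma_high = large/2`.
#' @param despeckle_kernel_px Odd median-window edge length (>= 3).
#' @param sharpen_kernel 3x3 convolution weights; the default is the
#'   ImageJ-style sharpen kernel (centre 12, eight neighbours -1, normalised
#'   by 4).
#' @param histogram_bins Number of histogram bins for Yen thresholding.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(background_radius_px = 50,
                              bandpass_small_px = 3,
                              bandpass_large_px = 40,
                              despeckle_kernel_px = 3,
                              sharpen_kernel = default_sharpen_kernel(),
                              histogram_bins = 256) {
  if (background_radius_px < 1) stop("`background_radius_px` must be >= 1")
  if (bandpass_small_px <= 0 || bandpass_small_px >= bandpass_large_px)
    stop("bandpass requires 0 < small < large")
  k <- as.integer(despeckle_kernel_px)
  if (k %% 2L != 1L || k < 3L) stop("`despeckle_kernel_px` must be odd and >= 3")
  if (!is.matrix(sharpen_kernel) || !all(dim(sharpen_kernel) == c(3L, 3L)))
    stop("`sharpen_kernel` must be a 3x3 matrix")
  if (histogram_bins < 2) stop("`histogram_bins` must be >= 2")
  structure(list(background_radius_px = background_radius_px,
                 bandpass_small_px = bandpass_small_px,
                 bandpass_large_px = bandpass_large_px,
                 despeckle_kernel_px = k,
                 sharpen_kernel = sharpen_kernel,
                 histogram_bins = as.integer(histogram_bins)),
            class = "preprocess_params")
}

#' @rdname preprocess_params
#' @export
default_sharpen_kernel <- function() {
  matrix(c(-1, -1, -1, -1, 12, -1, -1, -1, -1) / 4, 3, 3)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a flat
#' disc structuring element of the given radius and subtracts it, clipping at
#' zero. A flat background of any level is removed entirely; structures
#' smaller than the disc survive.
#'
#' @param img An [fl_image].
#' @param radius_px Disc radius in pixels (>= 1, < the smallest image
#'   dimension).
#' @return The background-subtracted [fl_image].
#' @export
subtract_background <- function(img, radius_px = 50) {
  stopifnot(is_fl_image(img))
  bg <- grey_opening_disc(img$values, radius_px)
  with_values(img, pmax(img$values - bg, 0))
}

#' Difference-of-Gaussians bandpass filter
#'
#' Suppresses structures smaller than `small_px` and larger than `large_px`
#' by subtracting a wide Gaussian blur (`sigma = large/2`) from a narrow one
#' (`sigma = small/2`). Output is clipped at zero (intensities stay
#' non-negative); set `clip = FALSE` for the signed response.
#'
#' @param img An [fl_image].
#' @param small_px,large_px Pass-band structure sizes in pixels, `small < large`.
#' @param clip Clip negative response at 0 (default).
#' @return The filtered [fl_image] (or a plain matrix when `clip = FALSE`
#'   would break the non-negativity invariant -- the signed response is
#'   returned as a matrix).
#' @export
bandpass <- function(img, small_px = 3, large_px = 40, clip = TRUE) {
  stopifnot(is_fl_image(img))
  if (small_px <= 0 || small_px >= large_px) stop("bandpass requires 0 < small < large")
  lo <- gauss_blur_reflect(img$values, small_px / 2)
  hi <- gauss_blur_reflect(img$values, large_px / 2)
  dog <- lo - hi
  if (!clip) return(dog)
  with_values(img, pmax(dog, 0))
}

#' Despeckle (median filter)
#'
#' Median filter over an odd square window with reflected edges; removes
#' isolated hot pixels while preserving punctum plateaus.
#'
#' @param img An [fl_image].
#' @param kernel_px Odd window edge length >= 3.
#' @return The filtered [fl_image].
#' @export
despeckle <- function(img, kernel_px = 3) {
  stopifnot(is_fl_image(img))
  with_values(img, median_filter_reflect(img$values, kernel_px))
}

#' Sharpen by 3x3 convolution
#'
#' 2D convolution with a 3x3 kernel, reflection padding, clipped at zero.
#'
#' @param img An [fl_image].
#' @param kernel 3x3 weight matrix; see [default_sharpen_kernel()].
#' @return The sharpened [fl_image].
#' @export
sharpen <- function(img, kernel = default_sharpen_kernel()) {
  stopifnot(is_fl_image(img))
  if (!is.matrix(kernel) || !all(dim(kernel) == c(3L, 3L)))
    stop("`kernel` must be a 3x3 matrix")
  with_values(img, pmax(conv2_reflect(img$values, kernel), 0))
}

# Yen threshold of a numeric matrix over a binned histogram. Intensities are
# normalised to [0, 1] over [min, upper] where upper is the clamp_quantile
# intensity quantile (1 = plain min-max); values above it fall into the top
# bin. The clamp keeps the binning stable when a handful of extreme pixels
# (coincident spots, saturation) would otherwise stretch the range and
# squash the informative part of the histogram into a few bins. Quantiles
# are affine-equivariant, so the mask stays invariant under monotone affine
# intensity rescaling. The criterion is maximised over all bin boundaries;
# the threshold is the centre of the maximising bin, on the original scale.
yen_threshold <- function(values, bins = 256L, clamp_quantile = 0.999) {
  rng <- range(values)
  if (!(rng[2] > rng[1]))
    stop("degenerate histogram: image has fewer than 2 distinct values")
  hi <- if (clamp_quantile >= 1) rng[2]
        else as.numeric(stats::quantile(values, clamp_quantile, names = FALSE))
  if (hi <= rng[1]) hi <- rng[2]
  vn <- pmin((values - rng[1]) / (hi - rng[1]), 1)
  edges <- seq(0, 1, length.out = bins + 1L)
  bi <- pmin(pmax(findInterval(vn, edges, rightmost.closed = TRUE), 1L), bins)
  p <- tabulate(bi, bins) / length(vn)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  t <- seq_len(bins - 1L)
  crit <- rep(-Inf, bins - 1L)
  ok <- P1sq[t] > 0 & P2sq[t] > 0 & P1[t] > 0 & P1[t] < 1
  crit[ok] <- log((P1[t][ok] * (1 - P1[t][ok]))^2 / (P1sq[t][ok] * P2sq[t][ok]))
  tbest <- which.max(crit)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  rng[1] + centers[tbest] * (hi - rng[1])
}

#' Yen thresholding
#'
#' Binarises an image at the threshold maximising Yen's maximum-correlation
#' criterion over the binned intensity histogram (after min-max
#' normalisation). The mask uses a strict "greater than threshold" rule
#' (deterministic tie policy); excluded pixels are never foreground.
#'
#' @param img An [fl_image] with at least two distinct values.
#' @param bins Number of histogram bins.
#' @param clamp_quantile Upper intensity quantile defining the histogram
#'   range (values above fall into the top bin); `1` for plain min-max.
#' @return A list: `mask` (logical-valued [fl_image]) and `threshold` (on the
#'   original intensity scale).
#' @export
binarize_yen <- function(img, bins = 256, clamp_quantile = 0.999) {
  stopifnot(is_fl_image(img))
  thr <- yen_threshold(img$values, as.integer(bins), clamp_quantile)
  mask <- img$values > thr
  if (!is.null(img$excluded_mask)) mask[img$excluded_mask] <- FALSE
  list(mask = fl_image(mask, img$pixel_size_um, img$excluded_mask),
       threshold = thr)
}

#' Full pre-processing chain: raw channel to binary puncta mask
#'
#' Applies, in this fixed order: background subtraction, bandpass filtering,
#' despeckling, sharpening, and Yen thresholding. Two degenerate cases return
#' an all-background mask instead of an error: a constant image (empty bin
#' crop), and a field with no detectable signal -- when no pixel of the
#' signed bandpass response rises above `noise_floor_sd` robust noise SDs
#' (median absolute deviation scale), thresholding would only split the noise
#' distribution, so the mask is empty.
#'
#' @param img An [fl_image].
#' @param params A [preprocess_params].
#' @param keep_intermediates Attach the intermediate images (for QC) as an
#'   attribute `"intermediates"`.
#' @param noise_floor_sd Signal-evidence requirement in robust noise SDs of
#'   the signed bandpass response; the maximum of ~10^6 correlated Gaussian
#'   noise pixels stays below ~5 SDs, while rendered puncta sit orders of
#'   magnitude higher.
#' @return A logical-valued [fl_image] mask, with the threshold attached as
#'   attribute `"threshold"`.
#' @export
preprocess <- function(img, params = preprocess_params(), keep_intermediates = FALSE,
                       noise_floor_sd = 6) {
  stopifnot(is_fl_image(img), inherits(params, "preprocess_params"))
  s1 <- subtract_background(img, params$background_radius_px)
  dog <- bandpass(s1, params$bandpass_small_px, params$bandpass_large_px,
                  clip = FALSE)
  noise_scale <- 1.4826 * stats::median(abs(dog - stats::median(dog)))
  no_signal <- noise_scale > 0 && max(dog) < noise_floor_sd * noise_scale
  s2 <- with_values(s1, pmax(dog, 0))
  s3 <- despeckle(s2, params$despeckle_kernel_px)
  s4 <- sharpen(s3, params$sharpen_kernel)
  if (no_signal || diff(range(s4$values)) <= 0) {
    mask <- fl_image(matrix(FALSE, nrow(s4$values), ncol(s4$values)),
                     img$pixel_size_um, img$excluded_mask)
    thr <- NA_real_
  } else {
    b <- binarize_yen(s4, params$histogram_bins)
    mask <- b$mask
    thr <- b$threshold
  }
  attr(mask, "threshold") <- thr
  if (keep_intermediates)
    attr(mask, "intermediates") <- list(background_subtracted = s1, bandpassed = s2,
                                        despeckled = s3, sharpened = s4)
  mask
}
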