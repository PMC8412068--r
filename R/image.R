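#' Single-channel fluorescence image
#'
#' The unit every image operation in the package consumes and returns: a
#' rectangular non-negative intensity grid with its physical pixel size, plus
#' an optional exclusion mask marking pixels (e.g. the astrocyte soma) that
#' must not contribute to puncta counts or area denominators.
#'
#' The coordinate convention is: matrix rows run along y, columns along x,
#' and the centre of pixel `[i, j]` sits at `((j - 0.5), (i - 0.5)) *
#' pixel_size_um` micrometres.
#'
#' @param values Numeric (or logical, for masks) matrix of intensities.
#' @param pixel_size_um Physical pixel edge length in micrometres per pixel.
#' @param excluded_mask Optional logical matrix of the same shape; `TRUE`
#'   pixels are ignored downstream (no puncta, no area contribution).
#' @return An object of class `fl_image`.
#' @export
fl_image <- function(values, pixel_size_um, excluded_mask = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  if (is.numeric(values) && any(values < 0))
    stop("intensity values must be non-negative")
  if (!is.null(excluded_mask)) {
    if (!is.logical(excluded_mask) || !identical(dim(excluded_mask), dim(values)))
      stop("`excluded_mask` must be a logical matrix with the same shape as `values`")
  }
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 excluded_mask = excluded_mask),
            class = "fl_image")
}

#' @export
print.fl_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fl_image> %d x %d px, %.4g um/px (%.4g x %.4g um)\n",
              d[1], d[2], x$pixel_size_um,
              d[2] * x$pixel_size_um, d[1] * x$pixel_size_um))
  if (!is.null(x$excluded_mask))
    cat(sprintf("  excluded pixels: %d\n", sum(x$excluded_mask)))
  invisible(x)
}

#' @export
dim.fl_image <- function(x) dim(x$values)

is_fl_image <- function(x) inherits(x, "fl_image")

#' Analysed (non-excluded) image area
#'
#' @param img An [fl_image].
#' @return Area in square micrometres of pixels not flagged in the exclusion
#'   mask.
#' @export
valid_area_um2 <- function(img) {
  stopifnot(is_fl_image(img))
  n <- length(img$values)
  if (!is.null(img$excluded_mask)) n <- n - sum(img$excluded_mask)
  n * img$pixel_size_um^2
}

# Rebuild an image with new values, preserving geometry and exclusion mask.
# Excluded pixels pass through untouched (operators never alter them).
with_values <- function(img, values) {
  if (!is.null(img$excluded_mask) && is.numeric(values) &&
      is.numeric(img$values)) {
    values[img$excluded_mask] <- img$values[img$excluded_mask]
  }
  fl_image(values, img$pixel_size_um, img$excluded_mask)
}

#' Multi-channel fluorescence scene
#'
#' A set of equally sized single-channel intensity grids sharing one pixel
#' size, as produced by the scene generator or read from a multi-page TIFF.
#'
#' @param channels Named list of numeric matrices (one per channel).
#' @param pixel_size_um Micrometres per pixel, shared by all channels.
#' @return An object of class `fl_scene`.
#' @export
fl_scene <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a non-empty named list of matrices")
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!is.matrix(ch) || !identical(dim(ch), d))
      stop("all channels must be matrices of identical shape")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "fl_scene")
}

#' @export
print.fl_scene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<fl_scene> %d channel(s) [%s], %d x %d px, %.4g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Extract one channel of a scene as an image
#'
#' @param scene An [fl_scene].
#' @param name Channel name.
#' @return An [fl_image].
#' @export
scene_channel <- function(scene, name) {
  stopifnot(inherits(scene, "fl_scene"))
  if (!name %in% names(scene$channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(scene$channels), collapse = ", ")))
  fl_image(scene$channels[[name]], scene$pixel_size_um)
}
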