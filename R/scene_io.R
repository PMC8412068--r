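#' Write a multi-channel scene as a 16-bit TIFF with metadata sidecar
#'
#' Channels are stored as TIFF pages (one per channel) at 16-bit depth, and
#' the pixel size plus channel names go to a JSON sidecar next to the TIFF
#' (`<path>.json`), so that the physical geometry survives the round trip
#' exactly.
#'
#' @param scene An [fl_scene] or a `sim_scene` (its `image` is written).
#' @param path Output path; `.tif` is appended when missing.
#' @return The TIFF path, invisibly.
#' @export
write_scene <- function(scene, path) {
  if (inherits(scene, "sim_scene")) scene <- scene$image
  stopifnot(inherits(scene, "fl_scene"))
  if (!grepl("\\.tif{1,2}$", path, ignore.case = TRUE)) path <- paste0(path, ".tif")
  pages <- lapply(scene$channels, function(v) {
    v <- round(v)
    if (any(v < 0 | v > 65535)) stop("intensities outside the 16-bit range")
    v / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(pixel_size_um = scene$pixel_size_um,
               channels = as.list(names(scene$channels)),
               bit_depth = 16L)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tif{1,2}$", "", path, ignore.case = TRUE), ".json")

#' Read a scene written by [write_scene]
#'
#' 8-bit TIFFs are promoted to the 16-bit scale with a warning (values are
#' preserved injectively, `x -> x * 257`).
#'
#' @param path TIFF path.
#' @return An [fl_scene].
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing metadata sidecar '%s': field `pixel_size_um` unavailable", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("metadata sidecar lacks required field `pixel_size_um`")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  values <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    v <- if (!is.null(bits) && bits == 8L) {
      warning("8-bit TIFF promoted to 16-bit scale (values preserved)")
      round(p * 255) * 257
    } else {
      round(p * 65535)
    }
    matrix(as.numeric(v), nrow(p), ncol(p))  # drop TIFF tag attributes
  })
  nms <- unlist(meta$channels)
  if (is.null(nms) || length(nms) != length(values))
    nms <- paste0("ch", seq_along(values))
  names(values) <- nms
  fl_scene(values, as.numeric(meta$pixel_size_um))
}

#' Write/read ground-truth puncta tables
#'
#' Plain-CSV persistence of the generator's ground truth (`channel`, `x_um`,
#' `y_um`, `radius_um`, `pair_id`).
#'
#' @param truth Ground-truth data frame from a `sim_scene`.
#' @param path CSV path.
#' @return `write_ground_truth`: the path, invisibly. `read_ground_truth`:
#'   the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
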