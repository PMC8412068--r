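#' Build the 17-bin Sholl-like layout around an astrocyte core
#'
#' One square bin sits on the core ("center"); for each further distance
#' class, four bins are placed at the cardinal directions (+x, -x, +y, -y) at
#' the class distance, measured core to bin centre. The default five classes
#' (center, close, mid, distant, out) at 0, 30, 60, 90, 120 um with 27 um
#' bins yield 17 bins with class multiplicities (1, 4, 4, 4, 4), a total
#' sampled area of 12,393 um^2, of which the 9 center+close+mid bins
#' (6,561 um^2) constitute the astrocytic domain proper.
#'
#' @param core_center_um Numeric `c(x, y)` of the astrocyte core in
#'   micrometres.
#' @param side_um Bin edge length.
#' @param class_distances_um Strictly increasing core-to-bin-centre distances
#'   starting at 0; with five entries the canonical class labels are used.
#' @param angles_deg Placement angles of the non-centre bins.
#' @return A `bin_layout` data frame: `index`, `distance_class` (ordered
#'   factor), `distance_um`, `center_x_um`, `center_y_um`, `side_um`; the
#'   core, side and angles are carried as attributes.
#' @export
build_bin_layout <- function(core_center_um,
                             side_um = 27,
                             class_distances_um = c(0, 30, 60, 90, 120),
                             angles_deg = c(0, 90, 180, 270)) {
  if (length(core_center_um) != 2L) stop("`core_center_um` must be c(x, y)")
  if (class_distances_um[1] != 0 || any(diff(class_distances_um) <= 0))
    stop("class distances must be strictly increasing from 0")
  if (side_um <= 0) stop("`side_um` must be positive")
  nclass <- length(class_distances_um)
  labels <- if (nclass == 5L) c("center", "close", "mid", "distant", "out")
            else paste0("d", class_distances_um)
  rows <- list(data.frame(distance_class = labels[1],
                          distance_um = 0,
                          center_x_um = core_center_um[1],
                          center_y_um = core_center_um[2]))
  for (k in seq_len(nclass - 1L) + 1L) {
    th <- angles_deg * pi / 180
    rows[[k]] <- data.frame(distance_class = labels[k],
                            distance_um = class_distances_um[k],
                            center_x_um = core_center_um[1] + class_distances_um[k] * cos(th),
                            center_y_um = core_center_um[2] + class_distances_um[k] * sin(th))
  }
  layout <- do.call(rbind, rows)
  layout <- data.frame(index = seq_len(nrow(layout)),
                       distance_class = factor(layout$distance_class,
                                               levels = labels, ordered = TRUE),
                       distance_um = layout$distance_um,
                       center_x_um = layout$center_x_um,
                       center_y_um = layout$center_y_um,
                       side_um = side_um)
  structure(layout, class = c("bin_layout", "data.frame"),
            core_center_um = core_center_um, angles_deg = angles_deg)
}

#' Total sampled area of a bin layout
#'
#' @param layout A `bin_layout`.
#' @return Area in square micrometres (`n_bins * side^2`).
#' @export
layout_total_area_um2 <- function(layout) {
  stopifnot(inherits(layout, "bin_layout"))
  nrow(layout) * layout$side_um[1]^2
}

#' Domain-assigned bins of a layout
#'
#' The astrocytic domain is identified with the center, close and mid bins
#' (9 bins under the default layout), matching a domain circle of radius
#' ~71 um (half the ~142 um human domain diameter).
#'
#' @param layout A `bin_layout`.
#' @param domain_radius_um Radius of the ascribed domain circle; bins whose
#'   centre lies within it are domain bins.
#' @return The subset of `layout` rows inside the domain.
#' @export
domain_bins <- function(layout, domain_radius_um = 71) {
  stopifnot(inherits(layout, "bin_layout"))
  core <- attr(layout, "core_center_um")
  d <- sqrt((layout$center_x_um - core[1])^2 + (layout$center_y_um - core[2])^2)
  layout[d <= domain_radius_um, , drop = FALSE]
}

#' Exclude the astrocyte soma from analysis
#'
#' Flags all pixels within `soma_radius_um` of the core in the image's
#' exclusion mask, so that somatic off-target signal contributes neither
#' puncta nor analysed area downstream.
#'
#' @param img An [fl_image].
#' @param core_center_um Core position `c(x, y)` in micrometres.
#' @param soma_radius_um Exclusion radius; 0 disables exclusion.
#' @return The [fl_image] with an updated `excluded_mask`.
#' @export
exclude_soma <- function(img, core_center_um, soma_radius_um = 7.5) {
  stopifnot(is_fl_image(img))
  if (soma_radius_um < 0) stop("`soma_radius_um` must be >= 0")
  if (soma_radius_um == 0) return(img)
  px <- img$pixel_size_um
  nr <- nrow(img$values); nc <- ncol(img$values)
  ys <- (seq_len(nr) - 0.5) * px
  xs <- (seq_len(nc) - 0.5) * px
  d2 <- outer((ys - core_center_um[2])^2, (xs - core_center_um[1])^2, "+")
  excl <- d2 < soma_radius_um^2
  if (!is.null(img$excluded_mask)) excl <- excl | img$excluded_mask
  fl_image(img$values, px, excl)
}

# Pixel index range [lo, hi] of bin extent [a, b) along one axis, by pixel
# centres; returns NULL when no pixel centre falls inside.
bin_pixel_range <- function(a, b, px, n) {
  lo <- max(1L, as.integer(ceiling(a / px + 0.5 - 1e-9)))
  hi <- min(n, as.integer(floor(b / px + 0.5 - 1e-9)))
  if (lo > hi) return(NULL)
  c(lo, hi)
}

#' Per-bin puncta densities from an image
#'
#' Crops each bin of the layout out of the image, runs the pre-processing
#' chain and puncta detection independently on the crop (each bin is
#' processed on its own, as in the domain workflow), and reports puncta per
#' square micrometre of the bin's valid area: pixels inside the field and not
#' excluded. Bins clipped by the field edge are normalised by their in-field
#' valid area; bins entirely outside the field are flagged missing (`NA`),
#' not zero.
#'
#' @param img An [fl_image] of the quantified (postsynaptic) channel, with
#'   any soma exclusion already applied via [exclude_soma()].
#' @param layout A `bin_layout`.
#' @param params A [field_params]; its size filter and pre-processing
#'   settings are used.
#' @return Data frame: layout columns plus `n_puncta`, `valid_area_um2`,
#'   `density`, `missing`.
#' @export
extract_bin_densities <- function(img, layout, params = field_params()) {
  stopifnot(is_fl_image(img), inherits(layout, "bin_layout"))
  px <- img$pixel_size_um
  nr <- nrow(img$values); nc <- ncol(img$values)
  half <- layout$side_um / 2
  out <- as.data.frame(layout)
  out$n_puncta <- NA_integer_
  out$valid_area_um2 <- NA_real_
  out$density <- NA_real_
  out$missing <- FALSE
  for (b in seq_len(nrow(layout))) {
    xr <- bin_pixel_range(layout$center_x_um[b] - half[b],
                          layout$center_x_um[b] + half[b], px, nc)
    yr <- bin_pixel_range(layout$center_y_um[b] - half[b],
                          layout$center_y_um[b] + half[b], px, nr)
    if (is.null(xr) || is.null(yr)) {
      out$missing[b] <- TRUE
      next
    }
    crop_excl <- if (!is.null(img$excluded_mask))
      img$excluded_mask[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE]
    crop <- fl_image(img$values[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE], px, crop_excl)
    mask <- preprocess(crop, params$preprocess)
    set <- detect_puncta(mask, params$min_area_um2, params$max_area_um2)
    out$n_puncta[b] <- nrow(set$puncta)
    out$valid_area_um2[b] <- set$field_area_um2
    out$density[b] <- puncta_density(set)
  }
  out
}

# Valid bin area for point-based counting: bin rectangle clipped to the
# field, minus its overlap with the soma disc (computed on a fine fixed
# grid -- deterministic and accurate to ~1e-4 of the bin area).
bin_valid_area_points <- function(cx, cy, half, field_size_um = NULL,
                                  core = NULL, soma_radius_um = 0) {
  x0 <- cx - half; x1 <- cx + half
  y0 <- cy - half; y1 <- cy + half
  if (!is.null(field_size_um)) {
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, field_size_um); y1 <- min(y1, field_size_um)
  }
  if (x1 <= x0 || y1 <= y0) return(0)
  area <- (x1 - x0) * (y1 - y0)
  if (soma_radius_um > 0 && !is.null(core)) {
    # quick reject: disc far from the rectangle
    ddx <- max(x0 - core[1], 0, core[1] - x1)
    ddy <- max(y0 - core[2], 0, core[2] - y1)
    if (ddx^2 + ddy^2 < soma_radius_um^2) {
      g <- 400L
      gx <- seq(x0, x1, length.out = g)
      gy <- seq(y0, y1, length.out = g)
      inside <- outer((gy - core[2])^2, (gx - core[1])^2, "+") < soma_radius_um^2
      area <- area * (1 - mean(inside))
    }
  }
  area
}

#' Per-bin densities from true punctum positions
#'
#' Point-process counterpart of [extract_bin_densities()]: counts ground-truth
#' centroids per bin and normalises by the bin's valid area (clipped to the
#' field, minus the soma disc). Used for generator calibration and for fast
#' large-scale cohort simulations where rendering and detection are not the
#' question.
#'
#' @param x_um,y_um Punctum coordinates in micrometres.
#' @param layout A `bin_layout`.
#' @param field_size_um Optional square-field edge for clipping.
#' @param soma_radius_um Radius of the soma exclusion around the layout core;
#'   points inside are dropped and the area denominator reduced.
#' @return Data frame as in [extract_bin_densities()].
#' @export
bin_counts <- function(x_um, y_um, layout, field_size_um = NULL,
                       soma_radius_um = 0) {
  stopifnot(inherits(layout, "bin_layout"))
  core <- attr(layout, "core_center_um")
  if (soma_radius_um > 0) {
    d2 <- (x_um - core[1])^2 + (y_um - core[2])^2
    keep <- d2 >= soma_radius_um^2
    x_um <- x_um[keep]; y_um <- y_um[keep]
  }
  half <- layout$side_um / 2
  out <- as.data.frame(layout)
  out$n_puncta <- NA_integer_
  out$valid_area_um2 <- NA_real_
  out$density <- NA_real_
  out$missing <- FALSE
  for (b in seq_len(nrow(layout))) {
    area <- bin_valid_area_points(layout$center_x_um[b], layout$center_y_um[b],
                                  half[b], field_size_um, core, soma_radius_um)
    if (area <= 0) {
      out$missing[b] <- TRUE
      next
    }
    inx <- x_um >= layout$center_x_um[b] - half[b] & x_um < layout$center_x_um[b] + half[b]
    iny <- y_um >= layout$center_y_um[b] - half[b] & y_um < layout$center_y_um[b] + half[b]
    out$n_puncta[b] <- sum(inx & iny)
    out$valid_area_um2[b] <- area
    out$density[b] <- out$n_puncta[b] / area
  }
  out
}

#' Collapse per-bin densities into the ordered density distribution
#'
#' Averages the member bins of each distance class, in the fixed
#' center-to-out order; missing bins are omitted from their class mean (with
#' a message), never imputed as zero.
#'
#' @param bin_densities Data frame from [extract_bin_densities()] or
#'   [bin_counts()].
#' @return A `density_distribution` data frame: `distance_class`,
#'   `distance_um`, `mean_density`, `n_bins`.
#' @export
density_distribution <- function(bin_densities) {
  req <- c("distance_class", "distance_um", "density")
  if (!all(req %in% names(bin_densities)))
    stop("`bin_densities` must carry distance_class, distance_um and density")
  miss <- if ("missing" %in% names(bin_densities)) bin_densities$missing
          else is.na(bin_densities$density)
  if (any(miss))
    message(sprintf("%d bin(s) missing; class means use the available bins", sum(miss)))
  ok <- bin_densities[!miss, , drop = FALSE]
  cls <- levels(bin_densities$distance_class)
  res <- data.frame(distance_class = factor(cls, levels = cls, ordered = TRUE),
                    distance_um = vapply(cls, function(l)
                      bin_densities$distance_um[bin_densities$distance_class == l][1],
                      numeric(1)),
                    mean_density = vapply(cls, function(l) {
                      v <- ok$density[ok$distance_class == l]
                      if (length(v)) mean(v) else NA_real_
                    }, numeric(1)),
                    n_bins = vapply(cls, function(l)
                      sum(ok$distance_class == l), integer(1)))
  rownames(res) <- NULL
  class(res) <- c("density_distribution", "data.frame")
  res
}
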