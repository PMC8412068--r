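#' Channel specification for the scene generator
#'
#' Describes one fluorescence channel as a homogeneous Poisson field of
#' diffraction-limited puncta rendered as isotropic 2D Gaussian spots.
#'
#' @param name Channel label, e.g. `"pre"`, `"post"`, `"astro"`.
#' @param density_per_um2 Poisson rate of puncta per square micrometre.
#' @param punctum_radius_um Mean spot radius in micrometres. Spots are
#'   rendered as Gaussians with `sigma = radius / 2`, truncated at 3 sigma.
#' @param punctum_radius_sd_um Standard deviation of the per-punctum radius.
#' @param amplitude Peak intensity of a spot (16-bit scale).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, density_per_um2,
                         punctum_radius_um = 0.25,
                         punctum_radius_sd_um = 0.05,
                         amplitude = 20000) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (density_per_um2 < 0) stop("`density_per_um2` must be >= 0")
  if (punctum_radius_um <= 0) stop("`punctum_radius_um` must be > 0")
  if (punctum_radius_sd_um < 0) stop("`punctum_radius_sd_um` must be >= 0")
  structure(list(name = name, density_per_um2 = density_per_um2,
                 punctum_radius_um = punctum_radius_um,
                 punctum_radius_sd_um = punctum_radius_sd_um,
                 amplitude = amplitude),
            class = "channel_spec")
}

#' Scene configuration
#'
#' Collects the acquisition geometry, channel composition, colocalization
#' ground truth and noise model of one synthetic field. Defaults mirror the
#' acquisition geometry of the study: 1024 px square fields at 0.049 um/px
#' (50.2 x 50.2 um) for general synapse counting.
#'
#' @param field_size_um Square field edge length in micrometres. Must resolve
#'   to an integer pixel grid together with `pixel_size_um`.
#' @param pixel_size_um Micrometres per pixel.
#' @param channels List of [channel_spec] objects.
#' @param coloc_fraction Fraction in `[0, 1]` of presynaptic puncta that
#'   receive a matched postsynaptic partner. Matched partners are appended to
#'   the post channel on top of its own (unpaired) Poisson puncta.
#' @param coloc_jitter_um Isotropic Gaussian SD of the centroid offset of a
#'   matched partner.
#' @param pre_channel,post_channel Names of the channels the colocalization
#'   fraction refers to. Ignored when either is absent.
#' @param background_level Additive intensity offset.
#' @param noise_sd Gaussian read-noise SD.
#' @param blob_density_per_um2 Rate of large, faint autofluorescence blobs
#'   (rendered into every channel, mimicking tissue autofluorescence).
#' @param seed Integer master seed; per-channel sub-streams are derived
#'   deterministically, so ground truth is reproducible channel by channel.
#' @return A `scene_config` list.
#' @export
scene_config <- function(field_size_um = 50.176,
                         pixel_size_um = 0.049,
                         channels = list(),
                         coloc_fraction = 0,
                         coloc_jitter_um = 0.08,
                         pre_channel = "pre",
                         post_channel = "post",
                         background_level = 800,
                         noise_sd = 250,
                         blob_density_per_um2 = 5e-4,
                         seed = 1L) {
  if (field_size_um <= 0 || pixel_size_um <= 0)
    stop("field and pixel sizes must be positive")
  npx <- field_size_um / pixel_size_um
  if (abs(npx - round(npx)) > 1e-6)
    stop(sprintf("field_size_um / pixel_size_um = %.8g is not an integer pixel grid", npx))
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("`coloc_fraction` must be in [0, 1]")
  if (coloc_jitter_um < 0 || background_level < 0 || noise_sd < 0 ||
      blob_density_per_um2 < 0)
    stop("jitter, background, noise and blob rates must be >= 0")
  if (length(channels)) {
    ok <- vapply(channels, inherits, logical(1), what = "channel_spec")
    if (!all(ok)) stop("`channels` must be a list of channel_spec objects")
    names(channels) <- vapply(channels, `[[`, character(1), "name")
    if (anyDuplicated(names(channels))) stop("channel names must be unique")
  }
  structure(list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
                 channels = channels, coloc_fraction = coloc_fraction,
                 coloc_jitter_um = coloc_jitter_um,
                 pre_channel = pre_channel, post_channel = post_channel,
                 background_level = background_level, noise_sd = noise_sd,
                 blob_density_per_um2 = blob_density_per_um2,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Radial density profile around an astrocyte core
#'
#' Piecewise-linear multiplicative modulation of a channel's puncta density
#' as a function of distance to the core: linear interpolation between knots,
#' constant beyond the last knot.
#'
#' @param knot_distances_um Strictly increasing distances, starting at 0.
#' @param multipliers Non-negative density multipliers at the knots.
#' @return A `radial_profile` object.
#' @export
radial_profile <- function(knot_distances_um, multipliers) {
  if (length(knot_distances_um) != length(multipliers) || !length(multipliers))
    stop("knots and multipliers must have equal, positive length")
  if (knot_distances_um[1] != 0 || any(diff(knot_distances_um) <= 0))
    stop("knot distances must be strictly increasing and start at 0")
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  structure(list(knot_distances_um = as.numeric(knot_distances_um),
                 multipliers = as.numeric(multipliers)),
            class = "radial_profile")
}

#' Evaluate a radial profile
#'
#' @param profile A [radial_profile].
#' @param distance_um Distances (vectorised) from the core in micrometres.
#' @return Density multipliers.
#' @export
profile_multiplier <- function(profile, distance_um) {
  stopifnot(inherits(profile, "radial_profile"))
  if (length(profile$multipliers) == 1L)
    return(rep(profile$multipliers, length(distance_um)))
  stats::approx(profile$knot_distances_um, profile$multipliers,
                xout = distance_um, rule = 2)$y
}

# Deterministic sub-stream seeds below 2^31, one per (master seed, stream id).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e6) * 2057 + stream * 7919) %% 2147483399L + 1L
}

# Draw puncta of one channel as a homogeneous Poisson process on the field.
draw_poisson_puncta <- function(spec, field_size_um) {
  area <- field_size_um^2
  n <- stats::rpois(1L, spec$density_per_um2 * area)
  radius <- pmax(stats::rnorm(n, spec$punctum_radius_um, spec$punctum_radius_sd_um),
                 0.2 * spec$punctum_radius_um)
  data.frame(channel = rep(spec$name, n),
             x_um = stats::runif(n, 0, field_size_um),
             y_um = stats::runif(n, 0, field_size_um),
             radius_um = radius,
             pair_id = rep(NA_integer_, n))
}

# Render truncated-Gaussian spots onto an intensity matrix (in place add).
render_spots <- function(values, pts, amplitude, pixel_size_um) {
  nr <- nrow(values); nc <- ncol(values)
  for (k in seq_len(nrow(pts))) {
    sigma_px <- (pts$radius_um[k] / 2) / pixel_size_um
    ext <- ceiling(3 * sigma_px)
    cx <- pts$x_um[k] / pixel_size_um + 0.5  # pixel-centre coordinates
    cy <- pts$y_um[k] / pixel_size_um + 0.5
    j0 <- max(1L, floor(cx - ext)); j1 <- min(nc, ceiling(cx + ext))
    i0 <- max(1L, floor(cy - ext)); i1 <- min(nr, ceiling(cy + ext))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    dx2 <- (jj - cx)^2; dy2 <- (ii - cy)^2
    d2 <- outer(dy2, dx2, "+")
    spot <- amplitude * exp(-d2 / (2 * sigma_px^2))
    spot[d2 > (3 * sigma_px)^2] <- 0
    values[ii, jj] <- values[ii, jj] + spot
  }
  values
}

# Shared background: offset + Gaussian noise + sparse large blobs.
render_background <- function(config, blob_pts, channel_amplitude, stream_seed) {
  npx <- as.integer(round(config$field_size_um / config$pixel_size_um))
  set.seed(stream_seed)
  values <- matrix(config$background_level, npx, npx)
  if (config$noise_sd > 0)
    values <- values + matrix(stats::rnorm(npx * npx, 0, config$noise_sd), npx, npx)
  values[values < 0] <- 0
  if (nrow(blob_pts))
    values <- render_spots(values, blob_pts, 0.15 * channel_amplitude,
                           config$pixel_size_um)
  values
}

draw_blobs <- function(config) {
  n <- stats::rpois(1L, config$blob_density_per_um2 * config$field_size_um^2)
  data.frame(channel = rep("blob", n),
             x_um = stats::runif(n, 0, config$field_size_um),
             y_um = stats::runif(n, 0, config$field_size_um),
             radius_um = stats::runif(n, 1.5, 4),
             pair_id = rep(NA_integer_, n))
}

finish_scene <- function(config, truth, channel_values, extra = list()) {
  clipped <- 0; total <- 0
  for (nm in names(channel_values)) {
    v <- channel_values[[nm]]
    clipped <- clipped + sum(v > 65535)
    total <- total + length(v)
    v[v > 65535] <- 65535
    v[v < 0] <- 0
    channel_values[[nm]] <- v
  }
  truth <- truth[order(truth$channel, truth$x_um, truth$y_um), , drop = FALSE]
  rownames(truth) <- NULL
  out <- c(list(image = fl_scene(channel_values, config$pixel_size_um),
                truth = truth,
                clipped_fraction = clipped / max(total, 1L),
                config = config),
           extra)
  class(out) <- "sim_scene"
  if (out$clipped_fraction > 0)
    message(sprintf("scene rendering clipped %.3g%% of pixels at the 16-bit ceiling",
                    100 * out$clipped_fraction))
  out
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("<sim_scene> %d true puncta over %d channel(s); clipped fraction %.3g\n",
              nrow(x$truth), length(x$image$channels), x$clipped_fraction))
  print(x$image)
  invisible(x)
}

#' Generate a synthetic multi-channel field with known ground truth
#'
#' Puncta are placed by a homogeneous Poisson process per channel; a
#' `coloc_fraction` share of presynaptic puncta receives a matched
#' postsynaptic partner whose centroid is displaced by isotropic Gaussian
#' jitter and whose radius is drawn independently from the post channel's
#' radius distribution. Spots are rendered as 2D Gaussians (sigma = radius/2,
#' truncated at 3 sigma) onto background + noise + sparse autofluorescence
#' blobs, and clipped at the 16-bit ceiling. Ground truth is generated on
#' separate random sub-streams from the rendering noise, so it is independent
#' of rendering and of intensity clipping.
#'
#' @param config A [scene_config].
#' @param render If `FALSE`, skip intensity rendering and return only ground
#'   truth (channels are left as zero matrices). Useful for large point-process
#'   simulations where only true positions matter.
#' @return A `sim_scene` list: `image` ([fl_scene]), `truth` (data frame with
#'   `channel`, `x_um`, `y_um`, `radius_um`, `pair_id`), `clipped_fraction`.
#' @export
generate_scene <- function(config, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  npx <- as.integer(round(config$field_size_um / config$pixel_size_um))
  truth_list <- list()
  for (k in seq_along(config$channels)) {
    set.seed(derive_seed(config$seed, k))
    truth_list[[k]] <- draw_poisson_puncta(config$channels[[k]], config$field_size_um)
  }
  truth <- do.call(rbind, c(truth_list,
                            list(data.frame(channel = character(), x_um = numeric(),
                                            y_um = numeric(), radius_um = numeric(),
                                            pair_id = integer()))))
  # matched pre/post pairs
  pre <- config$pre_channel; post <- config$post_channel
  if (config$coloc_fraction > 0 && all(c(pre, post) %in% names(config$channels))) {
    is_pre <- truth$channel == pre
    n_pre <- sum(is_pre)
    n_pair <- round(config$coloc_fraction * n_pre)
    if (n_pair > 0) {
      set.seed(derive_seed(config$seed, 97L))
      pick <- which(is_pre)[seq_len(n_pair)]  # pre positions are already i.i.d.
      truth$pair_id[pick] <- seq_len(n_pair)
      ps <- config$channels[[post]]
      partner <- data.frame(
        channel = rep(post, n_pair),
        x_um = truth$x_um[pick] + stats::rnorm(n_pair, 0, config$coloc_jitter_um),
        y_um = truth$y_um[pick] + stats::rnorm(n_pair, 0, config$coloc_jitter_um),
        radius_um = pmax(stats::rnorm(n_pair, ps$punctum_radius_um,
                                      ps$punctum_radius_sd_um),
                         0.2 * ps$punctum_radius_um),
        pair_id = seq_len(n_pair))
      partner$x_um <- pmin(pmax(partner$x_um, 0), config$field_size_um)
      partner$y_um <- pmin(pmax(partner$y_um, 0), config$field_size_um)
      truth <- rbind(truth, partner)
    }
  }
  channel_values <- stats::setNames(
    replicate(max(length(config$channels), 1L), matrix(0, npx, npx), simplify = FALSE),
    if (length(config$channels)) names(config$channels) else "empty")
  if (render) {
    set.seed(derive_seed(config$seed, 211L))
    blobs <- draw_blobs(config)
    for (k in seq_along(config$channels)) {
      spec <- config$channels[[k]]
      v <- render_background(config, blobs, spec$amplitude,
                             derive_seed(config$seed, 300L + k))
      pts <- truth[truth$channel == spec$name, , drop = FALSE]
      v <- render_spots(v, pts, spec$amplitude, config$pixel_size_um)
      channel_values[[spec$name]] <- v
    }
  }
  finish_scene(config, truth, channel_values)
}

#' Generate a synthetic astrocytic-domain scene
#'
#' Like [generate_scene], but the designated (postsynaptic) channel is an
#' inhomogeneous Poisson process whose rate is the channel density multiplied
#' by a [radial_profile] of the distance to the astrocyte core (simulated by
#' thinning). A channel named `"astro"` renders the astrocyte body as a bright
#' annulus around an empty core centre, so that core detection is visually
#' meaningful; a channel named `"ptau"` places its puncta with a Gaussian
#' annular weight peaking 20 um from the core (an astrocytic-plaque-like
#' corona).
#'
#' @param config A [scene_config] (use the domain geometry: 4080 px at
#'   0.052 um/px for the 212 um fields of the study).
#' @param profile A [radial_profile] applied to `profiled_channel`.
#' @param core_center_um Numeric `c(x, y)` of the astrocyte core; must lie
#'   inside the field.
#' @param profiled_channel Channel the radial profile applies to.
#' @param core_radius_um Radius of the rendered astrocyte annulus.
#' @param render As in [generate_scene].
#' @return A `sim_scene`; `truth` carries all channels' true puncta.
#' @export
generate_domain_scene <- function(config, profile, core_center_um,
                                  profiled_channel = "post",
                                  core_radius_um = 7.5,
                                  render = TRUE) {
  stopifnot(inherits(config, "scene_config"), inherits(profile, "radial_profile"))
  if (length(core_center_um) != 2L ||
      any(core_center_um < 0) || any(core_center_um > config$field_size_um))
    stop("`core_center_um` must lie inside the field")
  if (!profiled_channel %in% names(config$channels))
    stop(sprintf("profiled channel '%s' is not in the configuration", profiled_channel))
  npx <- as.integer(round(config$field_size_um / config$pixel_size_um))
  mult_max <- max(profile$multipliers)
  truth_list <- list()
  for (k in seq_along(config$channels)) {
    spec <- config$channels[[k]]
    set.seed(derive_seed(config$seed, k))
    if (spec$name == profiled_channel && mult_max > 0) {
      # thinning of a homogeneous process at the envelope rate
      spec_env <- spec
      spec_env$density_per_um2 <- spec$density_per_um2 * mult_max
      pts <- draw_poisson_puncta(spec_env, config$field_size_um)
      d <- sqrt((pts$x_um - core_center_um[1])^2 + (pts$y_um - core_center_um[2])^2)
      keep <- stats::runif(nrow(pts)) < profile_multiplier(profile, d) / mult_max
      pts <- pts[keep, , drop = FALSE]
    } else if (spec$name == "astro") {
      pts <- pts_empty()
    } else if (spec$name == "ptau") {
      pts <- draw_poisson_puncta(spec, config$field_size_um)
      d <- sqrt((pts$x_um - core_center_um[1])^2 + (pts$y_um - core_center_um[2])^2)
      keep <- stats::runif(nrow(pts)) < exp(-((d - 20) / 10)^2)
      pts <- pts[keep, , drop = FALSE]
    } else if (spec$name == profiled_channel && mult_max == 0) {
      pts <- pts_empty()
    } else {
      pts <- draw_poisson_puncta(spec, config$field_size_um)
    }
    truth_list[[k]] <- pts
  }
  truth <- do.call(rbind, c(truth_list, list(pts_empty())))
  channel_values <- stats::setNames(
    replicate(length(config$channels), matrix(0, npx, npx), simplify = FALSE),
    names(config$channels))
  if (render) {
    set.seed(derive_seed(config$seed, 211L))
    blobs <- draw_blobs(config)
    for (k in seq_along(config$channels)) {
      spec <- config$channels[[k]]
      v <- render_background(config, blobs, spec$amplitude,
                             derive_seed(config$seed, 300L + k))
      if (spec$name == "astro") {
        v <- v + astro_annulus(npx, config$pixel_size_um, core_center_um,
                               core_radius_um, spec$amplitude)
      }
      pts <- truth[truth$channel == spec$name, , drop = FALSE]
      v <- render_spots(v, pts, spec$amplitude, config$pixel_size_um)
      channel_values[[spec$name]] <- v
    }
  }
  finish_scene(config, truth, channel_values,
               extra = list(core_center_um = core_center_um,
                            profile = profile))
}

pts_empty <- function() {
  data.frame(channel = character(), x_um = numeric(), y_um = numeric(),
             radius_um = numeric(), pair_id = integer())
}

# Bright annulus with empty centre marking the astrocyte core.
astro_annulus <- function(npx, pixel_size_um, core_center_um, core_radius_um,
                          amplitude) {
  xs <- ((seq_len(npx)) - 0.5) * pixel_size_um
  d2 <- outer((xs - core_center_um[2])^2, (xs - core_center_um[1])^2, "+")
  d <- sqrt(d2)
  ring <- 0.75 * amplitude * exp(-((d - core_radius_um) / (0.25 * core_radius_um))^2)
  ring[d < 0.5 * core_radius_um] <- 0
  matrix(ring, npx, npx)
}
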