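test_that("default layout satisfies the 17-bin Sholl-like geometry", {
  core <- c(140, 140)
  layout <- build_bin_layout(core)
  expect_identical(nrow(layout), 17L)
  expect_identical(as.integer(table(layout$distance_class)), c(1L, 4L, 4L, 4L, 4L))
  expect_true(all(layout$side_um == 27))
  d <- sqrt((layout$center_x_um - core[1])^2 + (layout$center_y_um - core[2])^2)
  expect_equal(sort(unique(round(d, 9))), c(0, 30, 60, 90, 120))
  # total sampled area and the 9-bin domain area
  expect_equal(layout_total_area_um2(layout), 17 * 27^2)  # 12393
  dom <- domain_bins(layout, 71)
  expect_identical(nrow(dom), 9L)
  expect_identical(levels(droplevels(dom$distance_class)), c("center", "close", "mid"))
  expect_equal(nrow(dom) * 27^2, 6561)
  # distant and out bins fall outside the domain circle
  expect_true(all(!c("distant", "out") %in% dom$distance_class))
})

test_that("layout construction validates distances", {
  expect_error(build_bin_layout(c(0, 0), class_distances_um = c(10, 20)),
               "from 0")
  expect_error(build_bin_layout(c(0, 0), class_distances_um = c(0, 30, 30)),
               "increasing")
})

test_that("soma exclusion removes the expected area and puncta", {
  img <- fl_image(matrix(0, 400, 400), 0.25)  # 100 x 100 um
  expect_identical(exclude_soma(img, c(50, 50), 0)$excluded_mask, NULL)
  r <- 7.5
  ex <- exclude_soma(img, c(50, 50), r)
  excluded_area <- sum(ex$excluded_mask) * 0.25^2
  expect_lt(abs(excluded_area - pi * r^2) / (pi * r^2), 0.01)
  expect_equal(valid_area_um2(ex), 100^2 - excluded_area)
  # puncta with centroid inside the soma are dropped
  m <- matrix(FALSE, 400, 400)
  m[199:202, 199:202] <- TRUE  # centroid at the core
  m[40:43, 40:43] <- TRUE      # far away
  mask <- fl_image(m, 0.25, ex$excluded_mask)
  set <- detect_puncta(mask, 0.5, 10)
  expect_identical(nrow(set$puncta), 1L)
  expect_lt(set$puncta$x_um, 20)
})

test_that("point-path bin densities recover a uniform rate in every bin", {
  lambda <- 0.3
  field <- 280.8
  core <- c(field / 2, field / 2)
  layout <- build_bin_layout(core)
  per_bin <- 27^2 * lambda  # expectation 218.7
  counts <- matrix(NA_real_, 20, 17)
  for (s in 1:20) {
    cfg <- scene_config(field_size_um = field, pixel_size_um = 0.2,
                        channels = list(channel_spec("post", lambda)), seed = s)
    sc <- generate_scene(cfg, render = FALSE)
    pts <- sc$truth
    counts[s, ] <- bin_counts(pts$x_um, pts$y_um, layout, field)$n_puncta
  }
  means <- colMeans(counts)
  expect_true(all(abs(means - per_bin) < 3 * sqrt(per_bin / 20)))
})

test_that("empty images give all-zero densities; fully outside bins are missing", {
  img <- fl_image(matrix(0, 128, 128), 0.5)  # 64 x 64 um
  layout <- build_bin_layout(c(32, 32))
  out <- extract_bin_densities(img, layout, test_field_params())
  inside <- !out$missing
  expect_true(all(out$density[inside] == 0))
  # 90 and 120 um rings lie outside a 64 um field
  expect_true(all(out$missing[out$distance_um == 120]))
  expect_false(any(out$missing[out$distance_um == 0]))
})

test_that("clipped bins keep estimating the true rate via valid-area normalisation", {
  lambda <- 0.3
  field <- 220
  layout <- build_bin_layout(c(110, 110))  # the 120 um ring clips the field edge
  dens <- matrix(NA_real_, 30, 17)
  for (s in 1:30) {
    cfg <- scene_config(field_size_um = field, pixel_size_um = 0.5,
                        channels = list(channel_spec("post", lambda)), seed = 50 + s)
    sc <- generate_scene(cfg, render = FALSE)
    dens[s, ] <- bin_counts(sc$truth$x_um, sc$truth$y_um, layout, field)$density
  }
  a <- vapply(seq_len(17), function(b)
    astrodomain:::bin_valid_area_points(layout$center_x_um[b], layout$center_y_um[b],
                                        13.5, field), numeric(1))
  expect_true(all(a > 0 & a <= 27^2 + 1e-9))
  clipped <- a < 27^2 - 1e-9
  expect_true(any(clipped))  # the out ring genuinely loses area to the edge
  # pooled density of the clipped bins still estimates lambda (valid-area
  # normalisation), as does the pooled density of the full bins
  for (sel in list(clipped, !clipped)) {
    pooled <- mean(dens[, sel])
    se <- sqrt(lambda / (30 * sum(a[sel])))
    expect_lt(abs(pooled - lambda), 3 * se + 0.01 * lambda)
  }
})

test_that("distribution collapses classes in fixed order with missing-bin policy", {
  layout <- build_bin_layout(c(100, 100))
  bins <- as.data.frame(layout)
  bins$n_puncta <- 10L
  bins$valid_area_um2 <- 729
  bins$density <- 0.25
  bins$missing <- FALSE
  dd <- density_distribution(bins)
  expect_identical(as.character(dd$distance_class),
                   c("center", "close", "mid", "distant", "out"))
  expect_true(all(dd$mean_density == 0.25))
  expect_identical(dd$n_bins, c(1L, 4L, 4L, 4L, 4L))
  # a missing out-ring bin is omitted from its class mean, not zeroed
  bins$missing[17] <- TRUE
  bins$density[16] <- 0.5
  expect_message(dd2 <- density_distribution(bins), "missing")
  out_bins <- bins[bins$distance_class == "out" & !bins$missing, ]
  expect_equal(dd2$mean_density[5], mean(out_bins$density))
  expect_identical(dd2$n_bins[5], 3L)
})

test_that("image-path bin extraction matches truth counts on a rendered domain scene", {
  field <- 280.8
  core <- c(field / 2, field / 2)
  cfg <- scene_config(field_size_um = field, pixel_size_um = 0.15,
                      channels = list(channel_spec("post", 0.15)),
                      background_level = 800, noise_sd = 150,
                      blob_density_per_um2 = 0, seed = 17)
  pr <- radial_profile(c(0, 30, 60), c(1, 1.2, 1))
  sim <- generate_domain_scene(cfg, pr, core)
  layout <- build_bin_layout(core)
  img <- exclude_soma(scene_channel(sim$image, "post"), core, 7.5)
  params <- field_params(preprocess = test_preprocess(),
                         min_area_um2 = 0.05, max_area_um2 = 2)
  got <- extract_bin_densities(img, layout, params)
  want <- bin_counts(sim$truth$x_um, sim$truth$y_um, layout, field,
                     soma_radius_um = 7.5)
  expect_false(any(got$missing))
  # detection efficiency is uniform across bins (merging losses cap it below
  # 1; see the methods vignette)
  rel <- got$density / want$density
  expect_gt(mean(rel), 0.6)
  expect_lt(mean(rel), 1.05)
  expect_lt(stats::sd(rel), 0.15)
})

test_that("AP-like profiles depress inner classes; CA-like peaks at close", {
  field <- 280.8
  core <- c(field / 2, field / 2)
  layout <- build_bin_layout(core)
  ap <- radial_profile(c(0, 89, 91), c(0.6, 0.6, 1))
  ca <- radial_profile(c(0, 30, 60), c(1, 1.2, 1))
  ap_hits <- 0L; ca_hits <- 0L
  for (s in 1:20) {
    cfg <- scene_config(field_size_um = field, pixel_size_um = 0.2,
                        channels = list(channel_spec("post", 0.3)), seed = 600 + s)
    simap <- generate_domain_scene(cfg, ap, core, render = FALSE)
    dd <- density_distribution(bin_counts(simap$truth$x_um, simap$truth$y_um,
                                          layout, field))
    if (mean(dd$mean_density[1:4]) < dd$mean_density[5]) ap_hits <- ap_hits + 1L
    simca <- generate_domain_scene(cfg, ca, core, render = FALSE)
    ddc <- density_distribution(bin_counts(simca$truth$x_um, simca$truth$y_um,
                                           layout, field))
    if (which.max(ddc$mean_density) == 2L) ca_hits <- ca_hits + 1L
  }
  expect_gte(ap_hits, 18L)
  expect_gte(ca_hits, 15L)
})

test_that("class means recover the area-weighted profile expectation", {
  field <- 280.8
  core <- c(field / 2, field / 2)
  layout <- build_bin_layout(core)
  pr <- radial_profile(c(0, 40, 80, 120), c(1, 1.4, 0.7, 1))
  lambda <- 0.3
  # area-weighted mean multiplier per bin on a fine grid
  expected_bin <- vapply(seq_len(17), function(b) {
    gx <- seq(layout$center_x_um[b] - 13.5, layout$center_x_um[b] + 13.5,
              length.out = 60)
    gy <- seq(layout$center_y_um[b] - 13.5, layout$center_y_um[b] + 13.5,
              length.out = 60)
    g <- expand.grid(x = gx, y = gy)
    mean(profile_multiplier(pr, sqrt((g$x - core[1])^2 + (g$y - core[2])^2)))
  }, numeric(1)) * lambda
  dens <- matrix(NA_real_, 20, 17)
  for (s in 1:20) {
    cfg <- scene_config(field_size_um = field, pixel_size_um = 0.2,
                        channels = list(channel_spec("post", lambda)), seed = 800 + s)
    sim <- generate_domain_scene(cfg, pr, core, render = FALSE)
    dens[s, ] <- bin_counts(sim$truth$x_um, sim$truth$y_um, layout, field)$density
  }
  m <- colMeans(dens)
  tol <- 3 * sqrt(expected_bin * 27^2 / 20) / 27^2
  expect_true(all(abs(m - expected_bin) < tol))
})
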