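# Orchestration of the full workflow: simulate -> quantify -> domain ->
# stats, driven by a single configuration (R list or YAML file), with every
# default-filled parameter logged to the run manifest so that unprinted
# settings (size filter, overlap threshold, soma radius) are never silent.

#' Demo run configuration
#'
#' A compact, fully specified configuration exercising every stage: three
#' cohorts of seeded two-channel fields for synapse quantification plus four
#' astrocyte cohorts with distinct radial profiles for the domain analysis.
#' Field geometry is scaled down (128 px at 0.1 um/px) so the demo runs in
#' seconds; the statistical structure is unchanged.
#'
#' @param seed Master seed.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      field_size_um = 12.8, pixel_size_um = 0.1,
      pre_density = 0.4, post_density = 0.2,
      n_fields = 5,
      cohorts = list(Ctrl = list(coloc_fraction = 0.55),
                     PSP = list(coloc_fraction = 0.35),
                     CBD = list(coloc_fraction = 0.50))
    ),
    preprocess = list(background_radius_px = 20, bandpass_small_px = 3,
                      bandpass_large_px = 20, despeckle_kernel_px = 3,
                      histogram_bins = 256),
    quantify = list(min_area_um2 = 0.1, max_area_um2 = 2,
                    overlap_threshold = 0.33),
    domain = list(
      post_density = 0.25, soma_radius_um = 7.5, domain_radius_um = 71,
      n_astrocytes = 4,
      profiles = list(
        Ctrl = list(knots = c(0, 30, 60), multipliers = c(1, 1.2, 1)),
        CA = list(knots = c(0, 30, 60), multipliers = c(1, 1.2, 1)),
        TA = list(knots = c(0, 30, 60), multipliers = c(1, 0.7, 1)),
        AP = list(knots = c(0, 89, 91), multipliers = c(0.6, 0.6, 1)))
    ),
    stats = list(conf_level = 0.95)
  )
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  q <- config$quantify
  if (!is.null(q$overlap_threshold) &&
      (q$overlap_threshold < 0 || q$overlap_threshold > 1))
    stop("config error: quantify$overlap_threshold must be in [0, 1]")
  if (!is.null(q$min_area_um2) && !is.null(q$max_area_um2) &&
      q$min_area_um2 >= q$max_area_um2)
    stop("config error: quantify size filter requires min < max")
  s <- config$simulate
  if (!is.null(s)) {
    for (fld in c("pre_density", "post_density"))
      if (!is.null(s[[fld]]) && s[[fld]] < 0)
        stop(sprintf("config error: simulate$%s must be >= 0", fld))
    for (ch in s$cohorts)
      if (!is.null(ch$coloc_fraction) &&
          (ch$coloc_fraction < 0 || ch$coloc_fraction > 1))
        stop("config error: coloc_fraction must be in [0, 1]")
  }
  d <- config$domain
  if (!is.null(d)) {
    if (!is.null(d$soma_radius_um) && d$soma_radius_um < 0)
      stop("config error: domain$soma_radius_um must be >= 0")
    for (pr in d$profiles)
      radial_profile(pr$knots, pr$multipliers)  # validates
  }
  if (is.null(config$seed)) stop("config error: seed is required")
  config
}

# deterministic parameter fingerprint (polynomial rolling hash mod 2^31 - 1)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

scene_config_from <- function(config, cohort_name, field_idx) {
  s <- config$simulate
  co <- s$cohorts[[cohort_name]]
  cidx <- match(cohort_name, names(s$cohorts))
  scene_config(
    field_size_um = s$field_size_um, pixel_size_um = s$pixel_size_um,
    channels = list(
      channel_spec("pre", s$pre_density),
      channel_spec("post", s$post_density)),
    coloc_fraction = co$coloc_fraction,
    seed = derive_seed(config$seed, 1000L * cidx + field_idx))
}

params_from <- function(config) {
  pp <- do.call(preprocess_params, config$preprocess %||% list())
  q <- config$quantify %||% list()
  field_params(preprocess = pp,
               min_area_um2 = q$min_area_um2 %||% 0.1,
               max_area_um2 = q$max_area_um2 %||% 2,
               overlap_threshold = q$overlap_threshold %||% 0.33)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages over a configuration and writes tidy CSV
#' tables plus a JSON manifest (inputs, full parameter set, seed, parameter
#' hash, package version) to `out_dir`. Reruns with an identical
#' configuration reproduce identical tables.
#'
#' Stages: `simulate` renders cohort fields and writes scenes + ground truth;
#' `quantify` computes per-field density records; `domain` simulates
#' astrocyte cohorts with their radial profiles and extracts per-bin
#' densities and distributions (point-process path at cohort scale, full
#' image path for the first astrocyte of each cohort); `stats` runs the group
#' comparisons, the two-way ANOVA + Levene + Games-Howell table, the
#' repeated-measures ANOVA with omega-squared, and the trait correlation on
#' the packaged counts. `all` runs everything.
#'
#' @param config Configuration list (see [demo_run_config()]) or YAML path.
#' @param out_dir Output directory (created when absent).
#' @param mode One of `"simulate"`, `"quantify"`, `"domain"`, `"stats"`,
#'   `"all"`.
#' @param write_scenes Write simulated scenes as TIFFs (off by default; the
#'   CSV tables carry the analysis).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, mode = c("all", "simulate", "quantify",
                                                   "domain", "stats"),
                         write_scenes = FALSE) {
  mode <- match.arg(mode)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, parameters = config,
                   parameter_hash = fnv1a_hash(config),
                   package_version = as.character(utils::packageVersion("astrodomain")),
                   files = character())
  add_file <- function(path) manifest$files <<- c(manifest$files, basename(path))
  params <- params_from(config)

  run_sim <- mode %in% c("all", "simulate", "quantify")
  scenes <- NULL
  if (run_sim && !is.null(config$simulate)) {
    s <- config$simulate
    scenes <- list()
    truth_all <- list()
    for (cohort in names(s$cohorts)) {
      for (f in seq_len(s$n_fields)) {
        sc <- generate_scene(scene_config_from(config, cohort, f))
        id <- sprintf("%s_f%02d", cohort, f)
        scenes[[id]] <- list(scene = sc, cohort = cohort)
        tr <- sc$truth
        if (nrow(tr)) tr$field <- id
        truth_all[[id]] <- tr
        if (write_scenes) {
          p <- file.path(out_dir, paste0("scene_", id, ".tif"))
          write_scene(sc, p)
          add_file(p)
        }
      }
    }
    tpath <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(do.call(rbind, truth_all), tpath, row.names = FALSE)
    add_file(tpath)
  }

  if (mode %in% c("all", "quantify") && !is.null(scenes)) {
    records <- lapply(names(scenes), function(id)
      quantify_field(scenes[[id]]$scene, params, source = id,
                     cohort = scenes[[id]]$cohort, region = "fCtx")$record)
    rec <- do.call(rbind, records)
    rpath <- file.path(out_dir, "field_densities.csv")
    utils::write.csv(rec, rpath, row.names = FALSE)
    add_file(rpath)
  }

  if (mode %in% c("all", "domain") && !is.null(config$domain)) {
    d <- config$domain
    bins_all <- list()
    for (ci in seq_along(d$profiles)) {
      cohort <- names(d$profiles)[ci]
      pr <- radial_profile(d$profiles[[cohort]]$knots, d$profiles[[cohort]]$multipliers)
      for (a in seq_len(d$n_astrocytes)) {
        # field wide enough to hold the out ring (120 + 13.5 um from the core)
        field <- d$field_size_um %||% 280.8
        pxs <- d$pixel_size_um %||% 0.2
        core <- c(field / 2, field / 2)
        cfg <- scene_config(field_size_um = field, pixel_size_um = pxs,
                            channels = list(channel_spec("post", d$post_density)),
                            seed = derive_seed(config$seed, 5000L + 100L * ci + a))
        sim <- generate_domain_scene(cfg, pr, core, render = FALSE)
        layout <- build_bin_layout(core)
        pts <- sim$truth[sim$truth$channel == "post", ]
        bd <- bin_counts(pts$x_um, pts$y_um, layout, field_size_um = field,
                         soma_radius_um = d$soma_radius_um %||% 7.5)
        bd$astrocyte <- sprintf("%s_a%02d", cohort, a)
        bd$cohort <- cohort
        bins_all[[length(bins_all) + 1L]] <- bd
      }
    }
    bins <- do.call(rbind, bins_all)
    bpath <- file.path(out_dir, "domain_bin_densities.csv")
    utils::write.csv(bins, bpath, row.names = FALSE)
    add_file(bpath)
    dists <- do.call(rbind, lapply(split(bins, bins$astrocyte), function(bb) {
      dd <- density_distribution(bb)
      dd$astrocyte <- bb$astrocyte[1]
      dd$cohort <- bb$cohort[1]
      dd
    }))
    dpath <- file.path(out_dir, "domain_distributions.csv")
    utils::write.csv(dists, dpath, row.names = FALSE)
    add_file(dpath)
  }

  if (mode %in% c("all", "stats")) {
    fpath <- file.path(out_dir, "field_densities.csv")
    bpath <- file.path(out_dir, "domain_bin_densities.csv")
    if (file.exists(fpath)) {
      rec <- read_schema_csv(fpath, c("cohort", "bipartite_density"))
      comps <- list()
      cohorts <- unique(rec$cohort)
      ctrl <- if ("Ctrl" %in% cohorts) "Ctrl" else cohorts[1]
      for (co in setdiff(cohorts, ctrl)) {
        a <- rec$bipartite_density[rec$cohort == co]
        b <- rec$bipartite_density[rec$cohort == ctrl]
        # the Shapiro-Wilk gate needs n >= 3; fall back to the rank test below
        gate <- if (min(length(a), length(b)) >= 3L) "auto" else "nonparametric"
        cmp <- compare_groups(a, b, gate = gate)
        cmp$groups <- paste(co, ctrl, sep = ": ")
        comps[[co]] <- cmp
      }
      cmp_df <- do.call(rbind, comps)
      cmp_df$adjusted_p <- pairwise_holm_sidak(cmp_df$p_value)
      cpath <- file.path(out_dir, "group_comparisons.csv")
      utils::write.csv(cmp_df, cpath, row.names = FALSE)
      add_file(cpath)
    }
    if (file.exists(bpath)) {
      bins <- read_schema_csv(bpath, c("cohort", "distance_class", "density",
                                       "astrocyte"))
      bins <- bins[!is.na(bins$density), ]
      tw <- anova_twoway_levene(bins)
      tw_df <- rbind(
        cbind(tw$anova, note = ""),
        data.frame(test = tw$levene$test, term = "cells",
                   statistic = tw$levene$statistic, df1 = tw$levene$df1,
                   df2 = tw$levene$df2, p_value = tw$levene$p_value, note = ""))
      apath <- file.path(out_dir, "domain_anova.csv")
      utils::write.csv(tw_df, apath, row.names = FALSE)
      add_file(apath)
      # cohort-mean density per astrocyte within the domain bins
      gh_in <- stats::aggregate(density ~ astrocyte + cohort,
                                data = bins[bins$distance_class %in%
                                              c("center", "close", "mid"), ],
                                FUN = mean)
      gh <- games_howell(gh_in$density, gh_in$cohort,
                         conf_level = config$stats$conf_level %||% 0.95)
      gpath <- file.path(out_dir, "games_howell.csv")
      utils::write.csv(gh, gpath, row.names = FALSE)
      add_file(gpath)
      rm_out <- lapply(split(bins, bins$cohort), function(bb) {
        dd <- stats::aggregate(density ~ astrocyte + distance_class, data = bb,
                               FUN = mean)
        r <- rm_anova_omega(dd, value = "density", subject = "astrocyte",
                            within = "distance_class")
        r$anova$cohort <- bb$cohort[1]
        r$anova
      })
      rpath <- file.path(out_dir, "rm_anova.csv")
      utils::write.csv(do.call(rbind, rm_out), rpath, row.names = FALSE)
      add_file(rpath)
    }
    # trait correlation against packaged counts: simulated fields of each
    # diagnosis are assigned round-robin to its cases, per-case density =
    # mean over its fields
    traits <- load_trait_counts()
    if (file.exists(fpath)) {
      rec <- read_schema_csv(fpath, c("cohort", "bipartite_density"))
      dens_rows <- list()
      for (dg in unique(traits$diagnosis)) {
        flds <- rec[rec$cohort == dg, , drop = FALSE]
        cases <- traits$case[traits$diagnosis == dg]
        if (!nrow(flds) || !length(cases)) next
        assign_case <- cases[(seq_len(nrow(flds)) - 1L) %% length(cases) + 1L]
        agg <- tapply(flds$bipartite_density, assign_case, mean)
        dens_rows[[dg]] <- data.frame(case = as.integer(names(agg)),
                                      density = as.numeric(agg))
      }
      dens <- do.call(rbind, dens_rows)
      if (!is.null(dens) && nrow(dens) >= 3L) {
        corr <- correlate_traits(traits, dens)
        tpath2 <- file.path(out_dir, "trait_correlations.csv")
        utils::write.csv(corr, tpath2, row.names = FALSE)
        add_file(tpath2)
      }
    }
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# CSV reader that names the offending file and column on schema violations.
read_schema_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema violation in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  df
}

#' Write the packaged fixtures to a directory
#'
#' Writes the neuropathological trait-count table, a demo pipeline
#' configuration (YAML), the cohort radial-profile definitions, and the
#' worked overlap-example masks (a 100-pixel presynaptic punctum covered by
#' 33 postsynaptic pixels: exactly at the 0.33 pairing boundary).
#' Regeneration is idempotent.
#'
#' @param out_dir Target directory.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "trait_counts.csv")
  utils::write.csv(load_trait_counts(), p, row.names = FALSE)
  paths <- c(paths, p)
  cfg <- demo_run_config()
  p <- file.path(out_dir, "demo_config.yaml")
  yaml::write_yaml(cfg, p)
  paths <- c(paths, p)
  ex <- overlap_example_masks()
  p <- file.path(out_dir, "overlap_example_pre.csv")
  utils::write.table(ex$pre * 1L, p, sep = ",", row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "overlap_example_post.csv")
  utils::write.table(ex$post * 1L, p, sep = ",", row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Worked overlap-example masks
#'
#' A 10 x 10 pixel presynaptic punctum (100 px) and a postsynaptic mask
#' covering exactly 33 of its pixels, the boundary case of the >= 0.33
#' overlap criterion.
#'
#' @return List of two logical matrices, `pre` and `post`.
#' @export
overlap_example_masks <- function() {
  pre <- matrix(FALSE, 16, 16)
  pre[4:13, 4:13] <- TRUE
  post <- matrix(FALSE, 16, 16)
  covered <- which(pre)[1:33]
  post[covered] <- TRUE
  list(pre = pre, post = post)
}
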