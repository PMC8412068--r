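# 8-connected component labelling. EBImage::bwlabel labels 4-connected
# components; diagonal-only neighbours are then merged with a union-find
# pass, which yields exact 8-connectivity (pinned by the flood-fill oracle
# in the tests).
label_components <- function(m) {
  if (is.logical(m)) m <- m * 1
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl == 0L) return(lab)
  parent <- seq_len(nl)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merge_pairs <- function(a, b) {
    w <- which(a > 0L & b > 0L & a != b)
    for (k in w) {
      ra <- find_root(a[k]); rb <- find_root(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs(lab[-nr, -nc, drop = FALSE], lab[-1, -1, drop = FALSE])
  merge_pairs(lab[-1, -nc, drop = FALSE], lab[-nr, -1, drop = FALSE])
  roots <- vapply(seq_len(nl), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Detect puncta in a binary mask
#'
#' Labels 8-connected foreground components, discards components whose
#' physical area falls outside `[min_area_um2, max_area_um2]`, and reports
#' centroids and areas. Components touching the border are kept. Puncta whose
#' centroid falls on an excluded pixel are dropped, and the analysed field
#' area is the non-excluded area.
#'
#' @param mask A logical- (or 0/1-) valued [fl_image], e.g. from
#'   [preprocess()].
#' @param min_area_um2,max_area_um2 Size filter in square micrometres
#'   (inclusive bounds, `min < max`).
#' @param channel Optional channel label carried into the puncta table.
#' @param source Optional field identifier.
#' @return A `puncta_set`: list with `puncta` (data frame: `id`, `x_um`,
#'   `y_um`, `pixel_count`, `area_um2`, `channel`), `field_area_um2`,
#'   `pixel_size_um`, `source`; the filtered label matrix is attached as
#'   attribute `"labels"`.
#' @export
detect_puncta <- function(mask, min_area_um2 = 0.1, max_area_um2 = 2,
                          channel = NA_character_, source = NA_character_) {
  stopifnot(is_fl_image(mask))
  v <- mask$values
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) stop("mask must be binary (logical or 0/1)")
    v <- v > 0
  } else if (!is.logical(v)) {
    stop("mask must be binary (logical or 0/1)")
  }
  if (min_area_um2 >= max_area_um2) stop("size filter requires min < max")
  px <- mask$pixel_size_um
  px_area <- px^2
  lab <- label_components(v)
  n <- max(lab)
  puncta <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                       pixel_count = integer(), area_um2 = numeric(),
                       channel = character())
  if (n > 0L) {
    idx <- which(lab > 0L)
    li <- lab[idx]
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    count <- tabulate(li, n)
    cx <- rowsum(cols - 0.5, li)[, 1] / count * px
    cy <- rowsum(rows - 0.5, li)[, 1] / count * px
    puncta <- data.frame(id = seq_len(n), x_um = cx, y_um = cy,
                         pixel_count = count, area_um2 = count * px_area,
                         channel = rep(channel, n))
    keep <- puncta$area_um2 >= min_area_um2 & puncta$area_um2 <= max_area_um2
    # drop puncta whose centroid is excluded
    if (!is.null(mask$excluded_mask)) {
      ci <- pmin(pmax(ceiling(puncta$y_um / px), 1L), nrow(lab))
      cj <- pmin(pmax(ceiling(puncta$x_um / px), 1L), ncol(lab))
      keep <- keep & !mask$excluded_mask[cbind(ci, cj)]
    }
    puncta <- puncta[keep, , drop = FALSE]
    rownames(puncta) <- NULL
    lab[!(lab %in% puncta$id)] <- 0L
  }
  structure(list(puncta = puncta,
                 field_area_um2 = valid_area_um2(mask),
                 pixel_size_um = px,
                 source = source),
            class = "puncta_set", labels = lab)
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta over %.5g um^2 (%.4g per um^2)\n",
              nrow(x$puncta), x$field_area_um2, puncta_density(x)))
  invisible(x)
}

#' Puncta density of a field
#'
#' @param set A `puncta_set` from [detect_puncta()].
#' @return Puncta per square micrometre of analysed (non-excluded) area.
#' @export
puncta_density <- function(set) {
  stopifnot(inherits(set, "puncta_set"))
  if (set$field_area_um2 <= 0) stop("field area must be positive")
  nrow(set$puncta) / set$field_area_um2
}

#' Call bipartite synapses by the overlap-fraction criterion
#'
#' For every presynaptic punctum, the overlap fraction is the share of its
#' pixels that are also foreground in the postsynaptic mask (the presynaptic
#' punctum area is the denominator). A pair is emitted iff the fraction
#' reaches `threshold`; the reported partner is the postsynaptic component
#' contributing the most overlapping pixels (ties broken by the lowest post
#' id). With `post_set` supplied, overlap is computed against that set's
#' size-filtered puncta instead of the raw post foreground.
#'
#' @param pre A `puncta_set` for the presynaptic channel.
#' @param post_mask Logical-valued [fl_image] of the postsynaptic channel.
#' @param threshold Minimum overlap fraction (default 0.33).
#' @param post_set Optional `puncta_set` for the postsynaptic channel; when
#'   given, only its (size-filtered) puncta count as post foreground.
#' @return Data frame with `pre_id`, `post_id`, `overlap_fraction`; one row
#'   per paired presynaptic punctum (each `pre_id` at most once).
#' @export
pair_bipartite <- function(pre, post_mask, threshold = 0.33, post_set = NULL) {
  stopifnot(inherits(pre, "puncta_set"), is_fl_image(post_mask))
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  prelab <- attr(pre, "labels")
  if (!identical(dim(prelab), dim(post_mask$values)))
    stop("pre puncta and post mask do not share geometry")
  if (abs(pre$pixel_size_um - post_mask$pixel_size_um) > 1e-9)
    stop("pre puncta and post mask do not share pixel size")
  empty <- data.frame(pre_id = integer(), post_id = integer(),
                      overlap_fraction = numeric())
  if (nrow(pre$puncta) == 0L) return(empty)
  if (is.null(post_set)) {
    postfg <- post_mask$values > 0
    if (!is.null(post_mask$excluded_mask)) postfg[post_mask$excluded_mask] <- FALSE
    postlab <- label_components(postfg)
  } else {
    postlab <- attr(post_set, "labels")
    postfg <- postlab > 0L
  }
  sel <- which(prelab > 0L)
  ov <- rowsum(as.numeric(postfg[sel]), prelab[sel])
  ov_ids <- as.integer(rownames(ov))
  m <- match(pre$puncta$id, ov_ids)
  frac <- ov[m, 1] / pre$puncta$pixel_count
  paired <- which(frac >= threshold)
  if (!length(paired)) return(empty)
  # best-overlapping post component per paired pre punctum
  joint <- sel[postlab[sel] > 0L]
  best <- rep(NA_integer_, length(paired))
  if (length(joint)) {
    dfj <- data.frame(pre = prelab[joint], post = postlab[joint])
    cnt <- stats::aggregate(list(n = rep(1L, nrow(dfj))),
                            by = list(pre = dfj$pre, post = dfj$post), FUN = sum)
    cnt <- cnt[order(cnt$pre, -cnt$n, cnt$post), , drop = FALSE]
    top <- cnt[!duplicated(cnt$pre), , drop = FALSE]
    best <- top$post[match(pre$puncta$id[paired], top$pre)]
  }
  data.frame(pre_id = pre$puncta$id[paired],
             post_id = best,
             overlap_fraction = unname(frac[paired]))
}

#' Field-quantification parameters
#'
#' @param preprocess A [preprocess_params].
#' @param min_area_um2,max_area_um2 Punctum size filter.
#' @param overlap_threshold Bipartite overlap-fraction threshold.
#' @param pre_channel,post_channel Channel roles.
#' @param post_filtered Compute overlap against the size-filtered post puncta
#'   instead of the raw post foreground.
#' @return A `field_params` list.
#' @export
field_params <- function(preprocess = preprocess_params(),
                         min_area_um2 = 0.1, max_area_um2 = 2,
                         overlap_threshold = 0.33,
                         pre_channel = "pre", post_channel = "post",
                         post_filtered = FALSE) {
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stop("`overlap_threshold` must be in [0, 1]")
  if (min_area_um2 >= max_area_um2) stop("size filter requires min < max")
  structure(list(preprocess = preprocess, min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2, overlap_threshold = overlap_threshold,
                 pre_channel = pre_channel, post_channel = post_channel,
                 post_filtered = isTRUE(post_filtered)),
            class = "field_params")
}

#' Quantify one field: densities and bipartite synapse calls
#'
#' Runs the pre-processing chain and puncta detection on the pre- and
#' postsynaptic channels and calls bipartite synapses by the overlap
#' criterion, yielding one per-field density record.
#'
#' @param scene An [fl_scene] (or `sim_scene`).
#' @param params A [field_params].
#' @param source Field identifier for the record.
#' @param cohort,region Optional labels carried into the record.
#' @return A list of class `field_quant`: `record` (one-row data frame with
#'   `pre_density`, `post_density`, `bipartite_density` in puncta per um^2
#'   and the thresholds in force), `pre`, `post` (`puncta_set`s), `pairs`.
#' @export
quantify_field <- function(scene, params = field_params(), source = NA_character_,
                           cohort = NA_character_, region = NA_character_) {
  if (inherits(scene, "sim_scene")) scene <- scene$image
  stopifnot(inherits(scene, "fl_scene"), inherits(params, "field_params"))
  pre_img <- scene_channel(scene, params$pre_channel)
  post_img <- scene_channel(scene, params$post_channel)
  pre_mask <- preprocess(pre_img, params$preprocess)
  post_mask <- preprocess(post_img, params$preprocess)
  pre_set <- detect_puncta(pre_mask, params$min_area_um2, params$max_area_um2,
                           channel = params$pre_channel, source = source)
  post_set <- detect_puncta(post_mask, params$min_area_um2, params$max_area_um2,
                            channel = params$post_channel, source = source)
  pairs <- pair_bipartite(pre_set, post_mask, params$overlap_threshold,
                          post_set = if (params$post_filtered) post_set)
  area <- pre_set$field_area_um2
  record <- data.frame(source = source, cohort = cohort, region = region,
                       pre_density = puncta_density(pre_set),
                       post_density = puncta_density(post_set),
                       bipartite_density = nrow(pairs) / area,
                       n_pre = nrow(pre_set$puncta), n_post = nrow(post_set$puncta),
                       n_pairs = nrow(pairs),
                       overlap_threshold = params$overlap_threshold,
                       min_area_um2 = params$min_area_um2,
                       max_area_um2 = params$max_area_um2)
  structure(list(record = record, pre = pre_set, post = post_set, pairs = pairs),
            class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  r <- x$record
  cat(sprintf("<field_quant> pre %.4g, post %.4g, bipartite %.4g per um^2 (%d pairs)\n",
              r$pre_density, r$post_density, r$bipartite_density, r$n_pairs))
  invisible(x)
}
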