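#' Shapiro-Wilk normality gate
#'
#' Decides the downstream two-group test family: parametric when normality
#' is not rejected at `alpha`, nonparametric otherwise.
#'
#' @param x Numeric sample, `n >= 3`, non-constant.
#' @param alpha Rejection level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("normality gate needs n >= 3")
  if (stats::sd(x) == 0) stop("normality gate is undefined for a constant sample")
  p <- stats::shapiro.test(x)$p.value
  if (p >= alpha) "parametric" else "nonparametric"
}

#' Two-group comparison gated on normality
#'
#' Welch's unequal-variance t-test (two-sided) when the gate is parametric,
#' two-sided Mann-Whitney U otherwise. With `gate = "auto"`, both samples
#' are gated with [normality_gate()] and the parametric branch is taken only
#' when neither rejects.
#'
#' @param a,b Numeric samples.
#' @param gate `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param alpha Gate level for `"auto"`.
#' @return One-row data frame: `test`, `groups`, `statistic`, `df`,
#'   `p_value`, `mean_difference`, `ci_lower`, `ci_upper`.
#' @export
compare_groups <- function(a, b, gate = c("auto", "parametric", "nonparametric"),
                           alpha = 0.05) {
  gate <- match.arg(gate)
  if (gate == "auto") {
    gate <- if (normality_gate(a, alpha) == "parametric" &&
                normality_gate(b, alpha) == "parametric")
      "parametric" else "nonparametric"
  }
  if (gate == "parametric") {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(test = "Welch t-test", groups = "a:b",
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value,
               mean_difference = mean(a) - mean(b),
               ci_lower = ht$conf.int[1], ci_upper = ht$conf.int[2])
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(test = "Mann-Whitney U", groups = "a:b",
               statistic = unname(ht$statistic), df = NA_real_,
               p_value = ht$p.value,
               mean_difference = stats::median(a) - stats::median(b),
               ci_lower = NA_real_, ci_upper = NA_real_)
  }
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak correction: the i-th smallest p-value is adjusted to
#' `1 - (1 - p)^(m - i + 1)`, with monotonicity enforced and capping at 1.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
pairwise_holm_sidak <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return List: `anova` (one-row data frame with F, dfs, p) and `tukey`
#'   (pairwise data frame with mean differences, CIs and adjusted p).
#' @export
anova_oneway_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  res <- data.frame(test = "one-way ANOVA", term = "groups",
                    statistic = s[["F value"]][1],
                    df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                    p_value = s[["Pr(>F)"]][1])
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(groups = rownames(tk),
                      mean_difference = tk[, "diff"],
                      ci_lower = tk[, "lwr"], ci_upper = tk[, "upr"],
                      adjusted_p = tk[, "p adj"])
  rownames(tukey) <- NULL
  list(anova = res, tukey = tukey)
}

#' Two-way fixed-effects ANOVA with Levene homogeneity check
#'
#' Fits `response ~ A * B` on the long table (e.g. bin-level densities by
#' cohort and distance class) and reports the factor and interaction tests
#' together with a Brown-Forsythe Levene test (centre = median) across the
#' A x B cells.
#'
#' @param data Long-format data frame.
#' @param response,factor_a,factor_b Column names.
#' @return List: `anova` (data frame, one row per term) and `levene`
#'   (one-row data frame).
#' @export
anova_twoway_levene <- function(data, response = "density",
                                factor_a = "cohort", factor_b = "distance_class") {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) stop(sprintf("column '%s' not in data", col))
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  fit <- stats::aov(y ~ A * B)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  res <- data.frame(test = "two-way ANOVA",
                    term = c(factor_a, factor_b,
                             paste(factor_a, factor_b, sep = ":"))[seq_len(sum(keep))],
                    statistic = s[["F value"]][keep],
                    df1 = s[["Df"]][keep], df2 = s[["Df"]][!keep][1],
                    p_value = s[["Pr(>F)"]][keep])
  lv <- car::leveneTest(y ~ A * B, center = stats::median)
  levene <- data.frame(test = "Levene (Brown-Forsythe)",
                       statistic = lv[["F value"]][1],
                       df1 = lv[["Df"]][1], df2 = lv[["Df"]][2],
                       p_value = lv[["Pr(>F)"]][1])
  list(anova = res, levene = levene)
}

#' Games-Howell post hoc comparisons
#'
#' Pairwise comparisons for unequal variances: per pair, the standard error
#' is `sqrt(s1^2/n1 + s2^2/n2)`, degrees of freedom are Welch-Satterthwaite,
#' and the p-value and confidence limits come from the studentized-range
#' distribution with `q = |diff| * sqrt(2) / SE` and `k` the total number of
#' groups.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param conf_level Confidence level of the limits.
#' @return Data frame in the domain-analysis table schema: `groups`,
#'   `mean_difference`, `standard_error`, `t_value`, `df`, `p_value`,
#'   `ci_upper`, `ci_lower`.
#' @export
games_howell <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  g <- levels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  if (any(n < 2L)) stop("every group needs n >= 2")
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    diff <- m[i] - m[j]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- (v[i] / n[i] + v[j] / n[j])^2 /
      ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    tval <- abs(diff) / se
    p <- stats::ptukey(tval * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    qc <- stats::qtukey(conf_level, nmeans = k, df = df) / sqrt(2)
    data.frame(groups = paste(g[i], g[j], sep = ": "),
               mean_difference = unname(diff),
               standard_error = unname(se),
               t_value = unname(tval),
               df = unname(df),
               p_value = unname(p),
               ci_upper = unname(diff + qc * se),
               ci_lower = unname(diff - qc * se))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated-measures one-way ANOVA with omega-squared effect size
#'
#' Within-subject one-way ANOVA across the distance classes of the domain
#' analysis (one row per subject and class), with the low-bias omega-squared
#' effect size `df_e (MS_e - MS_err) / (SS_total + MS_subject)` and a paired
#' Holm-Sidak post hoc. Negative omega-squared estimates are reported as
#' computed. When the class effect sum of squares is exactly zero the F
#' statistic is defined as 0 with p = 1 (the 0/0 case of identical class
#' profiles).
#'
#' @param data Long-format data frame.
#' @param value,subject,within Column names: response, subject id, within
#'   factor.
#' @return List: `anova` (one-row data frame with F, dfs, p and
#'   `effect_size` = omega squared) and `posthoc` (paired comparisons with
#'   Holm-Sidak-adjusted p).
#' @export
rm_anova_omega <- function(data, value = "density", subject = "astrocyte",
                           within = "distance_class") {
  for (col in c(value, subject, within))
    if (!col %in% names(data)) stop(sprintf("column '%s' not in data", col))
  y <- data[[value]]
  subj <- factor(data[[subject]])
  cls <- factor(data[[within]])
  tab <- table(subj, cls)
  if (any(tab != 1L)) {
    complete <- rownames(tab)[apply(tab == 1L, 1, all)]
    if (length(complete) < 2L)
      stop("repeated-measures ANOVA needs >= 2 subjects complete in every class")
    message(sprintf("dropping %d incomplete subject(s)", nlevels(subj) - length(complete)))
    keep <- subj %in% complete
    y <- y[keep]; subj <- droplevels(subj[keep]); cls <- droplevels(cls[keep])
  }
  n <- nlevels(subj); k <- nlevels(cls)
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  ss_subj <- k * sum((tapply(y, subj, mean) - gm)^2)
  ss_cls <- n * sum((tapply(y, cls, mean) - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cls
  df_cls <- k - 1L
  df_err <- (n - 1L) * (k - 1L)
  ms_cls <- ss_cls / df_cls
  ms_err <- ss_err / df_err
  ms_subj <- ss_subj / (n - 1L)
  if (ss_cls <= .Machine$double.eps * max(ss_tot, 1)) {
    f <- 0; p <- 1
  } else if (ms_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_cls / ms_err
    p <- stats::pf(f, df_cls, df_err, lower.tail = FALSE)
  }
  omega2 <- (df_cls * (ms_cls - ms_err)) / (ss_tot + ms_subj)
  res <- data.frame(test = "repeated-measures one-way ANOVA", term = within,
                    statistic = f, df1 = df_cls, df2 = df_err, p_value = p,
                    effect_size = omega2, n_subjects = n)
  # paired post hoc across class levels
  lv <- levels(cls)
  prs <- utils::combn(length(lv), 2)
  wide <- tapply(y, list(subj, cls), mean)
  ph <- lapply(seq_len(ncol(prs)), function(c_) {
    i <- prs[1, c_]; j <- prs[2, c_]
    d <- wide[, i] - wide[, j]
    if (stats::sd(d) == 0) {
      data.frame(groups = paste(lv[i], lv[j], sep = ": "),
                 mean_difference = mean(d), standard_error = 0,
                 statistic = if (mean(d) == 0) 0 else Inf,
                 df = n - 1, p_value = if (mean(d) == 0) 1 else 0,
                 ci_lower = mean(d), ci_upper = mean(d))
    } else {
      ht <- stats::t.test(d)
      data.frame(groups = paste(lv[i], lv[j], sep = ": "),
                 mean_difference = mean(d),
                 standard_error = stats::sd(d) / sqrt(n),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 ci_lower = ht$conf.int[1], ci_upper = ht$conf.int[2])
    }
  })
  posthoc <- do.call(rbind, ph)
  posthoc$adjusted_p <- pairwise_holm_sidak(posthoc$p_value)
  rownames(posthoc) <- NULL
  list(anova = res, posthoc = posthoc)
}

#' Correlate neuropathological trait counts with synapse densities
#'
#' Pearson correlation (two-sided) of each trait column against the per-case
#' density, within each diagnosis cohort. The neuropil-thread grade enters as
#' a numeric 0-5 score; Spearman rank correlation is available behind
#' `method`.
#'
#' @param traits Data frame with `case`, `diagnosis` and trait columns (see
#'   [load_trait_counts()]).
#' @param densities Data frame with `case` and `density` columns.
#' @param trait_cols Trait columns to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame: `diagnosis`, `trait`, `r`, `p_value`, `n`.
#' @export
correlate_traits <- function(traits, densities,
                             trait_cols = c("ta_ap", "nft_pretangles", "cb", "nt_grade"),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  merged <- merge(traits, densities, by = "case")
  if (!nrow(merged)) stop("no cases shared between traits and densities")
  out <- list()
  for (dg in unique(merged$diagnosis)) {
    sub <- merged[merged$diagnosis == dg, , drop = FALSE]
    for (tc in trait_cols) {
      if (nrow(sub) < 3L) next
      ct <- suppressWarnings(stats::cor.test(sub[[tc]], sub$density, method = method))
      out[[length(out) + 1L]] <- data.frame(diagnosis = dg, trait = tc,
                                            r = unname(ct$estimate),
                                            p_value = ct$p.value, n = nrow(sub))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Packaged neuropathological trait counts
#'
#' Per-case counts of tufted astrocytes / astrocytic plaques (`ta_ap`),
#' neurofibrillary tangles and pretangles (`nft_pretangles`), coiled bodies
#' (`cb`) per ten 250x visual fields, and the semi-quantitative neuropil
#' thread grade (`nt_grade`, 0-5), for the three PSP and three CBD cases.
#'
#' @return Data frame with columns `case`, `diagnosis`, `ta_ap`,
#'   `nft_pretangles`, `cb`, `nt_grade`.
#' @export
load_trait_counts <- function() {
  path <- system.file("extdata", "trait_counts.csv", package = "astrodomain",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
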