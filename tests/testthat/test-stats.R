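test_that("normality gate routes by Shapiro-Wilk and rejects degenerate input", {
  par_hits <- 0L; nonpar_hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    if (normality_gate(rnorm(50)) == "parametric") par_hits <- par_hits + 1L
    if (normality_gate(rexp(50)) == "nonparametric") nonpar_hits <- nonpar_hits + 1L
  }
  expect_gte(par_hits, 180L)
  expect_gte(nonpar_hits, 180L)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(4, 10)), "constant")
})

test_that("two-group comparison: identity, power, and branch selection", {
  a <- c(1.1, 2.3, 0.7, 1.9, 1.4, 2.2, 0.9, 1.6)
  same <- compare_groups(a, a, gate = "parametric")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)
  # 5-SD shift at n = 20/20 is detected decisively
  set.seed(99)
  x <- rnorm(20); y <- rnorm(20) + 5
  expect_lt(compare_groups(x, y, gate = "parametric")$p_value, 1e-3)
  expect_lt(compare_groups(x, y, gate = "nonparametric")$p_value, 1e-3)
  expect_identical(compare_groups(x, y, gate = "nonparametric")$test,
                   "Mann-Whitney U")
})

test_that("Welch and Mann-Whitney type-I error is calibrated at alpha = 0.05", {
  n_rej_t <- 0L; n_rej_u <- 0L
  reps <- 2000
  for (s in 1:reps) {
    set.seed(10000 + s)
    x <- rnorm(10); y <- rnorm(10)
    if (compare_groups(x, y, gate = "parametric")$p_value < 0.05)
      n_rej_t <- n_rej_t + 1L
    if (compare_groups(x, y, gate = "nonparametric")$p_value < 0.05)
      n_rej_u <- n_rej_u + 1L
  }
  expect_gt(n_rej_t / reps, 0.035)
  expect_lt(n_rej_t / reps, 0.065)
  expect_gt(n_rej_u / reps, 0.025)  # exact U test is conservative at n = 10
  expect_lt(n_rej_u / reps, 0.065)
})

test_that("Holm-Sidak matches the closed form and preserves ordering", {
  expect_equal(pairwise_holm_sidak(0.04), 0.04)
  adj <- pairwise_holm_sidak(c(0.05, 0.05, 0.05))
  expect_equal(adj, rep(1 - (1 - 0.05)^3, 3))
  expect_equal(adj[1], 0.142625)
  set.seed(7)
  p <- runif(12)
  adj2 <- pairwise_holm_sidak(p)
  # monotone in the raw p-values (ties allowed after step-down enforcement)
  expect_true(all(diff(adj2[order(p)]) >= -1e-15))
  expect_true(all(adj2 >= p & adj2 <= 1))
  # the smallest p dominates the tail through monotonicity enforcement here
  expect_equal(pairwise_holm_sidak(c(0.9, 0.95, 0.99)), rep(1 - 0.1^3, 3),
               tolerance = 1e-12)
})

test_that("one-way ANOVA: degenerate equality, k = 2 identity, Tukey table", {
  g <- rep(c("a", "b", "c"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 3)
  res <- anova_oneway_tukey(v, g)
  expect_lt(res$anova$statistic, 1e-12)
  expect_gt(res$anova$p_value, 0.999)
  expect_identical(nrow(res$tukey), 3L)
  # at k = 2 the F statistic is the square of the pooled t statistic
  set.seed(31)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  res2 <- anova_oneway_tukey(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res2$anova$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$anova$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("one-way ANOVA type-I error is calibrated", {
  rej <- 0L
  reps <- 2000
  for (s in 1:reps) {
    set.seed(20000 + s)
    v <- rnorm(24)
    g <- rep(c("a", "b", "c"), each = 8)
    if (anova_oneway_tukey(v, g)$anova$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.035)
  expect_lt(rej / reps, 0.065)
})

test_that("two-way ANOVA p-values are uniform under the null", {
  reps <- 500
  p_a <- p_b <- numeric(reps)
  for (s in 1:reps) {
    set.seed(30000 + s)
    df <- expand.grid(cohort = c("g1", "g2"), distance_class = paste0("c", 1:5),
                      rep = 1:4)
    df$density <- rnorm(nrow(df))
    res <- anova_twoway_levene(df)$anova
    p_a[s] <- res$p_value[res$term == "cohort"]
    p_b[s] <- res$p_value[res$term == "distance_class"]
  }
  expect_gt(stats::ks.test(p_a, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(p_b, "punif")$p.value, 0.01)
})

test_that("two-way ANOVA detects a one-SD cohort effect; Levene flags heteroscedasticity", {
  reps <- 100
  hits <- 0L
  for (s in 1:reps) {
    set.seed(40000 + s)
    df <- expand.grid(cohort = c("g1", "g2"), distance_class = paste0("c", 1:5),
                      rep = 1:12)
    df$density <- rnorm(nrow(df)) + (df$cohort == "g2") * 1
    res <- anova_twoway_levene(df)$anova
    if (res$p_value[res$term == "cohort"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
  # Brown-Forsythe flags a 4x variance ratio (two of four cohorts of n = 20
  # at twice the SD)
  lev_hits <- 0L
  for (s in 1:reps) {
    set.seed(50000 + s)
    df <- data.frame(cohort = factor(rep(c("g1", "g2", "g3", "g4"), each = 20)),
                     density = c(rnorm(40, 0, 2), rnorm(40, 0, 1)))
    lv <- car::leveneTest(density ~ cohort, data = df, center = stats::median)
    if (lv[["Pr(>F)"]][1] < 0.05) lev_hits <- lev_hits + 1L
  }
  expect_gte(lev_hits / reps, 0.8)
})

test_that("Games-Howell reduces to Welch at k = 2 and to Tukey for equal variances", {
  set.seed(61)
  for (rep in 1:20) {
    x <- rnorm(8, sd = runif(1, 0.5, 2))
    y <- rnorm(14, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    gh <- games_howell(c(x, y), rep(c("a", "b"), c(8, 14)))
    wt <- stats::t.test(x, y, var.equal = FALSE)
    expect_lt(abs(gh$p_value - wt$p.value), 2e-3)
    expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-9)
    expect_equal(gh$standard_error,
                 sqrt(stats::var(x) / 8 + stats::var(y) / 14), tolerance = 1e-12)
  }
  # identical groups: zero difference, p = 1
  z <- c(1, 2, 3, 4, 5)
  gh0 <- games_howell(c(z, z), rep(c("a", "b"), each = 5))
  expect_equal(gh0$mean_difference, 0)
  expect_equal(gh0$p_value, 1)
  # equal variances, large equal n: agrees with Tukey HSD within 5% relative
  set.seed(62)
  v <- rnorm(300); g <- rep(c("a", "b", "c"), each = 100)
  v[g == "b"] <- v[g == "b"] + 0.25
  gh3 <- games_howell(v, g)
  tk <- anova_oneway_tukey(v, g)$tukey
  key <- function(x) vapply(strsplit(gsub("[^a-z]", "", tolower(x)), ""),
                            function(ch) paste(sort(ch), collapse = ""), "")
  tkp <- tk$adjusted_p[match(key(gh3$groups), key(tk$groups))]
  expect_false(anyNA(tkp))
  expect_true(all(abs(gh3$p_value - tkp) / pmax(tkp, 1e-6) < 0.05))
})

test_that("Games-Howell output carries the domain-analysis table schema", {
  set.seed(63)
  v <- rnorm(40)
  g <- rep(c("PSP_CA", "PSP_TA", "CBD_AP", "Ctrl"), each = 10)
  gh <- games_howell(v, g)
  expect_identical(names(gh), c("groups", "mean_difference", "standard_error",
                                "t_value", "df", "p_value", "ci_upper", "ci_lower"))
  expect_identical(nrow(gh), 6L)
  expect_true(all(gh$ci_lower <= gh$mean_difference & gh$mean_difference <= gh$ci_upper))
  expect_true(all(gh$p_value >= 0 & gh$p_value <= 1))
})

test_that("repeated-measures ANOVA handles identical profiles and recovers effects", {
  # identical class values per subject: F defined as 0, p = 1, omega^2 <= 0
  df0 <- expand.grid(astrocyte = paste0("a", 1:6), distance_class = paste0("c", 1:5))
  df0$density <- as.numeric(factor(df0$astrocyte))  # subject offsets only
  r0 <- rm_anova_omega(df0)
  expect_equal(r0$anova$statistic, 0)
  expect_equal(r0$anova$p_value, 1)
  expect_lte(r0$anova$effect_size, 0)
  # cross-check F and p against aov with an Error stratum
  set.seed(71)
  df <- expand.grid(astrocyte = paste0("a", 1:8), distance_class = paste0("c", 1:5))
  df$density <- rnorm(40) + rep(rnorm(8), 5) + (df$distance_class == "c2") * 0.8
  r <- rm_anova_omega(df)
  fit <- summary(stats::aov(density ~ distance_class + Error(astrocyte), data = df))
  ftab <- fit[["Error: Within"]][[1]]
  expect_equal(r$anova$statistic, ftab[["F value"]][1], tolerance = 1e-9)
  expect_equal(r$anova$p_value, ftab[["Pr(>F)"]][1], tolerance = 1e-9)
  # empirical power for a one-within-SD effect on one of five classes at
  # n = 12 matches the noncentral-F prediction (ncp = 12 * sum(dev^2) = 9.6)
  hits <- 0L
  for (s in 1:200) {
    set.seed(80000 + s)
    dfp <- expand.grid(astrocyte = paste0("a", 1:12), distance_class = paste0("c", 1:5))
    dfp$density <- rnorm(60) + rep(rnorm(12), 5) + (dfp$distance_class == "c3") * 1
    if (rm_anova_omega(dfp)$anova$p_value < 0.05) hits <- hits + 1L
  }
  theory <- stats::pf(stats::qf(0.95, 4, 44), 4, 44, ncp = 9.6, lower.tail = FALSE)
  se <- sqrt(theory * (1 - theory) / 200)
  expect_lt(abs(hits / 200 - theory), 3 * se)
})

test_that("omega-squared is near zero under the null and its test is calibrated", {
  reps <- 500
  om <- numeric(reps)
  rej <- 0L
  for (s in 1:reps) {
    set.seed(90000 + s)
    df <- expand.grid(astrocyte = paste0("a", 1:10), distance_class = paste0("c", 1:5))
    df$density <- rnorm(50) + rep(rnorm(10), 5)
    r <- rm_anova_omega(df)
    om[s] <- r$anova$effect_size
    if (r$anova$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(mean(om)), 0.05)
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.075)
})

test_that("paired Holm-Sidak post hoc accompanies the repeated-measures ANOVA", {
  set.seed(72)
  df <- expand.grid(astrocyte = paste0("a", 1:9), distance_class = paste0("c", 1:4))
  df$density <- rnorm(36) + (df$distance_class == "c1") * 2
  r <- rm_anova_omega(df)
  expect_identical(nrow(r$posthoc), 6L)
  expect_true(all(r$posthoc$adjusted_p >= r$posthoc$p_value))
  sig <- grepl("c1", r$posthoc$groups)
  expect_true(all(r$posthoc$adjusted_p[sig] < 0.05))
})

test_that("trait correlations reproduce exact linear relations and invariances", {
  traits <- load_trait_counts()
  expect_identical(nrow(traits), 6L)
  r108 <- traits[traits$case == 108, ]
  expect_identical(r108$diagnosis, "CBD")
  expect_identical(c(r108$ta_ap, r108$nft_pretangles, r108$cb, r108$nt_grade),
                   c(94L, 134L, 34L, 5L))
  # densities exactly linear in the CBD astro-trait counts give R = -1
  cbd <- traits[traits$diagnosis == "CBD", ]
  dens <- data.frame(case = cbd$case, density = -cbd$ta_ap)
  out <- correlate_traits(traits, dens)
  r_ap <- out[out$diagnosis == "CBD" & out$trait == "ta_ap", ]
  expect_equal(r_ap$r, -1)
  # affine invariance of Pearson R
  dens2 <- data.frame(case = cbd$case, density = 100 - 0.004 * cbd$ta_ap)
  out2 <- correlate_traits(traits, dens2)
  expect_equal(out2[out2$diagnosis == "CBD" & out2$trait == "ta_ap", "r"], -1)
  expect_identical(names(out), c("diagnosis", "trait", "r", "p_value", "n"))
})
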