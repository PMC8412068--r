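#!/usr/bin/env Rscript
# Stage 4 -- the statistical workflow over the domain distributions.
#
# (a) Two-way ANOVA (cohort x distance class) on bin-level densities with a
#     Brown-Forsythe Levene check, followed by Games-Howell pairwise
#     comparisons of astrocyte-level domain densities (center+close+mid
#     bins), written in the standard domain-analysis table schema.
# (b) Per-cohort repeated-measures ANOVA across the five distance classes
#     with omega^2 effect sizes and paired Holm-Sidak post hocs.
# (c) Pearson correlation of the packaged neuropathological trait counts
#     with per-case bipartite densities from stage 2.

suppressMessages(library(astrodomain))

bins <- read.csv("results/domain_bin_densities.csv")
bins <- bins[!is.na(bins$density), ]
bins$distance_class <- factor(bins$distance_class,
                              levels = c("center", "close", "mid", "distant", "out"),
                              ordered = TRUE)

## (a) two-way ANOVA + Levene + Games-Howell
tw <- anova_twoway_levene(bins)
cat("two-way ANOVA (density ~ cohort x distance_class):\n")
print(tw$anova, row.names = FALSE)
cat(sprintf("Levene (Brown-Forsythe): F = %.3f, p = %.4g\n\n",
            tw$levene$statistic, tw$levene$p_value))

dom <- bins[bins$distance_class %in% c("center", "close", "mid"), ]
per_astro <- aggregate(density ~ astrocyte + cohort, data = dom, FUN = mean)
gh <- games_howell(per_astro$density, per_astro$cohort)
write.csv(gh, "results/games_howell.csv", row.names = FALSE)
cat("Games-Howell on astrocyte-level domain densities:\n")
print(cbind(gh[, 1, drop = FALSE], round(gh[, -1], 4)), row.names = FALSE)

## (b) repeated-measures ANOVA per cohort
rm_rows <- list()
for (cohort in unique(bins$cohort)) {
  bb <- bins[bins$cohort == cohort, ]
  dd <- aggregate(density ~ astrocyte + distance_class, data = bb, FUN = mean)
  r <- rm_anova_omega(dd, value = "density", subject = "astrocyte",
                      within = "distance_class")
  r$anova$cohort <- cohort
  rm_rows[[cohort]] <- r$anova
  close_out <- r$posthoc[r$posthoc$groups == "close: out", ]
  cat(sprintf("%-4s RM-ANOVA: F(%d,%d) = %.2f, p = %.3g, omega^2 = %.3f; close-vs-out adj. p = %.3g\n",
              cohort, r$anova$df1, r$anova$df2, r$anova$statistic,
              r$anova$p_value, r$anova$effect_size, close_out$adjusted_p))
}
write.csv(do.call(rbind, rm_rows), "results/rm_anova.csv", row.names = FALSE)

## (c) trait correlations: fields of each diagnosis assigned to its cases
rec <- read.csv("results/field_densities.csv")
traits <- load_trait_counts()
dens_rows <- list()
for (dg in unique(traits$diagnosis)) {
  flds <- rec[rec$cohort == dg, ]
  cases <- traits$case[traits$diagnosis == dg]
  if (!nrow(flds)) next
  assign_case <- cases[(seq_len(nrow(flds)) - 1L) %% length(cases) + 1L]
  agg <- tapply(flds$bipartite_density, assign_case, mean)
  dens_rows[[dg]] <- data.frame(case = as.integer(names(agg)),
                                density = as.numeric(agg))
}
dens <- do.call(rbind, dens_rows)
corr <- correlate_traits(traits, dens)
write.csv(corr, "results/trait_correlations.csv", row.names = FALSE)
cat("\ntrait correlations (Pearson R of density vs trait, by diagnosis):\n")
print(cbind(corr[, 1:2], round(corr[, 3:4], 3), n = corr$n), row.names = FALSE)

cat("\nwrote results/games_howell.csv, results/rm_anova.csv, results/trait_correlations.csv\n")
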