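#!/usr/bin/env Rscript
# Filter the simulated feature table with the standard quality rules and
# compare chloroplast prevalence across diet classes: Kruskal-Wallis over
# the three classes, then Holm-corrected pairwise Wilcoxon rank-sum tests.

suppressPackageStartupMessages(library(trophmix))

tab <- read_feature_table("results/simulated")
filtered <- filter_feature_table(tab, filter_spec())
cat("filtering kept", nrow(filtered$counts), "of", nrow(tab$counts),
    "OTUs and", ncol(filtered$counts), "of", ncol(tab$counts), "samples\n")

prev <- chloroplast_proportions(filtered)
write.csv(prev, "results/prevalence.csv", row.names = FALSE)

summ <- group_summary(prev$proportion, prev$diet_class)
write.csv(summ, "results/prevalence_summary.csv", row.names = FALSE)
print(summ)

kw <- kruskal_wallis(prev$proportion, prev$diet_class)
pw <- pairwise_ranksum(prev$proportion, prev$diet_class, correction = "holm")
tests <- rbind(
  data.frame(method = kw$method, groups = kw$groups,
             statistic = kw$statistic, p_value = kw$p_value,
             p_adjusted = NA_real_),
  data.frame(method = pw$method, groups = pw$groups,
             statistic = pw$statistic, p_value = pw$p_value,
             p_adjusted = pw$p_adjusted)
)
write.csv(tests, "results/prevalence_tests.csv", row.names = FALSE)
cat(sprintf("Kruskal-Wallis: chi-square(%d) = %.3f, p = %.4g\n",
            kw$df, kw$statistic, kw$p_value))
for (i in seq_len(nrow(pw))) {
  cat(sprintf("  %s: adjusted p = %.4g\n", pw$groups[i], pw$p_adjusted[i]))
}
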