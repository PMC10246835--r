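#!/usr/bin/env Rscript
# Stage 2: population-level enrichment statistics.
# From the count table: per-variant log2(FC) fitness proxies for each
# passage and condition, weighted mean population fitness and (normalized)
# Shannon diversity per timepoint.

suppressPackageStartupMessages(library(codonfit))

cm <- read_count_matrix("results/counts.tsv")
conds <- attr(cm, "conditions")

fit_all <- list(); summ_all <- list()
for (cond in conds) {
  for (p in c("day1", "day2"))
    fit_all[[paste(cond, p)]] <- passage_fitness(cm, cond, p)
  summ_all[[cond]] <- population_summary(cm, cond)
}
fitness <- do.call(rbind, fit_all)
summary_tab <- do.call(rbind, summ_all)
utils::write.table(fitness, "results/fitness.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(summary_tab, "results/population_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (cond in conds) {
  s <- summ_all[[cond]]
  ft <- fit_all[[paste(cond, "day1")]]
  rt <- rank_table(ft)
  cat(sprintf(
    "condition %s ug/ml: w-bar day1 = %.2f, H_norm day1 = %.2f, %d/%d variants depleted\n",
    cond, s$w_bar[s$timepoint == "day1"], s$H_norm[s$timepoint == "day1"],
    attr(rt, "partition_index"), nrow(rt)))
}
top_cond <- conds[length(conds)]
ft <- fit_all[[paste(top_cond, "day1")]]
top <- ft$variant_id[which.max(ft$log2FC)]
cat(sprintf(
  "top variant at %s ug/ml day1: %s, frequency %.1f%% -> %.1f%% -> %.1f%%\n",
  top_cond, top,
  100 * normalize_counts(cm, "day0", top_cond)[[top]],
  100 * normalize_counts(cm, "day1", top_cond)[[top]],
  100 * normalize_counts(cm, "day2", top_cond)[[top]]))
write_manifest("results", "02_population_stats",
               inputs = "results/counts.tsv")
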