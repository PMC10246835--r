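#!/usr/bin/env Rscript
# Stage 3: which sequence feature explains fitness?
# Spearman rank associations between log2(FC) and codon-optimality scores,
# GC content and per-window 5'-mRNA folding stability, per condition.

suppressPackageStartupMessages(library(codonfit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cm <- read_count_matrix("results/counts.tsv")
features <- utils::read.delim("results/features.tsv")
lib_manifest <- utils::read.delim("results/library_manifest.tsv")
reg <- read_fasta("results/gene_pair.fasta")[["regulatory"]]
seqs <- setNames(lib_manifest$sequence, lib_manifest$variant_id)

prof <- library_window_profiles(seqs, reg, n_windows = 110L)

assoc <- list(); wcors <- list()
for (cond in attr(cm, "conditions")) {
  ft <- passage_fitness(cm, cond, "day1")
  assoc[[cond]] <- assoc_table(
    ft, features[, c("variant_id", "dg_window1", "tAIg", "CAIg",
                     "gc_percent")])
  wc <- window_correlation_profile(ft, prof)
  wc$condition <- cond
  wcors[[cond]] <- wc
}
utils::write.table(do.call(rbind, assoc), "results/associations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, wcors), "results/window_correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (cond in attr(cm, "conditions")) {
  wc <- wcors[[cond]]
  best <- wc$window[which.min(wc$p)]
  a <- assoc[[cond]]
  cat(sprintf(
    "condition %s: best window %s (r = %.2f, p = %.2g); dG r = %.2f, tAIg r = %.2f\n",
    cond, best, wc$r[best], wc$p[best],
    a$r[a$feature == "dg_window1"], a$r[a$feature == "tAIg"]))
}
write_manifest("results", "03_feature_association", seed,
               inputs = c("results/counts.tsv", "results/features.tsv"),
               engine_ids = c(folding = default_engine()$id))
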