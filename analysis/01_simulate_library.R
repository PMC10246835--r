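#!/usr/bin/env Rscript
# Stage 1: generate the synthetic selection experiment.
# A combinatorial library (codons 1-15, k = 9 -> 512 variants) under a
# host-like GC-biased codon-usage regime is put through two serial passages
# at 0/20/100/200 ug/ml drug, with true fitness driven by window-1 mRNA
# folding stability. Writes the observable count table and per-variant
# features; the hidden truth goes to its own subdirectory.

suppressPackageStartupMessages(library(codonfit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results"
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

tabs <- gen_weight_tables(gc_bias = 0.7, seed = seed)
write_weight_table(tabs$cai, file.path(out, "cai_weights.tsv"))
write_weight_table(tabs$tai, file.path(out, "tai_weights.tsv"))

syn <- synth_library(codon_range = c(1, 15), k = 9L, weights = tabs$cai,
                     seed = seed)
seqs <- enumerate_variants(syn$lib)
write_fasta(c(org = syn$lib$org_cds, mod = syn$lib$mod_cds,
              regulatory = syn$regulatory_seq),
            file.path(out, "gene_pair.fasta"))
utils::write.table(
  data.frame(variant_id = names(seqs), sequence = unname(seqs)),
  file.path(out, "library_manifest.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

ex <- gen_library_experiment(
  syn, truth_model(beta_dg_max = 0.4, beta_opt_max = 0, depth = 1e5L),
  conditions = c(0, 20, 100, 200), tai_wt = tabs$tai, cai_wt = tabs$cai,
  seed = seed)
write_count_matrix(ex$counts, file.path(out, "counts.tsv"))
utils::write.table(ex$features, file.path(out, "features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ex$truth, file.path(out, "truth", "true_fitness.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

day0 <- counts_at(ex$counts, "day0", 200)
cat(sprintf("library: %d variants over diversified codons %d-%d (k = %d)\n",
            length(seqs), syn$lib$codon_range[1], syn$lib$codon_range[2],
            length(syn$lib$diff_positions)))
cat(sprintf("day-0 coverage at 200 ug/ml: %.1f%% of 2^%d combinations\n",
            coverage(names(day0)[day0 > 0], 9L),
            length(syn$lib$diff_positions)))
write_manifest(out, "01_simulate_library", seed,
               engine_ids = c(folding = default_engine()$id))
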