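test_that("synthetic weight tables are internally consistent", {
  tabs <- gen_weight_tables(gc_bias = 0.7, seed = 5)
  fam <- split(tabs$cai$weights,
               codonfit:::GENETIC_CODE_DNA[names(tabs$cai$weights)])
  for (f in fam) expect_equal(max(f), 1)
  expect_true(all(tabs$tgcn > 0))
  expect_true(all(tabs$tai$weights > 0 & tabs$tai$weights <= 1))
})

test_that("gc bias controls the codon GC vs weight correlation", {
  gc_codon <- vapply(codonfit:::SENSE_CODONS, gc_content, numeric(1))
  r_bias <- vapply(1:20, function(s) {
    w <- gen_weight_tables(gc_bias = 0.8, seed = s)$cai$weights
    cor(gc_codon[names(w)], w, method = "spearman")
  }, numeric(1))
  expect_true(all(r_bias > 0.2))
  r_flat <- vapply(1:20, function(s) {
    w <- gen_weight_tables(gc_bias = 0.5, seed = s)$cai$weights
    cor(gc_codon[names(w)], w, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(r_flat)), 0.15)   # no systematic direction
})

test_that("the synthetic library reaches folding window 1 and stays synonymous", {
  syn <- synth_library(codon_range = c(1, 15), k = 9, seed = 12)
  expect_identical(translate_cds(syn$lib$org_cds),
                   translate_cds(syn$lib$mod_cds))
  expect_true(2L %in% syn$lib$diff_positions)
  seqs <- enumerate_variants(syn$lib)
  dg1 <- vapply(seqs[c("M", "O")], function(cds)
    mfe(tx_slice(syn$transcripts(cds), -25, 5)), numeric(1))
  expect_false(dg1[["M"]] == dg1[["O"]])  # codon 2 changes window 1
  syn2 <- synth_library(codon_range = c(16, 30), k = 5, seed = 12)
  expect_true(all(syn2$lib$diff_positions >= 16 &
                    syn2$lib$diff_positions <= 30))
})

test_that("a neutral noiseless experiment shows only sampling-scale fold changes", {
  syn <- synth_library(k = 6, seed = 8)
  ex <- gen_library_experiment(
    syn, truth_model(beta_dg_max = 0, beta_opt_max = 0, noise_sd = 0,
                     depth = 1e5),
    conditions = c(0, 200), seed = 8)
  ft <- passage_fitness(ex$counts, 200, "day1")
  expect_lt(max(abs(ft$log2FC)), 1)       # multinomial noise only
  expect_equal(mean(ft$log2FC), 0, tolerance = 0.05)
})

test_that("dG-driven truth is recovered by the enrichment-association pipeline", {
  syn <- synth_library(k = 9, seed = 15)
  ex <- gen_library_experiment(
    syn, truth_model(beta_dg_max = 0.4, beta_opt_max = 0, depth = 1e5),
    conditions = c(0, 200), seed = 15)
  ft <- passage_fitness(ex$counts, 200, "day1")
  m <- match(ft$variant_id, ex$features$variant_id)
  r <- spearman_assoc(ex$features$dg_window1[m], ft$log2FC)
  expect_gt(r$r, 0.6)
  # and no dG association in the no-drug condition
  ft0 <- passage_fitness(ex$counts, 0, "day1")
  r0 <- spearman_assoc(ex$features$dg_window1[match(ft0$variant_id,
                                                    ex$features$variant_id)],
                       ft0$log2FC)
  expect_gt(r0$p, 0.01)
})

test_that("mean population fitness rises with drug concentration in expectation", {
  wbars <- vapply(1:15, function(s) {
    syn <- synth_library(k = 6, seed = s)
    ex <- gen_library_experiment(
      syn, truth_model(beta_dg_max = 0.4, depth = 2e4),
      conditions = c(0, 20, 100, 200), seed = s)
    vapply(c(0, 20, 100, 200), function(cond) {
      ft <- passage_fitness(ex$counts, cond, "day1")
      mean_fitness(ft$f_curr, ft$FC)
    }, numeric(1))
  }, numeric(4))
  means <- rowMeans(wbars)
  expect_true(all(diff(means) > 0))
})

test_that("the hidden truth channel is separate from the observable counts", {
  syn <- synth_library(k = 4, seed = 2)
  ex <- gen_library_experiment(syn, truth_model(depth = 5000),
                               conditions = c(0, 100), seed = 2)
  expect_s3_class(ex$counts, "count_matrix")
  expect_true(is.data.frame(ex$truth))
  expect_false("s" %in% c(colnames(ex$counts), names(attributes(ex$counts))))
})

test_that("generated dose-response curves honor their logistic scaling", {
  curves <- gen_growth_curves(ic50_true = 50, hill = 1.5, noise = 0, seed = 4)
  auc <- vapply(curves, function(d) growth_auc(d$times, d$od), numeric(1))
  conc <- as.numeric(names(auc))
  expect_equal(unname(auc / auc[conc == 0]),
               1 / (1 + (conc / 50)^1.5), tolerance = 1e-10)
  big <- gen_growth_curves(ic50_true = 1, noise = 0,
                           conditions = c(0, 1000), seed = 4)
  expect_lt(growth_auc(big[["1000"]]$times, big[["1000"]]$od) /
              growth_auc(big[["0"]]$times, big[["0"]]$od), 1e-4)
})
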