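test_that("relative adaptiveness normalizes each synonymous family to max 1", {
  counts <- c(GGC = 30, GGT = 10, GGA = 5, GGG = 5, ATG = 7)
  wt <- relative_adaptiveness(counts)
  expect_equal(wt$weights[["GGC"]], 1)
  expect_equal(wt$weights[["GGT"]], 1 / 3)
  expect_equal(wt$weights[["ATG"]], 1)          # single-codon family
  # unseen codons get the 0.5 pseudocount before normalization
  expect_equal(wt$weights[["TTT"]], 1)          # whole family unseen -> ties
  counts2 <- c(AAA = 10, AAG = 0)
  expect_equal(relative_adaptiveness(counts2)$weights[["AAG"]], 0.5 / 10)
  expect_error(relative_adaptiveness(numeric(0)), "empty")
})

test_that("every multi-codon family has at least one weight exactly 1", {
  set.seed(4)
  counts <- setNames(sample(0:50, 61, replace = TRUE),
                     codonfit:::SENSE_CODONS)
  wt <- relative_adaptiveness(counts)
  fam <- split(wt$weights,
               codonfit:::GENETIC_CODE_DNA[names(wt$weights)])
  for (f in fam) expect_equal(max(f), 1)
})

test_that("tAI weights combine Watson-Crick and wobble decoding", {
  # codon GGC: perfect anticodon GCC (tGCN 4, s = 0), wobble anticodon
  # ACC read through inosine (tGCN 2, s = 0.5) -> W = 4 + 1 = 5
  s <- c(wc = 0, g_t = 0.41, i_c = 0.5, i_a = 0.9999, t_g = 0.68)
  tg <- c(GCC = 4L, ACC = 2L, CAT = 10L)  # CAT: Met anticodon, W = 10 (max)
  wt <- tai_weights(tg, s)
  expect_equal(wt$weights[["GGC"]], 5 / 10)
  expect_equal(wt$weights[["ATG"]], 1)   # maximal W, Watson-Crick only
  # codons with no decoding tRNA get the geometric mean of nonzero weights
  nz <- c(wt$weights[["GGC"]], wt$weights[["ATG"]],
          wt$weights[["GGT"]], wt$weights[["GGA"]])
  expect_equal(wt$weights[["TTT"]], exp(mean(log(nz[nz > 0]))),
               tolerance = 1e-12)
  expect_error(tai_weights(c(GCC = 0L)), "zero")
})

test_that("fully penalized single pairing leads to geometric-mean substitution", {
  s <- c(wc = 1, g_t = 1, i_c = 1, i_a = 1, t_g = 1)
  tg <- c(GCC = 4L)
  expect_error(tai_weights(tg, s), "no decoding capacity")
})

test_that("gene score is the geometric mean with standard exclusions", {
  wt <- codon_weight_table(
    c(AAA = 1, AAG = 0.25, ATG = 0.1, GGT = 1), "CAI")
  expect_equal(gene_score("AAAAAA", wt), 1)            # all w = 1
  expect_equal(gene_score("AAAAAG", wt), 0.5)          # sqrt(0.25 * 1)
  # ATG excluded on the CAI scale: identical score with or without it
  expect_equal(gene_score("ATGAAAAAG", wt), 0.5)
  wt_tai <- codon_weight_table(
    c(AAA = 1, AAG = 0.25, ATG = 0.1, GGT = 1), "tAI")
  expect_equal(gene_score("ATGAAAAAG", wt_tai), (0.1 * 1 * 0.25)^(1 / 3))
  expect_error(gene_score("ATG", wt), "no scorable")
})

test_that("gene score is permutation-invariant and pulled toward 1 by optimal codons", {
  wt <- fixture_cai()
  set.seed(8)
  codons <- sample(codonfit:::SENSE_CODONS, 20, replace = TRUE)
  s1 <- gene_score(paste(codons, collapse = ""), wt)
  s2 <- gene_score(paste(sample(codons), collapse = ""), wt)
  expect_equal(s1, s2)
  # appending a w = 1 codon moves the score toward 1
  fam_max <- names(wt$weights)[wt$weights == 1 &
                                 codonfit:::GENETIC_CODE_DNA[names(wt$weights)] == "K"]
  s3 <- gene_score(paste(c(codons, fam_max[1]), collapse = ""), wt)
  expect_gte(s3, s1)
  expect_lte(s3, 1)
})

test_that("recoding every codon to its family maximum yields score 1", {
  wt <- fixture_cai()
  p <- fixture_pair()
  codons <- substring(p$org, seq(1, nchar(p$org), 3), seq(3, nchar(p$org), 3))
  recoded <- vapply(codons, function(cd) {
    fam <- names(wt$weights)[codonfit:::GENETIC_CODE_DNA[names(wt$weights)] ==
                               codonfit:::GENETIC_CODE_DNA[[cd]]]
    fam[which.max(wt$weights[fam])]
  }, character(1))
  expect_equal(gene_score(paste(recoded, collapse = ""), wt), 1)
  expect_lte(gene_score(p$org, wt), gene_score(paste(recoded, collapse = ""), wt))
})

test_that("gc content is the G+C percentage", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_error(gc_content(""), "empty")
})

test_that("metric shift test reports the signed mean shift and sane p-values", {
  x <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  same <- metric_shift_test(x, x)
  expect_equal(same$mean_shift, 0)
  expect_equal(same$t_p, 1)
  up <- metric_shift_test(x + 0.1, x)
  expect_equal(up$mean_shift, 0.1)
  expect_error(metric_shift_test(x[1:2], x[1:2]), "at least 3")
})

test_that("a one-sigma shift is detected in the majority of simulated samples", {
  set.seed(21)
  hits <- replicate(1000, {
    a <- rnorm(10, 0.5, 0.05)
    b <- rnorm(10, 0.55, 0.05)
    metric_shift_test(a, b)$t_p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
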