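test_that("frequencies normalize to the column total", {
  cm <- count_matrix(data.frame(variant_id = c("a", "b"),
                                timepoint = "day0", condition = "0",
                                count = c(10, 30)))
  expect_equal(unname(normalize_counts(cm, "day0", 0)), c(0.25, 0.75))
  one <- count_matrix(data.frame(variant_id = "a", timepoint = "day0",
                                 condition = "0", count = 5))
  expect_equal(unname(normalize_counts(one, "day0", 0)), 1)
  zero <- count_matrix(data.frame(variant_id = c("a", "b"),
                                  timepoint = c("day0", "day1"),
                                  condition = "0", count = c(0, 3)))
  expect_error(normalize_counts(zero, "day0", 0), "all-zero")
})

test_that("fold change is the frequency ratio on the right baseline", {
  fc <- fold_change(c(a = 0.04, b = 0.96), c(a = 0.02, b = 0.98))
  expect_equal(fc$FC[1], 2)
  expect_equal(fc$log2FC[1], 1)
  expect_equal(fold_change(0.3, 0.3)$log2FC, 0)
  expect_error(fold_change(0.5, 0), "pseudocount")
})

test_that("passage fitness uses day0 then day1 baselines and the zero policy", {
  df <- fixture_counts_df()
  cm <- count_matrix(df)
  ft <- passage_fitness(cm, 100, "day1")
  expect_equal(sort(ft$variant_id), c("v1", "v2", "v3"))
  expect_equal(ft$FC[ft$variant_id == "v1"], (300 / 400) / (100 / 400))
  expect_equal(sum(ft$f_curr), 1)

  # variant unseen at both timepoints of the passage is excluded
  df2 <- rbind(df, data.frame(variant_id = "ghost",
                              timepoint = c("day0", "day1"),
                              condition = "100", count = 0))
  ft2 <- passage_fitness(count_matrix(df2), 100, "day1")
  expect_false("ghost" %in% ft2$variant_id)
  expect_identical(attr(ft2, "excluded"), "ghost")

  # single-timepoint zero triggers the pseudocount, keeping FC finite
  df3 <- rbind(df, data.frame(variant_id = "late",
                              timepoint = c("day0", "day1"),
                              condition = "100", count = c(0, 40)))
  ft3 <- passage_fitness(count_matrix(df3), 100, "day1")
  late <- ft3[ft3$variant_id == "late", ]
  expect_true(is.finite(late$FC) && late$FC > 1)
  expect_true(late$zero_flag)
})

test_that("an identity passage gives FC = 1, mean fitness 1 and unchanged H", {
  df <- expand.grid(variant_id = paste0("v", 1:6),
                    timepoint = c("day0", "day1"), condition = "0",
                    stringsAsFactors = FALSE)
  df$count <- rep(c(10, 20, 30, 40, 50, 60), 2)
  cm <- count_matrix(df)
  ft <- passage_fitness(cm, 0, "day1")
  expect_equal(ft$FC, rep(1, 6))
  expect_equal(mean_fitness(ft$f_curr, ft$FC), 1)
  ps <- population_summary(cm, 0, timepoints = c("day0", "day1"))
  expect_equal(ps$H[1], ps$H[2])
  expect_equal(ps$w_bar, c(1, 1))
  expect_equal(ps$H_norm[1], 1)
})

test_that("mean fitness reproduces the hand-computed weighted average", {
  f0 <- c(0.5, 0.5); f1 <- c(0.8, 0.2)
  FC <- f1 / f0
  expect_equal(mean_fitness(f1, FC), 0.8 * 1.6 + 0.2 * 0.4)  # 1.36
  expect_error(mean_fitness(c(0.5), c(1, 1)), "mismatch")
})

test_that("current-day weighting makes mean fitness at least 1", {
  set.seed(13)
  for (i in 1:50) {
    n0 <- rpois(12, 50) + 1
    n1 <- rpois(12, 50) + 1
    f0 <- n0 / sum(n0); f1 <- n1 / sum(n1)
    expect_gte(mean_fitness(f1, f1 / f0), 1 - 1e-12)
  }
})

test_that("Shannon diversity matches closed forms and the vegan cross-check", {
  expect_equal(shannon(rep(1 / 8, 8)), log(8))
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.8, 0.2)), -0.8 * log(0.8) - 0.2 * log(0.2))
  expect_equal(shannon(c(0.8, 0.2)), 0.5004, tolerance = 1e-4)
  expect_equal(shannon(c(0.5, 0.5, 0)), log(2))
  expect_error(shannon(c(-0.1, 1.1)), "negative")
  skip_if_not_installed("vegan")
  set.seed(3)
  p <- rgamma(20, 2); p <- p / sum(p)
  expect_equal(shannon(p), unname(vegan::diversity(p, index = "shannon")))
})

test_that("normalized diversity is the ratio to the naive library", {
  expect_equal(normalized_diversity(1.5, 1.5), 1)
  expect_equal(normalized_diversity(0, 2), 0)
  expect_equal(normalized_diversity(1, 2), 0.5)
  expect_error(normalized_diversity(1, 0), "zero")
})

test_that("rank table sorts stably and partitions depleted from enriched", {
  ft <- data.frame(variant_id = c("a", "b", "c", "d"),
                   log2FC = c(0.5, -1, 0.5, -0.2))
  rt <- rank_table(ft)
  expect_identical(rt$variant_id, c("b", "d", "a", "c"))  # stable tie a<c
  expect_identical(attr(rt, "partition_index"), 2L)
  all_up <- rank_table(data.frame(variant_id = "a", log2FC = 0.3))
  expect_identical(attr(all_up, "partition_index"), 0L)
})

test_that("stronger selection raises mean fitness and lowers diversity", {
  set.seed(99)
  G <- 10
  s <- seq(-0.2, 0.2, length.out = 24)   # fixed variant effects
  stats_at <- function(scale) {
    f0 <- rep(1 / 24, 24)
    f1 <- f0 * 2^(G * s * scale); f1 <- f1 / sum(f1)
    n0 <- drop(rmultinom(1, 2e4, f0)); n1 <- drop(rmultinom(1, 2e4, f1))
    ff0 <- n0 / sum(n0); ff1 <- n1 / sum(n1)
    keep <- n0 > 0 & n1 > 0
    c(w = sum(ff1[keep] * ff1[keep] / ff0[keep]), H = shannon(ff1))
  }
  res <- replicate(100, vapply(c(0.3, 1), stats_at, numeric(2)))
  expect_gt(mean(res["w", 2, ]), mean(res["w", 1, ]))
  expect_lt(mean(res["H", 2, ]), mean(res["H", 1, ]))
})
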