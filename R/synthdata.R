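# Synthetic-data generator: weight/tGCN tables, a synthetic ORG/MOD gene
# pair with a combinatorial library, multinomial deep-sequencing counts with
# condition-dependent selection on 5'-mRNA stability and/or codon
# optimality, dose-response growth curves, and FASTQ reads.

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate internally consistent synthetic codon-usage tables
#'
#' Synthetic CAI reference counts and a tRNA gene-copy table. `gc_bias`
#' above 0.5 makes G/C-ending codons more frequent (and their anticodons
#' more abundant), inducing the optimality-vs-folding-stability collinearity
#' seen in GC-rich genomes; 0.5 is neutral.
#'
#' @param gc_bias in (0, 1).
#' @param seed integer seed.
#' @return list with `cai` (a `codon_weight_table`), `tai` (tAI weight
#'   table), `tgcn` (anticodon copy numbers) and `counts`.
#' @export
#' @importFrom stats rgamma rpois rnorm runif
gen_weight_tables <- function(gc_bias = 0.7, seed = 1L) {
  stopifnot(gc_bias > 0, gc_bias < 1)
  set.seed(as.integer(seed))
  third <- substr(SENSE_CODONS, 3L, 3L)
  bias <- ifelse(third %in% c("G", "C"), gc_bias / (1 - gc_bias),
                 (1 - gc_bias) / gc_bias)
  counts <- stats::rgamma(length(SENSE_CODONS), shape = 4, rate = 1) * bias
  counts <- setNames(round(counts * 250) + 1, SENSE_CODONS)
  cai <- relative_adaptiveness(counts)
  # anticodon pool tracks codon usage so tAI and CAI are realistically linked
  tgcn <- setNames(integer(length(SENSE_CODONS)), revcomp(SENSE_CODONS))
  for (i in seq_along(SENSE_CODONS))
    tgcn[i] <- stats::rpois(1L, 1 + 8 * counts[i] / max(counts))
  tgcn <- tgcn[tgcn > 0]
  if (length(tgcn) == 0L) tgcn <- c(CAT = 1L)
  list(cai = cai, tai = tai_weights(tgcn), tgcn = tgcn, counts = counts)
}

# Fixed synthetic 5' regulatory region (constructed, not a natural promoter).
# Mostly AT-rich, with a Shine-Dalgarno-like GGAGG and, at positions -9..-5,
# a CTCAT segment complementary to an ATGAG start: variants whose second
# codon begins AG close a 5-bp helix across the start codon (stable window
# 1), while TC-starting synonyms leave only the constitutive 3-bp CAT:ATG
# contact, so codon choice at the start modulates window-1 folding the way
# GC-rich xenologue starts do against a host 5'-UTR.
SYNTH_REGULATORY <- paste0("TTATAAGTTAACTATTAAGGAGGTAA", "TATTA",
                           "CTCAT", "ATAA")

#' Synthetic ORG/MOD gene pair with a combinatorial library
#'
#' Constructs a synthetic folA-like coding sequence: the MOD backbone uses
#' each family's maximal-weight codon, and ORG codons (lower-weight
#' synonyms) are restored at `k` positions inside `codon_range`. The second
#' codon is drawn from a six-codon family (Ser/Leu/Arg) whose synonyms
#' differ in their first two nucleotides, so variant choice reaches into
#' folding window 1 (-25..+5). Returns the library plus the shared
#' regulatory sequence.
#'
#' @param codon_range diversified interval, `c(1, 15)` or `c(16, 30)`.
#' @param k number of diversified positions (default 9; 512 variants).
#' @param n_codons CDS length in codons (default 55).
#' @param weights a CAI-scale `codon_weight_table` defining "most frequent".
#' @param seed integer seed.
#' @return list with `lib` (a `variant_library`), `regulatory_seq`,
#'   and `transcripts` helper (function variant_cds -> `transcript_model`).
#' @export
synth_library <- function(codon_range = c(1, 15), k = 9L, n_codons = 55L,
                          weights = gen_weight_tables(seed = 1L)$cai,
                          seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(k >= 1L, codon_range[2L] <= n_codons)
  aa_families <- split(SENSE_CODONS, GENETIC_CODE_DNA[SENSE_CODONS])
  multi <- aa_families[vapply(aa_families, length, integer(1)) >= 2L]
  # amino-acid sequence: Met start, serine at codon 2 (its six synonyms
  # split into AG- and TC-starting groups, giving codon choice reach into
  # window 1), then residues with synonymous room
  aa <- c("M", "S", sample(names(multi), n_codons - 2L, replace = TRUE))
  mod <- vapply(aa, function(a) {
    fam <- aa_families[[a]]
    fam[which.max(weights$weights[fam])]
  }, character(1))
  org <- mod
  # diversified positions: codon 2 first (window-1 leverage), then others
  pool <- setdiff(seq.int(codon_range[1L], codon_range[2L]), 1L)
  dp <- if (codon_range[1L] == 1L)
    c(2L, sample(setdiff(pool, 2L), k - 1L))
  else sample(pool, k)
  dp <- sort(dp)
  for (i in dp) {
    fam <- setdiff(aa_families[[aa[i]]], mod[i])
    if (i == 2L) {
      # ORG serine from the opposite dinucleotide group, so ORG and MOD
      # differ inside window 1 (-25..+5)
      d2 <- vapply(fam, function(cd)
        sum(strsplit(cd, "")[[1]][1:2] != strsplit(mod[i], "")[[1]][1:2]),
        numeric(1))
      fam <- fam[d2 == max(d2)]
    }
    org[i] <- fam[which.min(weights$weights[fam])]
  }
  lib <- variant_library("synth", paste(org, collapse = ""),
                         paste(mod, collapse = ""), codon_range)
  list(lib = lib, regulatory_seq = SYNTH_REGULATORY,
       transcripts = function(cds)
         build_transcript(SYNTH_REGULATORY, cds, gene_id = "synth"))
}

#' Truth model for the synthetic selection experiment
#'
#' True per-variant log2 fitness under condition c:
#' s_i = beta_dg(c) * z(dG window 1) + beta_opt(c) * z(tAIg) + N(0, noise_sd),
#' where z() standardizes over the library and the betas scale linearly with
#' drug concentration (0 at concentration 0, matching the no-selection
#' regime without drug).
#'
#' @param beta_dg_max effect of window-1 dG at the highest concentration.
#' @param beta_opt_max effect of tAIg at the highest concentration.
#' @param noise_sd sd of variant-level noise on s_i.
#' @param depth reads per (timepoint, condition).
#' @param gens_per_passage generations per 16-h passage (default 10: a
#'   1/100 dilution regrown to saturation is ~log2(100) = 6.6 doublings,
#'   rounded up with margin).
#' @return object of class `truth_model`.
#' @export
truth_model <- function(beta_dg_max = 0.4, beta_opt_max = 0,
                        noise_sd = 0.05, depth = 1e5L,
                        gens_per_passage = 10L) {
  stopifnot(beta_dg_max >= 0, noise_sd >= 0, depth >= 0)
  structure(list(beta_dg_max = beta_dg_max, beta_opt_max = beta_opt_max,
                 noise_sd = noise_sd, depth = as.integer(depth),
                 gens_per_passage = as.integer(gens_per_passage)),
            class = "truth_model")
}

#' Simulate the combinatorial-library selection experiment
#'
#' Enumerates the library, computes each variant's window-1 dG and tAIg,
#' assigns true log2 fitness per the truth model, evolves frequencies
#' deterministically over passages (f(t+1) proportional to
#' f(t) * 2^(G * s_i)) and samples multinomial read counts at fixed depth
#' for day0/day1/day2 at every condition. The hidden truth is returned on a
#' separate channel from the counts.
#'
#' @param synth output of [synth_library()].
#' @param truth a `truth_model`.
#' @param conditions drug concentrations (must include 0 for the
#'   no-selection regime to be exercised), ug/ml.
#' @param passages number of serial passages (default 2).
#' @param tai_wt tAI weight table for the optimality feature.
#' @param cai_wt CAI weight table for the CAIg feature column.
#' @param seed integer seed.
#' @param engine folding engine for the dG feature.
#' @return list with `counts` (a `count_matrix`), `truth` (data.frame of
#'   hidden s_i per condition), and `features` (variant_id, dg_window1,
#'   tAIg, CAIg, gc_percent).
#' @export
gen_library_experiment <- function(synth, truth = truth_model(),
                                   conditions = c(0, 20, 100, 200),
                                   passages = 2L,
                                   tai_wt = gen_weight_tables(seed = 1L)$tai,
                                   cai_wt = gen_weight_tables(seed = 1L)$cai,
                                   seed = 1L,
                                   engine = default_engine()) {
  set.seed(as.integer(seed))
  lib <- synth$lib
  variants <- enumerate_variants(lib)
  n <- length(variants)
  if (truth$depth < n)
    warning("read depth below library size; most variants unobserved")
  dg1 <- vapply(variants, function(cds)
    engine$fun(tx_slice(synth$transcripts(cds), -25L, 5L)), numeric(1))
  taig <- vapply(variants, gene_score, numeric(1), wt = tai_wt)
  caig <- vapply(variants, gene_score, numeric(1), wt = cai_wt)
  gc <- vapply(variants, gc_content, numeric(1))
  features <- data.frame(variant_id = names(variants),
                         dg_window1 = unname(dg1), tAIg = unname(taig),
                         CAIg = unname(caig), gc_percent = unname(gc),
                         row.names = NULL)
  cmax <- max(conditions)
  f0 <- stats::rgamma(n, shape = 5, rate = 1)
  f0 <- f0 / sum(f0)
  rows <- list()
  truth_rows <- list()
  for (cond in conditions) {
    scale <- if (cmax > 0) cond / cmax else 0
    s <- truth$beta_dg_max * scale * zscore(dg1) +
      truth$beta_opt_max * scale * zscore(taig) +
      stats::rnorm(n, 0, truth$noise_sd)
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(variant_id = names(variants), condition = cond_key(cond),
                 s = unname(s), row.names = NULL)
    f <- f0
    freqs <- list(day0 = f)
    for (p in seq_len(passages)) {
      f <- f * 2^(truth$gens_per_passage * s)
      f <- f / sum(f)
      freqs[[paste0("day", p)]] <- f
    }
    for (tp in names(freqs)) {
      cnt <- drop(stats::rmultinom(1L, size = truth$depth,
                                   prob = freqs[[tp]]))
      rows[[length(rows) + 1L]] <-
        data.frame(variant_id = names(variants), timepoint = tp,
                   condition = cond_key(cond), count = cnt, row.names = NULL)
    }
  }
  list(counts = count_matrix(do.call(rbind, rows)),
       truth = do.call(rbind, truth_rows),
       features = features)
}

#' Generate dose-response growth curves
#'
#' A baseline modified-Gompertz curve scaled multiplicatively by the
#' logistic g(c) = 1 / (1 + (c / ic50_true)^hill), with optional
#' multiplicative noise per sample point, so the AUC ratio to the 0-drug
#' curve equals g(c) in expectation.
#'
#' @param ic50_true true IC50 (ug/ml).
#' @param hill Hill slope.
#' @param noise multiplicative noise sd (0 = noiseless).
#' @param conditions concentrations, should include 0.
#' @param seed integer seed.
#' @param times sampling times, hours (default 10-min intervals over 16 h).
#' @param rate,lag,asymptote baseline Gompertz parameters.
#' @return list of `data.frame(times, od)` per condition, named by
#'   canonical condition key.
#' @export
gen_growth_curves <- function(ic50_true, hill = 2, noise = 0,
                              conditions = c(0, 12.5, 25, 50, 100, 200,
                                             400, 800),
                              seed = 1L, times = seq(0, 16, by = 1 / 6),
                              rate = 0.25, lag = 2, asymptote = 1) {
  stopifnot(ic50_true > 0)
  set.seed(as.integer(seed))
  base <- gompertz_od(times, rate, lag, asymptote)
  out <- lapply(conditions, function(cond) {
    g <- 1 / (1 + (cond / ic50_true)^hill)
    od <- base * g
    if (noise > 0) od <- od * exp(stats::rnorm(length(od), 0, noise))
    data.frame(times = times, od = od)
  })
  names(out) <- cond_key(conditions)
  out
}

#' Generate reads for a library at given variant frequencies
#'
#' Exact-sequence reads over the full CDS sampled multinomially; an optional
#' fraction of reads is truncated below the expected length to exercise the
#' length filter.
#'
#' @param lib a `variant_library`.
#' @param frequencies named frequency vector over variant ids.
#' @param depth total reads.
#' @param truncated_fraction fraction of reads shortened by 1-5 nt.
#' @param seed integer seed.
#' @return character vector of reads.
#' @export
gen_reads <- function(lib, frequencies, depth, truncated_fraction = 0,
                      seed = 1L) {
  set.seed(as.integer(seed))
  if (depth == 0L) return(character(0))
  variants <- enumerate_variants(lib)
  stopifnot(setequal(names(frequencies), names(variants)))
  cnt <- drop(stats::rmultinom(1L, size = depth,
                               prob = frequencies[names(variants)]))
  reads <- rep(unname(variants), cnt)
  if (truncated_fraction > 0) {
    cut <- stats::runif(length(reads)) < truncated_fraction
    reads[cut] <- substr(reads[cut], 1L,
                         nchar(reads[cut]) - sample(1:5, sum(cut), TRUE))
  }
  sample(reads)
}
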