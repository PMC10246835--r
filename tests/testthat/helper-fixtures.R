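# Shared fixtures, built in code.

# deterministic CAI table: G/C-ending codons twice as frequent
fixture_cai <- function() {
  counts <- setNames(rep(10, length(codonfit:::SENSE_CODONS)),
                     codonfit:::SENSE_CODONS)
  gc_end <- substr(names(counts), 3, 3) %in% c("G", "C")
  counts[gc_end] <- 20
  relative_adaptiveness(counts)
}

# small synonymous ORG/MOD pair: 6 codons, differences at codons 2, 4, 5
fixture_pair <- function() {
  list(
    org = "ATGTCTAAACTTCGTGGT",  # M S K L R G
    mod = "ATGAGCAAACTGCGCGGT") # M S K L R G (AGC/CTG/CGC swaps)
}

fixture_library <- function() {
  p <- fixture_pair()
  variant_library("toy", p$org, p$mod, c(1, 6))
}

# long count table for a 3-variant, 2-condition experiment
fixture_counts_df <- function() {
  expand_df <- expand.grid(variant_id = c("v1", "v2", "v3"),
                           timepoint = c("day0", "day1"),
                           condition = c("0", "100"),
                           stringsAsFactors = FALSE)
  expand_df$count <- c(100, 100, 200, 100, 100, 200,   # day0 both conds
                       100, 100, 200, 300, 50, 50)     # day1
  expand_df
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
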