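# Codon-optimality metrics: CAI/tAI relative adaptiveness, gene-level
# geometric means (CAIg/tAIg), GC content, donor-vs-host metric shift.

GENETIC_CODE_DNA <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_DNA), STOP_CODONS)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(cds) {
  cds <- norm_seq(cds)
  if (nchar(cds) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Translate a coding sequence (standard genetic code)
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return amino-acid string ("*" for stops).
#' @export
translate_cds <- function(cds) {
  paste(GENETIC_CODE_DNA[split_codons(cds)], collapse = "")
}

#' Codon relative-adaptiveness table
#'
#' Container for per-codon relative adaptiveness w_c in (0, 1], on either the
#' CAI scale (relative synonymous codon frequency in a reference gene set) or
#' the tAI scale (tRNA decoding capacity with wobble penalties).
#'
#' @param weights named numeric vector, codon -> w in (0, 1].
#' @param scale "CAI" or "tAI".
#' @param provenance free-text source note.
#' @return object of class `codon_weight_table`.
#' @export
codon_weight_table <- function(weights, scale = c("CAI", "tAI"),
                               provenance = "unspecified") {
  scale <- match.arg(scale)
  if (length(weights) == 0L || is.null(names(weights)))
    stop("weights must be a non-empty named vector")
  names(weights) <- toupper(chartr("U", "T", names(weights)))
  bad <- setdiff(names(weights), names(GENETIC_CODE_DNA))
  if (length(bad) > 0L) stop("unknown codons: ", paste(bad, collapse = ", "))
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1))
    stop("weights must lie in (0, 1]")
  structure(list(weights = weights, scale = scale, provenance = provenance),
            class = "codon_weight_table")
}

#' @export
print.codon_weight_table <- function(x, ...) {
  cat("codon_weight_table (", x$scale, "), ", length(x$weights),
      " codons, provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' CAI relative adaptiveness from reference codon counts
#'
#' For every sense codon, w_c = count_c / max count among its synonymous
#' family, so family maxima are exactly 1. Codons with zero observed count
#' receive a pseudocount before normalization (avoids w = 0 and the log
#' divergence in the geometric mean).
#'
#' @param codon_counts named numeric vector of codon usage counts over a
#'   reference gene set (highly expressed genes).
#' @param pseudocount substituted for zero counts (default 0.5).
#' @return a `codon_weight_table` on the CAI scale.
#' @export
relative_adaptiveness <- function(codon_counts, pseudocount = 0.5) {
  if (length(codon_counts) == 0L) stop("empty reference codon counts")
  names(codon_counts) <- toupper(chartr("U", "T", names(codon_counts)))
  counts <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  known <- intersect(names(codon_counts), SENSE_CODONS)
  counts[known] <- codon_counts[known]
  if (sum(counts) <= 0) stop("reference set has no sense-codon counts")
  counts[counts == 0] <- pseudocount
  aa <- GENETIC_CODE_DNA[SENSE_CODONS]
  w <- counts
  for (a in unique(aa)) {
    fam <- SENSE_CODONS[aa == a]
    w[fam] <- counts[fam] / max(counts[fam])
  }
  codon_weight_table(w, "CAI", provenance = "relative_adaptiveness()")
}

#' Default wobble selective constraints for tAI
#'
#' Selective constraints s in [0, 1] per codon:anticodon pairing class,
#' following the published prokaryotic defaults: Watson-Crick pairings are
#' unpenalized; G34:U3, I34:C3, I34:A3 and U34:G3 wobble pairings carry
#' increasing penalties.
#'
#' @return named numeric vector of s values.
#' @export
default_s_values <- function() {
  c(wc = 0, g_t = 0.41, i_c = 0.28, i_a = 0.9999, t_g = 0.68)
}

#' tAI relative adaptiveness from tRNA gene copy numbers
#'
#' For each sense codon, absolute adaptiveness
#' W_c = sum_j (1 - s_ij) * tGCN_ij over the admissible codon-anticodon
#' pairings (the Watson-Crick anticodon plus the standard wobble anticodon
#' for the codon's third base); w_c = W_c / max W. Codons with W = 0 are
#' assigned the geometric mean of the nonzero weights.
#'
#' @param tgcn named non-negative integer vector, anticodon (DNA, 5'->3') ->
#'   tRNA gene copy number.
#' @param s_values wobble constraints, see [default_s_values()].
#' @return a `codon_weight_table` on the tAI scale.
#' @export
tai_weights <- function(tgcn, s_values = default_s_values()) {
  if (length(tgcn) == 0L || all(tgcn <= 0)) stop("all-zero tGCN table")
  if (any(tgcn < 0)) stop("negative tRNA gene copy number")
  if (any(s_values < 0) || any(s_values > 1)) stop("s values must lie in [0,1]")
  names(tgcn) <- toupper(chartr("U", "T", names(tgcn)))
  gcn <- function(ac) if (ac %in% names(tgcn)) as.numeric(tgcn[[ac]]) else 0
  W <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (codon in SENSE_CODONS) {
    n12 <- substr(codon, 1L, 2L)
    n3 <- substr(codon, 3L, 3L)
    perfect <- revcomp(codon)
    wob <- switch(n3,
      T = list(ac = revcomp(paste0(n12, "C")), s = s_values[["g_t"]]),
      C = list(ac = revcomp(paste0(n12, "T")), s = s_values[["i_c"]]),
      A = list(ac = revcomp(paste0(n12, "T")), s = s_values[["i_a"]]),
      G = list(ac = revcomp(paste0(n12, "A")), s = s_values[["t_g"]]))
    W[codon] <- (1 - s_values[["wc"]]) * gcn(perfect) +
      (1 - wob$s) * gcn(wob$ac)
  }
  if (max(W) <= 0) stop("no decoding capacity for any sense codon")
  w <- W / max(W)
  nz <- w > 0
  if (any(!nz)) w[!nz] <- exp(mean(log(w[nz])))
  codon_weight_table(w, "tAI", provenance = "tai_weights()")
}

#' Gene-level codon-optimality score (CAIg / tAIg)
#'
#' Geometric mean of the per-codon relative adaptiveness over the gene's
#' codons. On the CAI scale, codons without synonymous alternatives (ATG,
#' TGG) and stop codons are excluded (the Sharp-Li convention); on the tAI
#' scale only stop codons are excluded.
#'
#' @param cds coding sequence.
#' @param wt a `codon_weight_table`.
#' @return geometric-mean score in (0, 1].
#' @export
gene_score <- function(cds, wt) {
  stopifnot(inherits(wt, "codon_weight_table"))
  codons <- split_codons(cds)
  excl <- if (wt$scale == "CAI") c("ATG", "TGG", STOP_CODONS) else STOP_CODONS
  codons <- codons[!codons %in% excl]
  if (length(codons) == 0L) stop("no scorable codons in sequence")
  missing <- setdiff(unique(codons), names(wt$weights))
  if (length(missing) > 0L)
    stop("codons without weights: ", paste(missing, collapse = ", "))
  exp(mean(log(wt$weights[codons])))
}

#' GC content of a sequence, percent
#'
#' @param seq nucleotide string.
#' @return 100 * (#G + #C) / length.
#' @export
gc_content <- function(seq) {
  s <- norm_seq(seq)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Per-gene metric table (CAIg, tAIg, GC)
#'
#' @param seqs named character vector of coding sequences.
#' @param cai_wt CAI `codon_weight_table`.
#' @param tai_wt tAI `codon_weight_table`.
#' @return data.frame with columns gene_id, CAIg, tAIg, gc_percent.
#' @export
metric_table <- function(seqs, cai_wt, tai_wt) {
  data.frame(
    gene_id = names(seqs),
    CAIg = vapply(seqs, gene_score, numeric(1), wt = cai_wt),
    tAIg = vapply(seqs, gene_score, numeric(1), wt = tai_wt),
    gc_percent = vapply(seqs, gc_content, numeric(1)),
    row.names = NULL)
}

#' Donor-metric vs host-metric score-shift comparison
#'
#' Given gene-level scores for a common set of orthologues computed under the
#' donor species' codon metrics and under the host's metrics, tests each
#' sample for normality (Kolmogorov-Smirnov against a fitted normal) and
#' compares the means with a two-tailed t-test.
#'
#' @param donor_scores,host_scores numeric vectors of gene scores (n >= 3).
#' @return list with `normality` (per-sample D statistic and p),
#'   `mean_shift` (mean donor - mean host) and `t_p` (two-tailed p).
#' @export
#' @importFrom stats ks.test sd t.test
metric_shift_test <- function(donor_scores, host_scores) {
  if (length(donor_scores) < 3L || length(host_scores) < 3L)
    stop("need at least 3 scores per sample")
  ksn <- function(x) {
    k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    c(D = unname(k$statistic), p = k$p.value)
  }
  norm_tab <- rbind(donor = ksn(donor_scores), host = ksn(host_scores))
  shift <- mean(donor_scores) - mean(host_scores)
  # constant samples break t.test; degenerate case resolved by the means
  tp <- tryCatch(stats::t.test(donor_scores, host_scores)$p.value,
                 error = function(e)
                   if (isTRUE(all.equal(shift, 0))) 1 else 0)
  list(normality = as.data.frame(norm_tab), mean_shift = shift, t_p = tp)
}
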