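# Deep-sequencing enrichment statistics: normalized frequencies, fold
# change / log2(FC) fitness proxies, weighted population mean fitness,
# Shannon diversity.

#' Normalized variant frequencies at one timepoint
#'
#' f_i = n_i / N for one (timepoint, condition) column.
#'
#' @param cm a `count_matrix`.
#' @param timepoint one of day0/day1/day2.
#' @param condition drug concentration.
#' @return named numeric vector summing to 1.
#' @export
normalize_counts <- function(cm, timepoint, condition) {
  n <- counts_at(cm, timepoint, condition)
  N <- sum(n)
  if (N <= 0) stop("all-zero counts at ", timepoint, ", condition ",
                   cond_key(condition))
  n / N
}

#' Fold change and log2 fold change between two frequency vectors
#'
#' @param f_curr,f_prev aligned frequency vectors; `f_prev` must be
#'   positive (apply the pseudocount policy upstream, see
#'   [passage_fitness()]).
#' @return data.frame with FC and log2FC per variant.
#' @export
fold_change <- function(f_curr, f_prev) {
  if (length(f_curr) != length(f_prev)) stop("length mismatch")
  if (any(f_prev <= 0)) stop("non-positive baseline frequency; apply pseudocounts")
  FC <- f_curr / f_prev
  data.frame(variant_id = if (is.null(names(f_curr))) seq_along(f_curr)
             else names(f_curr),
             FC = unname(FC), log2FC = unname(log2(FC)), row.names = NULL)
}

#' Per-variant fitness proxies for one selection passage
#'
#' For passage day1 the baseline is day0 (FC = f(day1)/f(day0)); for passage
#' day2 the baseline is day1. Variants with zero reads at both timepoints of
#' the passage are excluded (and reported); if any included variant has a
#' zero at one of the two timepoints, a 0.5 pseudocount is added to every
#' included count before frequencies are formed, which keeps fold changes
#' finite while preserving ranks.
#'
#' @param cm a `count_matrix`.
#' @param condition drug concentration.
#' @param passage "day1" or "day2".
#' @param pseudocount value added under the zero policy (default 0.5).
#' @return data.frame (variant_id, condition, passage, f_prev, f_curr, FC,
#'   log2FC, zero_flag) with attribute `excluded` listing dropped variants.
#' @export
passage_fitness <- function(cm, condition, passage = c("day1", "day2"),
                            pseudocount = 0.5) {
  passage <- match.arg(passage)
  prev_tp <- if (passage == "day1") "day0" else "day1"
  n_prev <- counts_at(cm, prev_tp, condition)
  n_curr <- counts_at(cm, passage, condition)
  excluded <- names(n_prev)[n_prev == 0L & n_curr == 0L]
  keep <- !(names(n_prev) %in% excluded)
  n_prev <- n_prev[keep]; n_curr <- n_curr[keep]
  if (length(n_prev) == 0L) stop("no variants observed in this passage")
  zero_flag <- n_prev == 0L | n_curr == 0L
  if (any(zero_flag)) {
    n_prev <- n_prev + pseudocount
    n_curr <- n_curr + pseudocount
  }
  f_prev <- n_prev / sum(n_prev)
  f_curr <- n_curr / sum(n_curr)
  out <- data.frame(variant_id = names(f_prev),
                    condition = cond_key(condition), passage = passage,
                    f_prev = unname(f_prev), f_curr = unname(f_curr),
                    FC = unname(f_curr / f_prev),
                    log2FC = unname(log2(f_curr / f_prev)),
                    zero_flag = unname(zero_flag), row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Weighted population mean fitness
#'
#' w-bar = sum_i f_i(current day) * FC_i, the frequency-weighted average of
#' the enrichment scores; at day 0 it is 1 by definition. Weighting uses
#' current-day frequencies: weighting by the baseline day collapses the sum
#' to 1 identically (sum f0 * f1/f0 = 1), carrying no information.
#'
#' @param frequencies_curr current-day frequency vector.
#' @param FC aligned fold-change vector.
#' @return w-bar (dimensionless, >= 1 for a within-passage weighting).
#' @export
mean_fitness <- function(frequencies_curr, FC) {
  if (length(frequencies_curr) != length(FC)) stop("length mismatch")
  sum(frequencies_curr * FC)
}

#' Shannon diversity (nats)
#'
#' H = -sum_i p_i ln p_i over variant frequencies; zero entries contribute 0.
#'
#' @param frequencies numeric vector summing to 1.
#' @return H in nats; 0 for a monomorphic population, ln(s) when uniform.
#' @export
shannon <- function(frequencies) {
  if (any(frequencies < 0)) stop("negative frequency")
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", signif(sum(frequencies), 6), ")")
  p <- frequencies[frequencies > 0]
  -sum(p * log(p))
}

#' Diversity relative to the naive library
#'
#' @param H_t diversity at time t.
#' @param H_day0 diversity of the naive (day 0) library, set to 1.
#' @return H_t / H_day0.
#' @export
normalized_diversity <- function(H_t, H_day0) {
  if (H_day0 <= 0) stop("naive library has zero diversity")
  H_t / H_day0
}

#' Per-timepoint population summary for one condition
#'
#' w-bar (1 at day0 by definition, then the weighted mean enrichment of each
#' passage), Shannon diversity H, and H normalized to the naive library.
#'
#' @param cm a `count_matrix`.
#' @param condition drug concentration.
#' @param timepoints timepoints present (default day0/day1/day2).
#' @return data.frame (timepoint, condition, w_bar, H, H_norm).
#' @export
population_summary <- function(cm, condition,
                               timepoints = attr(cm, "timepoints")) {
  H <- vapply(timepoints, function(tp)
    shannon(normalize_counts(cm, tp, condition)), numeric(1))
  w_bar <- setNames(rep(NA_real_, length(timepoints)), timepoints)
  w_bar["day0"] <- 1
  for (tp in intersect(c("day1", "day2"), timepoints)) {
    ft <- passage_fitness(cm, condition, tp)
    w_bar[tp] <- mean_fitness(ft$f_curr, ft$FC)
  }
  data.frame(timepoint = timepoints, condition = cond_key(condition),
             w_bar = unname(w_bar[timepoints]), H = unname(H),
             H_norm = unname(H / H[["day0"]]), row.names = NULL)
}

#' Rank variants by fitness proxy
#'
#' Stable sort by log2FC (ties keep the original variant order), with the
#' partition index separating depleted (log2FC < 0) from enriched variants.
#'
#' @param fitness data.frame from [passage_fitness()].
#' @return the sorted data.frame with attribute `partition_index` = number
#'   of depleted variants (0 when all are enriched).
#' @export
rank_table <- function(fitness) {
  ord <- order(fitness$log2FC)   # order() is a stable sort
  out <- fitness[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "partition_index") <- sum(out$log2FC < 0)
  out
}
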