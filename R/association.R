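# Rank / linear association between variant fitness proxies (log2FC) and
# sequence features (CAIg, tAIg, GC, fragment dG, per-window dG).

#' Spearman rank correlation with two-sided p
#'
#' Average ranks for ties; exact permutation p for n <= 9 (no ties),
#' t-approximation otherwise. A constant vector leaves the correlation
#' undefined: an error state (NA r/p plus a message) is returned rather
#' than an exception so window sweeps can continue.
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @return list with r, p, n, and error (NULL when defined).
#' @export
#' @importFrom stats cor.test sd
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, error = "constant input"))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9L))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, error = NULL)
}

#' Pearson product-moment correlation with two-sided p
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @return list with r, p, n, and error (NULL when defined).
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, error = "constant input"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, error = NULL)
}

#' Feature-fitness association table
#'
#' One Spearman rank test per feature column against the fitness proxy.
#' Raw per-feature p-values are the primary output (matching the study's
#' reporting); a Benjamini-Hochberg column is emitted alongside but not
#' used for headline calls.
#'
#' @param fitness data.frame from [passage_fitness()] (uses log2FC, keyed
#'   by variant_id).
#' @param features data.frame with a variant_id column and numeric feature
#'   columns (e.g. CAIg, tAIg, gc_percent, dg_fragment).
#' @return data.frame (feature, condition, passage, r, p, n, p_bh).
#' @export
#' @importFrom stats p.adjust
assoc_table <- function(fitness, features) {
  stopifnot("variant_id" %in% names(features))
  m <- match(fitness$variant_id, features$variant_id)
  if (anyNA(m)) stop("features missing for some variants")
  feat_cols <- setdiff(names(features), "variant_id")
  rows <- lapply(feat_cols, function(fc) {
    a <- spearman_assoc(features[[fc]][m], fitness$log2FC)
    data.frame(feature = fc, condition = fitness$condition[1L],
               passage = fitness$passage[1L],
               r = a$r, p = a$p, n = a$n)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-window dG vs fitness correlation profile
#'
#' One Spearman (r, p) per sliding window between the variants' window dG
#' values and their fitness proxies. Positive r means higher (less stable)
#' dG associates with higher fitness. All profiles must share window size,
#' count and anchoring.
#'
#' @param fitness data.frame from [passage_fitness()].
#' @param profiles named list of `folding_profile`s (names are variant ids),
#'   or a numeric matrix with variants as rownames and windows as columns.
#' @return data.frame (window, r, p, n, p_bh).
#' @export
window_correlation_profile <- function(fitness, profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      all(vapply(profiles, inherits, logical(1), "folding_profile"))) {
    anchors <- vapply(profiles, function(p)
      paste(p$start_pos, p$window, length(p$dg)), character(1))
    if (length(unique(anchors)) != 1L)
      stop("profiles differ in window anchoring")
    mat <- do.call(rbind, lapply(profiles, `[[`, "dg"))
    rownames(mat) <- names(profiles)
  } else {
    mat <- as.matrix(profiles)
  }
  m <- match(fitness$variant_id, rownames(mat))
  if (anyNA(m)) stop("profiles missing for variants: ",
                     paste(utils::head(fitness$variant_id[is.na(m)], 3L),
                           collapse = ", "))
  mat <- mat[m, , drop = FALSE]
  res <- lapply(seq_len(ncol(mat)), function(w) {
    a <- spearman_assoc(mat[, w], fitness$log2FC)
    data.frame(window = w, r = a$r, p = a$p, n = a$n)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
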