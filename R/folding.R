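# 5'-end mRNA folding stability: MFE engine wrappers, sliding-window
# profiles, single-fragment dG and ORG-MOD ddG profiles.

#' Nearest-neighbor folding parameters (37 degrees C)
#'
#' Parameter set for the built-in minimum-free-energy engine: a 6x6 helix
#' stacking table over pair types (AU, UA, CG, GC, GU, UG; values kcal/mol),
#' logarithmic hairpin and interior/bulge loop penalties, and an affine
#' multiloop cost. Values follow the shape of the standard Turner rules with
#' simplified loop terms; every downstream use is comparative (ddG, rank
#' correlations), which is robust to a consistent engine.
#'
#' @return list of engine parameters.
#' @export
folding_params <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU     UA     CG     GC     GU     UG     (outer by row)
            -0.9,  -1.1,  -2.2,  -2.1,  -0.6,  -1.4,  # AU
            -1.3,  -0.9,  -2.4,  -2.1,  -1.0,  -1.3,  # UA
            -2.1,  -2.1,  -3.3,  -2.4,  -1.4,  -2.1,  # CG
            -2.4,  -2.2,  -3.4,  -3.3,  -1.5,  -2.5,  # GC
            -1.3,  -1.4,  -2.5,  -2.1,  -0.5,  -0.5,  # GU
            -1.0,  -0.6,  -1.5,  -1.4,  -0.3,  -0.5), # UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  rt37 <- 0.0019872 * 310.15
  list(stack = stack,
       hairpin_a = 5.4, hairpin_ln = 1.75 * rt37,
       loop_a = 3.7, loop_ln = 1.75 * rt37,
       ml_a = 4.6, ml_b = 0.4,
       min_hairpin = 3L, max_interior = 12L)
}

#' Built-in folding engine
#'
#' The engine contract is a function `seq -> dG` plus an identifier recorded
#' in profiles; external tools with full Turner parameters can be plugged in
#' through [folding_engine()] with the same signature.
#'
#' @param params parameter list from [folding_params()].
#' @return a folding engine (list with `fun` and `id`).
#' @export
default_engine <- function(params = folding_params()) {
  force(params)
  folding_engine(function(seq) mfe_cpp(seq, params$stack, params),
                 id = "codonfit-nn37-v1")
}

#' Wrap an external minimum-free-energy backend
#'
#' @param fun function taking a DNA string and returning dG (kcal/mol, <= 0).
#' @param id engine identifier recorded in output profiles.
#' @return a folding engine.
#' @export
folding_engine <- function(fun, id) {
  stopifnot(is.function(fun), is.character(id), length(id) == 1L)
  structure(list(fun = fun, id = id), class = "folding_engine")
}

#' Minimum free energy of a sequence's secondary structure
#'
#' Minimum free energy over non-pseudoknotted secondary structures under the
#' engine's nearest-neighbor parameters; 0 when no structure has negative
#' energy. Deterministic for a fixed engine.
#'
#' @param seq nucleotide string (RNA accepted, folded as its DNA spelling).
#' @param engine a folding engine (default: built-in DP).
#' @return dG in kcal/mol (<= 0).
#' @export
mfe <- function(seq, engine = default_engine()) {
  s <- norm_seq(seq)
  if (!nzchar(s)) stop("empty sequence")
  engine$fun(s)
}

#' Exhaustive-enumeration reference MFE
#'
#' Enumerates every non-crossing secondary structure (min hairpin loop 3)
#' and scores each under the same parameter set as the DP engine, by an
#' independent code path (loop decomposition of an explicit pair set).
#' Exponential in length; intended for sequences <= ~16 nt as a
#' cross-validation oracle for [mfe()].
#'
#' @param seq nucleotide string.
#' @param params parameters from [folding_params()].
#' @return minimum energy over all structures (0 for the open chain).
#' @export
mfe_enumerate <- function(seq, params = folding_params()) {
  s <- strsplit(norm_seq(seq), "")[[1]]
  n <- length(s)
  if (n > 18L) stop("enumeration oracle limited to <= 18 nt")
  ptype <- function(a, b) {
    key <- paste0(a, b)
    switch(key, AT = 1L, TA = 2L, CG = 3L, GC = 4L, GT = 5L, TG = 6L, 0L)
  }
  mh <- params$min_hairpin
  # all structures over [i, j] as lists of pair matrices
  structs <- function(i, j) {
    if (j - i < mh + 1L) return(list(matrix(integer(0), ncol = 2)))
    out <- structs(i + 1L, j)                      # i unpaired
    for (k in (i + mh + 1L):j) {
      if (ptype(s[i], s[k]) == 0L) next
      left <- structs(i + 1L, k - 1L)
      right <- if (k + 1L <= j) structs(k + 1L, j)
               else list(matrix(integer(0), ncol = 2))
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
    }
    out
  }
  score <- function(pairs) {
    if (nrow(pairs) == 0L) return(0)
    e <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      # children: pairs directly nested inside (i, j)
      inside <- pairs[pairs[, 1L] > i & pairs[, 2L] < j, , drop = FALSE]
      if (nrow(inside) > 0L) {
        top <- vapply(seq_len(nrow(inside)), function(k) {
          !any(inside[, 1L] < inside[k, 1L] & inside[, 2L] > inside[k, 2L])
        }, logical(1))
        inside <- inside[top, , drop = FALSE]
      }
      nc <- nrow(inside)
      if (nc == 0L) {
        L <- j - i - 1L
        e <- e + params$hairpin_a +
          if (L > mh) params$hairpin_ln * log(L / mh) else 0
      } else if (nc == 1L) {
        p <- inside[1L, 1L]; q <- inside[1L, 2L]
        size <- (p - i - 1L) + (j - q - 1L)
        if (size == 0L) {
          e <- e + params$stack[ptype(s[i], s[j]), ptype(s[p], s[q])]
        } else if (size > params$max_interior) {
          return(Inf)
        } else {
          e <- e + params$loop_a + params$loop_ln * log(size)
        }
      } else {
        e <- e + params$ml_a + params$ml_b * (nc + 1L)
      }
    }
    e
  }
  min(0, vapply(structs(1L, n), score, numeric(1)))
}

#' Sliding-window folding-stability profile
#'
#' dG of consecutive windows of `window` nt, stepping 1 nt, anchored at the
#' transcription start (default -25) under the no-position-0 convention.
#' The study's defaults are 100 windows for whole-gene comparisons and 110
#' for library constructs.
#'
#' @param tm a `transcript_model` (or a plain nucleotide string, in which
#'   case `start_pos` indexes it 1-based).
#' @param window window size in nt (default 30, a ribosome footprint).
#' @param n_windows number of windows; default: as many as fit.
#' @param start_pos transcript coordinate of window 1 (default the TSS).
#' @param engine folding engine.
#' @return object of class `folding_profile` with per-window dG.
#' @export
window_profile <- function(tm, window = 30L, n_windows = NULL,
                           start_pos = NULL, engine = default_engine()) {
  if (inherits(tm, "transcript_model")) {
    if (is.null(start_pos)) start_pos <- tm$tss_offset
    full <- tx_slice(tm, start_pos, nchar(tm$cds))
    gene_id <- tm$gene_id
  } else {
    full <- norm_seq(tm)
    if (is.null(start_pos)) start_pos <- 1L
    gene_id <- "seq"
  }
  avail <- nchar(full) - window + 1L
  if (is.null(n_windows)) n_windows <- avail
  if (n_windows < 1L || avail < n_windows)
    stop("transcript supports only ", max(avail, 0L), " windows of ", window,
         " nt; ", n_windows, " requested")
  dg <- vapply(seq_len(n_windows), function(i)
    engine$fun(substr(full, i, i + window - 1L)), numeric(1))
  structure(list(gene_id = gene_id, window = as.integer(window),
                 start_pos = as.integer(start_pos), dg = dg,
                 engine_id = engine$id),
            class = "folding_profile")
}

#' @export
print.folding_profile <- function(x, ...) {
  cat("folding_profile ", x$gene_id, ": ", length(x$dg), " windows of ",
      x$window, " nt from position ", x$start_pos, " (engine ", x$engine_id,
      ")\n", sep = "")
  invisible(x)
}

#' Single-fragment folding stability
#'
#' dG of one contiguous 5'-end fragment. The study's fragment spans
#' nucleotide -25 (transcription start) to +120 (145 nt) to cover
#' diversified codons 1-30; figure-style analyses use -25..+90.
#'
#' @param tm a `transcript_model`.
#' @param from,to transcript coordinates (no position 0). Defaults -25, +120.
#' @param engine folding engine.
#' @return dG in kcal/mol.
#' @export
fragment_dg <- function(tm, from = -25L, to = 120L,
                        engine = default_engine()) {
  if (from >= to) stop("from must be < to")
  engine$fun(tx_slice(tm, from, to))
}

#' ORG-vs-MOD stability-difference profile
#'
#' Elementwise ddG = dG_mod - dG_org per window; negative values mean the
#' MOD (frequent-codon) sequence is overstabilized relative to ORG.
#'
#' @param profile_org,profile_mod `folding_profile`s with identical window
#'   size, count and anchoring.
#' @return numeric vector of ddG values.
#' @export
ddg_profile <- function(profile_org, profile_mod) {
  stopifnot(inherits(profile_org, "folding_profile"),
            inherits(profile_mod, "folding_profile"))
  if (length(profile_org$dg) != length(profile_mod$dg))
    stop("window count mismatch: ", length(profile_org$dg), " vs ",
         length(profile_mod$dg))
  if (profile_org$start_pos != profile_mod$start_pos ||
      profile_org$window != profile_mod$window)
    stop("profiles are not identically anchored")
  profile_mod$dg - profile_org$dg
}

#' Window dG matrix for a whole variant library
#'
#' Computes the sliding-window folding profile for every variant of a
#' combinatorial library sharing one regulatory sequence. Because variants
#' are identical outside the diversified region, each window position has
#' few distinct sequences; duplicates are folded once.
#'
#' @param seqs named character vector of variant CDSs.
#' @param regulatory_seq shared upstream sequence.
#' @param n_windows number of windows (default 110, the library-construct
#'   profile).
#' @param window window size (default 30).
#' @param start_pos transcript coordinate of window 1 (default -25).
#' @param engine folding engine.
#' @return numeric matrix, variants x windows.
#' @export
library_window_profiles <- function(seqs, regulatory_seq, n_windows = 110L,
                                    window = 30L, start_pos = -25L,
                                    engine = default_engine()) {
  reg_len <- nchar(regulatory_seq)
  stopifnot(start_pos < 0L, reg_len >= -start_pos)
  tail_reg <- substr(regulatory_seq, reg_len + start_pos + 1L, reg_len)
  full <- paste0(tail_reg, seqs)
  need <- n_windows + window - 1L
  if (any(nchar(full) < need))
    stop("transcripts too short for ", n_windows, " windows of ", window, " nt")
  mat <- matrix(NA_real_, length(seqs), n_windows,
                dimnames = list(names(seqs), NULL))
  for (w in seq_len(n_windows)) {
    sub <- substr(full, w, w + window - 1L)
    uniq <- unique(sub)
    dg <- vapply(uniq, engine$fun, numeric(1))
    mat[, w] <- dg[match(sub, uniq)]
  }
  mat
}

#' Write a folding profile as TSV
#'
#' Columns: window_index, start_pos, dg_kcal_mol. Start positions follow the
#' no-position-0 transcript convention.
#'
#' @param profile a `folding_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  starts <- profile$start_pos + seq_along(profile$dg) - 1L
  if (profile$start_pos < 0L) starts[starts >= 0L] <- starts[starts >= 0L] + 1L
  utils::write.table(
    data.frame(window_index = seq_along(profile$dg), start_pos = starts,
               dg_kcal_mol = profile$dg),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
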