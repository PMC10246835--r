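# Combinatorial ORG/MOD synonymous-codon libraries: diff positions, variant
# enumeration by bitmask, block-swap chimeras, exact-match read counting
# and coverage statistics.

#' Codon positions where two synonymous sequences differ
#'
#' Returns the 1-based codon indices inside `codon_range` where the ORG and
#' MOD sequences differ at the nucleotide level. Any non-synonymous
#' difference anywhere in the CDS is an error (the ORG/MOD pairing must
#' preserve the protein).
#'
#' @param org_cds,mod_cds equal-length coding sequences with identical
#'   translation.
#' @param codon_range inclusive 1-based codon interval, e.g. `c(1, 15)`;
#'   codon 1 is the start codon.
#' @return integer vector of differing codon indices within the range.
#' @export
diff_positions <- function(org_cds, mod_cds, codon_range) {
  org <- split_codons(org_cds)
  mod <- split_codons(mod_cds)
  if (length(org) != length(mod)) stop("ORG and MOD lengths differ")
  ns <- which(GENETIC_CODE_DNA[org] != GENETIC_CODE_DNA[mod])
  if (length(ns) > 0L)
    stop("non-synonymous difference at codon ", ns[1L], " (", org[ns[1L]],
         " vs ", mod[ns[1L]], ")")
  stopifnot(length(codon_range) == 2L, codon_range[1L] >= 1L,
            codon_range[2L] <= length(org), codon_range[1L] <= codon_range[2L])
  idx <- which(org != mod)
  idx[idx >= codon_range[1L] & idx <= codon_range[2L]]
}

#' Build a combinatorial variant library
#'
#' The library is the set of 2^k sequences obtained from the MOD backbone by
#' restoring ORG codons at any subset of the k differing positions within
#' `codon_range`. Variants are identified by a bitmask over the ordered
#' differing positions (bit set = ORG codon at that position), rendered as
#' e.g. `"c2=O,c5=M,..."`; the all-MOD and all-ORG variants carry the
#' reserved aliases `"M"` and `"O"`.
#'
#' @param gene_id identifier.
#' @param org_cds,mod_cds synonymous coding sequences.
#' @param codon_range diversified codon interval (1-15 or 16-30 in the study).
#' @param max_k refuse enumeration above this many differing positions
#'   (default 20; 2^20 sequences) unless raised explicitly.
#' @return object of class `variant_library`.
#' @export
variant_library <- function(gene_id, org_cds, mod_cds, codon_range,
                            max_k = 20L) {
  org_cds <- norm_seq(org_cds); mod_cds <- norm_seq(mod_cds)
  dp <- diff_positions(org_cds, mod_cds, codon_range)
  if (length(dp) > max_k)
    stop(length(dp), " diversified positions exceed cap of ", max_k)
  structure(list(gene_id = gene_id, org_cds = org_cds, mod_cds = mod_cds,
                 codon_range = as.integer(codon_range),
                 diff_positions = as.integer(dp)),
            class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  cat("variant_library ", x$gene_id, ": codons ", x$codon_range[1L], "-",
      x$codon_range[2L], ", k = ", length(x$diff_positions),
      " diversified positions (", 2^length(x$diff_positions),
      " variants)\n", sep = "")
  invisible(x)
}

#' Variant id for a bitmask
#'
#' @param lib a `variant_library`.
#' @param mask logical vector over `diff_positions` (TRUE = ORG codon).
#' @return variant id string ("M", "O", or "c<i>=O/M" per position).
#' @export
mask_id <- function(lib, mask) {
  stopifnot(length(mask) == length(lib$diff_positions))
  if (!any(mask)) return("M")
  if (all(mask)) return("O")
  paste(paste0("c", lib$diff_positions, "=", ifelse(mask, "O", "M")),
        collapse = ",")
}

#' Parse a variant id back to its bitmask
#'
#' @param lib a `variant_library`.
#' @param id variant id produced by [mask_id()].
#' @return logical vector over the library's diff positions.
#' @export
parse_mask <- function(lib, id) {
  k <- length(lib$diff_positions)
  if (id == "M") return(rep(FALSE, k))
  if (id == "O") return(rep(TRUE, k))
  parts <- strsplit(id, ",", fixed = TRUE)[[1]]
  pos <- as.integer(sub("^c(\\d+)=.*$", "\\1", parts))
  state <- sub("^c\\d+=", "", parts)
  if (!setequal(pos, lib$diff_positions) || !all(state %in% c("O", "M")))
    stop("variant id does not match the library: ", id)
  setNames(state == "O", paste0("c", pos))[paste0("c", lib$diff_positions)]
}

#' Sequence of one library variant
#'
#' MOD backbone with ORG codons substituted at the set bits of the mask.
#'
#' @param lib a `variant_library`.
#' @param mask logical vector over diff positions.
#' @return full-length CDS of the variant.
#' @export
variant_seq <- function(lib, mask) {
  stopifnot(length(mask) == length(lib$diff_positions))
  codons <- split_codons(lib$mod_cds)
  org <- split_codons(lib$org_cds)
  at <- lib$diff_positions[mask]
  codons[at] <- org[at]
  paste(codons, collapse = "")
}

#' Enumerate library variants
#'
#' @param lib a `variant_library`.
#' @param masks "all" (default) for all 2^k variants, or a logical matrix
#'   with k columns, one row per requested variant.
#' @return named character vector of CDS sequences, names are variant ids.
#' @export
enumerate_variants <- function(lib, masks = "all") {
  k <- length(lib$diff_positions)
  if (identical(masks, "all")) {
    if (k == 0L) masks <- matrix(logical(0), nrow = 1L, ncol = 0L)
    else {
      grid <- do.call(expand.grid, rep(list(c(FALSE, TRUE)), k))
      masks <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
    }
  }
  if (k == 0L) return(setNames(paste(split_codons(lib$mod_cds),
                                     collapse = ""), "M"))
  masks <- matrix(as.logical(masks), ncol = k)
  ids <- apply(masks, 1L, function(m) mask_id(lib, m))
  seqs <- apply(masks, 1L, function(m) variant_seq(lib, m))
  setNames(seqs, ids)
}

#' Block-swap chimera
#'
#' MOD backbone with an entire codon block restored to ORG codons (the
#' 30-codon stretch scan used to localize codon-bias fitness effects).
#'
#' @param org_cds,mod_cds synonymous coding sequences.
#' @param block inclusive codon interval `c(from, to)`; `c(0, 0)` (empty)
#'   returns the MOD sequence unchanged.
#' @return chimeric CDS.
#' @export
make_block_chimera <- function(org_cds, mod_cds, block) {
  org <- split_codons(org_cds); mod <- split_codons(mod_cds)
  if (length(org) != length(mod)) stop("ORG and MOD lengths differ")
  ns <- which(GENETIC_CODE_DNA[org] != GENETIC_CODE_DNA[mod])
  if (length(ns) > 0L) stop("non-synonymous difference at codon ", ns[1L])
  if (identical(as.integer(block), c(0L, 0L)) || length(block) == 0L)
    return(paste(mod, collapse = ""))
  stopifnot(length(block) == 2L, block[1L] <= block[2L])
  if (block[1L] < 1L || block[2L] > length(mod)) stop("block out of range")
  at <- seq.int(block[1L], block[2L])
  mod[at] <- org[at]
  paste(mod, collapse = "")
}

#' Diversified-region subsequence of a CDS
#'
#' @param lib a `variant_library`.
#' @param cds full-length CDS.
#' @return nucleotide substring covering `codon_range`.
#' @export
region_seq <- function(lib, cds) {
  substr(cds, (lib$codon_range[1L] - 1L) * 3L + 1L, lib$codon_range[2L] * 3L)
}

#' Assign reads to library variants by exact match
#'
#' Reads shorter than the expected length are discarded (the study's length
#' filter); surviving reads are assigned by exact match of the diversified
#' region to an enumerated variant, with no error tolerance (a 1-mismatch
#' allowance could mis-assign between variants that differ at single
#' positions). Non-matching reads are counted as unassigned. Reads are
#' conserved: assigned + unassigned + discarded = input.
#'
#' @param reads character vector of read sequences (e.g. from [read_fastq()]).
#' @param lib a `variant_library`.
#' @param region_start 1-based offset of the diversified region within a
#'   full-length read (default: region position within the CDS, i.e. reads
#'   that start at the first CDS base).
#' @param expected_length minimum read length (default: enough to span the
#'   diversified region).
#' @return list with `counts` (named integer vector per variant id),
#'   `unassigned`, `discarded` and `total`.
#' @export
count_reads <- function(reads, lib, region_start = NULL,
                        expected_length = NULL) {
  variants <- enumerate_variants(lib)
  if (length(variants) == 0L) stop("empty library")
  regions <- vapply(variants, function(s) region_seq(lib, s), character(1))
  if (anyDuplicated(regions))
    stop("library variants are not distinguishable within the region")
  if (is.null(region_start))
    region_start <- (lib$codon_range[1L] - 1L) * 3L + 1L
  region_len <- nchar(regions[[1L]])
  if (is.null(expected_length))
    expected_length <- region_start + region_len - 1L
  keep <- nchar(reads) >= expected_length
  discarded <- sum(!keep)
  obs <- substr(reads[keep], region_start, region_start + region_len - 1L)
  hit <- match(obs, regions)
  counts <- setNames(integer(length(variants)), names(variants))
  tab <- table(factor(names(variants)[hit[!is.na(hit)]],
                      levels = names(variants)))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, unassigned = sum(is.na(hit)),
       discarded = discarded, total = length(reads))
}

#' Library coverage: percent of theoretical variants observed
#'
#' @param observed_variant_ids character vector of observed ids.
#' @param k number of diversified positions (theoretical count 2^k).
#' @param lib optional `variant_library` to validate ids against.
#' @return percent of the 2^k combinations observed.
#' @export
coverage <- function(observed_variant_ids, k, lib = NULL) {
  obs <- unique(observed_variant_ids)
  if (!is.null(lib)) {
    valid <- names(enumerate_variants(lib))
    bad <- setdiff(obs, valid)
    if (length(bad) > 0L)
      stop("observed ids outside the enumerable set: ",
           paste(utils::head(bad, 3L), collapse = ", "))
  }
  100 * length(obs) / 2^k
}
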