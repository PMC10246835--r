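#' @useDynLib codonfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

# -- sequence normalization ---------------------------------------------------

#' Normalize a nucleotide string
#'
#' Uppercases, converts RNA (U) to DNA (T) and validates the alphabet.
#' All sequences are stored internally as DNA; folding reports may re-emit U.
#'
#' @param x character scalar, nucleotide sequence (DNA or RNA).
#' @return normalized DNA string (A/C/G/T only).
#' @export
norm_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string")
  s <- chartr("u", "t", toupper(x))
  s <- chartr("U", "T", s)
  if (nzchar(s) && grepl("[^ACGT]", s))
    stop("non-nucleotide characters in sequence: ",
         paste(unique(strsplit(gsub("[ACGT]", "", s), "")[[1]]), collapse = ","))
  s
}

# -- FASTA / FASTQ ------------------------------------------------------------

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and U is normalized to T. Multi-line records are
#' concatenated. Duplicate record ids and empty records are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(vapply(seqs, norm_seq, character(1), USE.NAMES = FALSE), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file as plain sequences
#'
#' Qualities are ignored; reads feed the exact-match variant counter.
#'
#' @param path path to a FASTQ file.
#' @return character vector of read sequences (normalized to DNA).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  vapply(as.character(set), norm_seq, character(1), USE.NAMES = FALSE)
}

#' Write reads to FASTQ (uniform placeholder qualities)
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq(1L, 4L * n, 4L)] <- paste0("@read", seq_len(n))
    lines[seq(2L, 4L * n, 4L)] <- reads
    lines[seq(3L, 4L * n, 4L)] <- "+"
    lines[seq(4L, 4L * n, 4L)] <- vapply(nchar(reads), function(k)
      strrep("I", k), character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

# -- transcript model ---------------------------------------------------------

#' Build a transcript model with a -25 transcription-start convention
#'
#' Couples a 5' regulatory sequence to a coding sequence. Transcript
#' coordinates follow the biological convention with no position 0:
#' ..., -2, -1, +1, +2, ... where +1 is the first CDS nucleotide and the
#' transcription start defaults to -25 (the host folA convention).
#'
#' @param regulatory_seq nucleotide string covering at least positions
#'   `tss_offset`..-1 immediately upstream of the CDS.
#' @param cds coding sequence; length divisible by 3, starting with ATG/GTG/TTG.
#' @param tss_offset negative integer, transcription start position relative
#'   to the first CDS nucleotide. Default -25.
#' @param gene_id identifier carried through downstream tables.
#' @return object of class `transcript_model`.
#' @export
build_transcript <- function(regulatory_seq, cds, tss_offset = -25L,
                             gene_id = "gene") {
  regulatory_seq <- norm_seq(regulatory_seq)
  cds <- norm_seq(cds)
  tss_offset <- as.integer(tss_offset)
  if (is.na(tss_offset) || tss_offset >= 0L)
    stop("tss_offset must be a negative integer")
  if (nchar(cds) %% 3L != 0L)
    stop("cds length (", nchar(cds), ") not divisible by 3")
  if (!substr(cds, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    stop("cds does not begin with a start codon")
  if (nchar(regulatory_seq) < -tss_offset)
    stop("regulatory region (", nchar(regulatory_seq),
         " nt) shorter than |tss_offset| = ", -tss_offset)
  structure(
    list(gene_id = gene_id, regulatory_seq = regulatory_seq, cds = cds,
         tss_offset = tss_offset),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$gene_id, ": ", nchar(x$cds), " nt CDS, ",
      nchar(x$regulatory_seq), " nt regulatory, TSS at ", x$tss_offset,
      "\n", sep = "")
  invisible(x)
}

#' Slice a transcript by biological coordinates
#'
#' Inclusive slice between two transcript positions under the no-position-0
#' convention; positions -1 and +1 are adjacent, so the slice length is
#' `to - from` when `from < 0 < to` and `to - from + 1` otherwise.
#'
#' @param tm a `transcript_model`.
#' @param from,to transcript coordinates (non-zero integers), `from < to` or
#'   equal sign-respecting positions.
#' @return nucleotide string.
#' @export
tx_slice <- function(tm, from, to) {
  stopifnot(inherits(tm, "transcript_model"))
  from <- as.integer(from); to <- as.integer(to)
  if (from == 0L || to == 0L) stop("there is no transcript position 0")
  if (from > to) stop("from must be <= to")
  reg_len <- nchar(tm$regulatory_seq)
  cds_len <- nchar(tm$cds)
  if (from < 0L && -from > reg_len)
    stop("position ", from, " precedes the available regulatory sequence")
  if (to > cds_len)
    stop("position ", to, " beyond CDS end (+", cds_len, ")")
  pos <- setdiff(seq.int(from, to), 0L)
  chars <- vapply(pos, function(p) {
    if (p < 0L) substr(tm$regulatory_seq, reg_len + p + 1L, reg_len + p + 1L)
    else substr(tm$cds, p, p)
  }, character(1))
  paste(chars, collapse = "")
}

#' Full transcript sequence from the transcription start
#'
#' @param tm a `transcript_model`.
#' @return nucleotide string from `tss_offset` through the CDS end.
#' @export
transcript_seq <- function(tm) {
  tx_slice(tm, tm$tss_offset, nchar(tm$cds))
}

# -- condition keys -----------------------------------------------------------

#' Canonical key for a drug-concentration condition
#'
#' Conditions are decimal micrograms per ml; keys are compared as canonical
#' strings with trailing zeros stripped, avoiding float-key drift
#' ("0.30" and 0.3 map to the same key).
#'
#' @param x numeric or character concentration(s).
#' @return character vector of canonical keys.
#' @export
cond_key <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(!is.finite(v)) || any(v < 0))
    stop("unparseable or negative condition value: ",
         paste(x[is.na(v) | !is.finite(suppressWarnings(as.numeric(x))) ],
               collapse = ", "))
  s <- sprintf("%.10f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# -- count matrix -------------------------------------------------------------

TIMEPOINTS <- c("day0", "day1", "day2")

#' Construct a variant read-count matrix
#'
#' @param df data.frame with columns variant_id, timepoint, condition, count.
#' @return object of class `count_matrix`: an integer matrix with variants as
#'   rows and `timepoint@condition` columns, zero-filled for missing
#'   combinations, plus `timepoints` and `conditions` attributes.
#' @export
count_matrix <- function(df) {
  need <- c("variant_id", "timepoint", "condition", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty count table")
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt))) stop("unparseable count value")
  if (any(cnt < 0)) stop("negative read count")
  if (any(cnt != floor(cnt))) stop("non-integer read count")
  tp <- as.character(df$timepoint)
  bad <- setdiff(unique(tp), TIMEPOINTS)
  if (length(bad) > 0L)
    stop("unknown timepoint(s): ", paste(bad, collapse = ", "))
  cond <- cond_key(df$condition)
  key <- paste(df$variant_id, tp, cond, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (variant, timepoint, condition) rows summed")
    agg <- rowsum(cnt, key)
    key <- rownames(agg); cnt <- as.numeric(agg[, 1L])
    parts <- strsplit(key, "\r", fixed = TRUE)
    df <- data.frame(variant_id = vapply(parts, `[`, "", 1L),
                     timepoint = vapply(parts, `[`, "", 2L),
                     condition = vapply(parts, `[`, "", 3L))
    tp <- df$timepoint; cond <- df$condition
  }
  variants <- sort(unique(as.character(df$variant_id)))
  tps <- TIMEPOINTS[TIMEPOINTS %in% unique(tp)]
  conds <- unique(cond)[order(as.numeric(unique(cond)))]
  cols <- as.vector(t(outer(tps, conds, paste, sep = "@")))
  m <- matrix(0L, length(variants), length(cols),
              dimnames = list(variants, cols))
  m[cbind(match(as.character(df$variant_id), variants),
          match(paste(tp, cond, sep = "@"), cols))] <- as.integer(cnt)
  structure(m, class = c("count_matrix", "matrix"),
            timepoints = tps, conditions = conds)
}

#' Read a variant count table (TSV)
#'
#' Expects a tab-separated file with header
#' `variant_id  timepoint  condition  count`.
#'
#' @param path input TSV path.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  count_matrix(df)
}

#' Write a count matrix as a long TSV
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  cols <- colnames(cm)
  parts <- strsplit(cols, "@", fixed = TRUE)
  df <- data.frame(
    variant_id = rep(rownames(cm), times = length(cols)),
    timepoint = rep(vapply(parts, `[`, "", 1L), each = nrow(cm)),
    condition = rep(vapply(parts, `[`, "", 2L), each = nrow(cm)),
    count = as.vector(cm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one (timepoint, condition) count column
#'
#' @param cm a `count_matrix`.
#' @param timepoint one of day0/day1/day2.
#' @param condition concentration (numeric or canonical string).
#' @return named integer vector of counts per variant.
#' @export
counts_at <- function(cm, timepoint, condition) {
  stopifnot(inherits(cm, "count_matrix"))
  col <- paste(timepoint, cond_key(condition), sep = "@")
  if (!col %in% colnames(cm))
    stop("no column for ", col, " in count matrix")
  setNames(as.integer(cm[, col]), rownames(cm))
}

# -- small table I/O ----------------------------------------------------------

#' Read a codon-weight table (TSV: codon, weight)
#'
#' @param path input path.
#' @param scale "CAI" or "tAI" (metadata only).
#' @return a `codon_weight_table` (see [codon_weight_table()]).
#' @export
read_weight_table <- function(path, scale = c("CAI", "tAI")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  codon_weight_table(setNames(as.numeric(df$weight), df$codon), scale,
                     provenance = path)
}

#' Write a codon-weight table to TSV
#'
#' @param wt a `codon_weight_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(wt, path) {
  utils::write.table(
    data.frame(codon = names(wt$weights), weight = unname(wt$weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tRNA gene-copy-number table (TSV: anticodon, copies)
#'
#' @param path input path.
#' @return named integer vector keyed by anticodon (DNA alphabet).
#' @export
read_tgcn <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- setNames(as.integer(df$copies), toupper(df$anticodon))
  if (any(is.na(v)) || any(v < 0L)) stop("tGCN copies must be non-negative integers")
  v
}
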