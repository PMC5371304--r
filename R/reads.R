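# Small RNA-seq read processing: adapter (linker) trimming, quality
# filtering, contaminant removal, exact-match miRNA counting and TPM.

check_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad))
    stop2("malformed read record (length mismatch): ",
          reads$id[which(bad)[1]])
  invisible(reads)
}

#' Trim the 3' adapter from reads
#'
#' Each read is truncated at the first exact occurrence of the adapter's
#' (at most) 8-nt prefix; reads without an occurrence pass unchanged. The
#' quality string is truncated alongside the sequence. An occurrence at
#' position 1 yields an empty read, which the length filter later removes.
#'
#' @param reads Data frame with columns id, sequence, quality.
#' @param adapter Non-empty DNA string.
#' @return Trimmed reads data frame.
#' @export
trim_adapter <- function(reads, adapter) {
  check_reads(reads)
  if (!is.character(adapter) || length(adapter) != 1L || nchar(adapter) < 1)
    stop2("'adapter' must be a non-empty string")
  if (nrow(reads) == 0) return(reads)
  pfx <- adapter_prefix(adapter)
  pos <- regexpr(pfx, reads$sequence, fixed = TRUE)
  hit <- pos > 0
  reads$sequence[hit] <- substr(reads$sequence[hit], 1L, pos[hit] - 1L)
  reads$quality[hit] <- substr(reads$quality[hit], 1L, pos[hit] - 1L)
  reads
}

#' Quality-filter reads
#'
#' A read passes iff its length is at least `min_len` AND the fraction of
#' bases at or above `phred_floor` is at least `hq_fraction` AND the
#' fraction of uncertain (N) bases is at most `max_uncertain`. Both
#' fraction boundaries are inclusive. Failures are attributed to the first
#' failing rule in the fixed order length, quality, uncertainty.
#'
#' @param reads Data frame with columns id, sequence, quality (adapter
#'   already removed).
#' @param min_len Minimum read length in bases.
#' @param phred_floor Phred score defining a high-quality base.
#' @param hq_fraction Minimum fraction of high-quality bases.
#' @param max_uncertain Maximum fraction of N bases.
#' @return List with `reads` (the passing records) and `report` (a data
#'   frame of reason/count rows: pass, length, quality, uncertainty).
#' @export
filter_reads_qc <- function(reads, min_len = 16L, phred_floor = 20L,
                            hq_fraction = 0.90, max_uncertain = 0.05) {
  check_reads(reads)
  n <- nrow(reads)
  if (n == 0) {
    return(list(reads = reads,
                report = data.frame(
                  reason = c("pass", "length", "quality", "uncertainty"),
                  count = 0L, stringsAsFactors = FALSE)))
  }
  len <- nchar(reads$sequence)
  floor_raw <- as.raw(phred_floor + 33L)
  hq <- vapply(reads$quality,
               function(q) sum(charToRaw(q) >= floor_raw), 0L,
               USE.NAMES = FALSE)
  n_count <- nchar(reads$sequence) -
    nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  fail_len <- len < min_len
  fail_q <- !fail_len & (hq / len < hq_fraction)
  fail_n <- !fail_len & !fail_q & (n_count / len > max_uncertain)
  pass <- !fail_len & !fail_q & !fail_n
  list(reads = reads[pass, , drop = FALSE],
       report = data.frame(
         reason = c("pass", "length", "quality", "uncertainty"),
         count = c(sum(pass), sum(fail_len), sum(fail_q), sum(fail_n)),
         stringsAsFactors = FALSE))
}

#' Remove contaminant (rRNA/tRNA/snRNA) reads
#'
#' A read is removed iff its sequence is an exact, same-strand substring of
#' any contaminant reference sequence.
#'
#' @param reads Data frame with columns id, sequence, quality.
#' @param contaminant_ref Named character vector of uppercase DNA references.
#' @return Reads data frame with contaminant reads removed.
#' @export
remove_contaminants <- function(reads, contaminant_ref) {
  check_reads(reads)
  if (length(contaminant_ref) == 0) {
    warning("empty contaminant reference; returning reads unchanged")
    return(reads)
  }
  if (nrow(reads) == 0) return(reads)
  u <- unique(reads$sequence)
  hit <- vapply(u, function(s)
    nzchar(s) && any(grepl(s, contaminant_ref, fixed = TRUE)), TRUE,
    USE.NAMES = FALSE)
  drop <- reads$sequence %in% u[hit]
  reads[!drop, , drop = FALSE]
}

#' Count miRNAs by exact match to mature sequences
#'
#' A read increments a miRNA's count iff it exactly equals the mature
#' sequence; all other reads are discarded.
#'
#' @param reads A per-sample data frame (columns id, sequence, quality) or a
#'   named list of such data frames (one per sample).
#' @param mature_ref Named character vector of unique mature sequences.
#' @return A `mirna_count_table`: list with `mirna_ids`, `sample_ids` and an
#'   integer `counts` matrix.
#' @export
count_mirna <- function(reads, mature_ref) {
  if (anyDuplicated(mature_ref))
    stop2("duplicate mature sequences in reference")
  if (is.data.frame(reads)) reads <- list(sample1 = reads)
  counts <- vapply(reads, function(r) {
    check_reads(r)
    idx <- match(r$sequence, mature_ref)
    tab <- tabulate(idx[!is.na(idx)], nbins = length(mature_ref))
    as.integer(tab)
  }, integer(length(mature_ref)))
  counts <- matrix(counts, nrow = length(mature_ref),
                   dimnames = list(names(mature_ref), names(reads)))
  structure(list(mirna_ids = names(mature_ref),
                 sample_ids = names(reads),
                 counts = counts, tpm = NULL),
            class = "mirna_count_table")
}

#' Compute TPM with all-zero exclusion and pseudo-value replacement
#'
#' Per sample, TPM = count x 10^6 / total sample count. miRNAs with zero
#' counts in every sample are dropped; remaining zero cells are then set to
#' the pseudo-value so that log-scale differential analysis is defined.
#' Pre-replacement TPM columns (kept in `tpm_unadjusted`) each sum to 10^6.
#'
#' @param table A `mirna_count_table` from [count_mirna()].
#' @param pseudo Pseudo-TPM assigned to zero cells after exclusion.
#' @return The table with `tpm` (and `tpm_unadjusted`) filled in and
#'   all-zero miRNAs removed.
#' @export
compute_tpm <- function(table, pseudo = 0.0001) {
  stopifnot(inherits(table, "mirna_count_table"))
  counts <- table$counts
  totals <- colSums(counts)
  if (any(totals == 0))
    stop2("sample with total count 0: ",
          colnames(counts)[which(totals == 0)[1]])
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  tpm <- tpm[keep, , drop = FALSE]
  adj <- tpm
  adj[adj == 0] <- pseudo
  table$counts <- counts
  table$tpm_unadjusted <- tpm
  table$tpm <- adj
  table$mirna_ids <- rownames(counts)
  table
}

#' Log2 TPM expression matrix for miRNA differential analysis
#'
#' @param table A `mirna_count_table` with TPM computed.
#' @param design Data frame (sample, group) matching the table's samples.
#' @return An [expression_matrix()] of log2(TPM) values, class miRNA.
#' @export
mirna_log2_tpm <- function(table, design) {
  stopifnot(inherits(table, "mirna_count_table"), !is.null(table$tpm))
  expression_matrix(log2(table$tpm), "miRNA", design)
}
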