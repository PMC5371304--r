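#' Quantile-normalize an expression matrix
#'
#' Rank-based replacement by cross-sample row means of the sorted columns:
#' every column's values are replaced by the reference distribution (the
#' mean, across samples, of each sorted-rank value). Ties within a column
#' receive the mean of the reference values at their tied ranks. On
#' tie-free input the operation is exactly idempotent and
#' post-normalization columns have identical sorted values; tied cells are
#' perturbed by the averaging, so with ties both properties hold only up
#' to the tie structure.
#'
#' @param em An [expression_matrix()] (or plain numeric matrix).
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(em) {
  m <- if (inherits(em, "expr_matrix")) em$values else em
  if (!is.numeric(m)) stop2("expression values must be numeric")
  if (nrow(m) < 1 || ncol(m) < 1) stop2("need >= 1 analyte and >= 1 sample")
  if (any(!is.finite(m))) stop2("non-finite values in expression matrix")
  if (ncol(m) == 1L) return(em)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    tmp <- numeric(length(x))
    tmp[order(x)] <- ref
    dup <- duplicated(x) | duplicated(x, fromLast = TRUE)
    if (any(dup))
      tmp[dup] <- ave(tmp[dup], match(x[dup], x[dup]), FUN = mean)
    out[, j] <- tmp
  }
  if (inherits(em, "expr_matrix")) {
    em$values <- out
    em
  } else out
}

#' Summarize probes to official identifiers
#'
#' Probe rows mapping to the same official ID are averaged per sample;
#' probes absent from the mapping are dropped (their records are omitted).
#'
#' @param em An [expression_matrix()] whose rows are probes.
#' @param probe_map Data frame with columns `probe` and `official`.
#' @return An [expression_matrix()] keyed by official IDs. Classes of merged
#'   probes must agree.
#' @export
summarize_probes <- function(em, probe_map) {
  stopifnot(inherits(em, "expr_matrix"),
            all(c("probe", "official") %in% names(probe_map)))
  keep <- rownames(em$values) %in% probe_map$probe
  if (!any(keep)) {
    warning("no probe matched the mapping; returning an empty matrix")
    return(expression_matrix(
      em$values[0, , drop = FALSE], character(0), em$design))
  }
  if (sum(!keep) > 0)
    message(sum(!keep), " unmapped probe(s) omitted")
  v <- em$values[keep, , drop = FALSE]
  off <- probe_map$official[match(rownames(v), probe_map$probe)]
  cls <- em$analyte_class[rownames(v)]
  agg <- rowsum(v, group = off, reorder = FALSE) /
    as.vector(table(factor(off, levels = unique(off))))
  cls_out <- cls[match(rownames(agg), off)]
  expression_matrix(agg, cls_out, em$design)
}

#' Match array lncRNA transcripts to official transcripts by overlap
#'
#' An array transcript maps to an official transcript iff they share
#' chromosome and strand and the overlap covers strictly more than 90% of
#' the array transcript's length. When several official transcripts
#' qualify, the largest overlap fraction wins; ties break to the
#' lexicographically smallest official ID.
#'
#' @param array_tx,official_tx Interval data frames with columns chrom,
#'   start, end, name, strand (0-based half-open).
#' @param min_fraction Strict lower bound on overlap / array length.
#' @return Data frame with columns `probe`, `official`, `overlap_fraction`.
#' @export
match_lncrna_ids <- function(array_tx, official_tx, min_fraction = 0.90) {
  for (d in list(array_tx, official_tx)) {
    stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(d)))
    if (any(d$end <= d$start)) stop2("zero-length transcript rejected")
  }
  if (nrow(array_tx) == 0 || nrow(official_tx) == 0)
    return(data.frame(probe = character(0), official = character(0),
                      overlap_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  cand <- merge(
    data.frame(probe = array_tx$name, chrom = array_tx$chrom,
               strand = array_tx$strand, a_start = array_tx$start,
               a_end = array_tx$end, stringsAsFactors = FALSE),
    data.frame(official = official_tx$name, chrom = official_tx$chrom,
               strand = official_tx$strand, o_start = official_tx$start,
               o_end = official_tx$end, stringsAsFactors = FALSE),
    by = c("chrom", "strand"))
  if (nrow(cand) == 0)
    return(data.frame(probe = character(0), official = character(0),
                      overlap_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  ov <- pmax(0, pmin(cand$a_end, cand$o_end) -
               pmax(cand$a_start, cand$o_start))
  cand$overlap_fraction <- ov / (cand$a_end - cand$a_start)
  cand <- cand[cand$overlap_fraction > min_fraction, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(probe = character(0), official = character(0),
                      overlap_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  # best candidate per probe: max fraction, ties to smallest official ID
  cand <- cand[order(cand$probe, -cand$overlap_fraction, cand$official), ,
               drop = FALSE]
  best <- cand[!duplicated(cand$probe),
               c("probe", "official", "overlap_fraction")]
  rownames(best) <- NULL
  best[order(best$probe), , drop = FALSE]
}
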