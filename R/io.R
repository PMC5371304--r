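# Readers and writers for every format the workflow touches. Dialect:
# tab-separated, UTF-8, '#' comment lines allowed, no quoting; writers are
# deterministic (canonical row order is the caller's responsibility, floats
# as %.6g, '\n' line endings). Every writer's output is re-readable to an
# equivalent object.

#' Read / write an expression TSV
#'
#' Header row holds sample IDs; the first column (named `analyte`) holds
#' analyte IDs.
#' @param path File path.
#' @param em,values An [expression_matrix()] (written with its design held
#'   separately) for writing.
#' @param analyte_class,design Class labels and design used to rebuild the
#'   [expression_matrix()] when reading.
#' @return `read_expression_tsv` returns an [expression_matrix()];
#'   writers return the path invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(analyte = rownames(em$values),
                   as.data.frame(em$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, analyte_class, design) {
  df <- read_tsv_strict(path, required = "analyte", what = "expression TSV")
  if (anyDuplicated(df$analyte))
    stop2(sprintf("expression TSV '%s' has duplicate analyte IDs", path))
  m <- as.matrix(df[, setdiff(colnames(df), "analyte"), drop = FALSE])
  if (nrow(m) > 0 && !is.numeric(m))
    stop2(sprintf("expression TSV '%s' has non-numeric values", path))
  rownames(m) <- df$analyte
  if (is.character(analyte_class) && !is.null(names(analyte_class)))
    analyte_class <- analyte_class[rownames(m)]
  expression_matrix(m, analyte_class, design)
}

#' Read / write FASTQ (Phred+33)
#'
#' Reads are plain data frames with columns `id`, `sequence`, `quality`.
#' Parsing is strict: truncated records or a quality string whose length
#' differs from the sequence raise an error naming the record.
#' @param reads Data frame with columns id, sequence, quality.
#' @param path File path.
#' @return `read_fastq` returns the reads data frame.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad))
    stop2("quality length mismatch for record ", reads$id[which(bad)[1]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                             "+", reads$quality))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop2("input file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop2(sprintf("FASTQ '%s' is truncated (%d lines)", path, length(lines)))
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1, by = 4, length.out = n)]
  if (any(substr(hdr, 1, 1) != "@"))
    stop2(sprintf("FASTQ '%s': malformed header at record %d", path,
                  which(substr(hdr, 1, 1) != "@")[1]))
  reads <- data.frame(id = sub("^@", "", hdr),
                      sequence = lines[seq(2, by = 4, length.out = n)],
                      quality = lines[seq(4, by = 4, length.out = n)],
                      stringsAsFactors = FALSE)
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad))
    stop2(sprintf("FASTQ '%s': quality length mismatch for record %s",
                  path, reads$id[which(bad)[1]]))
  reads
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; sequences are named character vectors.
#' @param seqs Named character vector of DNA sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("input file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read / write BED6 intervals (0-based, half-open)
#'
#' @param bed Data frame with columns chrom, start, end, name, score, strand.
#' @param path File path.
#' @return `read_bed6` returns the validated data frame.
#' @export
write_bed6 <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(bed)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(bed) > 0) {
    writeLines(paste(bed$chrom, bed$start, bed$end, bed$name, bed$score,
                     bed$strand, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop2("input file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop2(sprintf("BED '%s': line %d has %d fields, expected 6", path,
                  lineno[which(nf != 6L)[1]], nf[which(nf != 6L)[1]]))
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad))
    stop2(sprintf("BED '%s': invalid coordinates at line %d", path,
                  lineno[which(bad)[1]]))
  if (any(!m[, 6] %in% c("+", "-", ".")))
    stop2(sprintf("BED '%s': invalid strand at line %d", path,
                  lineno[which(!m[, 6] %in% c("+", "-", "."))[1]]))
  data.frame(chrom = m[, 1], start = as.integer(start),
             end = as.integer(end), name = m[, 4],
             score = as.integer(m[, 5]), strand = m[, 6],
             stringsAsFactors = FALSE)
}

#' Read / write interaction tables and other simple TSVs
#'
#' Interaction tables carry (mirna, target) or (gene_a, gene_b, channel)
#' rows; the GAF-like annotation table carries (gene, term, term_name); the
#' design table carries (sample, group).
#' @param df Data frame to write.
#' @param path File path.
#' @param required Required column names on read.
#' @return Readers return validated data frames.
#' @export
write_interaction_tsv <- function(df, path) write_tsv_strict(df, path)

#' @rdname write_interaction_tsv
#' @export
read_interaction_tsv <- function(path, required) {
  read_tsv_strict(path, required = required, what = "interaction TSV")
}

#' @rdname write_interaction_tsv
#' @export
read_gaf_tsv <- function(path) {
  read_tsv_strict(path, required = c("gene", "term", "term_name"),
                  what = "annotation TSV")
}

#' @rdname write_interaction_tsv
#' @export
read_design_tsv <- function(path) {
  df <- read_tsv_strict(path, required = c("sample", "group"),
                        what = "design TSV")
  if (anyDuplicated(df$sample))
    stop2(sprintf("design TSV '%s' has duplicate sample IDs", path))
  df
}

#' Write / read a network in SIF format
#'
#' Lines are `source<TAB>edge_type<TAB>target`.
#' @param network A `regulatory_network`.
#' @param path File path.
#' @return `read_sif` returns a data frame (from, edge_type, to).
#' @export
write_sif <- function(network, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  e <- network$edges
  if (nrow(e) > 0)
    writeLines(paste(e$from, e$edge_type, e$to, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop2("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(from = character(0), edge_type = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop2(sprintf("SIF '%s': line %d has %d fields, expected 3", path,
                  which(nf != 3L)[1], nf[which(nf != 3L)[1]]))
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  data.frame(from = m[, 1], edge_type = m[, 2], to = m[, 3],
             stringsAsFactors = FALSE)
}
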