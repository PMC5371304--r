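# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  if (integer && x != as.integer(x))
    stop2(sprintf("'%s' must be an integer", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  if (!ok_lo || x > upper)
    stop2(sprintf("'%s' = %s is outside its allowed range", name, format(x)))
  invisible(x)
}

# Canonical float formatting for all TSV writers: %.6g keeps files small and
# byte-stable; integers and strings pass through unchanged.
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

format_column <- function(x) {
  if (is.double(x)) fmt_num(x)
  else if (is.logical(x)) ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  else as.character(x)
}

#' Write a data frame as a strict, deterministic TSV
#'
#' Tab-separated, UTF-8, no quoting, '\\n' line endings, doubles rendered
#' with six significant digits; the dialect every table writer in the
#' package uses.
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_strict <- function(df, path) {
  lines <- paste(colnames(df), collapse = "\t")
  if (nrow(df) > 0) {
    cols <- lapply(df, format_column)
    body <- do.call(paste, c(cols, sep = "\t"))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

read_tsv_strict <- function(path, required = NULL, numeric_cols = NULL,
                            integer_cols = NULL, what = "table") {
  if (!file.exists(path)) stop2(sprintf("input file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, colnames(df))
    if (length(missing))
      stop2(sprintf("%s '%s' is missing required column(s): %s",
                    what, path, paste(missing, collapse = ", ")))
  }
  for (cc in intersect(numeric_cols, colnames(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop2(sprintf("%s '%s': column '%s' contains non-numeric values",
                    what, path, cc))
    df[[cc]] <- v
  }
  for (cc in intersect(integer_cols, colnames(df))) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop2(sprintf("%s '%s': column '%s' contains non-integer values",
                    what, path, cc))
    df[[cc]] <- v
  }
  df
}

# All randomness flows from one seed; sub-streams for independent generator
# stages are derived with fixed offsets (kept < 2^31).
derive_seed <- function(seed, stream) {
  offsets <- c(expression = 101L, expression_b = 202L, smallrna = 303L,
               annotations = 404L, misc = 505L, orphan = 606L)
  if (!stream %in% names(offsets)) stop2("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) + offsets[[stream]]) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

# Sorted, unbox-everything JSON used for config hashing and manifests.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

md5_of_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, open = "wb")
  writeLines(s, con, sep = "")
  close(con)
  unname(tools::md5sum(tf))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}
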