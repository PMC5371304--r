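#' Expression matrix with analyte classes and group design
#'
#' The substrate of normalization and differential expression: a numeric
#' analyte-by-sample matrix (log2 scale once normalized), a per-analyte class
#' label (mRNA, lncRNA or miRNA) and a sample design.
#'
#' @param values Numeric matrix with unique rownames (analyte IDs) and unique
#'   colnames (sample IDs); all values finite.
#' @param analyte_class Character vector (recycled) of per-analyte classes,
#'   each one of "mRNA", "lncRNA", "miRNA".
#' @param design Data frame with columns `sample` and `group`, rows matching
#'   the matrix columns.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, analyte_class, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop2("'values' must carry analyte rownames and sample colnames")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values)))
    stop2("'values' must carry analyte rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop2("duplicate analyte IDs")
  if (anyDuplicated(colnames(values))) stop2("duplicate sample IDs")
  if (nrow(values) > 0 && any(!is.finite(values)))
    stop2("expression values must all be finite")
  analyte_class <- rep_len(analyte_class, nrow(values))
  if (nrow(values) > 0 && !all(analyte_class %in% c("mRNA", "lncRNA", "miRNA")))
    stop2("analyte_class must be mRNA, lncRNA or miRNA")
  names(analyte_class) <- rownames(values)
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design)))
    stop2("'design' needs columns sample and group")
  if (!identical(as.character(design$sample), colnames(values)))
    stop2("design rows must match matrix columns in order")
  structure(list(values = values,
                 analyte_class = analyte_class,
                 design = design[, c("sample", "group")]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cls <- table(x$analyte_class)
  cat(sprintf("<expr_matrix> %d analytes (%s) x %d samples (%s)\n",
              nrow(x$values),
              paste(sprintf("%s %s", cls, names(cls)), collapse = ", "),
              ncol(x$values),
              paste(sprintf("%d %s", as.vector(table(x$design$group)),
                            names(table(x$design$group))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

subset_expr <- function(em, analytes = NULL, samples = NULL) {
  v <- em$values
  if (!is.null(analytes)) v <- v[analytes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  design <- em$design[match(colnames(v), em$design$sample), , drop = FALSE]
  rownames(design) <- NULL
  expression_matrix(v, em$analyte_class[rownames(v)], design)
}
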