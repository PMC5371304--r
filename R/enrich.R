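# Hypergeometric GO enrichment with BH FDR, term direction labels and
# cross-contrast term comparison.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(K annotated, N - K not annotated, n
#' drawn): the enrichment p-value of observing k or more annotated genes
#' among n differentially expressed genes in a universe of N with K
#' annotated. Computed stably in log space.
#'
#' @param k Observed annotated DE genes (vectorized).
#' @param K Annotated genes in the universe.
#' @param n DE genes drawn.
#' @param N Universe size.
#' @return Upper-tail probabilities in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop2("require 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a gene-set annotation object
#'
#' @param annotation Data frame with columns gene, term and optionally
#'   term_name.
#' @param universe Universe of genes; defaults to all annotated genes.
#' @return List of class `gene_set_annotation`.
#' @export
gene_set_annotation <- function(annotation, universe = NULL) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (is.null(universe)) universe <- unique(annotation$gene)
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  term_name <- if ("term_name" %in% names(ann))
    setNames(ann$term_name, ann$term)[!duplicated(ann$term)]
  else setNames(unique(ann$term), unique(ann$term))
  structure(list(gene2term = ann[, c("gene", "term")],
                 term_name = term_name,
                 universe = unique(universe)),
            class = "gene_set_annotation")
}

#' Hypergeometric gene-set enrichment
#'
#' One result row per term with at least `min_term_size` universe genes and
#' at least one DE member; BH adjustment is computed across exactly the
#' tested terms. DE genes outside the universe are dropped with a warning.
#' Results are sorted by p ascending, ties by term ID.
#'
#' @param de_genes Character vector of DE gene IDs.
#' @param annotation A [gene_set_annotation()] (or annotation data frame).
#' @param min_term_size Minimum universe term size tested.
#' @return `enrichment_result` data frame (term, term_name, k, K, n, N, p,
#'   fdr, member_genes as ';'-joined sorted IDs).
#' @export
enrich <- function(de_genes, annotation, min_term_size = 2L) {
  if (!inherits(annotation, "gene_set_annotation"))
    annotation <- gene_set_annotation(annotation)
  universe <- annotation$universe
  if (length(universe) == 0) stop2("empty annotation universe")
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, universe)
  if (length(outside))
    warning(length(outside), " DE gene(s) outside the universe dropped")
  de <- intersect(de_genes, universe)
  g2t <- annotation$gene2term
  K_tab <- table(g2t$term)
  de_rows <- g2t[g2t$gene %in% de, , drop = FALSE]
  members <- split(de_rows$gene, de_rows$term)
  terms <- names(members)
  K <- as.integer(K_tab[terms])
  keep <- K >= min_term_size
  terms <- terms[keep]; K <- K[keep]; members <- members[keep]
  k <- lengths(members)
  n <- length(de); N <- length(universe)
  p <- if (length(terms)) hypergeom_upper(k, K, n, N) else numeric(0)
  fdr <- if (length(p)) adjust_bh(p) else numeric(0)
  out <- data.frame(term = terms,
                    term_name = unname(annotation$term_name[terms]),
                    k = as.integer(k), K = K, n = n, N = N,
                    p = as.numeric(p), fdr = fdr,
                    member_genes = vapply(members, function(g)
                      paste(sort(g), collapse = ";"), ""),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Label enrichment results with a regulation direction
#'
#' A term is "up" if strictly more than half of its DE member genes are
#' upregulated, "down" if strictly more than half are downregulated,
#' otherwise "mixed".
#'
#' @param result An `enrichment_result`.
#' @param de_results A `de_result` providing per-gene directions.
#' @return The result with a `direction` column.
#' @export
assign_direction <- function(result, de_results) {
  dir_of <- de_direction(de_results)
  result$direction <- vapply(result$member_genes, function(s) {
    genes <- strsplit(s, ";", fixed = TRUE)[[1]]
    d <- dir_of[genes]
    n_up <- sum(d == "up", na.rm = TRUE)
    n_down <- sum(d == "down", na.rm = TRUE)
    tot <- length(genes)
    if (n_up > tot / 2) "up" else if (n_down > tot / 2) "down" else "mixed"
  }, "", USE.NAMES = FALSE)
  result
}

#' Compare significant term sets across two contrasts
#'
#' Intersects the significant terms of two enrichment results and reports
#' per-overlapping-term direction pairs plus each side's exclusive terms;
#' terms in `immune_terms` are flagged.
#'
#' @param a,b `enrichment_result` data frames (with directions assigned)
#'   from the same ontology namespace.
#' @param alpha Significance threshold.
#' @param gate "fdr" or "p".
#' @param immune_terms Optional immune-related term IDs.
#' @return List with `overlap` (term, term_name, direction_a, direction_b,
#'   immune), `only_a`, `only_b`.
#' @export
compare_term_sets <- function(a, b, alpha = 0.05, gate = c("fdr", "p"),
                              immune_terms = NULL) {
  gate <- match.arg(gate)
  sig <- function(x) x$term[x[[gate]] < alpha]
  sa <- sig(a); sb <- sig(b)
  common <- sort(intersect(sa, sb))
  dir_a <- setNames(a$direction %||% rep(NA_character_, nrow(a)), a$term)
  dir_b <- setNames(b$direction %||% rep(NA_character_, nrow(b)), b$term)
  nm <- setNames(a$term_name, a$term)
  list(overlap = data.frame(
         term = common,
         term_name = unname(nm[common]),
         direction_a = unname(dir_a[common]),
         direction_b = unname(dir_b[common]),
         immune = common %in% (immune_terms %||% character(0)),
         stringsAsFactors = FALSE),
       only_a = sort(setdiff(sa, sb)),
       only_b = sort(setdiff(sb, sa)))
}
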