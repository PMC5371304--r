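# Regulatory network construction: promoter windows, TF-miRNA pairs by
# binding-site intersection, miRNA target pair filtering, tripartite network
# assembly, ceRNA inference, PPI overlay, immune flagging, subnetwork
# extraction and Cytoscape export. Coordinates are 0-based half-open (BED)
# throughout; all outputs are canonically sorted for byte-stable export.

PPI_VALID_CHANNELS <- c("experiments", "textmining", "coexpression",
                        "database", "neighborhood", "fusion", "cooccurence")

#' Promoter window around a transcription start site
#'
#' The window spans `upstream` bp upstream to `downstream` bp downstream of
#' the TSS (the 0-based first transcribed base), with downstream including
#' the TSS base. On the '+' strand this is `[tss - upstream, tss +
#' downstream)`; on the '-' strand the mirror `[tss - downstream + 1, tss +
#' upstream + 1)`. Starts are clamped at 0.
#'
#' @param tss Integer vector of 0-based TSS positions.
#' @param strand "+" or "-" per TSS.
#' @param upstream,downstream Window extents in bp (defaults 1500/500).
#' @return Data frame with columns start, end (0-based half-open).
#' @export
promoter_window <- function(tss, strand, upstream = 1500L,
                            downstream = 500L) {
  stopifnot(all(tss >= 0), all(strand %in% c("+", "-")))
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  end <- ifelse(plus, tss + downstream, tss + upstream + 1L)
  data.frame(start = pmax(0L, as.integer(start)), end = as.integer(end))
}

loci_tss <- function(loci) {
  stopifnot(all(loci$strand %in% c("+", "-")))
  ifelse(loci$strand == "+", loci$start, loci$end - 1L)
}

#' Generate TF-miRNA pairs from promoter binding sites
#'
#' A (TF, miRNA) pair is emitted iff the miRNA is differentially expressed
#' and at least one binding site of the TF overlaps the miRNA's promoter
#' window by >= 1 bp on the same chromosome (site strand ignored). Output
#' is deduplicated and canonically sorted.
#'
#' @param binding_sites BED6-style data frame (chrom, start, end, name =
#'   TF, score, strand).
#' @param mirna_loci BED6-style data frame of miRNA gene loci with strand;
#'   the TSS is the strand-aware first transcribed base.
#' @param de_mirnas Character vector of DE miRNA IDs.
#' @param upstream,downstream Promoter window extents.
#' @return Data frame with columns tf, mirna.
#' @export
generate_tf_mirna_pairs <- function(binding_sites, mirna_loci, de_mirnas,
                                    upstream = 1500L, downstream = 500L) {
  empty <- data.frame(tf = character(0), mirna = character(0),
                      stringsAsFactors = FALSE)
  missing <- setdiff(de_mirnas, mirna_loci$name)
  if (length(missing)) {
    warning(length(missing), " DE miRNA(s) without a locus skipped: ",
            paste(head(missing, 5), collapse = ", "))
    de_mirnas <- setdiff(de_mirnas, missing)
  }
  loci <- mirna_loci[mirna_loci$name %in% de_mirnas, , drop = FALSE]
  if (nrow(loci) == 0 || nrow(binding_sites) == 0) return(empty)
  win <- promoter_window(loci_tss(loci), loci$strand, upstream, downstream)
  # 0-based half-open -> 1-based closed for IRanges
  wgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(win$start + 1L, win$end))
  sgr <- GenomicRanges::GRanges(binding_sites$chrom,
                                IRanges::IRanges(binding_sites$start + 1L,
                                                 binding_sites$end))
  ov <- GenomicRanges::findOverlaps(sgr, wgr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  pairs <- unique(data.frame(
    tf = binding_sites$name[S4Vectors::queryHits(ov)],
    mirna = loci$name[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$tf, pairs$mirna), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Filter a miRNA target table to DE pairs
#'
#' Keeps rows whose miRNA and target are both differentially expressed;
#' optionally additionally requires opposite DE directions. Deduplicated
#' and canonically sorted.
#'
#' @param target_table Data frame with columns mirna, target.
#' @param de_mirnas,de_targets Character vectors of DE IDs.
#' @param direction_constraint Require opposite regulatory directions.
#' @param mirna_directions,target_directions Named direction vectors
#'   ("up"/"down"), required when `direction_constraint` is TRUE.
#' @return Data frame with columns mirna, target.
#' @export
generate_mirna_target_pairs <- function(target_table, de_mirnas, de_targets,
                                        direction_constraint = FALSE,
                                        mirna_directions = NULL,
                                        target_directions = NULL) {
  stopifnot(all(c("mirna", "target") %in% names(target_table)))
  keep <- target_table$mirna %in% de_mirnas &
    target_table$target %in% de_targets
  out <- unique(target_table[keep, c("mirna", "target"), drop = FALSE])
  if (direction_constraint && nrow(out) > 0) {
    if (is.null(mirna_directions) || is.null(target_directions))
      stop2("direction_constraint needs direction vectors")
    opp <- mirna_directions[out$mirna] != target_directions[out$target]
    out <- out[opp, , drop = FALSE]
  }
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_kind_map <- c(tf_mirna_from = "TF", tf_mirna_to = "miRNA",
                   mirna_mrna_from = "miRNA", mirna_mrna_to = "mRNA",
                   mirna_lncrna_from = "miRNA", mirna_lncrna_to = "lncRNA")

#' Assemble a typed regulatory network from edge lists
#'
#' Unions the given edge lists into a network with typed nodes and edges;
#' node DE statistics are looked up in `de_annotation`, degrees are
#' recomputed from the final edge set, and the display enrichment score is
#' -log10(p) with p floored at 1e-300. Endpoints without any annotation
#' (e.g. TFs) get NA statistics and are flagged.
#'
#' @param edge_lists Named list with any of `tf_mirna` (columns tf, mirna),
#'   `mirna_mrna` (mirna, target), `mirna_lncrna` (mirna, target).
#' @param de_annotation Data frame with columns analyte_id, log2fc, p, fdr
#'   (e.g. a `de_result`), or NULL.
#' @return Object of class `regulatory_network`: list with `nodes` and
#'   `edges` data frames, canonically sorted.
#' @export
assemble_network <- function(edge_lists, de_annotation = NULL) {
  edges <- list()
  if (!is.null(edge_lists$tf_mirna) && nrow(edge_lists$tf_mirna))
    edges$tf_mirna <- data.frame(from = edge_lists$tf_mirna$tf,
                                 to = edge_lists$tf_mirna$mirna,
                                 edge_type = "tf_mirna",
                                 from_kind = "TF", to_kind = "miRNA",
                                 stringsAsFactors = FALSE)
  if (!is.null(edge_lists$mirna_mrna) && nrow(edge_lists$mirna_mrna))
    edges$mirna_mrna <- data.frame(from = edge_lists$mirna_mrna$mirna,
                                   to = edge_lists$mirna_mrna$target,
                                   edge_type = "mirna_mrna",
                                   from_kind = "miRNA", to_kind = "mRNA",
                                   stringsAsFactors = FALSE)
  if (!is.null(edge_lists$mirna_lncrna) && nrow(edge_lists$mirna_lncrna))
    edges$mirna_lncrna <- data.frame(
      from = edge_lists$mirna_lncrna$mirna,
      to = edge_lists$mirna_lncrna$target,
      edge_type = "mirna_lncrna",
      from_kind = "miRNA", to_kind = "lncRNA", stringsAsFactors = FALSE)
  edges <- do.call(rbind, unname(edges)) %||%
    data.frame(from = character(0), to = character(0),
               edge_type = character(0), from_kind = character(0),
               to_kind = character(0), stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$edge_type, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  node_ids <- unique(c(edges$from, edges$to))
  kinds <- setNames(character(length(node_ids)), node_ids)
  kinds[edges$from] <- edges$from_kind
  kinds[edges$to] <- edges$to_kind
  nodes <- data.frame(id = node_ids, kind = unname(kinds[node_ids]),
                      stringsAsFactors = FALSE)
  if (!is.null(de_annotation)) {
    m <- match(nodes$id, de_annotation$analyte_id)
    nodes$log2fc <- de_annotation$log2fc[m]
    nodes$p <- de_annotation$p[m]
    nodes$fdr <- de_annotation$fdr[m]
  } else {
    nodes$log2fc <- rep(NA_real_, nrow(nodes))
    nodes$p <- rep(NA_real_, nrow(nodes))
    nodes$fdr <- rep(NA_real_, nrow(nodes))
  }
  nodes$flagged <- is.na(nodes$p) & nodes$kind != "TF"
  nodes$enrichment_score <- ifelse(is.na(nodes$p), NA_real_,
                                   -log10(pmax(nodes$p, 1e-300)))
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  net <- structure(list(nodes = nodes,
                        edges = edges[, c("from", "to", "edge_type")]),
                   class = "regulatory_network")
  recompute_degrees(net)
}

#' Recompute node degrees from the edge set
#' @param network A `regulatory_network`.
#' @return The network with the `degree` node column refreshed.
#' @export
recompute_degrees <- function(network) {
  deg <- table(c(network$edges$from, network$edges$to))
  network$nodes$degree <- as.integer(deg[network$nodes$id])
  network$nodes$degree[is.na(network$nodes$degree)] <- 0L
  network
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$kind))
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

#' Infer ceRNA pairs from shared miRNAs
#'
#' For each miRNA with target set S, all C(|S|, 2) unordered target pairs
#' are competing endogenous RNA pairs; pairs arising from several miRNAs
#' are merged with the union of shared miRNAs. Endpoints are ordered
#' lexicographically within a pair and the output is canonically sorted.
#'
#' @param edges Data frame with columns mirna and mrna (or target),
#'   restricted to DE targets by the caller.
#' @return Data frame with columns gene_a, gene_b, shared_mirnas
#'   (';'-joined sorted IDs), n_shared.
#' @export
infer_cerna_pairs <- function(edges) {
  nm <- names(edges)
  tcol <- if ("mrna" %in% nm) "mrna" else "target"
  stopifnot("mirna" %in% nm, tcol %in% nm)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      shared_mirnas = character(0), n_shared = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0) return(empty)
  ed <- unique(data.frame(mirna = edges$mirna, target = edges[[tcol]],
                          stringsAsFactors = FALSE))
  by_mir <- split(ed$target, ed$mirna)
  acc <- new.env(parent = emptyenv())
  for (m in names(by_mir)) {
    tg <- sort(unique(by_mir[[m]]))
    if (length(tg) < 2) next
    cmb <- combn(tg, 2)
    keys <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    for (k in keys) assign(k, c(get0(k, envir = acc), m), envir = acc)
  }
  keys <- ls(acc)
  if (!length(keys)) return(empty)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  shared <- lapply(keys, function(k) sort(unique(get(k, envir = acc))))
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    shared_mirnas = vapply(shared, paste, "",
                                           collapse = ";"),
                    n_shared = lengths(shared), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlay protein-protein interaction evidence on ceRNA pairs
#'
#' A pair is PPI-supported iff it appears (unordered) in the PPI table with
#' at least one whitelisted evidence channel and at least one endpoint
#' differentially expressed. Pairs are retained regardless by default
#' (support is an attribute); `strict` drops unsupported pairs.
#'
#' @param pairs ceRNA pair data frame from [infer_cerna_pairs()].
#' @param ppi_table Data frame with columns gene_a, gene_b, channel.
#' @param allowed_channels Evidence-channel whitelist.
#' @param de_genes Character vector of DE gene IDs.
#' @param strict Drop unsupported pairs.
#' @return `pairs` with a logical `ppi_supported` column.
#' @export
overlay_ppi <- function(pairs, ppi_table,
                        allowed_channels = c("experiments", "textmining",
                                             "coexpression", "database"),
                        de_genes = character(0), strict = FALSE) {
  stopifnot(all(c("gene_a", "gene_b", "channel") %in% names(ppi_table)))
  bad <- setdiff(unique(c(allowed_channels, ppi_table$channel)),
                 PPI_VALID_CHANNELS)
  if (length(bad))
    stop2("unknown PPI evidence channel(s): ",
          paste(bad, collapse = ", "), "; valid labels are: ",
          paste(PPI_VALID_CHANNELS, collapse = ", "))
  ok <- ppi_table$channel %in% allowed_channels &
    (ppi_table$gene_a %in% de_genes | ppi_table$gene_b %in% de_genes)
  sup <- ppi_table[ok, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pairs$ppi_supported <- key(pairs$gene_a, pairs$gene_b) %in%
    key(sup$gene_a, sup$gene_b)
  if (strict) pairs <- pairs[pairs$ppi_supported, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Flag immune-response-related nodes and ceRNA pairs
#'
#' A gene is immune-related iff it is annotated to at least one term in
#' `immune_terms`; a ceRNA pair is immune iff both endpoints are.
#'
#' @param x A `regulatory_network` or a ceRNA pair data frame.
#' @param immune_terms Character vector of GO term IDs.
#' @param annotation Data frame with columns gene, term.
#' @return `x` with `immune` (nodes) and/or `immune_pair` columns added.
#' @export
flag_immune <- function(x, immune_terms, annotation) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  immune_genes <- unique(annotation$gene[annotation$term %in% immune_terms])
  if (inherits(x, "regulatory_network")) {
    x$nodes$immune <- x$nodes$id %in% immune_genes
    x
  } else {
    x$immune_pair <- x$gene_a %in% immune_genes &
      x$gene_b %in% immune_genes
    x
  }
}

#' Extract the subnetwork induced by an mRNA gene set
#'
#' Retains mRNA nodes in `gene_set`; miRNA nodes with at least one edge to
#' a retained mRNA; TF and lncRNA nodes with at least one edge to a
#' retained miRNA; and exactly the edges among retained nodes. Degrees are
#' recomputed.
#'
#' @param network A `regulatory_network`.
#' @param gene_set Character vector of mRNA IDs.
#' @return A `regulatory_network`.
#' @export
extract_subnetwork <- function(network, gene_set) {
  nodes <- network$nodes; edges <- network$edges
  keep_mrna <- nodes$id[nodes$kind == "mRNA" & nodes$id %in% gene_set]
  touches <- function(e, set) e$from %in% set | e$to %in% set
  mir_ids <- nodes$id[nodes$kind == "miRNA"]
  keep_mir <- unique(c(
    edges$from[edges$from %in% mir_ids & edges$to %in% keep_mrna],
    edges$to[edges$to %in% mir_ids & edges$from %in% keep_mrna]))
  periph <- nodes$id[nodes$kind %in% c("TF", "lncRNA")]
  keep_periph <- unique(c(
    edges$from[edges$from %in% periph & edges$to %in% keep_mir],
    edges$to[edges$to %in% periph & edges$from %in% keep_mir]))
  keep <- c(keep_mrna, keep_mir, keep_periph)
  nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  recompute_degrees(structure(list(nodes = nodes, edges = edges),
                              class = "regulatory_network"))
}

network_to_igraph <- function(network) {
  nodes <- network$nodes
  for (cc in names(nodes))
    if (is.numeric(nodes[[cc]]))
      nodes[[cc]][is.na(nodes[[cc]])] <- NaN
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = nodes)
}

# Canonical source kind per edge type; igraph stores undirected edges with
# arbitrary endpoint order, so orientation is restored on read.
EDGE_SOURCE_KIND <- c(tf_mirna = "TF", mirna_mrna = "miRNA",
                      mirna_lncrna = "miRNA")

igraph_to_network <- function(g) {
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  names(ed)[1:2] <- c("from", "to")
  if (nrow(ed) > 0 && "edge_type" %in% names(ed) && "kind" %in% names(vd)) {
    kind_of <- setNames(vd$kind, vd$name)
    src <- EDGE_SOURCE_KIND[ed$edge_type]
    flip <- !is.na(src) & kind_of[ed$from] != src & kind_of[ed$to] == src
    tmp <- ed$from[flip]; ed$from[flip] <- ed$to[flip]; ed$to[flip] <- tmp
  }
  nodes <- data.frame(id = vd$name, stringsAsFactors = FALSE)
  # graphml readers surface the XML node ids as an extra "id" attribute;
  # the authoritative identifier is the vertex name
  for (cc in setdiff(names(vd), c("name", "id"))) nodes[[cc]] <- vd[[cc]]
  for (cc in names(nodes))
    if (is.numeric(nodes[[cc]]))
      nodes[[cc]][is.nan(nodes[[cc]])] <- NA_real_
  if ("degree" %in% names(nodes))
    nodes$degree <- as.integer(nodes$degree)
  if ("flagged" %in% names(nodes)) nodes$flagged <- as.logical(nodes$flagged)
  if ("immune" %in% names(nodes)) nodes$immune <- as.logical(nodes$immune)
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- ed[, c("from", "to", setdiff(names(ed), c("from", "to")))]
  edges <- edges[order(edges$edge_type, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' Export a network for Cytoscape
#'
#' Writes SIF, node and edge attribute TSVs, and GraphML (which round-trips
#' through [read_graphml()] losslessly).
#'
#' @param network A `regulatory_network`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisible character vector of written paths.
#' @export
export_cytoscape <- function(network, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".sif", "_nodes.tsv",
                                           "_edges.tsv", ".graphml")))
  write_sif(network, paths[1])
  write_tsv_strict(network$nodes, paths[2])
  write_tsv_strict(network$edges, paths[3])
  igraph::write_graph(network_to_igraph(network), paths[4],
                      format = "graphml")
  invisible(paths)
}

#' Read a GraphML file written by [export_cytoscape()]
#' @param path GraphML file path.
#' @return A `regulatory_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop2("input file not found: ", path)
  igraph_to_network(igraph::read_graph(path, format = "graphml"))
}
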