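#' Pipeline configuration
#'
#' Houses every analysis threshold as a named, defaulted field, so the
#' study's settings are the shipped defaults: FDR < 0.05 with fold change
#' >= 2 or <= 0.5 for mRNA/lncRNA, raw p < 0.05 with the same fold-change
#' gate for miRNA, promoter windows of 1500 bp upstream / 500 bp
#' downstream, a strict 90% transcript-overlap bound for identifier
#' harmonization, read QC at length >= 16, Phred >= 20 on >= 90% of bases
#' and <= 5% uncertain bases, pseudo-TPM 0.0001, hypergeometric enrichment
#' gated on FDR < 0.05, and the PPI evidence-channel whitelist.
#'
#' @param array_policy,mirna_policy [threshold_policy()] objects for the
#'   microarray (mRNA + lncRNA) and miRNA differential-expression calls.
#' @param promoter_upstream,promoter_downstream Promoter window extents, bp.
#' @param overlap_fraction Strict lower bound for lncRNA transcript
#'   matching.
#' @param qc_min_len,qc_phred_floor,qc_hq_fraction,qc_max_uncertain Read QC
#'   thresholds.
#' @param pseudo_tpm Pseudo-value for zero TPM cells.
#' @param enrich_alpha,enrich_gate Significance threshold and gated
#'   statistic ("fdr" or "p") for GO terms.
#' @param min_term_size Minimum universe term size tested.
#' @param allowed_channels PPI evidence-channel whitelist.
#' @param strict_ppi Drop ceRNA pairs without PPI support.
#' @param restrict_de_tfs Restrict TF-miRNA pairs to differentially
#'   expressed TFs (the default keeps all TFs with promoter binding sites).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(array_policy = threshold_policy("fdr"),
                            mirna_policy = threshold_policy("p"),
                            promoter_upstream = 1500L,
                            promoter_downstream = 500L,
                            overlap_fraction = 0.90,
                            qc_min_len = 16L, qc_phred_floor = 20L,
                            qc_hq_fraction = 0.90, qc_max_uncertain = 0.05,
                            pseudo_tpm = 0.0001,
                            enrich_alpha = 0.05,
                            enrich_gate = c("fdr", "p"),
                            min_term_size = 2L,
                            allowed_channels = c("experiments",
                                                 "textmining",
                                                 "coexpression",
                                                 "database"),
                            strict_ppi = FALSE,
                            restrict_de_tfs = FALSE) {
  enrich_gate <- match.arg(enrich_gate)
  stopifnot(inherits(array_policy, "threshold_policy"),
            inherits(mirna_policy, "threshold_policy"))
  check_scalar_number(promoter_upstream, "promoter_upstream", lower = 0)
  check_scalar_number(promoter_downstream, "promoter_downstream", lower = 0)
  check_scalar_number(overlap_fraction, "overlap_fraction", lower = 0,
                      upper = 1)
  check_scalar_number(qc_min_len, "qc_min_len", lower = 0)
  check_scalar_number(qc_phred_floor, "qc_phred_floor", lower = 0,
                      upper = 93)
  check_scalar_number(qc_hq_fraction, "qc_hq_fraction", lower = 0,
                      upper = 1)
  check_scalar_number(qc_max_uncertain, "qc_max_uncertain", lower = 0,
                      upper = 1)
  check_scalar_number(pseudo_tpm, "pseudo_tpm", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(enrich_alpha, "enrich_alpha", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(min_term_size, "min_term_size", lower = 1)
  bad <- setdiff(allowed_channels, PPI_VALID_CHANNELS)
  if (length(bad))
    stop2("unknown PPI evidence channel(s): ", paste(bad, collapse = ", "))
  structure(list(array_policy = array_policy, mirna_policy = mirna_policy,
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 overlap_fraction = overlap_fraction,
                 qc_min_len = as.integer(qc_min_len),
                 qc_phred_floor = as.integer(qc_phred_floor),
                 qc_hq_fraction = qc_hq_fraction,
                 qc_max_uncertain = qc_max_uncertain,
                 pseudo_tpm = pseudo_tpm,
                 enrich_alpha = enrich_alpha, enrich_gate = enrich_gate,
                 min_term_size = as.integer(min_term_size),
                 allowed_channels = allowed_channels,
                 strict_ppi = strict_ppi,
                 restrict_de_tfs = restrict_de_tfs),
            class = "pipeline_config")
}

#' Run the full two-contrast network workflow on a bundle
#'
#' Executes every stage of the analysis on a synthetic (or equivalently
#' structured) bundle: quantile normalization, lncRNA identifier
#' harmonization and probe summarization, small-RNA adapter trimming,
#' quality filtering, contaminant removal, exact-match miRNA counting and
#' TPM, moderated-t differential expression for both array contrasts and
#' for miRNA, TF-miRNA / miRNA-mRNA / miRNA-lncRNA pair generation,
#' tripartite network assembly, shared-miRNA ceRNA inference with PPI
#' overlay and immune flagging, hypergeometric GO enrichment with term
#' directions for both contrasts, term-set and DE-gene overlap analysis,
#' and immune-response subnetwork extraction. When `out_dir` is given,
#' every result table and network is written along with a manifest of
#' row counts and output checksums.
#'
#' @param bundle A `synth_bundle` from [simulate_bundle()] or
#'   [read_bundle()].
#' @param pconfig A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with all intermediate and final objects plus `counts`, the
#'   per-stage row-count log.
#' @export
run_pipeline <- function(bundle, pconfig = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(bundle, "synth_bundle"),
            inherits(pconfig, "pipeline_config"))
  ann <- bundle$annotations
  counts <- list()

  ## --- microarray preprocessing --------------------------------------
  qn <- quantile_normalize(bundle$expression_raw)
  lnc_probes <- names(qn$analyte_class)[qn$analyte_class == "lncRNA"]
  mrna_ids <- names(qn$analyte_class)[qn$analyte_class == "mRNA"]
  mapping <- match_lncrna_ids(ann$array_lncrna_tx, ann$official_lncrna_tx,
                              pconfig$overlap_fraction)
  lnc_em <- subset_expr(qn, analytes = intersect(lnc_probes,
                                                 rownames(qn$values)))
  lnc_official <- suppressMessages(
    summarize_probes(lnc_em, mapping[, c("probe", "official")]))
  em_array <- expression_matrix(
    rbind(qn$values[mrna_ids, , drop = FALSE], lnc_official$values),
    c(rep("mRNA", length(mrna_ids)),
      rep("lncRNA", nrow(lnc_official$values))),
    qn$design)
  counts$array_analytes <- nrow(em_array$values)
  counts$lncrna_probes_matched <- nrow(mapping)

  em_hcc <- quantile_normalize(bundle$expression_hcc)

  ## --- small RNA preprocessing ----------------------------------------
  sr <- bundle$smallrna
  qc_reports <- list()
  processed <- lapply(names(sr$reads), function(s) {
    r <- trim_adapter(sr$reads[[s]], bundle$config$adapter)
    f <- filter_reads_qc(r, pconfig$qc_min_len, pconfig$qc_phred_floor,
                         pconfig$qc_hq_fraction, pconfig$qc_max_uncertain)
    qc_reports[[s]] <<- f$report
    remove_contaminants(f$reads, sr$contaminants)
  })
  names(processed) <- names(sr$reads)
  count_tab <- count_mirna(processed, sr$mature)
  count_tab <- compute_tpm(count_tab, pconfig$pseudo_tpm)
  em_mirna <- mirna_log2_tpm(count_tab, sr$design)
  counts$mirna_quantified <- nrow(count_tab$counts)

  ## --- differential expression ----------------------------------------
  de_array <- de_table(em_array, policy = pconfig$array_policy)
  de_mirna <- de_table(em_mirna, policy = pconfig$mirna_policy)
  de_hcc <- de_table(em_hcc, policy = pconfig$array_policy)
  cls_a <- em_array$analyte_class[de_array$analyte_id]
  de_mrna_a <- de_array[cls_a == "mRNA", , drop = FALSE]
  de_lnc_a <- de_array[cls_a == "lncRNA", , drop = FALSE]
  class(de_mrna_a) <- class(de_lnc_a) <- c("de_result", "data.frame")
  counts$de_mrna <- sum(de_mrna_a$significant)
  counts$de_lncrna <- sum(de_lnc_a$significant)
  counts$de_mirna <- sum(de_mirna$significant)
  counts$de_mrna_hcc <- sum(de_hcc$significant)

  sig_mirs <- de_significant(de_mirna)
  sig_mrnas <- de_significant(de_mrna_a)
  sig_lncs <- de_significant(de_lnc_a)

  ## --- pair generation -------------------------------------------------
  tf_pairs <- generate_tf_mirna_pairs(ann$binding_sites, ann$mirna_loci,
                                      sig_mirs,
                                      pconfig$promoter_upstream,
                                      pconfig$promoter_downstream)
  if (pconfig$restrict_de_tfs)
    tf_pairs <- tf_pairs[tf_pairs$tf %in%
                           de_significant(de_array), , drop = FALSE]
  mm_pairs <- generate_mirna_target_pairs(ann$mirna_mrna_targets,
                                          sig_mirs, sig_mrnas)
  ml_pairs <- generate_mirna_target_pairs(ann$mirna_lncrna_targets,
                                          sig_mirs, sig_lncs)
  counts$tf_mirna_pairs <- nrow(tf_pairs)
  counts$mirna_mrna_pairs <- nrow(mm_pairs)
  counts$mirna_lncrna_pairs <- nrow(ml_pairs)

  de_annotation <- rbind(
    de_array[, c("analyte_id", "log2fc", "p", "fdr")],
    de_mirna[, c("analyte_id", "log2fc", "p", "fdr")])
  tf_network <- assemble_network(list(tf_mirna = tf_pairs,
                                      mirna_mrna = mm_pairs),
                                 de_annotation)
  lnc_network <- assemble_network(list(mirna_lncrna = ml_pairs,
                                       mirna_mrna = mm_pairs),
                                  de_annotation)

  ## --- ceRNA + PPI + immune -------------------------------------------
  cerna <- infer_cerna_pairs(mm_pairs)
  cerna <- overlay_ppi(cerna, ann$ppi, pconfig$allowed_channels,
                       de_genes = sig_mrnas, strict = pconfig$strict_ppi)
  cerna <- flag_immune(cerna, ann$immune_terms, ann$go_annotation)
  counts$cerna_pairs <- nrow(cerna)

  ## --- enrichment and overlap ------------------------------------------
  gsa <- gene_set_annotation(ann$go_annotation)
  enr_a <- suppressWarnings(enrich(sig_mrnas, gsa, pconfig$min_term_size))
  enr_a <- assign_direction(enr_a, de_mrna_a)
  enr_b <- suppressWarnings(enrich(de_significant(de_hcc), gsa,
                                   pconfig$min_term_size))
  enr_b <- assign_direction(enr_b, de_hcc)
  term_comparison <- compare_term_sets(enr_a, enr_b,
                                       alpha = pconfig$enrich_alpha,
                                       gate = pconfig$enrich_gate,
                                       immune_terms = ann$immune_terms)
  gene_overlap <- overlap_de_sets(de_mrna_a, de_hcc)
  enr_overlap <- suppressWarnings(
    enrich(gene_overlap$overlap$analyte, gsa, pconfig$min_term_size))
  counts$overlap_genes <- nrow(gene_overlap$overlap)
  counts$overlap_terms <- nrow(term_comparison$overlap)

  immune_genes <- intersect(
    sig_mrnas,
    unique(ann$go_annotation$gene[ann$go_annotation$term %in%
                                    ann$immune_terms]))
  tf_subnetwork <- extract_subnetwork(tf_network, immune_genes)
  lnc_subnetwork <- extract_subnetwork(lnc_network, immune_genes)
  counts$immune_genes <- length(immune_genes)
  counts$immune_tf_subnetwork_nodes <- nrow(tf_subnetwork$nodes)
  counts$immune_lnc_subnetwork_nodes <- nrow(lnc_subnetwork$nodes)

  result <- list(pconfig = pconfig,
                 expression_array = em_array, expression_hcc = em_hcc,
                 expression_mirna = em_mirna,
                 probe_mapping = mapping, qc_reports = qc_reports,
                 mirna_counts = count_tab,
                 de_array = de_array, de_mrna = de_mrna_a,
                 de_lncrna = de_lnc_a, de_mirna = de_mirna,
                 de_hcc = de_hcc,
                 tf_pairs = tf_pairs, mm_pairs = mm_pairs,
                 ml_pairs = ml_pairs,
                 tf_network = tf_network, lnc_network = lnc_network,
                 cerna_pairs = cerna,
                 enrichment_cirrhosis = enr_a, enrichment_hcc = enr_b,
                 enrichment_overlap_genes = enr_overlap,
                 term_comparison = term_comparison,
                 gene_overlap = gene_overlap,
                 immune_genes = sort(immune_genes),
                 tf_subnetwork = tf_subnetwork,
                 lnc_subnetwork = lnc_subnetwork,
                 counts = counts)

  if (!is.null(out_dir)) write_pipeline_results(result, bundle, out_dir)
  result
}

de_output_columns <- function(de, analyte_class) {
  data.frame(analyte = de$analyte_id,
             class = unname(analyte_class[de$analyte_id]),
             log2fc = de$log2fc, fold_change = de$fold_change,
             t_mod = de$t_mod, p = de$p, fdr = de$fdr,
             direction = de$direction, significant = de$significant,
             stringsAsFactors = FALSE)
}

write_pipeline_results <- function(result, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv_strict(de_output_columns(result$de_array,
                                     result$expression_array$analyte_class),
                   p("de_cirrhosis_array.tsv"))
  write_tsv_strict(de_output_columns(result$de_mirna,
                                     result$expression_mirna$analyte_class),
                   p("de_cirrhosis_mirna.tsv"))
  write_tsv_strict(de_output_columns(result$de_hcc,
                                     result$expression_hcc$analyte_class),
                   p("de_hcc.tsv"))
  write_tsv_strict(result$tf_pairs, p("tf_mirna_pairs.tsv"))
  write_tsv_strict(result$mm_pairs, p("mirna_mrna_pairs.tsv"))
  write_tsv_strict(result$ml_pairs, p("mirna_lncrna_pairs.tsv"))
  write_tsv_strict(result$cerna_pairs, p("cerna_pairs.tsv"))
  export_cytoscape(result$tf_network, out_dir, "tf_network")
  export_cytoscape(result$lnc_network, out_dir, "lnc_network")
  export_cytoscape(result$tf_subnetwork, out_dir, "immune_tf_subnetwork")
  export_cytoscape(result$lnc_subnetwork, out_dir, "immune_lnc_subnetwork")
  write_tsv_strict(as.data.frame(result$enrichment_cirrhosis),
                   p("go_cirrhosis.tsv"))
  write_tsv_strict(as.data.frame(result$enrichment_hcc), p("go_hcc.tsv"))
  write_tsv_strict(as.data.frame(result$enrichment_overlap_genes),
                   p("go_overlap_genes.tsv"))
  write_tsv_strict(result$term_comparison$overlap, p("overlap_terms.tsv"))
  write_tsv_strict(result$gene_overlap$overlap, p("overlap_genes.tsv"))

  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "run_manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(checksums) <- outputs
  manifest <- list(tool = "cirrnet",
                   version = as.character(utils::packageVersion("cirrnet")),
                   config_hash = config_hash(bundle$config),
                   stage_counts = result$counts,
                   output_checksums = checksums)
  con <- file(p("run_manifest.json"), open = "wb")
  writeLines(as.character(canonical_json(manifest)), con, sep = "\n")
  close(con)
  invisible(manifest)
}
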