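#' Simulate a complete synthetic input bundle
#'
#' Orchestrates the expression, small-RNA and annotation simulators into one
#' self-contained bundle emulating the study's inputs: a probe-level
#' microarray matrix (mRNA rows plus lncRNA array probes, including
#' duplicate and orphan probes for the identifier-harmonization stage), a
#' second-contrast (HCC) mRNA matrix whose planted DE set partially overlaps
#' the first, per-sample small-RNA read sets with references, every
#' annotation table, and the merged ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `synth_bundle` with elements `config`,
#'   `expression_raw` (probe-level), `expression` (official-level, for
#'   reference), `expression_hcc`, `smallrna`, `annotations`, `truth`.
#' @export
simulate_bundle <- function(config) {
  validate_sim_config(config)
  ea <- simulate_expression(config)
  cls_of <- ea$matrix$analyte_class

  mrna_ids <- names(cls_of)[cls_of == "mRNA"]
  de_mrna_a <- names(ea$truth$de_labels)[ea$truth$de_labels != "null" &
                                           names(ea$truth$de_labels) %in% mrna_ids]
  forced <- with_stream(config$seed, "misc", {
    k <- round(config$second_contrast_overlap * length(de_mrna_a))
    pick <- sample_some(de_mrna_a, k)
    setNames(sample(c("up", "down"), length(pick), replace = TRUE), pick)
  })
  eb <- simulate_expression(config, forced_de = forced, classes = "mRNA",
                            sample_prefix = c("LCB", "HCC"),
                            stream = "expression_b")
  sr <- simulate_small_rna(config)

  truth <- c(ea$truth, sr$truth)
  attr(truth$de_labels, "class_of") <- cls_of[names(truth$de_labels)]
  truth$de_labels_hcc <- eb$truth$de_labels
  truth$true_log2fc_hcc <- eb$truth$true_log2fc
  ann <- simulate_annotations(config, truth)
  truth <- c(truth, ann$truth)

  # Probe-level raw array matrix: mRNA rows as simulated; each lncRNA probe
  # row duplicates its official transcript's row (probe summarization then
  # recovers the official matrix exactly); orphan probes get independent
  # null rows.
  pm <- truth$probe_map
  probe_ids <- ann$array_lncrna_tx$name
  orphans <- setdiff(probe_ids, pm$probe)
  vals_a <- ea$matrix$values
  probe_vals <- vals_a[pm$official[match(setdiff(probe_ids, orphans),
                                         pm$probe)], , drop = FALSE]
  rownames(probe_vals) <- setdiff(probe_ids, orphans)
  orphan_vals <- with_stream(config$seed, "orphan", {
    mu <- rnorm(length(orphans), config$baseline_mean, config$baseline_sd)
    sg <- sqrt(config$s0_sq * config$d0 / rchisq(length(orphans),
                                                 df = config$d0))
    v <- mu + matrix(rnorm(length(orphans) * ncol(vals_a)),
                     length(orphans)) * sg
    dimnames(v) <- list(orphans, colnames(vals_a))
    v
  })
  raw_vals <- rbind(vals_a[mrna_ids, , drop = FALSE], probe_vals,
                    orphan_vals)
  raw_vals <- raw_vals[c(mrna_ids, probe_ids), , drop = FALSE]
  expression_raw <- expression_matrix(
    raw_vals, c(rep("mRNA", length(mrna_ids)),
                rep("lncRNA", length(probe_ids))), ea$matrix$design)

  structure(list(config = config,
                 expression_raw = expression_raw,
                 expression = ea$matrix,
                 expression_hcc = eb$matrix,
                 smallrna = sr,
                 annotations = ann,
                 truth = structure(truth, class = "ground_truth")),
            class = "synth_bundle")
}

#' Check the internal consistency of a ground truth
#'
#' Asserts that null DE labels coincide with zero true effects and that
#' every planted edge endpoint exists in the generated annotation universe.
#' @param bundle A `synth_bundle`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_ground_truth <- function(bundle) {
  tr <- bundle$truth
  stopifnot(identical(names(tr$de_labels), names(tr$true_log2fc)))
  if (!all((tr$de_labels == "null") == (tr$true_log2fc == 0)))
    stop2("de_labels = null must coincide with true_log2fc = 0")
  if (!all((tr$de_labels_mirna == "null") == (tr$true_log2fc_mirna == 0)))
    stop2("miRNA de_labels = null must coincide with true_log2fc = 0")
  ann <- bundle$annotations
  tfs <- unique(ann$binding_sites$name)
  mirs <- ann$mirna_loci$name
  stopifnot(all(tr$planted_tf_mirna$tf %in% tfs),
            all(tr$planted_tf_mirna$mirna %in% mirs),
            all(tr$planted_mirna_mrna$mirna %in% mirs),
            all(tr$planted_mirna_mrna$target %in% ann$go_annotation$gene |
                  tr$planted_mirna_mrna$target %in%
                    names(tr$de_labels)),
            all(tr$planted_mirna_lncrna$target %in%
                  ann$official_lncrna_tx$name),
            all(c(tr$planted_ppi$gene_a, tr$planted_ppi$gene_b) %in%
                  names(tr$de_labels)),
            all(tr$planted_enriched_terms %in% ann$go_annotation$term))
  invisible(TRUE)
}

bundle_file_map <- function() {
  c(expression_array = "expression_array.tsv",
    analyte_classes = "analyte_classes.tsv",
    design_array = "design_array.tsv",
    expression_hcc = "expression_hcc.tsv",
    design_hcc = "design_hcc.tsv",
    design_srna = "design_srna.tsv",
    mature_fasta = "mature_mirna.fasta",
    contaminant_fasta = "contaminants.fasta",
    mirna_loci = "mirna_loci.bed",
    binding_sites = "tf_binding_sites.bed",
    official_lncrna_tx = "official_lncrna_tx.bed",
    array_lncrna_tx = "array_lncrna_tx.bed",
    mirna_mrna_targets = "mirna_mrna_targets.tsv",
    mirna_lncrna_targets = "mirna_lncrna_targets.tsv",
    ppi = "ppi.tsv",
    go_annotation = "go_annotation.tsv",
    immune_terms = "immune_terms.txt")
}

#' Write a synthetic bundle to a directory
#'
#' Writes every file in the documented external formats plus a JSON manifest
#' listing relative paths, the seed and the config hash. Ground-truth tables
#' go under `truth/`.
#'
#' @param bundle A `synth_bundle` (or an empty list, which writes a valid
#'   manifest with zero data files).
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop2("cannot create directory ", dir)
  files <- character(0)
  put <- function(rel) { files <<- c(files, rel); file.path(dir, rel) }

  if (length(bundle)) {
    fm <- bundle_file_map()
    write_expression_tsv(bundle$expression_raw, put(fm[["expression_array"]]))
    write_tsv_strict(
      data.frame(analyte = names(bundle$expression_raw$analyte_class),
                 class = unname(bundle$expression_raw$analyte_class),
                 stringsAsFactors = FALSE),
      put(fm[["analyte_classes"]]))
    write_tsv_strict(bundle$expression_raw$design, put(fm[["design_array"]]))
    write_expression_tsv(bundle$expression_hcc, put(fm[["expression_hcc"]]))
    write_tsv_strict(bundle$expression_hcc$design, put(fm[["design_hcc"]]))
    write_tsv_strict(bundle$smallrna$design, put(fm[["design_srna"]]))
    write_fasta(bundle$smallrna$mature, put(fm[["mature_fasta"]]))
    write_fasta(bundle$smallrna$contaminants, put(fm[["contaminant_fasta"]]))
    dir.create(file.path(dir, "reads"), showWarnings = FALSE)
    for (s in names(bundle$smallrna$reads))
      write_fastq(bundle$smallrna$reads[[s]],
                  put(file.path("reads", paste0(s, ".fastq"))))
    ann <- bundle$annotations
    write_bed6(ann$mirna_loci, put(fm[["mirna_loci"]]))
    write_bed6(ann$binding_sites, put(fm[["binding_sites"]]))
    write_bed6(ann$official_lncrna_tx, put(fm[["official_lncrna_tx"]]))
    write_bed6(ann$array_lncrna_tx, put(fm[["array_lncrna_tx"]]))
    write_tsv_strict(ann$mirna_mrna_targets, put(fm[["mirna_mrna_targets"]]))
    write_tsv_strict(ann$mirna_lncrna_targets,
                     put(fm[["mirna_lncrna_targets"]]))
    write_tsv_strict(ann$ppi, put(fm[["ppi"]]))
    write_tsv_strict(ann$go_annotation, put(fm[["go_annotation"]]))
    con <- file(put(fm[["immune_terms"]]), open = "wb")
    writeLines(ann$immune_terms, con, sep = "\n"); close(con)

    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    tr <- bundle$truth
    write_tsv_strict(
      data.frame(analyte = names(tr$de_labels),
                 label = unname(tr$de_labels),
                 true_log2fc = unname(tr$true_log2fc),
                 stringsAsFactors = FALSE),
      put(file.path("truth", "de_labels_array.tsv")))
    write_tsv_strict(
      data.frame(analyte = names(tr$de_labels_mirna),
                 label = unname(tr$de_labels_mirna),
                 true_log2fc = unname(tr$true_log2fc_mirna),
                 stringsAsFactors = FALSE),
      put(file.path("truth", "de_labels_mirna.tsv")))
    write_tsv_strict(
      data.frame(analyte = names(tr$de_labels_hcc),
                 label = unname(tr$de_labels_hcc),
                 true_log2fc = unname(tr$true_log2fc_hcc),
                 stringsAsFactors = FALSE),
      put(file.path("truth", "de_labels_hcc.tsv")))
    write_tsv_strict(
      data.frame(mirna = rownames(tr$mirna_true_counts),
                 as.data.frame(tr$mirna_true_counts, check.names = FALSE),
                 check.names = FALSE, stringsAsFactors = FALSE),
      put(file.path("truth", "mirna_true_counts.tsv")))
    for (nm in c("planted_tf_mirna", "planted_tf_mirna_negatives",
                 "planted_mirna_mrna", "planted_mirna_lncrna",
                 "planted_ppi", "probe_map"))
      write_tsv_strict(tr[[nm]], put(file.path("truth", paste0(nm, ".tsv"))))
    write_tsv_strict(tr$qc_planted, put(file.path("truth", "qc_planted.tsv")))
    con <- file(put(file.path("truth", "planted_enriched_terms.txt")),
                open = "wb")
    writeLines(tr$planted_enriched_terms, con, sep = "\n"); close(con)
  }

  manifest <- list(
    seed = if (length(bundle)) bundle$config$seed else NA_integer_,
    config_hash = if (length(bundle)) config_hash(bundle$config)
      else NA_character_,
    config = if (length(bundle)) unclass(bundle$config) else NULL,
    n_files = length(files),
    files = as.list(files))
  json <- canonical_json(manifest)
  con <- file(file.path(dir, "manifest.json"), open = "wb")
  writeLines(as.character(json), con, sep = "\n"); close(con)
  invisible(manifest)
}

#' Read a synthetic bundle back from a directory
#'
#' Inverse of [write_bundle()]; reconstructs the in-memory bundle (ground
#' truth included) from the written files.
#' @param dir Directory written by [write_bundle()].
#' @return A `synth_bundle`.
#' @export
read_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop2("no manifest.json under ", dir)
  manifest <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, manifest$config)
  fm <- bundle_file_map()
  p <- function(rel) file.path(dir, rel)

  cls_df <- read_tsv_strict(p(fm[["analyte_classes"]]),
                            required = c("analyte", "class"))
  cls <- setNames(cls_df$class, cls_df$analyte)
  design_a <- read_design_tsv(p(fm[["design_array"]]))
  expression_raw <- read_expression_tsv(p(fm[["expression_array"]]),
                                        cls, design_a)
  design_h <- read_design_tsv(p(fm[["design_hcc"]]))
  expression_hcc <- read_expression_tsv(p(fm[["expression_hcc"]]), "mRNA",
                                        design_h)
  design_s <- read_design_tsv(p(fm[["design_srna"]]))
  reads <- lapply(design_s$sample, function(s)
    read_fastq(p(file.path("reads", paste0(s, ".fastq")))))
  names(reads) <- design_s$sample

  tru_tab <- function(nm) read_tsv_strict(p(file.path("truth",
                                                      paste0(nm, ".tsv"))))
  lab_a <- tru_tab("de_labels_array")
  lab_m <- tru_tab("de_labels_mirna")
  lab_h <- tru_tab("de_labels_hcc")
  cnt <- tru_tab("mirna_true_counts")
  cm <- as.matrix(cnt[, -1, drop = FALSE]); rownames(cm) <- cnt$mirna
  storage.mode(cm) <- "integer"

  truth <- list(
    de_labels = setNames(lab_a$label, lab_a$analyte),
    true_log2fc = setNames(lab_a$true_log2fc, lab_a$analyte),
    de_labels_mirna = setNames(lab_m$label, lab_m$analyte),
    true_log2fc_mirna = setNames(lab_m$true_log2fc, lab_m$analyte),
    de_labels_hcc = setNames(lab_h$label, lab_h$analyte),
    true_log2fc_hcc = setNames(lab_h$true_log2fc, lab_h$analyte),
    mirna_true_counts = cm,
    qc_planted = tru_tab("qc_planted"),
    planted_tf_mirna = tru_tab("planted_tf_mirna"),
    planted_tf_mirna_negatives = tru_tab("planted_tf_mirna_negatives"),
    planted_mirna_mrna = tru_tab("planted_mirna_mrna"),
    planted_mirna_lncrna = tru_tab("planted_mirna_lncrna"),
    planted_ppi = tru_tab("planted_ppi"),
    probe_map = tru_tab("probe_map"),
    planted_enriched_terms =
      readLines(p(file.path("truth", "planted_enriched_terms.txt"))))
  attr(truth$de_labels, "class_of") <-
    cls[names(truth$de_labels)][!is.na(cls[names(truth$de_labels)])]

  annotations <- structure(list(
    mirna_loci = read_bed6(p(fm[["mirna_loci"]])),
    binding_sites = read_bed6(p(fm[["binding_sites"]])),
    mirna_mrna_targets = read_interaction_tsv(p(fm[["mirna_mrna_targets"]]),
                                              c("mirna", "target")),
    mirna_lncrna_targets =
      read_interaction_tsv(p(fm[["mirna_lncrna_targets"]]),
                           c("mirna", "target")),
    ppi = read_interaction_tsv(p(fm[["ppi"]]),
                               c("gene_a", "gene_b", "channel")),
    go_annotation = read_gaf_tsv(p(fm[["go_annotation"]])),
    immune_terms = readLines(p(fm[["immune_terms"]])),
    official_lncrna_tx = read_bed6(p(fm[["official_lncrna_tx"]])),
    array_lncrna_tx = read_bed6(p(fm[["array_lncrna_tx"]]))),
    class = "annotation_bundle")

  structure(list(config = cfg,
                 expression_raw = expression_raw,
                 expression = NULL,
                 expression_hcc = expression_hcc,
                 smallrna = list(reads = reads,
                                 mature = read_fasta(p(fm[["mature_fasta"]])),
                                 contaminants =
                                   read_fasta(p(fm[["contaminant_fasta"]])),
                                 design = design_s,
                                 truth = truth[c("de_labels_mirna",
                                                 "true_log2fc_mirna",
                                                 "mirna_true_counts",
                                                 "qc_planted")]),
                 annotations = annotations,
                 truth = structure(truth, class = "ground_truth")),
            class = "synth_bundle")
}
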