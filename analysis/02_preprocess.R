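#!/usr/bin/env Rscript
# Preprocess the raw inputs.
#
# Microarray: quantile normalization of the probe-level matrix, lncRNA
# identifier harmonization by strict >90% transcript overlap, and probe
# summarization (probes sharing an official ID averaged, unmatched probes
# omitted). Small RNA-seq: adapter (linker) trimming, read QC (length >=
# 16 nt, Phred >= 20 on >= 90% of bases, <= 5% uncertain bases),
# contaminant (rRNA/tRNA/snRNA) removal, exact-match miRNA counting, and
# TPM with the all-zero exclusion and 0.0001 pseudo-value rules.

suppressPackageStartupMessages(library(cirrnet))

bundle <- read_bundle("results/bundle")
pc <- pipeline_config()
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## microarray ----------------------------------------------------------
qn <- quantile_normalize(bundle$expression_raw)
mapping <- match_lncrna_ids(bundle$annotations$array_lncrna_tx,
                            bundle$annotations$official_lncrna_tx,
                            pc$overlap_fraction)
lnc_probes <- names(qn$analyte_class)[qn$analyte_class == "lncRNA"]
lnc <- summarize_probes(
  expression_matrix(qn$values[lnc_probes, , drop = FALSE], "lncRNA",
                    qn$design),
  mapping[, c("probe", "official")])
mrna_ids <- names(qn$analyte_class)[qn$analyte_class == "mRNA"]
em_array <- expression_matrix(
  rbind(qn$values[mrna_ids, , drop = FALSE], lnc$values),
  c(rep("mRNA", length(mrna_ids)), rep("lncRNA", nrow(lnc$values))),
  qn$design)
write_expression_tsv(em_array, file.path(out, "expression_cirrhosis.tsv"))
write_tsv_strict(data.frame(analyte = names(em_array$analyte_class),
                            class = unname(em_array$analyte_class)),
                 file.path(out, "analyte_classes.tsv"))
write_tsv_strict(em_array$design, file.path(out, "design_cirrhosis.tsv"))
message(nrow(mapping), "/", length(lnc_probes),
        " lncRNA probes matched an official transcript; ",
        nrow(lnc$values), " official lncRNAs after probe summarization")

em_hcc <- quantile_normalize(bundle$expression_hcc)
write_expression_tsv(em_hcc, file.path(out, "expression_hcc.tsv"))
write_tsv_strict(em_hcc$design, file.path(out, "design_hcc.tsv"))

## small RNA-seq --------------------------------------------------------
sr <- bundle$smallrna
reports <- list()
processed <- lapply(names(sr$reads), function(s) {
  r <- trim_adapter(sr$reads[[s]], bundle$config$adapter)
  f <- filter_reads_qc(r, pc$qc_min_len, pc$qc_phred_floor,
                       pc$qc_hq_fraction, pc$qc_max_uncertain)
  reports[[s]] <<- cbind(sample = s, f$report)
  remove_contaminants(f$reads, sr$contaminants)
})
names(processed) <- names(sr$reads)
qc <- do.call(rbind, reports)
write_tsv_strict(qc, file.path(out, "qc_report.tsv"))
message("QC: ", sum(qc$count[qc$reason == "pass"]), " reads passed, ",
        sum(qc$count[qc$reason != "pass"]), " failed (",
        sum(qc$count[qc$reason == "length"]), " length, ",
        sum(qc$count[qc$reason == "quality"]), " quality, ",
        sum(qc$count[qc$reason == "uncertainty"]), " uncertainty)")

tab <- compute_tpm(count_mirna(processed, sr$mature), pc$pseudo_tpm)
em_mirna <- mirna_log2_tpm(tab, sr$design)
write_expression_tsv(em_mirna, file.path(out, "expression_mirna_log2tpm.tsv"))
write_tsv_strict(data.frame(mirna = rownames(tab$counts),
                            as.data.frame(tab$counts, check.names = FALSE),
                            check.names = FALSE),
                 file.path(out, "mirna_counts.tsv"))
write_tsv_strict(sr$design, file.path(out, "design_mirna.tsv"))
message(nrow(tab$counts), "/", bundle$config$n_mirna,
        " miRNAs quantified (all-zero records excluded)")
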