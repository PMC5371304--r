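#!/usr/bin/env Rscript
# GO enrichment for both contrasts and the two-contrast overlap analysis.
#
# Hypergeometric enrichment of the DE mRNA sets over the annotation
# universe with BH FDR (significant at FDR < 0.05), term directions by
# strict majority of DE members; then the Venn-style overlap of DE mRNAs
# between cirrhosis and HCC, the overlapping significant GO terms with
# their per-contrast directions, and enrichment of the overlapping genes
# themselves.

suppressPackageStartupMessages(library(cirrnet))

bundle <- read_bundle("results/bundle")
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
pc <- pipeline_config()

read_de <- function(f) {
  df <- read.delim(file.path("results/diffexpr", f))
  df$analyte_id <- df$analyte
  class(df) <- c("de_result", "data.frame")
  df
}
de_array <- read_de("de_cirrhosis_array.tsv")
de_mrna <- de_array[de_array$class == "mRNA", ]
class(de_mrna) <- c("de_result", "data.frame")
de_hcc <- read_de("de_hcc.tsv")

gsa <- gene_set_annotation(bundle$annotations$go_annotation)
run_enrich <- function(genes, de) {
  res <- suppressWarnings(enrich(genes, gsa, pc$min_term_size))
  assign_direction(res, de)
}
enr_cirr <- run_enrich(de_mrna$analyte[de_mrna$significant], de_mrna)
enr_hcc <- run_enrich(de_hcc$analyte[de_hcc$significant], de_hcc)
write_tsv_strict(as.data.frame(enr_cirr),
                 file.path(out, "go_cirrhosis.tsv"))
write_tsv_strict(as.data.frame(enr_hcc), file.path(out, "go_hcc.tsv"))
n_sig <- sum(enr_cirr$fdr < pc$enrich_alpha)
message(n_sig, " significant GO terms in cirrhosis; top term: ",
        enr_cirr$term_name[1], " (", enr_cirr$term[1], ", p = ",
        format(enr_cirr$p[1], digits = 3), ", direction ",
        enr_cirr$direction[1], ")")

cmp <- compare_term_sets(enr_cirr, enr_hcc, alpha = pc$enrich_alpha,
                         gate = pc$enrich_gate,
                         immune_terms = bundle$annotations$immune_terms)
write_tsv_strict(cmp$overlap, file.path(out, "overlap_terms.tsv"))
message(nrow(cmp$overlap), " GO terms significant in both contrasts (",
        sum(cmp$overlap$immune), " immune-related)")
flip <- cmp$overlap[cmp$overlap$direction_a != cmp$overlap$direction_b, ]
if (nrow(flip))
  message("direction flips across contrasts: ",
          paste(sprintf("%s (%s in cirrhosis, %s in HCC)",
                        flip$term_name, flip$direction_a,
                        flip$direction_b), collapse = "; "))

ov <- overlap_de_sets(de_mrna, de_hcc)
write_tsv_strict(ov$overlap, file.path(out, "overlap_genes.tsv"))
message(nrow(ov$overlap), " overlapping DE mRNAs across contrasts (",
        sum(ov$overlap$direction_a != ov$overlap$direction_b),
        " change direction)")

enr_ov <- run_enrich(ov$overlap$analyte, de_mrna)
write_tsv_strict(as.data.frame(enr_ov),
                 file.path(out, "go_overlap_genes.tsv"))
if (nrow(enr_ov))
  message("overlap-gene enrichment top term: ", enr_ov$term_name[1],
          " (fdr = ", format(enr_ov$fdr[1], digits = 3), ")")
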