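#!/usr/bin/env Rscript
# Protein-coding ceRNA network with PPI overlay and immune flagging.
#
# DE mRNAs regulated by the same miRNA are competing endogenous RNAs:
# every unordered pair of co-targeted DE mRNAs is a ceRNA pair, merged
# across miRNAs with the union of shared miRNAs. PPI evidence is overlaid
# from the interaction table, restricted to the whitelisted channels
# (experimental verification, text mining, co-expression, database
# records) and to pairs with at least one DE gene. Genes annotated to an
# immune-response GO term are flagged; a ceRNA edge is immune when both
# endpoints are.

suppressPackageStartupMessages(library(cirrnet))

bundle <- read_bundle("results/bundle")
out <- "results/cerna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
pc <- pipeline_config()

mm_pairs <- read_interaction_tsv("results/networks/mirna_mrna_pairs.tsv",
                                 c("mirna", "target"))
de_array <- read.delim("results/diffexpr/de_cirrhosis_array.tsv")
sig_mrnas <- de_array$analyte[de_array$significant &
                                de_array$class == "mRNA"]

cerna <- infer_cerna_pairs(mm_pairs)
cerna <- overlay_ppi(cerna, bundle$annotations$ppi, pc$allowed_channels,
                     de_genes = sig_mrnas, strict = pc$strict_ppi)
cerna <- flag_immune(cerna, bundle$annotations$immune_terms,
                     bundle$annotations$go_annotation)
write_tsv_strict(cerna, file.path(out, "cerna_pairs.tsv"))
message(nrow(cerna), " ceRNA pairs from ",
        length(unique(mm_pairs$mirna)), " miRNAs; ",
        sum(cerna$ppi_supported), " PPI-supported, ",
        sum(cerna$immune_pair), " immune pairs")

## immune-response subnetworks ----------------------------------------
immune_genes <- intersect(
  sig_mrnas,
  unique(bundle$annotations$go_annotation$gene[
    bundle$annotations$go_annotation$term %in%
      bundle$annotations$immune_terms]))
message(length(immune_genes),
        " DE mRNAs annotated to immune-response terms")

for (nm in c("tf_network", "lnc_network")) {
  net <- read_graphml(file.path("results/networks",
                                paste0(nm, ".graphml")))
  sub <- extract_subnetwork(net, immune_genes)
  sub <- flag_immune(sub, bundle$annotations$immune_terms,
                     bundle$annotations$go_annotation)
  export_cytoscape(sub, out, paste0("immune_", nm))
  message("immune ", nm, ": ", nrow(sub$nodes), " nodes (",
          paste(sprintf("%d %s", as.vector(table(sub$nodes$kind)),
                        names(table(sub$nodes$kind))), collapse = ", "),
          "), ", nrow(sub$edges), " edges")
}
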