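#!/usr/bin/env Rscript
# Construct the TF-miRNA-mRNA and lncRNA-miRNA-mRNA regulatory networks.
#
# TF-miRNA pairs: a pair is generated when a TF binding site overlaps the
# DE miRNA's promoter window (1500 bp upstream to 500 bp downstream of the
# TSS) by at least 1 bp. miRNA-mRNA and miRNA-lncRNA pairs come from the
# target tables restricted to DE endpoints, with no constraint on the
# regulatory directions (as required by the downstream ceRNA analysis).
# Nodes carry degree and enrichment score (-log10 p) attributes; networks
# are exported as SIF + attribute tables + GraphML for Cytoscape.

suppressPackageStartupMessages(library(cirrnet))

bundle <- read_bundle("results/bundle")
de_dir <- "results/diffexpr"
out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
pc <- pipeline_config()

de_array <- read.delim(file.path(de_dir, "de_cirrhosis_array.tsv"))
de_mirna <- read.delim(file.path(de_dir, "de_cirrhosis_mirna.tsv"))
sig <- function(de) de$analyte[de$significant]
sig_mirs <- sig(de_mirna)
sig_mrnas <- sig(de_array[de_array$class == "mRNA", ])
sig_lncs <- sig(de_array[de_array$class == "lncRNA", ])

ann <- bundle$annotations
tf_pairs <- generate_tf_mirna_pairs(ann$binding_sites, ann$mirna_loci,
                                    sig_mirs, pc$promoter_upstream,
                                    pc$promoter_downstream)
mm_pairs <- generate_mirna_target_pairs(ann$mirna_mrna_targets, sig_mirs,
                                        sig_mrnas)
ml_pairs <- generate_mirna_target_pairs(ann$mirna_lncrna_targets,
                                        sig_mirs, sig_lncs)
message(nrow(tf_pairs), " TF-miRNA pairs (",
        length(unique(tf_pairs$tf)), " TFs, ",
        length(unique(tf_pairs$mirna)), " miRNAs)")
message(nrow(mm_pairs), " miRNA-mRNA pairs (",
        length(unique(mm_pairs$mirna)), " miRNAs, ",
        length(unique(mm_pairs$target)), " mRNAs)")
message(nrow(ml_pairs), " miRNA-lncRNA pairs (",
        length(unique(ml_pairs$mirna)), " miRNAs, ",
        length(unique(ml_pairs$target)), " lncRNAs)")

stats <- rbind(
  data.frame(analyte_id = de_array$analyte, log2fc = de_array$log2fc,
             p = de_array$p, fdr = de_array$fdr),
  data.frame(analyte_id = de_mirna$analyte, log2fc = de_mirna$log2fc,
             p = de_mirna$p, fdr = de_mirna$fdr))
tf_net <- assemble_network(list(tf_mirna = tf_pairs,
                                mirna_mrna = mm_pairs), stats)
lnc_net <- assemble_network(list(mirna_lncrna = ml_pairs,
                                 mirna_mrna = mm_pairs), stats)
write_tsv_strict(tf_pairs, file.path(out, "tf_mirna_pairs.tsv"))
write_tsv_strict(mm_pairs, file.path(out, "mirna_mrna_pairs.tsv"))
write_tsv_strict(ml_pairs, file.path(out, "mirna_lncrna_pairs.tsv"))
export_cytoscape(tf_net, out, "tf_network")
export_cytoscape(lnc_net, out, "lnc_network")

top <- function(net, kind, n = 5) {
  nd <- net$nodes[net$nodes$kind == kind, ]
  nd <- nd[order(-nd$degree, nd$id), ]
  paste(sprintf("%s (degree = %d)", head(nd$id, n), head(nd$degree, n)),
        collapse = ", ")
}
message("highest-degree miRNAs in the TF network: ", top(tf_net, "miRNA"))
message("highest-degree lncRNAs: ", top(lnc_net, "lncRNA", 3))
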