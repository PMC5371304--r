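# Synthetic annotation resources: miRNA gene loci on a synthetic genome,
# TF binding sites placed inside (planted edges) or >= 10 kb away from
# (planted negatives) promoter windows, miRNA target tables with decoys,
# a PPI table with evidence channels, lncRNA transcript pairs for
# identifier harmonization, and a GO annotation with one planted
# over-represented term.

SYNTH_CHROM <- "chrS"
NEG_SITE_REGION <- c(1000, 15000)   # binding sites for planted negatives
LOCI_OFFSET <- 30000                # first miRNA locus position
LOCI_SLOT <- 25000                  # per-locus spacing (>= 10 kb guards)
LOCUS_LEN <- 80L
SITE_LEN <- 12L

de_ids <- function(labels) names(labels)[labels != "null"]
null_ids <- function(labels) names(labels)[labels == "null"]

sample_some <- function(x, k) {
  if (length(x) == 0 || k <= 0) return(x[0])
  sample(x, min(k, length(x)))
}

# k decoy rows pairing independent draws from a and b (empty when either is).
decoy_rows <- function(a, b, k, cols) {
  k <- min(k, length(a), length(b))
  if (k == 0)
    return(setNames(data.frame(x = character(0), y = character(0),
                               stringsAsFactors = FALSE), cols))
  setNames(data.frame(x = sample(a, k), y = sample(b, k),
                      stringsAsFactors = FALSE), cols)
}

#' Simulate annotation resources consistent with a ground truth
#'
#' Emits the resource tables the network-construction stages consume, with
#' the planted regulatory structure recoverable by construction: every
#' planted TF-miRNA edge has a binding site inside the miRNA's promoter
#' window, every planted negative has its sites placed at least 10 kb away
#' from any promoter window, target tables contain all planted edges plus
#' decoy edges whose endpoints are not differentially expressed, the PPI
#' table covers the planted pairs through whitelisted evidence channels, and
#' the planted GO term is over-represented among up-regulated DE mRNAs at
#' the configured odds ratio.
#'
#' @param config A [sim_config()].
#' @param truth Merged ground-truth list carrying `de_labels` (mRNA +
#'   lncRNA) and `de_labels_mirna` from the expression and small-RNA
#'   simulators run with the same config.
#' @return List of class `annotation_bundle`.
#' @export
simulate_annotations <- function(config, truth) {
  validate_sim_config(config)
  if (is.null(truth$de_labels) || is.null(truth$de_labels_mirna))
    stop2("truth must carry de_labels and de_labels_mirna")
  with_stream(config$seed, "annotations", {
    n_mir <- config$n_mirna
    mirna_ids <- names(truth$de_labels_mirna)
    cls <- attr(truth$de_labels, "class_of") %||%
      ifelse(grepl("^LNC", names(truth$de_labels)), "lncRNA", "mRNA")
    mrna_ids <- names(truth$de_labels)[cls == "mRNA"]
    lnc_ids <- names(truth$de_labels)[cls == "lncRNA"]
    tf_ids <- sprintf("TF%02d", seq_len(config$n_tf))

    lnc_region <- LOCI_OFFSET + n_mir * LOCI_SLOT + 10000
    need <- lnc_region + length(lnc_ids) * 3000 + 5000
    if (config$genome_length < need)
      stop2(sprintf(
        "genome_length %g too short to place all loci without overlap (need %g)",
        config$genome_length, need))

    # --- miRNA gene loci ------------------------------------------------
    jitter <- sample.int(500L, n_mir, replace = TRUE) - 1L
    starts <- as.integer(LOCI_OFFSET + (seq_len(n_mir) - 1L) * LOCI_SLOT +
                           jitter)
    strands <- sample(c("+", "-"), n_mir, replace = TRUE)
    mirna_loci <- data.frame(chrom = SYNTH_CHROM, start = starts,
                             end = starts + LOCUS_LEN, name = mirna_ids,
                             score = 0L, strand = strands,
                             stringsAsFactors = FALSE)

    de_mirs <- de_ids(truth$de_labels_mirna)
    null_mirs <- null_ids(truth$de_labels_mirna)
    de_mrnas <- de_ids(truth$de_labels)[de_ids(truth$de_labels) %in% mrna_ids]
    null_mrnas <- null_ids(truth$de_labels)[null_ids(truth$de_labels) %in% mrna_ids]
    de_lncs <- de_ids(truth$de_labels)[de_ids(truth$de_labels) %in% lnc_ids]
    null_lncs <- null_ids(truth$de_labels)[null_ids(truth$de_labels) %in% lnc_ids]

    # --- planted TF-miRNA edges and negatives ---------------------------
    planted_tf <- do.call(rbind, lapply(de_mirs, function(m) {
      tfs <- sample_some(tf_ids, config$tfs_per_mirna)
      if (!length(tfs)) return(NULL)
      data.frame(tf = tfs, mirna = m, stringsAsFactors = FALSE)
    }))
    if (is.null(planted_tf))
      planted_tf <- data.frame(tf = character(0), mirna = character(0),
                               stringsAsFactors = FALSE)
    negatives <- do.call(rbind, lapply(de_mirs, function(m) {
      used <- planted_tf$tf[planted_tf$mirna == m]
      free <- setdiff(tf_ids, used)
      if (!length(free)) return(NULL)
      data.frame(tf = sample(free, 1), mirna = m, stringsAsFactors = FALSE)
    }))
    if (is.null(negatives))
      negatives <- data.frame(tf = character(0), mirna = character(0),
                              stringsAsFactors = FALSE)

    tss <- ifelse(strands == "+", mirna_loci$start, mirna_loci$end - 1L)
    names(tss) <- mirna_ids
    names(strands) <- mirna_ids
    win <- promoter_window(tss, strands)
    rownames(win) <- mirna_ids

    site_rows <- list()
    if (nrow(planted_tf)) {
      for (i in seq_len(nrow(planted_tf))) {
        m <- planted_tf$mirna[i]
        ws <- win$start[match(m, mirna_ids)]
        we <- win$end[match(m, mirna_ids)]
        st <- ws + sample.int(we - ws - SITE_LEN + 1L, 1L) - 1L
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(chrom = SYNTH_CHROM, start = st, end = st + SITE_LEN,
                     name = planted_tf$tf[i], score = 0L, strand = ".",
                     stringsAsFactors = FALSE)
      }
    }
    if (nrow(negatives)) {
      lo <- NEG_SITE_REGION[1]; hi <- NEG_SITE_REGION[2] - SITE_LEN
      for (i in seq_len(nrow(negatives))) {
        st <- lo + sample.int(hi - lo, 1L) - 1L
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(chrom = SYNTH_CHROM, start = st, end = st + SITE_LEN,
                     name = negatives$tf[i], score = 0L, strand = ".",
                     stringsAsFactors = FALSE)
      }
    }
    # Decoy sites inside promoters of non-DE miRNAs: never yield pairs
    # because pair generation is restricted to DE miRNAs.
    for (m in sample_some(null_mirs, 2L)) {
      ws <- win$start[match(m, mirna_ids)]
      st <- ws + sample.int(win$end[match(m, mirna_ids)] - ws - SITE_LEN + 1L,
                            1L) - 1L
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(chrom = SYNTH_CHROM, start = st, end = st + SITE_LEN,
                   name = sample(tf_ids, 1), score = 0L, strand = ".",
                   stringsAsFactors = FALSE)
    }
    binding_sites <- if (length(site_rows)) do.call(rbind, site_rows)
      else data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)

    # --- target tables with planted edges + decoys ----------------------
    planted_mm <- do.call(rbind, lapply(de_mirs, function(m) {
      tg <- sample_some(de_mrnas, config$targets_per_mirna)
      if (!length(tg)) return(NULL)
      data.frame(mirna = m, target = tg, stringsAsFactors = FALSE)
    })) %||% data.frame(mirna = character(0), target = character(0))
    decoy_mm <- rbind(
      decoy_rows(null_mirs, null_mrnas, 5, c("mirna", "target")),
      decoy_rows(de_mirs, null_mrnas, 3, c("mirna", "target")),
      decoy_rows(null_mirs, de_mrnas, 3, c("mirna", "target")))
    mirna_mrna_targets <- unique(rbind(planted_mm, decoy_mm))

    planted_ml <- do.call(rbind, lapply(de_mirs, function(m) {
      tg <- sample_some(de_lncs, config$lnc_targets_per_mirna)
      if (!length(tg)) return(NULL)
      data.frame(mirna = m, target = tg, stringsAsFactors = FALSE)
    })) %||% data.frame(mirna = character(0), target = character(0))
    decoy_ml <- rbind(
      decoy_rows(null_mirs, null_lncs, 4, c("mirna", "target")),
      decoy_rows(de_mirs, null_lncs, 2, c("mirna", "target")))
    mirna_lncrna_targets <- unique(rbind(planted_ml, decoy_ml))

    # --- PPI table ------------------------------------------------------
    allowed <- c("experiments", "textmining", "coexpression", "database")
    implied <- infer_cerna_pairs(
      setNames(planted_mm[, c("mirna", "target")], c("mirna", "mrna")))
    planted_ppi <- implied[sample_some(seq_len(nrow(implied)), 30L),
                           c("gene_a", "gene_b"), drop = FALSE]
    rownames(planted_ppi) <- NULL
    ppi_rows <- list()
    if (nrow(planted_ppi))
      ppi_rows$planted <- data.frame(
        gene_a = planted_ppi$gene_a, gene_b = planted_ppi$gene_b,
        channel = sample(allowed, nrow(planted_ppi), replace = TRUE),
        stringsAsFactors = FALSE)
    if (length(de_mrnas) >= 2) {
      pick <- replicate(5, sample(de_mrnas, 2))
      ppi_rows$bad_channel <- data.frame(
        gene_a = pick[1, ], gene_b = pick[2, ], channel = "neighborhood",
        stringsAsFactors = FALSE)
    }
    if (length(null_mrnas) >= 2) {
      pick <- replicate(5, sample(null_mrnas, 2))
      ppi_rows$no_de <- data.frame(
        gene_a = pick[1, ], gene_b = pick[2, ],
        channel = sample(allowed, 5, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ppi <- do.call(rbind, unname(ppi_rows)) %||%
      data.frame(gene_a = character(0), gene_b = character(0),
                 channel = character(0), stringsAsFactors = FALSE)
    rownames(ppi) <- NULL

    # --- lncRNA transcripts and probes ----------------------------------
    n_lnc <- length(lnc_ids)
    lnc_len <- sample(500:1500, n_lnc, replace = TRUE)
    lnc_start <- as.integer(lnc_region + (seq_len(n_lnc) - 1L) * 3000L)
    lnc_strand <- sample(c("+", "-"), n_lnc, replace = TRUE)
    official_tx <- data.frame(chrom = SYNTH_CHROM, start = lnc_start,
                              end = lnc_start + lnc_len, name = lnc_ids,
                              score = 0L, strand = lnc_strand,
                              stringsAsFactors = FALSE)
    shift_of <- function(len) sample.int(pmax(1L, floor(0.08 * len)), 1L) - 1L
    probe_rows <- list(); probe_map <- list()
    pcount <- 0L
    add_probe <- function(i, official) {
      pcount <<- pcount + 1L
      pid <- sprintf("PR-%04d", pcount)
      sh <- shift_of(lnc_len[i])
      probe_rows[[pcount]] <<- data.frame(
        chrom = SYNTH_CHROM, start = lnc_start[i] + sh,
        end = lnc_start[i] + lnc_len[i] + sh, name = pid, score = 0L,
        strand = lnc_strand[i], stringsAsFactors = FALSE)
      probe_map[[pcount]] <<- data.frame(probe = pid, official = official,
                                         stringsAsFactors = FALSE)
      pid
    }
    for (i in seq_len(n_lnc)) add_probe(i, lnc_ids[i])
    dup_idx <- sample_some(seq_len(n_lnc), config$lncrna_duplicate_probes)
    for (i in dup_idx) add_probe(i, lnc_ids[i])
    # Orphan probes: intervals in a desert region, matching no official
    # transcript; their records must be omitted downstream.
    orphan_base <- as.integer(lnc_region + n_lnc * 3000L + 2000L)
    for (j in seq_len(config$lncrna_orphan_probes)) {
      pcount <- pcount + 1L
      pid <- sprintf("PR-%04d", pcount)
      st <- orphan_base + (j - 1L) * 400L
      probe_rows[[pcount]] <- data.frame(
        chrom = SYNTH_CHROM, start = st, end = st + 300L, name = pid,
        score = 0L, strand = "+", stringsAsFactors = FALSE)
    }
    array_tx <- do.call(rbind, probe_rows)
    probe_map <- do.call(rbind, probe_map)

    # --- GO annotation ---------------------------------------------------
    terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    term_names <- c("immune response", "activation of immune response",
                    "acute inflammatory response",
                    sprintf("biological process %02d",
                            seq_len(max(0, config$n_go_terms - 3))))
    term_names <- term_names[seq_len(config$n_go_terms)]
    immune_terms <- terms[seq_len(min(3L, config$n_go_terms))]
    planted_term <- terms[1]
    # The planted term is over-represented among mRNAs upregulated in the
    # first (cirrhosis) contrast and, when a second contrast is present,
    # among mRNAs downregulated in it — the planted analog of an immune
    # program induced in cirrhosis and lost in HCC, giving the
    # cross-contrast term comparison a planted direction flip.
    up_mrnas <- names(truth$de_labels)[truth$de_labels == "up" &
                                         cls == "mRNA"]
    if (!is.null(truth$de_labels_hcc))
      up_mrnas <- union(up_mrnas,
                        names(truth$de_labels_hcc)[
                          truth$de_labels_hcc == "down"])
    base_odds <- config$go_base_rate / (1 - config$go_base_rate)
    hi_rate <- config$go_odds_ratio * base_odds /
      (1 + config$go_odds_ratio * base_odds)
    ann_rows <- list()
    for (t in seq_along(terms)) {
      rate <- rep(config$go_base_rate, length(mrna_ids))
      if (terms[t] == planted_term)
        rate[mrna_ids %in% up_mrnas] <- hi_rate
      hit <- runif(length(mrna_ids)) < rate
      if (any(hit))
        ann_rows[[t]] <- data.frame(gene = mrna_ids[hit], term = terms[t],
                                    term_name = term_names[t],
                                    stringsAsFactors = FALSE)
    }
    go_annotation <- do.call(rbind, ann_rows) %||%
      data.frame(gene = character(0), term = character(0),
                 term_name = character(0), stringsAsFactors = FALSE)
    rownames(go_annotation) <- NULL

    structure(list(
      mirna_loci = mirna_loci, binding_sites = binding_sites,
      mirna_mrna_targets = mirna_mrna_targets,
      mirna_lncrna_targets = mirna_lncrna_targets,
      ppi = ppi, go_annotation = go_annotation,
      immune_terms = immune_terms,
      official_lncrna_tx = official_tx, array_lncrna_tx = array_tx,
      truth = list(planted_tf_mirna = planted_tf,
                   planted_tf_mirna_negatives = negatives,
                   planted_mirna_mrna = setNames(planted_mm,
                                                 c("mirna", "target")),
                   planted_mirna_lncrna = setNames(planted_ml,
                                                   c("mirna", "target")),
                   planted_ppi = planted_ppi,
                   planted_enriched_terms = planted_term,
                   probe_map = probe_map)),
      class = "annotation_bundle")
  })
}
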