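test_that("promoter windows follow the strand-aware -1500/+500 convention", {
  w <- promoter_window(10000, "+")
  expect_equal(c(w$start, w$end), c(8500, 10500))
  w <- promoter_window(10000, "-")
  expect_equal(c(w$start, w$end), c(9501, 11501))
  w <- promoter_window(100, "+")
  expect_equal(c(w$start, w$end), c(0, 600))

  # the '-' strand window is the per-base mirror of the '+' window
  withr::with_seed(2, {
    for (tss in sample(2000:50000, 20)) {
      wp <- promoter_window(tss, "+")
      wm <- promoter_window(tss, "-")
      mirrored <- sort(2L * tss - bases_of(wp$start, wp$end))
      expect_identical(bases_of(wm$start, wm$end), mirrored)
    }
  })
})

test_that("TF-miRNA pairs require >= 1 bp promoter overlap in half-open coords", {
  loci <- data.frame(chrom = "chrS", start = 10000, end = 10080,
                     name = "miR-x", score = 0, strand = "+")
  mk_site <- function(s, e, tf = "TFa")
    data.frame(chrom = "chrS", start = s, end = e, name = tf, score = 0,
               strand = ".")
  # window [8500, 10500): a site ending at 8501 overlaps by exactly 1 bp
  expect_identical(generate_tf_mirna_pairs(mk_site(8499, 8501), loci,
                                           "miR-x"),
                   data.frame(tf = "TFa", mirna = "miR-x",
                              stringsAsFactors = FALSE))
  # touching intervals do not overlap
  expect_identical(nrow(generate_tf_mirna_pairs(mk_site(8498, 8500), loci,
                                                "miR-x")), 0L)
  expect_identical(nrow(generate_tf_mirna_pairs(mk_site(10500, 10520),
                                                loci, "miR-x")), 0L)
  # non-DE miRNA yields nothing; missing locus warns and skips
  expect_identical(nrow(generate_tf_mirna_pairs(mk_site(9000, 9012), loci,
                                                character(0))), 0L)
  expect_warning(
    out <- generate_tf_mirna_pairs(mk_site(9000, 9012), loci,
                                   c("miR-x", "miR-ghost")),
    "miR-ghost")
  expect_identical(out$mirna, "miR-x")
  # duplicate sites collapse to one pair
  two <- rbind(mk_site(9000, 9012), mk_site(9100, 9112))
  expect_identical(nrow(generate_tf_mirna_pairs(two, loci, "miR-x")), 1L)
})

test_that("promoter intersection decisions match the per-base brute force", {
  withr::with_seed(19, {
    n_cfg <- 400
    for (i in seq_len(n_cfg)) {
      tss <- sample(0:9000, 1)
      strand <- sample(c("+", "-"), 1)
      loci <- data.frame(chrom = "c", start = NA, end = NA, name = "m",
                         score = 0, strand = strand)
      if (strand == "+") { loci$start <- tss; loci$end <- tss + 50 }
      else { loci$end <- tss + 1; loci$start <- max(0, tss - 49) }
      s <- sample(0:9990, 1)
      site <- data.frame(chrom = "c", start = s,
                         end = s + sample(1:200, 1), name = "T", score = 0,
                         strand = ".")
      got <- nrow(suppressWarnings(
        generate_tf_mirna_pairs(site, loci, "m"))) == 1L
      w <- promoter_window(tss, strand)
      want <- overlaps_brute(site$start, site$end, w$start, w$end)
      expect_identical(got, want)
    }
  })
})

test_that("miRNA target pairs are gated on DE status and optional direction", {
  tab <- data.frame(mirna = c("m1", "m1", "m2", "m1"),
                    target = c("G1", "G2", "G1", "G9"))
  dirs_m <- c(m1 = "up", m2 = "down")
  dirs_g <- c(G1 = "up", G2 = "down")
  out <- generate_mirna_target_pairs(tab, c("m1", "m2"), c("G1", "G2"))
  expect_identical(edge_key(out),
                   edge_key(data.frame(mirna = c("m1", "m1", "m2"),
                                       target = c("G1", "G2", "G1"))))
  # same-direction pair dropped under the constraint
  out2 <- generate_mirna_target_pairs(tab, c("m1", "m2"), c("G1", "G2"),
                                      direction_constraint = TRUE,
                                      mirna_directions = dirs_m,
                                      target_directions = dirs_g)
  expect_identical(edge_key(out2),
                   edge_key(data.frame(mirna = c("m1", "m2"),
                                       target = c("G2", "G1"))))
  # non-DE target dropped
  expect_false("G9" %in% out$target)
})

test_that("assembled networks carry consistent kinds, degrees and scores", {
  el <- list(tf_mirna = data.frame(tf = "T", mirna = "m1"),
             mirna_mrna = data.frame(mirna = c("m1", "m1"),
                                     target = c("G1", "G2")))
  ann <- data.frame(analyte_id = c("m1", "G1", "G2"),
                    log2fc = c(-2, 1, 3), p = c(1e-4, 1e-2, 1e-310),
                    fdr = c(1e-3, 5e-2, 1e-300))
  net <- assemble_network(el, ann)
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_identical(deg[["m1"]], 3L)
  expect_identical(deg[["T"]], 1L)
  expect_identical(net$nodes$kind[net$nodes$id == "T"], "TF")
  # p floored at 1e-300 for the display score
  expect_equal(net$nodes$enrichment_score[net$nodes$id == "G2"], 300)
  # TF without annotation has NA stats but is not flagged as dangling
  expect_true(is.na(net$nodes$p[net$nodes$id == "T"]))
  expect_false(net$nodes$flagged[net$nodes$id == "T"])

  empty <- assemble_network(list())
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("degrees equal brute-force incident-edge counts on random networks", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n_m <- sample(2:6, 1); n_g <- sample(2:15, 1)
      el <- list(mirna_mrna = unique(data.frame(
        mirna = sample(sprintf("m%d", 1:n_m), 20, TRUE),
        target = sample(sprintf("G%d", 1:n_g), 20, TRUE))))
      if (i %% 2 == 0)
        el$tf_mirna <- unique(data.frame(
          tf = sample(c("T1", "T2"), 5, TRUE),
          mirna = sample(sprintf("m%d", 1:n_m), 5, TRUE)))
      net <- assemble_network(el)
      want <- degree_oracle(net$edges, net$nodes$id)
      expect_identical(net$nodes$degree, unname(want))
    }
  })
})

test_that("ceRNA inference enumerates and merges shared-miRNA pairs", {
  ed <- data.frame(mirna = "mx", mrna = c("A", "B", "C"))
  out <- infer_cerna_pairs(ed)
  expect_identical(out$gene_a, c("A", "A", "B"))
  expect_identical(out$gene_b, c("B", "C", "C"))
  expect_true(all(out$shared_mirnas == "mx"))

  ed2 <- data.frame(mirna = c("mx", "mx", "my", "my"),
                    mrna = c("A", "B", "A", "B"))
  out2 <- infer_cerna_pairs(ed2)
  expect_identical(nrow(out2), 1L)
  expect_identical(out2$shared_mirnas, "mx;my")
  expect_identical(out2$n_shared, 2L)

  expect_identical(nrow(infer_cerna_pairs(ed2[0, ])), 0L)
})

test_that("ceRNA inference equals the quadratic brute force on random graphs", {
  withr::with_seed(29, {
    for (i in 1:40) {
      n_m <- sample(2:10, 1); n_g <- sample(3:30, 1)
      ed <- unique(data.frame(
        mirna = sample(sprintf("m%02d", 1:n_m), 60, TRUE),
        target = sample(sprintf("G%02d", 1:n_g), 60, TRUE)))
      got <- infer_cerna_pairs(ed)
      want <- cerna_oracle(ed)
      expect_equal(got, want)
    }
  })
})

test_that("PPI overlay honors the channel whitelist and DE requirement", {
  pairs <- infer_cerna_pairs(data.frame(mirna = "m", mrna = c("A", "B",
                                                              "C")))
  ppi <- data.frame(gene_a = c("B", "A", "C"), gene_b = c("A", "C", "Z"),
                    channel = c("experiments", "neighborhood",
                                "database"))
  out <- overlay_ppi(pairs, ppi, de_genes = c("A", "B"))
  sup <- setNames(out$ppi_supported, paste(out$gene_a, out$gene_b))
  expect_true(sup[["A B"]])      # whitelisted channel, DE endpoint
  expect_false(sup[["A C"]])     # neighborhood-only evidence
  expect_false(sup[["B C"]])     # absent from the PPI table
  strict <- overlay_ppi(pairs, ppi, de_genes = c("A", "B"), strict = TRUE)
  expect_identical(nrow(strict), 1L)
  # no DE endpoint: unsupported even with a whitelisted channel
  out2 <- overlay_ppi(pairs, ppi, de_genes = character(0))
  expect_false(any(out2$ppi_supported))
  expect_error(overlay_ppi(pairs, ppi, allowed_channels = "wizardry"),
               "valid labels")
})

test_that("immune flagging requires annotation for nodes and both endpoints for pairs", {
  ann <- data.frame(gene = c("A", "B", "C"),
                    term = c("GO:1", "GO:1", "GO:2"))
  pairs <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      shared_mirnas = "m", n_shared = 1L)
  out <- flag_immune(pairs, "GO:1", ann)
  expect_identical(out$immune_pair, c(TRUE, FALSE))
  net <- assemble_network(list(mirna_mrna = data.frame(
    mirna = "m", target = c("A", "C"))))
  net <- flag_immune(net, "GO:1", ann)
  expect_identical(setNames(net$nodes$immune, net$nodes$id)[c("A", "C")],
                   c(A = TRUE, C = FALSE))
  expect_false(any(flag_immune(pairs, character(0), ann)$immune_pair))
})

test_that("subnetwork extraction keeps regulators reaching the gene set", {
  el <- list(tf_mirna = data.frame(tf = c("T", "T2"),
                                   mirna = c("m1", "m2")),
             mirna_mrna = data.frame(mirna = c("m1", "m2"),
                                     target = c("G1", "G2")),
             mirna_lncrna = data.frame(mirna = "m1", target = "L1"))
  net <- assemble_network(el)
  sub <- extract_subnetwork(net, "G1")
  expect_setequal(sub$nodes$id, c("G1", "m1", "T", "L1"))
  expect_false("m2" %in% sub$nodes$id)   # its only mRNA is not retained
  expect_false("T2" %in% sub$nodes$id)
  expect_identical(sub$nodes$degree,
                   unname(degree_oracle(sub$edges, sub$nodes$id)))
  # the full gene set gives back the network; the empty set empties it
  all_genes <- net$nodes$id[net$nodes$kind == "mRNA"]
  expect_equal(extract_subnetwork(net, all_genes), net)
  expect_identical(nrow(extract_subnetwork(net, character(0))$nodes), 0L)
})

test_that("Cytoscape export writes SIF lines per edge and round-trips GraphML", {
  el <- list(tf_mirna = data.frame(tf = "T", mirna = "m1"),
             mirna_mrna = data.frame(mirna = c("m1", "m1"),
                                     target = c("G1", "G2")))
  ann <- data.frame(analyte_id = c("m1", "G1", "G2"),
                    log2fc = c(-2, 1, 3), p = c(1e-4, 1e-2, 1e-6),
                    fdr = c(1e-3, 5e-2, 1e-5))
  net <- assemble_network(el, ann)
  d <- withr::local_tempdir()
  paths <- export_cytoscape(net, d, "n1")
  sif <- read_sif(paths[1])
  expect_identical(nrow(sif), nrow(net$edges))
  back <- read_graphml(paths[4])
  expect_equal(back$nodes[names(net$nodes)], net$nodes)
  expect_equal(back$edges, net$edges)

  empty <- assemble_network(list())
  paths0 <- export_cytoscape(empty, d, "n0")
  expect_true(all(file.exists(paths0)))
  expect_identical(nrow(read_sif(paths0[1])), 0L)
})

test_that("exports are byte-identical across repeated runs", {
  el <- list(mirna_mrna = data.frame(mirna = c("m2", "m1"),
                                     target = c("G2", "G1")))
  net <- assemble_network(el)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- export_cytoscape(net, d1); p2 <- export_cytoscape(net, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
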