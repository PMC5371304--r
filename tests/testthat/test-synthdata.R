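test_that("de_fraction = 0 plants no effects and seeds give identical output", {
  cfg <- tiny_config(seed = 3, de_fraction = 0)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$truth$de_labels == "null"))
  expect_true(all(sim$truth$true_log2fc == 0))

  sim2 <- simulate_expression(cfg)
  expect_identical(sim$matrix$values, sim2$matrix$values)

  sr <- simulate_small_rna(cfg)
  expect_true(all(sr$truth$de_labels_mirna == "null"))
  sr2 <- simulate_small_rna(cfg)
  expect_identical(sr$reads, sr2$reads)
  expect_identical(sr$truth$mirna_true_counts, sr2$truth$mirna_true_counts)
})

test_that("null labels coincide with zero effects and invalid configs error", {
  b <- simulate_bundle(tiny_config(seed = 11))
  expect_true(validate_ground_truth(b))
  expect_error(sim_config(d0 = 0), "d0")
  expect_error(sim_config(s0_sq = -1), "s0_sq")
  expect_error(sim_config(adapter = "ACGU"), "adapter")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
})

test_that("sample mean differences track planted effects at n = 50 + 50", {
  # Normal theory: mean-difference SE = sigma * sqrt(2/50); under the
  # variance prior (d0 = 4, s0_sq = 0.05) deviations beyond +-0.5 are rare,
  # so well over 95% of DE analytes must land within +-0.5 of truth.
  cfg <- sim_config(seed = 5, n_mrna = 1000, n_lncrna = 100, n_mirna = 10,
                    n_control = 50, n_case = 50, min_abs_log2fc = 2,
                    d0 = 4, s0_sq = 0.05)
  sim <- simulate_expression(cfg)
  de <- names(sim$truth$de_labels)[sim$truth$de_labels != "null"]
  grp <- sim$matrix$design$group
  obs <- rowMeans(sim$matrix$values[de, grp == "case", drop = FALSE]) -
    rowMeans(sim$matrix$values[de, grp == "control", drop = FALSE])
  frac <- mean(abs(obs - sim$truth$true_log2fc[de]) <= 0.5)
  expect_gte(frac, 0.95)
})

test_that("null analyte variances follow the scaled inverse chi-squared prior", {
  # s2 / s0_sq is marginally F(d, d0) under the conjugate model.
  cfg <- sim_config(seed = 9, n_mrna = 2000, n_lncrna = 100, n_mirna = 10,
                    de_fraction = 0)
  sim <- simulate_expression(cfg)
  grp <- sim$matrix$design$group
  m <- sim$matrix$values
  x1 <- m[, grp == "control", drop = FALSE]
  x2 <- m[, grp == "case", drop = FALSE]
  d <- ncol(m) - 2
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
           rowSums((x2 - rowMeans(x2))^2)) / d
  ks <- suppressWarnings(
    ks.test(s2 / cfg$s0_sq, function(q) pf(q, d, cfg$d0)))
  expect_gt(ks$p.value, 0.01)
})

test_that("small-RNA reads reproduce true counts when nothing is planted to fail", {
  cfg <- tiny_config(seed = 21, contaminant_fraction = 0, fail_fraction = 0)
  sr <- simulate_small_rna(cfg)
  counted <- count_mirna(lapply(sr$reads, trim_adapter, cfg$adapter),
                         sr$mature)
  expect_identical(counted$counts, sr$truth$mirna_true_counts)
})

test_that("reads_per_sample = 0 yields empty read sets and zero counts", {
  cfg <- tiny_config(seed = 2, reads_per_sample = 0)
  sr <- simulate_small_rna(cfg)
  expect_true(all(vapply(sr$reads, nrow, 0L) == 0L))
  expect_true(all(sr$truth$mirna_true_counts == 0L))
})

test_that("constructed QC failures are placed deterministically and exactly", {
  cfg <- tiny_config(seed = 13, reads_per_sample = 1000,
                     fail_fraction = 0.2, contaminant_fraction = 0)
  sr <- simulate_small_rna(cfg)
  for (s in names(sr$reads)) {
    trimmed <- trim_adapter(sr$reads[[s]], cfg$adapter)
    rep <- filter_reads_qc(trimmed)$report
    n_fail <- sum(rep$count[rep$reason != "pass"])
    expect_identical(n_fail, 200L)  # round(0.2 * 1000), independent recount
    qp <- sr$truth$qc_planted
    expect_identical(n_fail,
                     qp$n_fail_short[qp$sample == s] +
                       qp$n_fail_quality[qp$sample == s] +
                       qp$n_fail_uncertain[qp$sample == s])
  }
})

test_that("planted binding sites intersect promoter windows; negatives stay clear", {
  b <- simulate_bundle(tiny_config(seed = 17))
  ann <- b$annotations
  loci <- ann$mirna_loci
  tss <- ifelse(loci$strand == "+", loci$start, loci$end - 1L)
  win <- promoter_window(tss, loci$strand)
  for (i in seq_len(nrow(b$truth$planted_tf_mirna))) {
    e <- b$truth$planted_tf_mirna[i, ]
    j <- match(e$mirna, loci$name)
    sites <- ann$binding_sites[ann$binding_sites$name == e$tf, ]
    hit <- any(mapply(overlaps_brute, sites$start, sites$end,
                      win$start[j], win$end[j]))
    expect_true(hit)
  }
  # planted negatives: no site of that TF within 10 kb of ANY window
  for (i in seq_len(nrow(b$truth$planted_tf_mirna_negatives))) {
    e <- b$truth$planted_tf_mirna_negatives[i, ]
    j <- match(e$mirna, loci$name)
    sites <- ann$binding_sites[ann$binding_sites$name == e$tf, ]
    near <- mapply(function(s, e2) s < win$end[j] + 10000 &&
                     e2 > win$start[j] - 10000, sites$start, sites$end)
    hit <- any(mapply(overlaps_brute, sites$start, sites$end,
                      win$start[j], win$end[j]))
    expect_false(hit)
    # sites that are near a window must belong to planted edges, not this one
    expect_true(all(!near | sites$end <= 15000))
  }
  expect_error(simulate_annotations(tiny_config(genome_length = 1e4),
                                    b$truth),
               "too short")
})

test_that("the planted GO term is detectably enriched across seeds", {
  # 40 up-regulated DE genes, universe ~2000, odds ratio 10: the planted
  # term's hypergeometric p must fall below 0.05 in >= 90% of seeds.
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 1000 + s, n_mrna = 2000, n_lncrna = 10,
                      n_mirna = 5, de_fraction = 0.04, go_odds_ratio = 10)
    mrna <- sprintf("G%04d", 1:2000)
    labels <- setNames(rep("null", 2010),
                       c(mrna, sprintf("LNC%04d", 1:10)))
    up <- sample(mrna, 40)
    labels[up] <- "up"
    attr(labels, "class_of") <- setNames(
      c(rep("mRNA", 2000), rep("lncRNA", 10)), names(labels))
    truth <- list(de_labels = labels,
                  de_labels_mirna = setNames(rep("null", 5),
                                             sprintf("miR-%03d", 1:5)))
    ann <- simulate_annotations(cfg, truth)
    g2t <- ann$go_annotation
    universe <- unique(g2t$gene)
    term <- ann$truth$planted_enriched_terms
    in_term <- unique(g2t$gene[g2t$term == term])
    de_in <- intersect(up, universe)
    p <- hypergeom_upper(length(intersect(de_in, in_term)),
                         length(in_term), length(de_in), length(universe))
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 0.90 * n_seeds)
})

test_that("bundle write/read round-trips and hashes track the config", {
  cfg <- tiny_config(seed = 23)
  b <- simulate_bundle(cfg)
  d <- withr::local_tempdir()
  manifest <- write_bundle(b, d)
  expect_identical(manifest$seed, cfg$seed)
  expect_identical(manifest$config_hash, config_hash(cfg))
  b2 <- read_bundle(d)
  expect_equal(b2$expression_raw$values, b$expression_raw$values,
               tolerance = 1e-5)
  expect_identical(b2$smallrna$reads, b$smallrna$reads)
  expect_identical(b2$annotations$mirna_loci, b$annotations$mirna_loci)
  expect_identical(b2$truth$planted_mirna_mrna, b$truth$planted_mirna_mrna)
  expect_identical(b2$truth$mirna_true_counts, b$truth$mirna_true_counts)
  expect_identical(
    as.character(b2$truth$de_labels[names(b$truth$de_labels)]),
    as.character(b$truth$de_labels))

  # identical config + seed => byte-identical bundle
  d2 <- withr::local_tempdir()
  write_bundle(simulate_bundle(cfg), d2)
  f <- list.files(d, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d, f))),
                   unname(tools::md5sum(file.path(d2, f))))

  # empty bundle: valid manifest, zero data files
  d3 <- withr::local_tempdir()
  m0 <- write_bundle(list(), d3)
  expect_identical(m0$n_files, 0L)
  expect_true(file.exists(file.path(d3, "manifest.json")))

  # hash changes iff a config field changes
  expect_identical(config_hash(cfg), config_hash(tiny_config(seed = 23)))
  expect_false(config_hash(cfg) ==
                 config_hash(tiny_config(seed = 24)))
  expect_false(config_hash(cfg) ==
                 config_hash(tiny_config(seed = 23, nb_dispersion = 0.3)))
})
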