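test_that("quantile normalization matches the hand-computed definition", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point; a single column is unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)
  m3 <- matrix(c(5, 1, 9), dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(quantile_normalize(m3), m3)

  # ties receive the mean of the reference values at their tied ranks
  mt <- cbind(a = c(1, 1, 2), b = c(1, 2, 3))
  rownames(mt) <- paste0("g", 1:3)
  out <- quantile_normalize(mt)
  expect_equal(unname(out[, 1]), c(1.25, 1.25, 2.5))

  expect_error(quantile_normalize(cbind(c(1, NA))), "finite")
})

test_that("quantile normalization is idempotent with column-identical sorted values", {
  # Tie-free matrices: with ties, averaging reference values at tied ranks
  # necessarily perturbs the column multiset, so exactness is a
  # continuous-data property.
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- sample(5:60, 1); k <- sample(2:8, 1)
      m <- matrix(rnorm(n * k), n,
                  dimnames = list(sprintf("g%d", 1:n), sprintf("s%d", 1:k)))
      out <- quantile_normalize(m)
      sorted <- apply(out, 2, sort)
      expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
      expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
    }
  })
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  withr::with_seed(8, {
    m <- matrix(rnorm(500), 100,
                dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:5)))
    expect_equal(unname(quantile_normalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
  })
})

test_that("probe summarization averages shared probes and drops unmapped ones", {
  v <- rbind(p1 = c(2, 6), p2 = c(4, 8), p3 = c(1, 1))
  colnames(v) <- c("s1", "s2")
  em <- expression_matrix(v, "lncRNA",
                          data.frame(sample = c("s1", "s2"),
                                     group = c("control", "case")))
  pm <- data.frame(probe = c("p1", "p2"), official = c("X", "X"))
  out <- suppressMessages(summarize_probes(em, pm))
  expect_equal(unname(out$values["X", ]), c(3, 7))
  expect_false("p3" %in% rownames(out$values))

  # one-to-one mapping renames without changing values
  pm2 <- data.frame(probe = c("p1", "p2", "p3"),
                    official = c("A", "B", "C"))
  out2 <- summarize_probes(em, pm2)
  expect_equal(unname(out2$values), unname(v))
  expect_identical(rownames(out2$values), c("A", "B", "C"))

  # nothing mapped: empty matrix plus a warning, not an error
  expect_warning(out3 <- summarize_probes(
    em, data.frame(probe = "zz", official = "Q")), "empty")
  expect_identical(nrow(out3$values), 0L)
})

test_that("lncRNA transcript matching enforces the strict 90% overlap rule", {
  off <- data.frame(chrom = "c1", start = c(0, 0), end = c(100, 90),
                    name = c("o_full", "o_90"), score = 0,
                    strand = c("+", "+"))
  arr <- data.frame(chrom = "c1", start = 0, end = 100, name = "t1",
                    score = 0, strand = "+")
  hit <- match_lncrna_ids(arr, off[1, ])
  expect_identical(hit$official, "o_full")
  expect_equal(hit$overlap_fraction, 1.0)

  # exactly 90% is NOT matched ("more than 90%" is strict)
  expect_identical(nrow(match_lncrna_ids(arr, off[2, ])), 0L)

  # largest fraction wins
  cand <- data.frame(chrom = "c1", start = c(0, 0), end = c(95, 99),
                     name = c("o1", "o2"), score = 0, strand = "+")
  expect_identical(match_lncrna_ids(arr, cand)$official, "o2")

  # ties break to the lexicographically smallest official ID
  tie <- data.frame(chrom = "c1", start = c(0, 1), end = c(99, 100),
                    name = c("zz", "aa"), score = 0, strand = "+")
  expect_identical(match_lncrna_ids(arr, tie)$official, "aa")

  # strand and chromosome must agree
  other <- data.frame(chrom = c("c1", "c2"), start = 0, end = 100,
                      name = c("neg", "chr"), score = 0,
                      strand = c("-", "+"))
  expect_identical(nrow(match_lncrna_ids(arr, other)), 0L)

  expect_error(match_lncrna_ids(
    data.frame(chrom = "c1", start = 5, end = 5, name = "z", score = 0,
               strand = "+"), off), "zero-length")
})

test_that("transcript matching agrees with brute-force all-pairs overlap", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n_a <- 80; n_o <- 60
      arr <- data.frame(chrom = sample(c("c1", "c2"), n_a, TRUE),
                        start = sample(0:500, n_a, TRUE),
                        name = sprintf("a%02d", 1:n_a), score = 0,
                        strand = sample(c("+", "-"), n_a, TRUE))
      arr$end <- arr$start + sample(10:120, n_a, TRUE)
      off <- data.frame(chrom = sample(c("c1", "c2"), n_o, TRUE),
                        start = sample(0:500, n_o, TRUE),
                        name = sprintf("o%02d", 1:n_o), score = 0,
                        strand = sample(c("+", "-"), n_o, TRUE))
      off$end <- off$start + sample(10:120, n_o, TRUE)
      got <- match_lncrna_ids(arr, off)
      for (i in seq_len(n_a)) {
        best <- NULL; best_frac <- -1
        for (j in seq_len(n_o)) {
          if (arr$chrom[i] != off$chrom[j] ||
              arr$strand[i] != off$strand[j]) next
          ov <- length(intersect(bases_of(arr$start[i], arr$end[i]),
                                 bases_of(off$start[j], off$end[j])))
          frac <- ov / (arr$end[i] - arr$start[i])
          if (frac > 0.90 &&
              (frac > best_frac ||
                 (frac == best_frac && off$name[j] < best))) {
            best <- off$name[j]; best_frac <- frac
          }
        }
        hit <- got$official[got$probe == arr$name[i]]
        if (is.null(best)) expect_identical(length(hit), 0L)
        else expect_identical(hit, best)
      }
    }
  })
})

test_that("adapter trimming truncates at the first prefix occurrence", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTAC"
  r <- make_reads(c(paste0(insert, adapter), "ACGTACGTACGTACGT",
                    paste0(adapter, "ACGT")))
  out <- trim_adapter(r, adapter)
  expect_identical(out$sequence, c(insert, "ACGTACGTACGTACGT", ""))
  expect_identical(nchar(out$quality), nchar(out$sequence))
  expect_error(trim_adapter(r, ""), "adapter")
})

test_that("QC filter boundaries are inclusive exactly as specified", {
  q20 <- rawToChar(as.raw(20 + 33)); q19 <- rawToChar(as.raw(19 + 33))
  seq20 <- strrep("A", 20)
  # 18/20 = 90% high-quality: passes; 17/20 fails
  q_pass <- paste0(strrep(q20, 18), strrep(q19, 2))
  q_fail <- paste0(strrep(q20, 17), strrep(q19, 3))
  r <- make_reads(c(seq20, seq20), quals = c(q_pass, q_fail))
  out <- filter_reads_qc(r)
  expect_identical(out$reads$id, "r001")
  expect_identical(out$report$count[out$report$reason == "quality"], 1L)

  # length 16 passes, 15 fails
  r2 <- make_reads(c(strrep("A", 16), strrep("A", 15)))
  out2 <- filter_reads_qc(r2)
  expect_identical(out2$reads$sequence, strrep("A", 16))
  expect_identical(out2$report$count[out2$report$reason == "length"], 1L)

  # 1 N in 20 (5%) passes; 2 N (10%) fails
  r3 <- make_reads(c(paste0("N", strrep("A", 19)),
                     paste0("NN", strrep("A", 18))))
  out3 <- filter_reads_qc(r3)
  expect_identical(out3$reads$id, "r001")
  expect_identical(out3$report$count[out3$report$reason == "uncertainty"],
                   1L)

  # failure attribution order: a short, low-quality read counts as length
  r4 <- make_reads(strrep("A", 10), quals = strrep(q19, 10))
  rep4 <- filter_reads_qc(r4)$report
  expect_identical(rep4$count[rep4$reason == "length"], 1L)
  expect_identical(rep4$count[rep4$reason == "quality"], 0L)

  bad <- data.frame(id = "x", sequence = "ACGT", quality = "II")
  expect_error(filter_reads_qc(bad), "x")
})

test_that("contaminant removal is exact-substring, same strand only", {
  ref <- c(tRNA1 = "ACCTGAGATCCAGTGATCGATCGTTACG")
  inside <- substr(ref, 3, 20)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", inside), "")[[1]]),
              collapse = "")
  r <- make_reads(c(unname(ref), inside, "GGGGCCCCAAAATTTT", rc))
  out <- remove_contaminants(r, ref)
  expect_identical(out$sequence, c("GGGGCCCCAAAATTTT", rc))
  expect_warning(out2 <- remove_contaminants(r, character(0)), "empty")
  expect_identical(out2, r)
})

test_that("miRNA counting requires exact equality to a unique mature sequence", {
  mature <- c(`miR-a` = "ACGTACGTACGTACGTAC", `miR-b` = "TTTTCCCCGGGGAAAATT")
  reads <- make_reads(c(rep(mature[["miR-a"]], 3), rep(mature[["miR-b"]], 2),
                        "ACGTACGTACGTACGTACG"))
  tab <- count_mirna(reads, mature)
  expect_identical(unname(tab$counts[, 1]), c(3L, 2L))
  tab0 <- count_mirna(reads[0, ], mature)
  expect_true(all(tab0$counts == 0L))
  expect_error(count_mirna(reads, c(a = "ACGT", b = "ACGT")), "duplicate")
})

test_that("TPM columns sum to one million before pseudo-replacement", {
  counts <- matrix(c(5L, 5L, 0L,
                     3L, 0L, 7L,
                     0L, 0L, 0L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("m1", "m2", "m3"), c("s1", "s2", "s3")))
  tab <- structure(list(mirna_ids = rownames(counts),
                        sample_ids = colnames(counts), counts = counts,
                        tpm = NULL), class = "mirna_count_table")
  out <- compute_tpm(tab)
  # TPM formula: counts [5, 5] against total 10 give 500000 each
  expect_equal(unname(out$tpm["m1", c("s1", "s2")]), c(625000, 1e6))
  expect_equal(unname(out$tpm_unadjusted["m2", ]), c(375000, 0, 1e6))
  # all-zero miRNA is dropped; remaining zeros become the pseudo-value
  expect_false("m3" %in% rownames(out$tpm))
  expect_equal(unname(out$tpm["m2", "s2"]), 0.0001)
  expect_equal(unname(colSums(out$tpm_unadjusted)), rep(1e6, 3),
               tolerance = 1e-6)

  counts2 <- matrix(c(5L, 0L), 1, dimnames = list("m1", c("s1", "bad")))
  tab2 <- structure(list(mirna_ids = "m1", sample_ids = colnames(counts2),
                         counts = counts2, tpm = NULL),
                    class = "mirna_count_table")
  expect_error(compute_tpm(tab2), "bad")
})

test_that("the documented 2-sample TPM example holds", {
  counts <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tab <- structure(list(mirna_ids = c("a", "b"), sample_ids = "s1",
                        counts = counts, tpm = NULL),
                   class = "mirna_count_table")
  out <- compute_tpm(tab)
  expect_equal(unname(out$tpm[, 1]), c(500000, 500000))
})
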