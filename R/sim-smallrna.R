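# Small RNA-seq simulator: mature miRNA references, per-sample FASTQ-style
# read sets with adapter suffixes, negative-binomial true counts, planted
# contaminant copies and constructed QC failures.

adapter_prefix <- function(adapter) substr(adapter, 1L, min(8L, nchar(adapter)))

# A mature sequence is adapter-safe when trimming (first occurrence of the
# adapter's >=8-nt prefix) of mature+adapter returns exactly the mature
# sequence.
adapter_safe <- function(seqs, adapter) {
  pfx <- adapter_prefix(adapter)
  pos <- regexpr(pfx, paste0(seqs, adapter), fixed = TRUE)
  pos == nchar(seqs) + 1L
}

generate_mature_seqs <- function(n, adapter, max_retries = 50L) {
  out <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      s <- random_dna(1, sample(18:24, 1))
      if (adapter_safe(s, adapter) && !(s %in% out)) {
        out <- c(out, s); ok <- TRUE; break
      }
    }
    if (!ok)
      stop2("could not generate a mature sequence avoiding the adapter ",
            "prefix after ", max_retries, " retries")
  }
  out
}

quality_string <- function(len, phred) {
  if (!length(len)) return(character(0))
  phred <- rep_len(phred, length(len))
  chars <- strsplit(rawToChar(as.raw(phred + 33L)), "", fixed = TRUE)[[1]]
  strrep(chars, len)
}

#' Simulate small RNA-seq reads with planted counts, contaminants and QC fails
#'
#' Produces per-sample read sets in which every clean read is one mature
#' miRNA sequence with the 3' adapter appended and uniformly high base
#' qualities. Per-sample per-miRNA clean read counts are drawn
#' NegativeBinomial(group mean, `nb_dispersion`) and recorded as the ground
#' truth count matrix; case-group means are the control means scaled by
#' 2^log2fc for planted DE miRNAs. A fraction of reads copy random substrings
#' of contaminant (rRNA/tRNA/snRNA-like) references, and a fraction are
#' constructed to fail quality control (too short after trimming, low base
#' quality, or N-rich), cycling through the three failure modes.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (named list of per-sample data frames with
#'   columns id, sequence, quality), `mature` (named character vector of
#'   mature miRNA sequences), `contaminants` (named character vector), and
#'   `truth` (de labels, log2 fold changes, `mirna_true_counts`, and the
#'   per-sample planted QC bookkeeping `qc_planted`).
#' @export
simulate_small_rna <- function(config) {
  validate_sim_config(config)
  with_stream(config$seed, "smallrna", {
    n <- config$n_mirna
    mirna_ids <- sprintf("miR-%03d", seq_len(n))
    mature <- setNames(generate_mature_seqs(n, config$adapter), mirna_ids)

    # Contaminant references: must not contain the adapter prefix nor any
    # mature sequence (clean reads must never match a contaminant).
    cont_ids <- sprintf("%s-%d",
                        rep(c("rRNA", "tRNA", "snRNA"),
                            length.out = config$n_contaminants),
                        seq_len(config$n_contaminants))
    contaminants <- character(config$n_contaminants)
    for (i in seq_len(config$n_contaminants)) {
      for (r in 1:50) {
        s <- random_dna(1, 90)
        hit <- grepl(adapter_prefix(config$adapter), s, fixed = TRUE) ||
          any(vapply(mature, function(m) grepl(m, s, fixed = TRUE), TRUE))
        if (!hit) { contaminants[i] <- s; break }
      }
      if (contaminants[i] == "")
        stop2("could not generate contaminant reference ", i)
    }
    names(contaminants) <- cont_ids

    # Down labels are assigned first, mirroring the predominance of
    # downregulated miRNAs in cirrhotic liver, and guaranteeing that any
    # upregulated planted miRNA can be composition-balanced (below).
    labels <- setNames(rep("null", n), mirna_ids)
    n_de <- if (config$de_fraction > 0) max(1L, round(config$de_fraction * n))
            else 0L
    if (n_de > 0) {
      pick <- sample(mirna_ids, n_de)
      labels[pick] <- rep(c("down", "up"), length.out = n_de)
    }
    lfc <- setNames(rep(0, n), mirna_ids)
    de <- labels != "null"
    if (any(de)) {
      mag <- config$min_abs_log2fc + runif(sum(de), 0, 0.5)
      lfc[de] <- ifelse(labels[de] == "up", mag, -mag)
    }

    # Abundance weights are bounded away from zero so that every miRNA is
    # quantifiable at the default sequencing depth; zero-inflated TPM cells
    # otherwise manufacture arbitrarily large fold changes.
    w <- rgamma(n, shape = 2, rate = 1) + 0.5
    # Composition balance: rescale the downregulated miRNAs' abundances so
    # the expected case-group total equals the control total. Relative
    # (TPM) and absolute fold changes then coincide; an unbalanced design
    # would shift every null miRNA's TPM through the library total, which
    # TPM quantitation cannot correct.
    up <- labels == "up"; dn <- labels == "down"
    delta_up <- sum(w[up] * (2^lfc[up] - 1))
    if (delta_up > 0 && any(dn)) {
      w[dn] <- w[dn] * delta_up / sum(w[dn] * (1 - 2^lfc[dn]))
    }
    mean_control <- config$reads_per_sample * w / sum(w)
    mean_case <- mean_control * 2^lfc

    n1 <- config$n_control_srna; n2 <- config$n_case_srna
    samples <- c(sprintf("SRNL%02d", seq_len(n1)),
                 sprintf("SRLC%02d", seq_len(n2)))
    group <- c(rep("control", n1), rep("case", n2))
    counts <- matrix(0L, n, n1 + n2, dimnames = list(mirna_ids, samples))
    for (s in seq_len(n1 + n2)) {
      mu <- if (group[s] == "control") mean_control else mean_case
      counts[, s] <- as.integer(rnbinom(n, mu = mu,
                                        size = 1 / config$nb_dispersion))
    }

    n_cont <- round(config$contaminant_fraction * config$reads_per_sample)
    n_fail <- round(config$fail_fraction * config$reads_per_sample)
    fail_modes <- rep(c("short", "quality", "uncertain"),
                      length.out = n_fail)
    adapter <- config$adapter

    reads <- vector("list", n1 + n2)
    names(reads) <- samples
    qc_planted <- data.frame(sample = samples, n_clean = 0L,
                             n_contaminant = 0L, n_fail_short = 0L,
                             n_fail_quality = 0L, n_fail_uncertain = 0L,
                             stringsAsFactors = FALSE)
    for (s in seq_len(n1 + n2)) {
      clean_seq <- rep(paste0(mature, adapter), counts[, s])
      clean_qual <- quality_string(nchar(clean_seq), rep(40L,
                                                         length(clean_seq)))
      cont_seq <- character(0)
      if (n_cont > 0) {
        idx <- sample(length(contaminants), n_cont, replace = TRUE)
        st <- vapply(idx, function(i)
          sample.int(nchar(contaminants[i]) - 22L + 1L, 1L), 1L)
        cont_seq <- paste0(substr(contaminants[idx], st, st + 21L), adapter)
      }
      cont_qual <- quality_string(nchar(cont_seq), rep(40L, length(cont_seq)))

      fail_seq <- character(n_fail); fail_qual <- character(n_fail)
      if (n_fail > 0) {
        for (j in seq_len(n_fail)) {
          mode <- fail_modes[j]
          if (mode == "short") {
            sq <- paste0(random_dna(1, 10), adapter)
            ql <- quality_string(nchar(sq), 40L)
          } else if (mode == "quality") {
            sq <- paste0(random_dna(1, 20), adapter)
            ql <- quality_string(nchar(sq), 10L)
          } else {
            base <- strsplit(random_dna(1, 20), "")[[1]]
            base[sample(20, 3)] <- "N"
            sq <- paste0(paste(base, collapse = ""), adapter)
            ql <- quality_string(nchar(sq), 40L)
          }
          fail_seq[j] <- sq; fail_qual[j] <- ql
        }
      }

      seqs <- c(clean_seq, cont_seq, fail_seq)
      quals <- c(clean_qual, cont_qual, fail_qual)
      ord <- if (length(seqs)) sample.int(length(seqs)) else integer(0)
      reads[[s]] <- data.frame(
        id = sprintf("%s_read%06d", samples[s], seq_along(ord)),
        sequence = seqs[ord], quality = quals[ord],
        stringsAsFactors = FALSE)
      qc_planted$n_clean[s] <- length(clean_seq)
      qc_planted$n_contaminant[s] <- length(cont_seq)
      qc_planted$n_fail_short[s] <- sum(fail_modes == "short")
      qc_planted$n_fail_quality[s] <- sum(fail_modes == "quality")
      qc_planted$n_fail_uncertain[s] <- sum(fail_modes == "uncertain")
    }

    list(reads = reads, mature = mature, contaminants = contaminants,
         design = data.frame(sample = samples, group = group,
                             stringsAsFactors = FALSE),
         truth = list(de_labels_mirna = labels, true_log2fc_mirna = lfc,
                      mirna_true_counts = counts, qc_planted = qc_planted))
  })
}
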