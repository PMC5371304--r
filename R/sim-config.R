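#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulator in one validated object. The defaults
#' describe the study conditions the generator emulates: an Arraystar-style
#' two-colour microarray cohort (10 normal vs 10 cirrhosis samples; a third,
#' HCC-vs-cirrhosis contrast shares the analyte universe) and a small RNA-seq
#' cohort (9 normal vs 15 cirrhosis). Expression noise follows the conjugate
#' model underlying the moderated t-test: per-analyte variances are drawn from
#' a scaled inverse chi-squared prior with `d0` degrees of freedom and scale
#' `s0_sq`, so that hyperparameter recovery by the differential-expression
#' module is a meaningful benchmark.
#'
#' @param seed Integer seed; all randomness flows from it through named
#'   sub-streams.
#' @param n_mrna,n_lncrna,n_mirna Number of analytes per class.
#' @param n_tf Number of transcription factors in the binding-site universe.
#' @param n_control,n_case Microarray samples per group.
#' @param n_control_srna,n_case_srna Small RNA-seq samples per group
#'   (defaults mirror the 9 + 15 sequencing cohort).
#' @param de_fraction Fraction of analytes per class planted as differentially
#'   expressed (split evenly between up and down).
#' @param min_abs_log2fc Effect-size floor in log2 units for planted DE
#'   analytes.
#' @param d0,s0_sq Prior degrees of freedom (> 0) and prior variance scale
#'   (> 0) of the scaled inverse chi-squared variance prior.
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution.
#' @param genome_length Length in bp of the synthetic genome on which miRNA
#'   loci, binding sites and lncRNA transcripts are placed.
#' @param reads_per_sample Expected clean small-RNA reads per sample.
#' @param adapter 3' adapter (linker) sequence appended to every read.
#' @param nb_dispersion Negative-binomial dispersion of miRNA counts.
#' @param contaminant_fraction,fail_fraction Fractions of
#'   `reads_per_sample` emitted as contaminant copies (rRNA/tRNA/snRNA
#'   substrings) and as constructed QC failures.
#' @param n_contaminants Number of contaminant reference sequences.
#' @param targets_per_mirna,lnc_targets_per_mirna,tfs_per_mirna Planted
#'   regulatory out-degrees per DE miRNA.
#' @param n_go_terms Number of GO terms in the synthetic annotation.
#' @param go_base_rate Per-gene annotation probability of a background term.
#' @param go_odds_ratio Odds ratio by which the planted enriched term is
#'   over-represented among up-regulated DE mRNAs.
#' @param second_contrast_overlap Fraction of the first contrast's DE mRNAs
#'   re-planted as DE in the second (HCC) contrast.
#' @param lncrna_duplicate_probes,lncrna_orphan_probes Number of official
#'   lncRNAs carried by two array probes, and of array probes matching no
#'   official transcript (exercising probe averaging and omission).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mrna = 2000L, n_lncrna = 300L, n_mirna = 60L,
                       n_tf = 10L,
                       n_control = 10L, n_case = 10L,
                       n_control_srna = 9L, n_case_srna = 15L,
                       de_fraction = 0.1, min_abs_log2fc = 2,
                       d0 = 4, s0_sq = 0.05,
                       baseline_mean = 8, baseline_sd = 1.5,
                       genome_length = 5e6,
                       reads_per_sample = 100000L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       nb_dispersion = 0.2,
                       contaminant_fraction = 0.02,
                       fail_fraction = 0.05,
                       n_contaminants = 5L,
                       targets_per_mirna = 8L,
                       lnc_targets_per_mirna = 2L,
                       tfs_per_mirna = 2L,
                       n_go_terms = 25L,
                       go_base_rate = 0.05,
                       go_odds_ratio = 10,
                       second_contrast_overlap = 0.5,
                       lncrna_duplicate_probes = 5L,
                       lncrna_orphan_probes = 5L) {
  cfg <- list(seed = as.integer(seed),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna), n_tf = as.integer(n_tf),
              n_control = as.integer(n_control), n_case = as.integer(n_case),
              n_control_srna = as.integer(n_control_srna),
              n_case_srna = as.integer(n_case_srna),
              de_fraction = de_fraction, min_abs_log2fc = min_abs_log2fc,
              d0 = d0, s0_sq = s0_sq,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              genome_length = genome_length,
              reads_per_sample = as.integer(reads_per_sample),
              adapter = toupper(adapter),
              nb_dispersion = nb_dispersion,
              contaminant_fraction = contaminant_fraction,
              fail_fraction = fail_fraction,
              n_contaminants = as.integer(n_contaminants),
              targets_per_mirna = as.integer(targets_per_mirna),
              lnc_targets_per_mirna = as.integer(lnc_targets_per_mirna),
              tfs_per_mirna = as.integer(tfs_per_mirna),
              n_go_terms = as.integer(n_go_terms),
              go_base_rate = go_base_rate,
              go_odds_ratio = go_odds_ratio,
              second_contrast_overlap = second_contrast_overlap,
              lncrna_duplicate_probes = as.integer(lncrna_duplicate_probes),
              lncrna_orphan_probes = as.integer(lncrna_orphan_probes))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_scalar_number(cfg$seed, "seed", integer = TRUE)
  for (f in c("n_mrna", "n_lncrna", "n_mirna", "n_tf", "n_control", "n_case",
              "n_control_srna", "n_case_srna", "n_contaminants",
              "targets_per_mirna", "lnc_targets_per_mirna", "n_go_terms"))
    check_scalar_number(cfg[[f]], f, lower = 1, integer = TRUE)
  check_scalar_number(cfg$tfs_per_mirna, "tfs_per_mirna", lower = 0,
                      integer = TRUE)
  check_scalar_number(cfg$reads_per_sample, "reads_per_sample", lower = 0,
                      integer = TRUE)
  check_scalar_number(cfg$de_fraction, "de_fraction", lower = 0, upper = 1)
  check_scalar_number(cfg$min_abs_log2fc, "min_abs_log2fc", lower = 0)
  check_scalar_number(cfg$d0, "d0", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$s0_sq, "s0_sq", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$baseline_sd, "baseline_sd", lower = 0)
  check_scalar_number(cfg$genome_length, "genome_length", lower = 1)
  check_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(cfg$contaminant_fraction, "contaminant_fraction",
                      lower = 0, upper = 1)
  check_scalar_number(cfg$fail_fraction, "fail_fraction", lower = 0, upper = 1)
  check_scalar_number(cfg$go_base_rate, "go_base_rate", lower = 0, upper = 1)
  check_scalar_number(cfg$go_odds_ratio, "go_odds_ratio", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(cfg$second_contrast_overlap, "second_contrast_overlap",
                      lower = 0, upper = 1)
  if (!is.character(cfg$adapter) || length(cfg$adapter) != 1L ||
      nchar(cfg$adapter) < 1L || grepl("[^ACGT]", cfg$adapter))
    stop2("'adapter' must be a non-empty ACGT string")
  # When de_fraction > 0 the simulators guarantee >= 1 planted DE analyte
  # per class (the planted count is max(1, round(de_fraction * n))).
  invisible(cfg)
}

#' Hash of the canonical serialization of a simulation config
#'
#' Changes iff any configuration field changes.
#' @param config A [sim_config()] object.
#' @return MD5 hex digest string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  md5_of_string(as.character(canonical_json(x)))
}
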