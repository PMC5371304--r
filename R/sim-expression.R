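#' Simulate a log2 expression matrix with planted differential expression
#'
#' Generates an mRNA + lncRNA microarray-style matrix under the conjugate
#' model assumed by the moderated t-test: per-analyte variances
#' \eqn{\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}}, values
#' \eqn{x_{gs} = \mu_g + \beta_g 1[s \in case] + \epsilon_{gs}} with
#' \eqn{\epsilon_{gs} \sim N(0, \sigma_g^2)}. Planted DE analytes receive
#' \eqn{|\beta_g| \ge} `min_abs_log2fc` with random sign; null analytes have
#' \eqn{\beta_g = 0}.
#'
#' @param config A [sim_config()].
#' @param forced_de Optional named character vector (values "up"/"down")
#'   forcing the DE label of specific analytes; used to plant an overlapping
#'   DE set for a second contrast.
#' @param classes Which analyte classes to simulate (subset of
#'   c("mRNA", "lncRNA")).
#' @param sample_prefix Length-2 prefixes for control and case sample IDs.
#' @param stream RNG sub-stream name.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (list with `de_labels` and `true_log2fc`, both named by analyte).
#' @export
simulate_expression <- function(config, forced_de = NULL,
                                classes = c("mRNA", "lncRNA"),
                                sample_prefix = c("NL", "LC"),
                                stream = "expression") {
  validate_sim_config(config)
  with_stream(config$seed, stream, {
    ids <- list()
    if ("mRNA" %in% classes)
      ids$mRNA <- sprintf("G%04d", seq_len(config$n_mrna))
    if ("lncRNA" %in% classes)
      ids$lncRNA <- sprintf("LNC%04d", seq_len(config$n_lncrna))
    all_ids <- unlist(ids, use.names = FALSE)
    cls <- rep(names(ids), lengths(ids))
    n <- length(all_ids)

    labels <- setNames(rep("null", n), all_ids)
    if (!is.null(forced_de)) {
      unknown <- setdiff(names(forced_de), all_ids)
      if (length(unknown)) stop2("forced_de names outside analyte universe")
      labels[names(forced_de)] <- forced_de
    }
    for (k in names(ids)) {
      in_class <- names(labels)[cls == k]
      n_de <- if (config$de_fraction > 0)
        max(1L, round(config$de_fraction * length(in_class))) else 0L
      already <- sum(labels[in_class] != "null")
      extra <- n_de - already
      if (extra > 0) {
        pool <- in_class[labels[in_class] == "null"]
        pick <- sample(pool, min(extra, length(pool)))
        labels[pick] <- rep(c("up", "down"), length.out = length(pick))
      }
    }

    # Planted effect sizes lie in a bounded band just above the floor;
    # an unbounded effect tail would push planted analytes beyond the null
    # intensity range, where rank-based normalization distorts fold changes.
    lfc <- setNames(rep(0, n), all_ids)
    de <- labels != "null"
    if (any(de)) {
      mag <- config$min_abs_log2fc + runif(sum(de), 0, 0.5)
      lfc[de] <- ifelse(labels[de] == "up", mag, -mag)
    }

    # Null baselines span the full intensity distribution; planted DE
    # analytes draw baselines from the central region (truncated normal,
    # +- 1 sd) so planted effects are not confounded with array floor or
    # ceiling saturation, which rank-based normalization cannot undo at
    # the extreme quantiles.
    mu <- rnorm(n, config$baseline_mean, config$baseline_sd)
    if (any(de)) {
      u <- runif(sum(de), pnorm(-1), pnorm(1))
      mu[de] <- config$baseline_mean + config$baseline_sd * qnorm(u)
    }
    sigma2 <- config$s0_sq * config$d0 / rchisq(n, df = config$d0)
    n1 <- config$n_control; n2 <- config$n_case
    samples <- c(sprintf("%s%02d", sample_prefix[1], seq_len(n1)),
                 sprintf("%s%02d", sample_prefix[2], seq_len(n2)))
    group <- c(rep("control", n1), rep("case", n2))
    eff <- outer(lfc, as.numeric(group == "case"))
    vals <- mu + eff +
      matrix(rnorm(n * (n1 + n2)), n, n1 + n2) * sqrt(sigma2)
    dimnames(vals) <- list(all_ids, samples)

    em <- expression_matrix(vals, cls,
                            data.frame(sample = samples, group = group,
                                       stringsAsFactors = FALSE))
    list(matrix = em,
         truth = list(de_labels = labels, true_log2fc = lfc))
  })
}
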