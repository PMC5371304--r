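# Moderated-t differential expression with BH FDR, threshold policies and
# cross-contrast overlap.

#' Invert the trigamma function
#'
#' Newton iteration solving trigamma(x) = y for x > 0; used by the
#' moment-matching hyperparameter estimator.
#' @param y Positive numeric vector.
#' @return x with trigamma(x) = y.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(all(is.finite(y)), all(y > 0))
  x <- ifelse(y > 1e7, 1 / sqrt(y), ifelse(y < 1e-6, 1 / y, 0.5 + 1 / y))
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x, na.rm = TRUE) < 1e-10) break
  }
  x
}

# Moment-matching estimate of the scaled inverse chi-squared prior
# (d0, s0^2) from observed residual variances s2 on d df, via the
# digamma/trigamma identities for log chi-squared moments.
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2 || var(log(s2[ok])) <= 0)
    return(list(d0 = 0, s0_sq = NA_real_, degenerate = TRUE))
  z <- log(s2[ok])
  emean <- mean(z) - digamma(d / 2) + log(d / 2)
  evar <- var(z) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq, degenerate = FALSE)
}

#' Unpaired moderated t-test
#'
#' Per analyte, the pooled two-sample residual variance \eqn{s_g^2} on
#' \eqn{d_g = n_1 + n_2 - 2} df is shrunk toward an empirical-Bayes prior:
#' hyperparameters \eqn{(d_0, s_0^2)} are estimated by matching moments of
#' \eqn{\log s_g^2} through digamma/trigamma relations, the posterior
#' variance is \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)},
#' and \eqn{t_g = \mathrm{log2fc}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})}
#' is referred to a t distribution on \eqn{d_0 + d_g} df (normal limit when
#' the estimated \eqn{d_0} is infinite).
#'
#' @param em An [expression_matrix()] (log2 scale; miRNA matrices enter as
#'   log2 TPM) or a plain matrix.
#' @param group Group labels over columns, exactly two levels; the second
#'   level of `factor(group)` is the case group unless the labels are
#'   "control"/"case".
#' @param prior_df Optional override of the prior degrees of freedom:
#'   0 gives the classical pooled t-test, Inf the normal-theory limit.
#' @return Data frame (analyte_id, mean_control, mean_case, log2fc, t_mod,
#'   p, df_total) with attributes `d0` and `s0_sq` (the estimated or forced
#'   hyperparameters).
#' @export
moderated_t <- function(em, group = NULL, prior_df = NULL) {
  m <- if (inherits(em, "expr_matrix")) em$values else em
  if (is.null(group) && inherits(em, "expr_matrix"))
    group <- em$design$group
  if (is.null(group)) stop2("'group' labels are required")
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L) stop2("exactly two groups are required")
  if (all(sort(lev) == c("case", "control"))) lev <- c("control", "case")
  n1 <- sum(group == lev[1]); n2 <- sum(group == lev[2])
  if (n1 < 2 || n2 < 2) stop2("each group needs at least 2 samples")
  x1 <- m[, group == lev[1], drop = FALSE]
  x2 <- m[, group == lev[2], drop = FALSE]
  mean1 <- rowMeans(x1); mean2 <- rowMeans(x2)
  ss <- rowSums((x1 - mean1)^2) + rowSums((x2 - mean2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  lfc <- mean2 - mean1

  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, d)
    if (prior$degenerate) {
      warning("degenerate variance moment matching; ",
              "falling back to the unmoderated t-test")
      prior <- list(d0 = 0, s0_sq = NA_real_)
    }
  } else {
    check_scalar_number(prior_df, "prior_df", lower = 0)
    prior <- list(d0 = prior_df,
                  s0_sq = if (prior_df > 0)
                    estimate_variance_prior(s2, d)$s0_sq else NA_real_)
    if (prior_df > 0 && (!is.finite(prior$s0_sq) || is.na(prior$s0_sq)))
      prior$s0_sq <- mean(s2)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(d, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- rep(d0 + d, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(t_mod)),
              2 * pt(-abs(t_mod), df = df_total))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(analyte_id = rownames(m) %||% seq_along(lfc),
                    mean_control = mean1, mean_case = mean2,
                    log2fc = lfc, t_mod = t_mod, p = p,
                    df_total = df_total, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' input order. Implemented literally from that definition (a running
#' minimum over \eqn{p_{(j)} m / j} from the largest rank down), so it is
#' bitwise reproducible against the definition; `stats::p.adjust` agrees
#' up to floating-point operation order.
#' @param p Numeric vector of p-values in (0, 1].
#' @return FDR-adjusted values in input order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop2("p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 1L) return(pmin(1, p))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

#' Threshold policy for significance calls
#'
#' @param stat_field "fdr" (mRNA/lncRNA regime) or "p" (miRNA regime).
#' @param alpha Strict significance threshold on the chosen statistic.
#' @param fc_up,fc_down Inclusive fold-change gates; `fc_up` must equal
#'   `1/fc_down`.
#' @return List of class `threshold_policy`.
#' @export
threshold_policy <- function(stat_field = c("fdr", "p"), alpha = 0.05,
                             fc_up = 2, fc_down = 0.5) {
  stat_field <- match.arg(stat_field)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(fc_up, "fc_up", lower = 1)
  if (abs(fc_up - 1 / fc_down) > 1e-12)
    stop2("fc_up must equal 1/fc_down")
  structure(list(stat_field = stat_field, alpha = alpha, fc_up = fc_up,
                 fc_down = fc_down), class = "threshold_policy")
}

#' Call differential expression under a threshold policy
#'
#' Significant iff the chosen statistic is strictly below `alpha` AND the
#' fold change passes an inclusive gate (>= `fc_up` or <= `fc_down`).
#' Direction is up for fold change >= `fc_up`, down for <= `fc_down`, none
#' otherwise.
#'
#' @param res Result of [moderated_t()].
#' @param policy A [threshold_policy()].
#' @param analyte_class Optional per-analyte class labels to carry through.
#' @return `de_result` data frame adding fold_change, fdr, direction and
#'   significant columns.
#' @export
call_de <- function(res, policy = threshold_policy(), analyte_class = NULL) {
  stopifnot(is.data.frame(res), inherits(policy, "threshold_policy"))
  out <- res
  out$fold_change <- 2^out$log2fc
  out$fdr <- adjust_bh(out$p)
  stat <- if (policy$stat_field == "fdr") out$fdr else out$p
  fc_pass <- out$fold_change >= policy$fc_up |
    out$fold_change <= policy$fc_down
  out$direction <- ifelse(out$fold_change >= policy$fc_up, "up",
                          ifelse(out$fold_change <= policy$fc_down,
                                 "down", "none"))
  out$significant <- stat < policy$alpha & fc_pass
  if (!is.null(analyte_class))
    out$class <- unname(analyte_class[out$analyte_id])
  attr(out, "policy") <- policy
  class(out) <- c("de_result", "data.frame")
  out
}

#' Moderated-t differential expression in one call
#'
#' Convenience wrapper: [moderated_t()], [adjust_bh()] and [call_de()].
#' @inheritParams moderated_t
#' @inheritParams call_de
#' @return A `de_result` data frame.
#' @export
de_table <- function(em, group = NULL, policy = threshold_policy(),
                     prior_df = NULL) {
  res <- moderated_t(em, group, prior_df = prior_df)
  cls <- if (inherits(em, "expr_matrix")) em$analyte_class else NULL
  out <- call_de(res, policy, analyte_class = cls)
  attr(out, "d0") <- attr(res, "d0")
  attr(out, "s0_sq") <- attr(res, "s0_sq")
  out
}

de_significant <- function(de) de$analyte_id[de$significant]

de_direction <- function(de) {
  setNames(de$direction, de$analyte_id)
}

#' Overlap two differential-expression result sets
#'
#' Intersects the significant calls of two contrasts and reports each
#' side's exclusive set plus the per-overlapping-gene direction pair.
#'
#' @param a,b `de_result` data frames sharing an ID namespace.
#' @return List with `overlap` (analyte, direction_a, direction_b),
#'   `only_a`, `only_b`.
#' @export
overlap_de_sets <- function(a, b) {
  sa <- de_significant(a); sb <- de_significant(b)
  common <- sort(intersect(sa, sb))
  da <- de_direction(a); db <- de_direction(b)
  list(overlap = data.frame(analyte = common,
                            direction_a = unname(da[common]),
                            direction_b = unname(db[common]),
                            stringsAsFactors = FALSE),
       only_a = sort(setdiff(sa, sb)),
       only_b = sort(setdiff(sb, sa)))
}
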