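# Independent from-definition oracles used to check the implementation.
# These deliberately use the most literal (often slowest) formulation.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by explicit log-space PMF summation.
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (length(j) == 0) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Classical pooled-variance two-sample t and its p-value.
classical_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Per-base interval intersection on a small genome.
bases_of <- function(start, end) if (end <= start) integer(0) else start:(end - 1L)
overlaps_brute <- function(s1, e1, s2, e2) {
  length(intersect(bases_of(s1, e1), bases_of(s2, e2))) > 0
}

# Quadratic common-neighbor ceRNA oracle over a bipartite edge list.
cerna_oracle <- function(edges) {
  targets <- sort(unique(edges$target))
  out <- list()
  for (i in seq_along(targets)) {
    for (j in seq_len(i - 1L)) {
      a <- targets[j]; b <- targets[i]
      shared <- intersect(edges$mirna[edges$target == a],
                          edges$mirna[edges$target == b])
      if (length(shared))
        out[[length(out) + 1L]] <- data.frame(
          gene_a = min(a, b), gene_b = max(a, b),
          shared_mirnas = paste(sort(unique(shared)), collapse = ";"),
          n_shared = length(unique(shared)), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      shared_mirnas = character(0), n_shared = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force node degree from an edge data frame.
degree_oracle <- function(edges, ids) {
  vapply(ids, function(v) sum(edges$from == v) + sum(edges$to == v), 0L)
}

# Compact edge-set comparison.
edge_key <- function(df) sort(do.call(paste, c(df, sep = "|")))

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_mrna = 300L, n_lncrna = 60L, n_mirna = 15L,
               n_control_srna = 5L, n_case_srna = 5L,
               reads_per_sample = 1000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

make_reads <- function(seqs, quals = NULL, phred = 40L) {
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(L)
      paste(rep(rawToChar(as.raw(phred + 33L)), L), collapse = ""), "")
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}
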