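---
title: "Methods: coding/non-coding regulatory network analysis of liver cirrhosis"
author: "cirrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding/non-coding regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cirrnet re-implements, as a tested and fully seeded workflow, a
coding/non-coding gene-regulatory-network analysis of liver cirrhosis and
its progression to hepatocellular carcinoma (HCC): differential expression
of mRNAs, lncRNAs and miRNAs, TF–miRNA–mRNA and lncRNA–miRNA–mRNA network
construction, competing-endogenous-RNA (ceRNA) inference with
protein–protein-interaction overlay and immune-response flagging,
hypergeometric GO enrichment, and a two-contrast overlap analysis. The
original study ran on two GEO cohorts and half a dozen external databases;
this package replaces those inputs with a synthetic-data generator that
plants known differential expression, known regulatory edges and a known
enriched GO term, so that every stage can be held to a recovery contract.

# The statistical model

## Expression and the moderated t-test

Microarray intensities are modeled on the log2 scale as

$$x_{gs} = \mu_g + \beta_g\,\mathbf{1}[s \in \text{case}] + \varepsilon_{gs},
\qquad \varepsilon_{gs} \sim N(0, \sigma_g^2),
\qquad \sigma_g^2 \sim \frac{d_0 s_0^2}{\chi^2_{d_0}},$$

the conjugate scaled-inverse-chi-squared variance prior that underlies the
empirical-Bayes moderated t-test. Per analyte the pooled two-sample
residual variance $s_g^2$ on $d_g = n_1+n_2-2$ degrees of freedom is shrunk
toward the prior,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with two-sided p-values from a t distribution on $d_0 + d_g$ df. The
hyperparameters $(d_0, s_0^2)$ are estimated by matching the moments of
$\log s_g^2$ through the digamma/trigamma identities for log-chi-squared
variables; an infinite estimated $d_0$ falls back to the normal limit, and
a degenerate variance structure (all $s_g^2$ equal) falls back to the
classical unmoderated t with a warning. Setting `prior_df = 0` recovers
the classical pooled t exactly, which is both a unit-test anchor and an
escape hatch. The implementation is cross-checked against limma in the
test suite but does not call it: the module contract requires forcing
$d_0$ and exposing the estimated hyperparameters.

```{r}
library(cirrnet)
res <- moderated_t(em, group = c(rep("control", 10), rep("case", 10)))
attr(res, "d0"); attr(res, "s0_sq")
```

## Significance policies

Two threshold regimes are used, both with strict significance and
inclusive fold-change gates:

* mRNA/lncRNA: BH-adjusted FDR $< 0.05$ and fold change $\ge 2$ or
  $\le 0.5$;
* miRNA: raw moderated-t $p < 0.05$ with the same fold-change gate (the
  FDR gate yields nothing at small-RNA power on this design; BH values are
  still computed and reported).

Fold change is $2^{\Delta}$ with $\Delta$ the difference of group means of
log2 values, so the gate is equivalent to $|\Delta| \ge 1$. BH adjustment
is implemented literally from the step-up definition
($q_{(i)} = \min_{j\ge i} p_{(j)} m / j$, capped at 1) so it is bitwise
reproducible against a from-definition oracle; `stats::p.adjust` agrees up
to floating-point operation order.

## Preprocessing

*Quantile normalization* replaces each column by the cross-sample means of
the sorted columns; ties receive the mean of the reference values at their
tied ranks. On tie-free data the operation is exactly idempotent and
leaves every column with identical sorted values; column-specific tie
patterns necessarily perturb the tied cells, so the exactness claims are
asserted on continuous data.

*lncRNA identifier harmonization*: an array transcript maps to an official
transcript when both share chromosome and strand and the overlap exceeds
90% of the **array** transcript's length (the matching direction is
array-to-official, which fixes the denominator the source text leaves
open); the largest overlap fraction wins, ties break to the
lexicographically smallest official ID, and the bound is strict. Probes
mapping to one official ID are averaged; unmatched probes are omitted.
Coordinates are 0-based half-open (BED convention) throughout the package.

*Small-RNA processing*: reads are truncated at the first exact occurrence
of the adapter's 8-nt prefix; QC requires length $\ge 16$ nt, Phred
$\ge 20$ on at least 90% of bases, and at most 5% uncertain (N) bases,
with failures attributed in the fixed order length, quality, uncertainty.
Contaminant removal and miRNA counting are exact, same-strand matches
(a read is a contaminant iff it is a substring of an rRNA/tRNA/snRNA
reference; a read counts for a miRNA iff it equals the mature sequence) —
the study used heuristic aligners whose tolerances are unreported, and
exactness keeps every test bit-stable. TPM is
$\text{count} \times 10^6 / \text{library total}$; miRNAs with zero counts
in all samples are dropped, then remaining zero cells are set to 0.0001 so
log-scale differential analysis is defined.

## Networks

The promoter window spans 1500 bp upstream to 500 bp downstream of the
strand-aware TSS, downstream including the TSS base: `[tss-1500, tss+500)`
on the plus strand and its per-base mirror `[tss-499, tss+1501)` on the
minus strand, clamped at zero. A TF–miRNA pair requires at least 1 bp of
overlap between a binding site and a DE miRNA's promoter window on the
same chromosome; site strand is ignored (ChIP signals are unstranded), and
TFs are not required to be differentially expressed (a
`restrict_de_tfs` flag provides the stricter reading). miRNA–mRNA and
miRNA–lncRNA pairs are target-table rows with both endpoints DE, with no
constraint on regulatory direction — required downstream, because ceRNA
partners respond in the same direction.

ceRNA inference: for each miRNA with DE-target set $S$, all
$\binom{|S|}{2}$ unordered pairs are ceRNA pairs; pairs induced by several
miRNAs merge with the union of shared miRNAs. PPI support is an attribute,
not a filter (an optional strict mode drops unsupported pairs): a pair is
supported when the PPI table contains it with at least one whitelisted
evidence channel (experiments, textmining, coexpression, database) and at
least one DE endpoint. A gene is immune-related when annotated to at least
one immune-response GO term; a ceRNA edge is immune when both endpoints
are. The immune subnetwork retains the immune DE mRNAs, miRNAs with an
edge to a retained mRNA, and TFs/lncRNAs with an edge to a retained miRNA.

Node attributes follow the field's display conventions: degree (recomputed
from the final edge set) and enrichment score $-\log_{10} p$ with p floored
at $10^{-300}$. Exports (SIF, attribute TSVs, GraphML) are canonically
sorted, so identical inputs give byte-identical files.

## Enrichment

GO enrichment is the hypergeometric upper tail
$P(X \ge k)$ for $k$ DE genes in a term of $K$ universe genes, $n$ DE
genes, universe $N$, computed in log space (`phyper`); BH adjustment runs
across exactly the tested terms (universe genes with at least one
annotation; terms with $K \ge 2$ and $k \ge 1$). Term direction is the
strict majority of DE member directions, else "mixed". The significance
gate defaults to FDR $< 0.05$ (the source's stray "FDR\<0.5" is treated as
a typo; both the gate statistic and alpha are configurable).

# The synthetic-data generator

The generator emulates the study's structure: a 10+10 microarray contrast
(cirrhosis vs normal) carrying mRNAs and probe-level lncRNAs, a second
10+10 contrast (HCC) on the same analyte universe with a partially
overlapping planted DE set (fraction 0.5 by default), a 9+15 small RNA-seq
cohort, and every annotation resource, all derived from one seed through
named sub-streams, so identical configurations are byte-identical.

Design choices that matter, and why:

* **Conjugate noise.** Expression noise follows exactly the variance prior
  the moderated t assumes, making hyperparameter recovery a meaningful
  benchmark (estimated $(d_0, s_0^2)$ recover the truth within a few
  percent at 20000 analytes).
* **Bounded planted effects on well-measured analytes.** Planted
  $|\beta_g|$ is drawn uniformly from
  `[min_abs_log2fc, min_abs_log2fc + 0.5]`, and planted analytes take
  baselines from the central $\pm 1$ sd of the intensity distribution
  (truncated normal). Both bounds exist because quantile normalization is
  rank-based: effects that push planted analytes beyond the null intensity
  range displace the ranks of extreme-tail null genes, where reference
  spacing is widest, and the displacement can cross the fold-change gate.
  Planting inside the bulk keeps normalization near-faithful for planted
  and null analytes alike — the standard "avoid floor/ceiling saturation"
  benchmark practice.
* **Quantifiable, composition-balanced miRNAs.** Abundance weights are
  Gamma(2)-distributed plus a floor of 0.5 (relative units), so no miRNA
  is sequenced to death and the 0.0001 pseudo-TPM never dominates a fold
  change. Downregulated labels are assigned first (downregulation
  dominates in cirrhotic liver), and the downregulated miRNAs' abundances
  are rescaled so the expected case-group library total equals the control
  total. TPM is a relative measure: without this balance, one abundant
  upregulated miRNA deflates every other miRNA's TPM through the library
  total, producing systematic spurious "down" calls that no TPM-based
  pipeline can distinguish from real ones.
* **Recoverable annotations.** Every planted TF–miRNA edge gets a binding
  site placed inside the promoter window; planted negatives get sites at
  least 10 kb from any window, making intersection decisions unambiguous.
  Target tables contain all planted edges plus decoys whose endpoints are
  not DE (so DE gating must remove exactly the decoys). The planted GO
  term ("immune response") is over-represented at a configurable odds
  ratio (default 10 over a base annotation rate of 0.05) among mRNAs
  upregulated in cirrhosis and downregulated in HCC — planting both the
  enrichment and the cross-contrast direction flip the overlap analysis
  looks for.
* **Constructed QC failures.** A configurable fraction of reads fails QC
  by construction, cycling through too-short, low-quality and N-rich
  modes, and a fraction copies contaminant substrings; the generator
  records per-sample bookkeeping so the filter's survivor count has an
  exact expected value.

What the generator does **not** emulate: probe-level microarray signal
(RMA background correction is out of scope; pre-summarized intensities are
the input), sequencing error models beyond the constructed failures,
isomiRs, GO DAG structure (terms are flat sets), and database
version drift. Passing the recovery tests therefore demonstrates that the
pipeline's logic is faithful — not that these thresholds would reproduce
any particular study's counts on real data, which depend on the cohorts
and database versions used.

# Numerical and policy choices

* Significance thresholds are strict (`< 0.05`); fold-change gates are
  inclusive (`>= 2`, `<= 0.5`), following the stated rules literally.
* "Base uncertainty" is read as the fraction of N calls.
* The p-value floor for display scores is $10^{-300}$; p-values from the
  t distribution are floored at the smallest positive double.
* The moment-matching trigamma inverse uses Newton iteration with the
  asymptotic starts $1/\sqrt y$ (large $y$) and $1/y$ (small $y$).
* Table writers render doubles at six significant digits with `\n`
  endings and canonical row order; run manifests record config hash, row
  counts and output checksums, and deliberately no wall-clock timestamps,
  so re-running a seed reproduces the result tree byte for byte.
* Ties: quantile-normalization ties average reference values at tied
  ranks; transcript-matching ties break to the smallest official ID;
  enrichment ties sort by term ID.

# Problem sizes used by the tests

The test and acceptance workloads run the full pipeline on bundles of 1200
mRNAs, 150 lncRNAs, 30 miRNAs and 6000 reads per small-RNA library at the
study's sample sizes, with planted $|\log_2 \text{FC}| \ge 3$
("well-separated" effects, where differential-expression calls are
essentially error-free and the planted structure must be recovered
exactly, 100 seeds for the top-ranked-term rate); calibration studies
(type-I error, FDR control, hyperparameter recovery) use 20000 analytes at
10+10 samples. The generator's own defaults are larger (2000 mRNAs,
100000 reads per library) and drive the `analysis/` scripts.

# Limitations

* TPM compositionality is inherited from the quantified method, not
  corrected; the generator balances planted effects rather than the
  pipeline correcting totals.
* Exact-match counting understates abundance when reads carry errors; the
  generator emits error-free reads.
* The enrichment universe is "annotated genes on the platform"; DAVID-like
  tools make other choices, and absolute p-values shift with the universe.
* The two contrasts are simulated as independent cohorts sharing planted
  labels; the study's second contrast reused the cirrhosis arrays, which
  induces correlations this generator does not model.
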