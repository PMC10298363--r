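---
title: "Quantifying isoform switches: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isoform switches: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A gene usually produces several transcript isoforms. The *usage* (isoform
fraction) of transcript $t$ in sample $s$ is

$$ u_{ts} = \frac{x_{ts}}{\sum_{t' \in g(t)} x_{t's}}, $$

where $x_{ts}$ is the transcript's expression in TPM and the sum runs over
all transcripts of the parent gene $g(t)$. Where the gene is unexpressed
(denominator 0) the usage of all its transcripts is set to 0, so for each
(gene, sample) the usages sum to exactly 1 or are all zero.

An *isoform switch* between a normal and a cancer condition is a pair of
transcripts of one gene in which one transcript is significantly up-used
and the other significantly down-used. With
$\Delta IF_t = \bar u_t^{cancer} - \bar u_t^{normal}$ (means taken over
per-sample usages within condition), transcript $t$ is up-used when
$\Delta IF_t > \delta$ at adjusted significance $\alpha$, and down-used
when $\Delta IF_t < -\delta$. Within each (gene, cohort), all combinations
of up-used and down-used transcripts form switches; the up-used member is
called the *cancer transcript* and the down-used member the *normal
transcript* (the naming follows usage, never expression). One transcript
can take part in several switches.

Usage is a ratio, so a transcript's usage can change without its own
expression changing at all. The package therefore classifies each switch
by the *concordance* of its transcripts' expression changes with their
usage changes, using per-transcript differential expression calls (by
adjusted significance only — fold-change magnitude never enters the call)
and the sign of the log2 fold change:

| class | cancer tx expression | normal tx expression |
|---|---|---|
| `concordant` | DE, up | DE, down |
| `reverse` | DE, down | DE, up |
| `both_down` | DE, down | DE, down |
| `both_up` | DE, up | DE, up |
| `cancer_not_de` | not DE | DE |
| `normal_not_de` | DE | not DE |
| `both_not_de` | not DE | not DE |

`both_not_de` cannot occur in expectation when a genuine usage shift is
present — if neither transcript changes expression, their usages cannot
move in opposite directions — and `reverse` is not realizable by a usage
shift either; both classes are monitored empirically and logged rather
than forbidden.

## Characteristic frequencies and scores

Independent of the testing machinery, each switch is scored by how often
the pair actually swaps its order of prevalence across samples:

* $f_{cancer}$ — the proportion of cancer samples in which the cancer
  transcript has strictly higher expression than the normal transcript;
* $f_{normal}$ — the proportion of normal samples with the reverse order;
* the *combined frequency* $f_{cancer} \cdot f_{normal}$;
* the *legacy score* $f_{cancer} + f_{normal} - 1$.

The product is preferred because the sum is degenerate: frequencies
$(1, 0)$ — one transcript always ahead, i.e. no actual swapping — and
$(0.5, 0.5)$ both give a legacy score of 0, while their combined
frequencies are 0 and 0.25. A tie within a sample (typically both values
zero) counts toward neither frequency: the definition requires *strictly
higher* expression. Because both transcripts share the gene's positive
denominator, the frequencies are identical whether computed from TPM or
from usage whenever the gene is expressed in every sample; the
implementation uses TPM and documents the zero-expression edge case.

## Statistical testing

The built-in two-group test for both usage and expression is the
Mann-Whitney rank-sum test, applied per transcript to per-sample usages
(DTU) and to $\log_2(\mathrm{TPM} + 0.01)$ (DTE). Raw p-values from all
cohorts are pooled and adjusted once with the Benjamini-Hochberg step-up
procedure, separately for the usage and expression analyses; significance
means adjusted $p < \alpha$.

Two implementation details matter:

* **Small samples.** For combined $n \le 20$ the p-value is computed by
  exhaustive enumeration of all $\binom{n+m}{n}$ group assignments of the
  observed midranks, which handles ties exactly.
* **Calibration at scale.** For larger samples the *mid-p* value is
  reported — the exact discrete tail with half the probability of the
  observed statistic (tie-free groups under 50), or the tie-corrected
  normal approximation without continuity correction otherwise. The
  classical "at least as extreme" convention is conservative for discrete
  statistics: with 25 samples per group the rank-sum support makes pooled
  null p-values detectably non-uniform (Kolmogorov-Smirnov distance
  around 0.016 even for continuous data), which distorts a global FDR
  adjustment over tens of thousands of tests. The mid-p convention is the
  standard calibration device for this situation and restores approximate
  uniformity without changing the test statistic.

Zero-variance inputs (identical values in both groups) give $p = 1$ by
convention, and paired signed-rank comparisons with all-zero differences
do the same.

Dedicated DTU/DTE engines (quasi-binomial usage models, TMM-normalized
quasi-likelihood count models) can replace the built-in tests through the
adapter functions `load_external_dtu()` / `load_external_dte()`: imported
p-values (and fold changes, for DTE) override the built-in values
verbatim, with the global BH adjustment re-applied when the table carries
no adjusted column.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `dif_threshold` | 0.1 | usage fraction | minimum \|dIF\| for up/down-usage |
| `alpha` | 0.05 | — | adjusted significance level, DTU and DTE |
| `low_expression_tpm` | 1 | TPM | low/high baseline-expression split |
| `min_combined_freq` | 0.5 | — | optional combined-frequency cut (strict >) |
| `lfc_filter` | 1 | log2 | optional \|log2FC\| cut (strict >), off by default |
| `rho_threshold` | -0.8 | — | usage anticorrelation ceiling (strict <) |
| `pseudocount` | 0.01 | TPM | stabilizes log2 fold changes |

The 0.1 usage threshold and $\alpha = 0.05$ follow the most widely used
switch definition; 1 TPM is the conventional boundary between lowly and
highly expressed transcripts. Boundary semantics are deliberate: the
combined-frequency and fold-change cuts are strict ("higher than"), the
TPM floor in `expression_floor_filter()` is at-least.

The expression filter applied before testing keeps a transcript when its
CPM reaches `min_count` scaled by the median library size (in millions)
in at least as many samples as the smaller condition group has, and its
total count reaches `min_total` — a simplified, group-aware restatement of
the default count filter used by differential-expression workflows.
Filtering is per cohort (each cohort is tested separately), controllable
via the `filter` argument of `analyze_dtu()` / `analyze_dte()`.

## The prioritization chain

`filter_chain()` shortlists switches in stages, with per-stage
accounting: (1) keep concordant switches — this single rule enforces both
differential expression of both transcripts and codirectionality of
expression with usage; (2) drop combined frequency 0 (pairs that never
actually swap); (3) optionally require combined frequency > 0.5;
(4) optionally require both \|log2FC\| > 1. Stage 4 ships disabled: it is
an alternative shortlist rule rather than part of the canonical chain.
Survivors are ranked by combined frequency with a deterministic
lexicographic tie-break. Two further stand-alone filters mirror an older
frequency-based detection pipeline: a 1 TPM mean-expression floor (in
either condition) and a Spearman anticorrelation requirement
($\rho < -0.8$) on the pair's pooled usage vectors.

## The synthetic cohort generator

Real tumor-vs-normal switch catalogs come from consortium-scale RNA-seq;
the generator replaces that input with a controlled cohort whose ground
truth is known exactly.

Structure: each of $G$ genes carries 2-5 isoforms; baseline usage is
symmetric Dirichlet($\alpha = 2$), which avoids degenerate near-0/near-1
baselines; expected gene TPM is log-normal (natural-log mean 4, sd 1);
transcript lengths are unit, so expected counts are proportional to TPM
times the library share (default library size $2 \times 10^6$). Counts
are negative binomial with size `dispersion` (default 10; larger = less
noise; `Inf` switches to a deterministic mode where counts equal their
expectations), and TPM is recomputed from counts by column normalization
to $10^6$ — so usage and expression noise propagate exactly as through a
real quantifier's output. Defaults of 25 samples per condition match the
smallest cohorts such analyses are run on.

A planted switch moves `delta_if` usage mass from the normal transcript
(assigned the gene's largest baseline usage; the draw is rejected until
it can cover the shift with a 0.05 margin, with a deterministic fallback
after 200 tries) to the cancer transcript (second largest), leaving other
isoforms untouched — which guarantees opposite dIF signs of exactly
$\pm$`delta_if`. The expression class is realized through a gene-level
fold on the *measured* (post-normalization) scale: the `*_not_de` classes
pin the designated transcript's expected expression to exact equality
($F = \pi_c / (\pi_c + \delta)$ for `cancer_not_de`), and `both_down` /
`both_up` scale relative to that pinning fold, so the intended class
holds for any feasible baseline. Because TPM is compositional, a naive
implementation would leak the planted folds into every unplanted gene as
a spurious global fold change; a single-isoform ballast transcript
absorbs the net abundance difference between conditions so that unplanted
genes stay exactly null on the measured scale.

What the generator does **not** emulate: transcript length bias (unit
lengths), per-gene dispersion heterogeneity, batch effects and sample
covariates, correlated co-regulation across genes, annotation errors, and
the cohort-to-cohort effect-size heterogeneity of real cancer types
(multi-cohort generation shares one gene universe and planted effect
set, with independent sampling noise per cohort). Passing benchmarks on
these cohorts therefore demonstrates the correctness and calibration of
the pipeline's statistics, not robustness to every artifact of real
RNA-seq.

## Numerical choices and degenerate inputs

* Usage of an unexpressed gene is exactly 0, and per-(gene, sample)
  usages otherwise sum to 1 within $10^{-9}$.
* dIF is antisymmetric under swapping condition labels, exactly; so is
  the log2 fold change (symmetric pseudocount).
* Switch pairing output is ordered (cohort, gene, cancer transcript,
  normal transcript); summary counts deduplicate unique genes and unique
  *ordered* pairs across cohorts — roles are condition-defined, so
  (A, B) and (B, A) are different events.
* Undefined Spearman correlations (constant vectors) drop the switch
  from the anticorrelation filter with a warning, and are reported as
  missing in the baseline-expression correlation table.
* TPM matrices are linear scale; log-transformed input is rejected
  implicitly by the non-negativity validation only, so the documentation
  states the expectation explicitly.

## Problem sizes used in the checks

The test-suite benchmarks run at the design scale of the method: null
calibration on 20 cohorts of 200 genes at 25 samples per condition
(pooled uniformity checked on one transcript per gene, since same-gene
usages are compositionally dependent and the KS test assumes independent
draws); recovery of 50 planted concordant switches (dIF 0.3, dispersion
20) over 10 seeds; classification recovery of four planted classes at 50
samples per condition with dispersion 100. The reference run in
`scripts/acceptance.R` uses 200 genes, 62 planted switches across five
classes, dispersion 20 and 25 samples per condition.

## Known limitations

The built-in tests are distribution-free but less powerful than
parametric usage/count models at small $n$; the adapters exist precisely
so results from those engines can flow through the same classification,
scoring and prioritization stages. Classification accuracy inherits the
miscalibration of whichever test supplies the DE calls. The frequency
scores are descriptive statistics without a significance model — ranking
by combined frequency is a prioritization heuristic, not a test.
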