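# switchquant

Quantitative detection, classification and prioritization of **isoform
switches** from two-condition transcript-level RNA-seq expression data.

## What problem this solves

Genes express several transcript isoforms, and in tumors the *proportions*
of those isoforms often shift even when total gene output does not. The
*usage* (isoform fraction) of transcript *t* in sample *s* is

```
u(t, s) = TPM(t, s) / sum of TPM over all transcripts of t's gene in s
```

(set to 0 where the gene is unexpressed). With
`dIF(t) = mean usage in cancer − mean usage in normal`, an **isoform
switch** is a pair of transcripts of one gene where one member has
`dIF > 0.1` and the other `dIF < −0.1`, both at adjusted significance
(BH-adjusted rank-sum p < 0.05); the up-used member is the *cancer
transcript*, the down-used member the *normal transcript*.

Usage is a ratio, so a "switching" transcript need not change its own
expression at all — its partner may simply collapse. switchquant therefore
goes beyond detection and quantifies each switch:

* **Concordance class** — whether each transcript's expression change
  (DE call and direction) agrees with its usage change: `concordant`,
  `cancer_not_de`, `normal_not_de`, `both_down`, `both_up`, `both_not_de`,
  `reverse`.
* **Characteristic frequencies** — `f_cancer`: share of cancer samples
  where the cancer transcript out-expresses the normal transcript;
  `f_normal`: share of normal samples with the reverse order; the
  **combined frequency** `f_cancer × f_normal` (the ranking score) and the
  legacy score `f_cancer + f_normal − 1` (degenerate: it cannot separate a
  never-swapping (1, 0) pair from a (0.5, 0.5) pair).
* **Prioritization** — a staged filter chain (concordant class → nonzero
  combined frequency → combined frequency > 0.5 → optional |log2FC| > 1)
  with per-stage accounting, plus stand-alone 1 TPM expression-floor and
  usage-anticorrelation (Spearman ρ < −0.8) filters.

A seeded synthetic cohort generator plants switches of every concordance
class into negative-binomial transcript counts with Dirichlet usage
baselines, providing exact ground truth for sensitivity / FDR /
classification benchmarks. Adapters let externally computed DTU/DTE result
tables (from dedicated engines) replace the built-in rank-sum tests.

Intended users: computational biologists analyzing differential transcript
usage in tumor-vs-normal (or any two-condition) designs who want switch
calls enriched with expression-concordance and prevalence-swap evidence.

## Worked example

```r
library(switchquant)

spec <- scenario_spec(
  n_genes = 100,
  planted = plant_switches(c(concordant = 8, both_down = 6,
                             cancer_not_de = 4, both_up = 2),
                           delta_if = 0.3),
  dispersion = 20, seed = 42)
gen <- generate_cohort(spec)          # counts, tpm, annotation, samples, truth

cfg <- analysis_config()
dtu <- analyze_dtu(gen$tpm, gen$counts, gen$annotation, gen$samples, cfg)
dte <- analyze_dte(gen$tpm, gen$counts, gen$annotation, gen$samples, cfg)
sw  <- identify_switches(dtu, cfg)
q   <- quantify_switches(sw, dte, gen$tpm, gen$samples)

count_switches(q)
#>   n_switches n_genes n_pairs
#> 1         20      20      20

subset(class_summary(q), cohort == "all" & n > 0)
#>  cohort concordance_class n pct
#>     all        concordant 8  40
#>     all     cancer_not_de 4  20
#>     all         both_down 6  30
#>     all           both_up 2  10

rep <- filter_chain(q, cfg)
rep
#> filter_report
#>                  stage                              rule n_in n_out
#>       concordant_class concordance_class == 'concordant'   20     8
#>  nonzero_combined_freq                 combined_freq > 0    8     8
#>      min_combined_freq               combined_freq > 0.5    8     7
#> 7 switch(es) retained

head(rep$switches[, c("gene_id", "cancer_tx", "normal_tx",
                      "combined_freq", "rank")], 3)
#>  gene_id cancer_tx normal_tx combined_freq rank
#>    G0005  G0005.T2  G0005.T1          0.96    1
#>    G0006  G0006.T2  G0006.T1          0.92    2
#>    G0001  G0001.T2  G0001.T1          0.84    3

evaluate_against_truth(q, gen$truth)
#>  n_planted n_detected n_matched sensitivity fdr class_accuracy freq_rmse
#>         20         20        20           1   0              1 0.2615339
```

All 20 planted switches are recovered with no false positives, every
switch is assigned its planted concordance class, and the chain shortlists
the concordant, frequently swapping pairs. `freq_rmse` compares observed
combined frequencies with the generator's deterministic expectation (the
indicator of expected expression ordering), so moderate values simply
reflect sampling noise in the frequencies.

The same pipeline runs from files: `run_all("config.yaml", "outdir")`
reads a YAML configuration with either an `inputs:` block (paths to TPM,
counts, tx2gene and sample-sheet TSVs) or a `simulate:` block, writes
every stage table (`dtu_results.tsv`, `dte_results.tsv`, `switches.tsv`,
`switches_quantified.tsv`, `class_summary.tsv`, `frequency_curve.tsv`,
`stats_battery.tsv`, `prioritized.tsv`, `filter_report.json`) plus a JSON
run manifest, and is byte-reproducible for a fixed seed. The same
functionality is available from the shell via the installed
`exec/switchquant` script (`simulate`, `run-all`, `prioritize`,
`evaluate` subcommands).

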