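#' Identify isoform switches from differential-usage results
#'
#' Within each (gene, cohort), every significantly up-used transcript
#' (`usage_direction == "up"`, i.e. dIF above the threshold at adjusted
#' significance) is paired with every significantly down-used transcript in
#' all possible combinations. By convention the up-used member is called the
#' cancer transcript and the down-used member the normal transcript — the
#' naming follows usage direction, not expression. A transcript may take
#' part in several switches of the same gene.
#'
#' @param dtu Result table from [analyze_dtu()].
#' @param config [analysis_config()] (thresholds are already baked into the
#'   direction labels; kept for the record).
#' @return data.frame with one row per switch per cohort: `gene_id`,
#'   `cohort`, `cancer_tx`, `normal_tx`, `dIF_cancer`, `dIF_normal`,
#'   ordered deterministically by (cohort, gene_id, cancer_tx, normal_tx).
#' @export
identify_switches <- function(dtu, config = analysis_config()) {
  up <- dtu[dtu$usage_direction == "up", , drop = FALSE]
  dn <- dtu[dtu$usage_direction == "down", , drop = FALSE]
  pairs <- merge(
    up[, c("gene_id", "cohort", "transcript_id", "dIF")],
    dn[, c("gene_id", "cohort", "transcript_id", "dIF")],
    by = c("gene_id", "cohort"), suffixes = c("_cancer", "_normal"))
  out <- data.frame(gene_id = pairs$gene_id, cohort = pairs$cohort,
                    cancer_tx = pairs$transcript_id_cancer,
                    normal_tx = pairs$transcript_id_normal,
                    dIF_cancer = pairs$dIF_cancer,
                    dIF_normal = pairs$dIF_normal,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cohort, out$gene_id, out$cancer_tx, out$normal_tx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary counts for a switch set
#'
#' Reports the granularities a switch catalog is usually quoted at: total
#' switches (one per gene pair per cohort), unique genes, and unique ordered
#' transcript pairs (the same pair found in two cohorts counts once).
#'
#' @param switches Result of [identify_switches()].
#' @return data.frame with `n_switches`, `n_genes`, `n_pairs` and per-cohort
#'   switch counts attached as attribute `per_cohort`.
#' @export
count_switches <- function(switches) {
  per <- if (nrow(switches)) {
    tab <- table(switches$cohort)
    data.frame(cohort = names(tab), n_switches = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cohort = character(), n_switches = integer())
  }
  out <- data.frame(
    n_switches = nrow(switches),
    n_genes = length(unique(switches$gene_id)),
    n_pairs = nrow(unique(switches[, c("cancer_tx", "normal_tx")])))
  attr(out, "per_cohort") <- per
  out
}
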