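#' Prioritization filter chain
#'
#' Applies the staged shortlist rules to a quantified switch table:
#'
#' 1. `concordant_class` — keep only concordant switches (both transcripts
#'    differentially expressed with expression moving in the direction of
#'    usage);
#' 2. `nonzero_combined_freq` — drop switches with a combined frequency of
#'    exactly 0, i.e. pairs in which one transcript out-expresses the other
#'    in every sample of one condition;
#' 3. `min_combined_freq` (optional) — keep switches with combined
#'    frequency strictly greater than `config$min_combined_freq`;
#' 4. `lfc` (optional, off by default) — keep switches in which both
#'    transcripts' absolute log2 fold changes strictly exceed
#'    `config$lfc_filter`.
#'
#' Survivors are ranked by combined frequency, descending, with
#' deterministic lexicographic tie-breaking on (gene, cancer transcript,
#' normal transcript).
#'
#' @param switches Quantified switch table (with classes and frequencies).
#' @param config [analysis_config()].
#' @param apply_min_combined Apply stage 3. Default `TRUE`.
#' @param apply_lfc Apply stage 4. Default `FALSE`: the absolute
#'   fold-change cut is an alternative shortlist rule rather than part of
#'   the canonical chain.
#' @return A list of class `filter_report` with elements `stages`
#'   (data.frame `stage`, `rule`, `n_in`, `n_out`) and `switches` (the
#'   ranked survivors with a `rank` column).
#' @export
filter_chain <- function(switches, config = analysis_config(),
                         apply_min_combined = TRUE, apply_lfc = FALSE) {
  stages <- list(
    list(name = "concordant_class",
         rule = "concordance_class == 'concordant'",
         fn = function(df) df[df$concordance_class == "concordant", , drop = FALSE]),
    list(name = "nonzero_combined_freq",
         rule = "combined_freq > 0",
         fn = function(df) df[df$combined_freq > 0, , drop = FALSE]))
  if (apply_min_combined) {
    stages <- c(stages, list(list(
      name = "min_combined_freq",
      rule = sprintf("combined_freq > %g", config$min_combined_freq),
      fn = function(df) df[df$combined_freq > config$min_combined_freq, ,
                           drop = FALSE])))
  }
  if (apply_lfc) {
    stages <- c(stages, list(list(
      name = "lfc",
      rule = sprintf("min(|log2fc|) > %g", config$lfc_filter),
      fn = function(df) df[pmin(abs(df$log2fc_cancer), abs(df$log2fc_normal)) >
                             config$lfc_filter, , drop = FALSE])))
  }
  acc <- list()
  cur <- switches
  for (st in stages) {
    n_in <- nrow(cur)
    cur <- st$fn(cur)
    acc[[st$name]] <- data.frame(stage = st$name, rule = st$rule,
                                 n_in = n_in, n_out = nrow(cur),
                                 stringsAsFactors = FALSE)
  }
  ord <- order(-cur$combined_freq, cur$gene_id, cur$cancer_tx, cur$normal_tx)
  cur <- cur[ord, , drop = FALSE]
  cur$rank <- seq_len(nrow(cur))
  rownames(cur) <- NULL
  report <- do.call(rbind, acc)
  rownames(report) <- NULL
  structure(list(stages = report, switches = cur), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("%d switch(es) retained\n", nrow(x$switches)))
  invisible(x)
}

#' Usage anticorrelation filter
#'
#' Keeps switches whose two transcripts' per-sample usage vectors (both
#' conditions of the cohort pooled) are strongly negatively correlated
#' (Spearman rho below `rho_threshold`). A two-isoform gene gives exactly
#' rho = -1 wherever the gene is expressed. Switches with an undefined
#' correlation (a constant usage vector) are dropped with a warning.
#'
#' @param switches Switch table.
#' @param usage Usage matrix from [compute_usage()].
#' @param samples Sample sheet.
#' @param rho_threshold Keep when rho is strictly below this. Default -0.8.
#' @return Filtered switch table.
#' @export
anticorrelation_filter <- function(switches, usage, samples,
                                   rho_threshold = -0.8) {
  if (nrow(switches) == 0) return(switches)
  u <- unclass(usage)
  keep <- logical(nrow(switches))
  for (i in seq_len(nrow(switches))) {
    sub <- cohort_samples(align_samples(usage, samples), switches$cohort[i])
    a <- u[switches$cancer_tx[i], sub$sample_id]
    b <- u[switches$normal_tx[i], sub$sample_id]
    if (stats::var(a) == 0 || stats::var(b) == 0) {
      warning(sprintf("dropping %s/%s: constant usage vector, correlation undefined",
                      switches$cancer_tx[i], switches$normal_tx[i]))
      keep[i] <- FALSE
    } else {
      keep[i] <- stats::cor(a, b, method = "spearman") < rho_threshold
    }
  }
  out <- switches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression floor filter
#'
#' Keeps switches in which each transcript has a mean expression of at
#' least `floor_tpm` in the cohort's cancer samples or in its normal
#' samples (at-least semantics: a mean of exactly the floor passes).
#'
#' @param switches Switch table.
#' @param tpm TPM [expression_matrix()].
#' @param samples Sample sheet.
#' @param floor_tpm Floor in TPM. Default 1.
#' @return Filtered switch table.
#' @export
expression_floor_filter <- function(switches, tpm, samples, floor_tpm = 1.0) {
  if (nrow(switches) == 0) return(switches)
  v <- unclass(tpm)
  keep <- logical(nrow(switches))
  for (i in seq_len(nrow(switches))) {
    sub <- cohort_samples(align_samples(tpm, samples), switches$cohort[i])
    ns <- sub$sample_id[sub$condition == "normal"]
    cs <- sub$sample_id[sub$condition == "cancer"]
    ok <- function(tx) {
      mean(v[tx, cs]) >= floor_tpm || mean(v[tx, ns]) >= floor_tpm
    }
    keep[i] <- ok(switches$cancer_tx[i]) && ok(switches$normal_tx[i])
  }
  out <- switches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
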