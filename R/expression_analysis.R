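#' Transcript-level log2 fold change from TPM means
#'
#' `log2((mean cancer TPM + pseudocount) / (mean normal TPM + pseudocount))`
#' per transcript within one cohort. The symmetric pseudocount keeps the
#' fold change defined (and equal to 0) for transcripts unexpressed in both
#' conditions.
#'
#' @param tpm An [expression_matrix()] of kind `"tpm"`.
#' @param samples Sample sheet.
#' @param cohort Cohort label.
#' @param pseudocount Positive pseudocount. Default 0.01.
#' @return data.frame with `transcript_id`, `mean_tpm_normal`,
#'   `mean_tpm_cancer`, `log2fc`.
#' @export
log2_fold_change <- function(tpm, samples, cohort, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  sub <- cohort_samples(align_samples(tpm, samples), cohort)
  ns <- sub$sample_id[sub$condition == "normal"]
  cs <- sub$sample_id[sub$condition == "cancer"]
  mn <- rowMeans(unclass(tpm)[, ns, drop = FALSE])
  mc <- rowMeans(unclass(tpm)[, cs, drop = FALSE])
  data.frame(transcript_id = rownames(tpm), mean_tpm_normal = mn,
             mean_tpm_cancer = mc,
             log2fc = log2((mc + pseudocount) / (mn + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential transcript expression test
#'
#' Two-sided rank-sum test on per-sample `log2(TPM + pseudocount)` between
#' the cancer and normal samples of one cohort, applied to the same
#' transcript set that was tested for differential usage.
#'
#' @inheritParams log2_fold_change
#' @param kept Transcripts to test (the DTU-stage filter output).
#' @return data.frame with `transcript_id` and raw `p`.
#' @export
test_dte <- function(tpm, samples, cohort, kept = rownames(tpm),
                     pseudocount = 0.01) {
  sub <- cohort_samples(align_samples(tpm, samples), cohort)
  ns <- sub$sample_id[sub$condition == "normal"]
  cs <- sub$sample_id[sub$condition == "cancer"]
  if (length(ns) < 3 || length(cs) < 3) {
    stop("differential expression testing needs at least 3 samples per condition")
  }
  kept <- intersect(rownames(tpm), kept)
  lt <- log2(unclass(tpm) + pseudocount)
  p <- vapply(kept, function(t) rank_sum_test(lt[t, cs], lt[t, ns]),
              numeric(1))
  data.frame(transcript_id = kept, p = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

label_expr_direction <- function(log2fc, de_flag) {
  ifelse(de_flag & log2fc > 0, "up", ifelse(de_flag & log2fc < 0, "down", "none"))
}

#' Run the differential-transcript-expression stage over all cohorts
#'
#' Computes log2 fold changes and DTE tests per cohort on the filtered
#' transcript set, pools raw p-values across cohorts for one global BH
#' adjustment, and flags differential expression by adjusted significance
#' alone — fold-change magnitude plays no part in the call, only its sign
#' labels the direction of significant changes.
#'
#' @inheritParams analyze_dtu
#' @return data.frame with one row per (transcript, cohort):
#'   `transcript_id`, `gene_id`, `cohort`, `mean_tpm_normal`,
#'   `mean_tpm_cancer`, `log2fc`, `p`, `adj_p`, `de_flag`,
#'   `expr_direction`.
#' @export
analyze_dte <- function(tpm, counts, annotation, samples,
                        config = analysis_config(), filter = TRUE) {
  check_matching_keys(counts, tpm)
  res <- lapply(unique(samples$cohort), function(ch) {
    kept <- if (filter) filter_transcripts(counts, samples, ch)
            else rownames(counts)
    fc <- log2_fold_change(tpm, samples, ch, config$pseudocount)
    pv <- test_dte(tpm, samples, ch, kept, config$pseudocount)
    out <- merge(pv, fc, by = "transcript_id", sort = FALSE)
    out$cohort <- ch
    out
  })
  res <- do.call(rbind, res)
  res$adj_p <- adjust_global(res$p)
  res$de_flag <- res$adj_p < config$alpha
  res$expr_direction <- label_expr_direction(res$log2fc, res$de_flag)
  res$gene_id <- annotation$gene_id[match(res$transcript_id,
                                          annotation$transcript_id)]
  res[, c("transcript_id", "gene_id", "cohort", "mean_tpm_normal",
          "mean_tpm_cancer", "log2fc", "p", "adj_p", "de_flag",
          "expr_direction")]
}

#' Load externally computed differential-expression results
#'
#' Adapter for result tables from dedicated DTE engines (for example
#' TMM-normalized quasi-likelihood pipelines): a TSV with columns
#' `transcript_id`, `cohort`, `log2fc`, `p` and optionally `adj_p`.
#' External log2 fold changes are retained verbatim, never recomputed.
#'
#' @param path Path to the TSV file.
#' @return data.frame with `transcript_id`, `cohort`, `log2fc`, `p`,
#'   `adj_p`.
#' @export
load_external_dte <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "cohort", "log2fc", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("external DTE table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"adj_p" %in% names(df)) df$adj_p <- adjust_global(df$p)
  df[, c("transcript_id", "cohort", "log2fc", "p", "adj_p")]
}

#' Merge external DTE values into a built-in result table
#'
#' Replaces `log2fc`, `p` and `adj_p` for the (transcript, cohort) pairs in
#' the external table and refreshes the DE flags and direction labels.
#'
#' @param dte Result of [analyze_dte()].
#' @param external Result of [load_external_dte()].
#' @param config [analysis_config()].
#' @return Updated DTE result table.
#' @export
apply_external_dte <- function(dte, external, config = analysis_config()) {
  key <- paste(dte$transcript_id, dte$cohort)
  ext_key <- paste(external$transcript_id, external$cohort)
  hit <- match(key, ext_key)
  sel <- !is.na(hit)
  dte$p[sel] <- external$p[hit[sel]]
  dte$adj_p[sel] <- external$adj_p[hit[sel]]
  dte$log2fc[sel] <- external$log2fc[hit[sel]]
  dte$de_flag <- dte$adj_p < config$alpha
  dte$expr_direction <- label_expr_direction(dte$log2fc, dte$de_flag)
  dte
}
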