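#' Compute per-sample transcript usage (isoform fractions)
#'
#' Usage of a transcript in a sample is its TPM divided by the summed TPM of
#' all transcripts of its parent gene in that sample. Where the gene is not
#' expressed (summed TPM of 0) the usage of all its transcripts is set to 0,
#' so usages of a gene's transcripts sum to 1 in expressed samples and to 0
#' otherwise.
#'
#' @param tpm An [expression_matrix()] of kind `"tpm"`.
#' @param annotation tx2gene data.frame covering every transcript in `tpm`.
#' @return A numeric matrix of class `usage_matrix` (same dimnames as
#'   `tpm`), with the gene map attached as attribute `gene`.
#' @export
compute_usage <- function(tpm, annotation) {
  if (!identical(matrix_kind(tpm), "tpm")) {
    stop("usage must be computed from a TPM matrix, not counts")
  }
  check_annotation_total(tpm, annotation)
  gene <- annotation$gene_id[match(rownames(tpm), annotation$transcript_id)]
  gsum <- rowsum(unclass(tpm), gene)          # gene x sample sums
  denom <- gsum[gene, , drop = FALSE]
  usage <- ifelse(denom > 0, unclass(tpm) / denom, 0)
  dimnames(usage) <- dimnames(tpm)
  structure(usage, gene = gene, class = c("usage_matrix", "matrix", "array"))
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("usage_matrix: %d transcripts x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Mean usage per condition and its change (dIF)
#'
#' For every transcript, the arithmetic mean of its per-sample usage values
#' within each condition of one cohort, and the difference
#' `dIF = mean usage in cancer - mean usage in normal`.
#'
#' @param usage A usage matrix from [compute_usage()].
#' @param samples Sample sheet data.frame.
#' @param cohort Cohort label to restrict to.
#' @return data.frame with `transcript_id`, `mean_usage_normal`,
#'   `mean_usage_cancer`, `dIF`.
#' @export
mean_usage_change <- function(usage, samples, cohort) {
  sub <- cohort_samples(align_samples(usage, samples), cohort)
  ns <- sub$sample_id[sub$condition == "normal"]
  cs <- sub$sample_id[sub$condition == "cancer"]
  if (!length(ns) || !length(cs)) {
    stop("cohort ", cohort, " lacks samples in one condition")
  }
  mn <- rowMeans(usage[, ns, drop = FALSE])
  mc <- rowMeans(usage[, cs, drop = FALSE])
  data.frame(transcript_id = rownames(usage), mean_usage_normal = mn,
             mean_usage_cancer = mc, dIF = mc - mn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression filter on the count matrix
#'
#' Keeps a transcript when its counts-per-million reach
#' `min_count / median library size (in millions)` in at least as many
#' samples as the smaller condition group contains, and its total count
#' across the cohort's samples reaches `min_total`. This reproduces the
#' documented default logic of the standard count-based expression filter
#' used by differential-expression workflows, in a simplified group-aware
#' form.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param samples Sample sheet.
#' @param cohort Cohort label.
#' @param min_count Count threshold scaled by the median library size.
#'   Default 10.
#' @param min_total Minimum total count over all cohort samples. Default 15.
#' @return Character vector of retained transcript ids.
#' @export
filter_transcripts <- function(counts, samples, cohort,
                               min_count = 10, min_total = 15) {
  if (!identical(matrix_kind(counts), "counts")) {
    stop("expression filtering operates on the counts matrix")
  }
  sub <- cohort_samples(align_samples(counts, samples), cohort)
  m <- unclass(counts)[, sub$sample_id, drop = FALSE]
  lib <- colSums(m)
  cpm <- sweep(m, 2, pmax(lib, 1), "/") * 1e6
  cutoff <- min_count / stats::median(lib / 1e6)
  n_min <- min(table(sub$condition))
  keep <- rowSums(cpm >= cutoff) >= n_min & rowSums(m) >= min_total
  kept <- rownames(m)[keep]
  if (!length(kept)) {
    stop("the expression filter removed every transcript; lower min_count/min_total")
  }
  kept
}

#' Two-group rank-sum test
#'
#' The Mann-Whitney/Wilcoxon rank-sum test used for both the usage and the
#' expression comparisons. For a combined sample size of at most 20 the
#' p-value is exact by exhaustive enumeration of all group assignments of
#' the observed midranks (so ties are handled exactly). For larger samples
#' the mid-p value is reported: the exact discrete null with half the
#' probability of the observed statistic (tie-free groups below 50), or the
#' tie-corrected normal approximation without continuity correction (its
#' smooth analog) otherwise. The mid-p convention keeps null p-values
#' calibrated close to uniform despite the discreteness of the rank-sum
#' statistic, which matters when many tests are pooled for one global FDR
#' adjustment. Groups with zero combined variance give p = 1 by convention.
#'
#' @param x,y Numeric vectors (condition groups).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return A p-value in (0, 1].
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) return(1)
  if (stats::var(c(x, y)) == 0) return(1)
  n <- length(x); m <- length(y)
  if (n + m <= 20) {
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n)])
    combos <- utils::combn(n + m, n)
    ws <- colSums(matrix(r[combos], nrow = n))
    p_le <- mean(ws <= w)
    p_ge <- mean(ws >= w)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(max(p, .Machine$double.xmin))
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2       # Mann-Whitney U for x
  if (!any(duplicated(c(x, y))) && n < 50 && m < 50) {
    lo <- stats::pwilcox(u - 1, n, m) + 0.5 * stats::dwilcox(u, n, m)
    hi <- 1 - stats::pwilcox(u, n, m) + 0.5 * stats::dwilcox(u, n, m)
  } else {
    nt <- n + m
    ties <- table(r)
    sg <- sqrt(n * m / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1))))
    z <- (u - n * m / 2) / sg
    lo <- stats::pnorm(z)
    hi <- 1 - stats::pnorm(z)
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(lo, hi)),
              greater = min(1, hi),
              less = min(1, lo))
  max(p, .Machine$double.xmin)
}

#' Differential transcript usage test
#'
#' Two-sided rank-sum test on per-sample usage values between the cancer
#' and normal samples of one cohort, for every retained transcript.
#'
#' @param usage Usage matrix from [compute_usage()].
#' @inheritParams filter_transcripts
#' @param kept Character vector of transcripts to test (from
#'   [filter_transcripts()]); defaults to all transcripts.
#' @return data.frame with `transcript_id` and raw `p`.
#' @export
test_dtu <- function(usage, samples, cohort, kept = rownames(usage)) {
  sub <- cohort_samples(align_samples(usage, samples), cohort)
  ns <- sub$sample_id[sub$condition == "normal"]
  cs <- sub$sample_id[sub$condition == "cancer"]
  if (length(ns) < 3 || length(cs) < 3) {
    stop("differential usage testing needs at least 3 samples per condition")
  }
  kept <- intersect(rownames(usage), kept)
  u <- unclass(usage)
  p <- vapply(kept, function(t) {
    rank_sum_test(u[t, cs], u[t, ns])
  }, numeric(1))
  data.frame(transcript_id = kept, p = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global Benjamini-Hochberg adjustment
#'
#' Applied once to the p-values pooled across all cohorts (and across the
#' usage and expression analyses separately), mirroring a global correction
#' over the whole experiment rather than per-cohort corrections.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (same length/order), capped at 1.
#' @export
adjust_global <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

label_usage_direction <- function(dIF, adj_p, config) {
  ifelse(adj_p < config$alpha & dIF > config$dif_threshold, "up",
         ifelse(adj_p < config$alpha & dIF < -config$dif_threshold, "down",
                "none"))
}

#' Run the differential-transcript-usage stage over all cohorts
#'
#' Computes usage, applies the expression filter per cohort, runs the DTU
#' test, pools raw p-values across cohorts for one global BH adjustment,
#' and labels each transcript's usage direction (`up` / `down` / `none`)
#' by the dIF threshold and significance level in `config`.
#'
#' @param tpm,counts [expression_matrix()]s with identical keys.
#' @param annotation tx2gene map.
#' @param samples Sample sheet (possibly several cohorts).
#' @param config [analysis_config()].
#' @param filter Apply the count filter per cohort (default `TRUE`).
#' @return data.frame with one row per (transcript, cohort):
#'   `transcript_id`, `gene_id`, `cohort`, `mean_usage_normal`,
#'   `mean_usage_cancer`, `dIF`, `p`, `adj_p`, `usage_direction`.
#' @export
analyze_dtu <- function(tpm, counts, annotation, samples,
                        config = analysis_config(), filter = TRUE) {
  check_matching_keys(counts, tpm)
  usage <- compute_usage(tpm, annotation)
  res <- lapply(unique(samples$cohort), function(ch) {
    kept <- if (filter) filter_transcripts(counts, samples, ch)
            else rownames(counts)
    mu <- mean_usage_change(usage, samples, ch)
    pv <- test_dtu(usage, samples, ch, kept)
    out <- merge(pv, mu, by = "transcript_id", sort = FALSE)
    out$cohort <- ch
    out
  })
  res <- do.call(rbind, res)
  res$adj_p <- adjust_global(res$p)
  res$usage_direction <- label_usage_direction(res$dIF, res$adj_p, config)
  res$gene_id <- annotation$gene_id[match(res$transcript_id,
                                          annotation$transcript_id)]
  res[, c("transcript_id", "gene_id", "cohort", "mean_usage_normal",
          "mean_usage_cancer", "dIF", "p", "adj_p", "usage_direction")]
}

#' Load externally computed differential-usage results
#'
#' Adapter for result tables produced by dedicated DTU engines (for example
#' quasi-binomial or empirical-null based tools): a TSV with columns
#' `transcript_id`, `cohort`, `p` and optionally `adj_p`. When `adj_p` is
#' absent the global BH adjustment is applied to the imported raw p-values.
#'
#' @param path Path to the TSV file.
#' @return data.frame with `transcript_id`, `cohort`, `p`, `adj_p`.
#' @export
load_external_dtu <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "cohort", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("external DTU table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"adj_p" %in% names(df)) df$adj_p <- adjust_global(df$p)
  df[, c("transcript_id", "cohort", "p", "adj_p")]
}

#' Merge external DTU p-values into a built-in result table
#'
#' Replaces the built-in test's `p`/`adj_p` for the (transcript, cohort)
#' pairs present in the external table, then refreshes the usage-direction
#' labels. Descriptive columns (mean usages, dIF) are retained from the
#' built-in computation.
#'
#' @param dtu Result of [analyze_dtu()].
#' @param external Result of [load_external_dtu()].
#' @param config [analysis_config()].
#' @return Updated DTU result table.
#' @export
apply_external_dtu <- function(dtu, external, config = analysis_config()) {
  key <- paste(dtu$transcript_id, dtu$cohort)
  ext_key <- paste(external$transcript_id, external$cohort)
  hit <- match(key, ext_key)
  dtu$p[!is.na(hit)] <- external$p[hit[!is.na(hit)]]
  dtu$adj_p[!is.na(hit)] <- external$adj_p[hit[!is.na(hit)]]
  dtu$usage_direction <- label_usage_direction(dtu$dIF, dtu$adj_p, config)
  dtu
}
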