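CONCORDANCE_CLASSES <- c("concordant", "cancer_not_de", "normal_not_de",
                         "both_not_de", "both_down", "both_up", "reverse")

#' Classify switches by usage/expression concordance
#'
#' Joins each switch with the differential-expression calls of its two
#' transcripts and assigns exactly one concordance class:
#'
#' * `concordant` — both transcripts differentially expressed, the cancer
#'   transcript up and the normal transcript down in expression (expression
#'   moves with usage);
#' * `reverse` — both DE with the opposite pattern;
#' * `both_down` / `both_up` — both DE in the same direction;
#' * `cancer_not_de` / `normal_not_de` — exactly one transcript without a
#'   significant expression change;
#' * `both_not_de` — neither transcript differentially expressed.
#'
#' DE status is taken from adjusted significance alone; fold-change
#' magnitude never enters the call.
#'
#' @param switches Result of [identify_switches()].
#' @param dte Result of [analyze_dte()].
#' @return `switches` with added columns `log2fc_cancer`, `log2fc_normal`,
#'   `concordance_class`.
#' @export
classify_switches <- function(switches, dte) {
  if (nrow(switches) == 0) {
    switches$log2fc_cancer <- numeric(0)
    switches$log2fc_normal <- numeric(0)
    switches$concordance_class <- character(0)
    return(switches)
  }
  key <- paste(dte$transcript_id, dte$cohort)
  lookup <- function(tx) {
    i <- match(paste(tx, switches$cohort), key)
    if (anyNA(i)) {
      stop("no differential-expression result for transcript(s): ",
           paste(unique(tx[is.na(i)]), collapse = ", "))
    }
    i
  }
  ic <- lookup(switches$cancer_tx)
  im <- lookup(switches$normal_tx)
  dir_c <- dte$expr_direction[ic]
  dir_n <- dte$expr_direction[im]
  cls <- ifelse(dir_c == "none" & dir_n == "none", "both_not_de",
         ifelse(dir_c == "none", "cancer_not_de",
         ifelse(dir_n == "none", "normal_not_de",
         ifelse(dir_c == "up" & dir_n == "down", "concordant",
         ifelse(dir_c == "down" & dir_n == "up", "reverse",
         ifelse(dir_c == "down", "both_down", "both_up"))))))
  switches$log2fc_cancer <- dte$log2fc[ic]
  switches$log2fc_normal <- dte$log2fc[im]
  switches$concordance_class <- cls
  switches
}

#' Characteristic switch frequencies
#'
#' For each switch, `f_cancer` is the proportion of the cohort's cancer
#' samples in which the cancer transcript has strictly higher expression
#' than the normal transcript, and `f_normal` the proportion of normal
#' samples with the reverse order. A sample where the two values tie
#' (typically both zero) counts toward neither frequency. The combined
#' frequency is the product `f_cancer * f_normal`, and the legacy score is
#' the sum minus one. The frequencies are invariant to whether expression
#' (TPM) or usage values are supplied, whenever the parent gene is
#' expressed in every sample.
#'
#' @param switches Result of [identify_switches()] (or downstream).
#' @param values An [expression_matrix()] of TPM (default) or a usage
#'   matrix.
#' @param samples Sample sheet.
#' @return `switches` with added columns `f_cancer`, `f_normal`,
#'   `combined_freq`, `legacy_score`.
#' @export
switch_frequencies <- function(switches, values, samples) {
  v <- unclass(values)
  n <- nrow(switches)
  f_c <- f_n <- numeric(n)
  for (ch in unique(switches$cohort)) {
    sub <- cohort_samples(align_samples(values, samples), ch)
    cs <- sub$sample_id[sub$condition == "cancer"]
    ns <- sub$sample_id[sub$condition == "normal"]
    rows <- which(switches$cohort == ch)
    for (i in rows) {
      ctx <- switches$cancer_tx[i]; ntx <- switches$normal_tx[i]
      f_c[i] <- mean(v[ctx, cs] > v[ntx, cs])
      f_n[i] <- mean(v[ntx, ns] > v[ctx, ns])
    }
  }
  switches$f_cancer <- f_c
  switches$f_normal <- f_n
  switches$combined_freq <- f_c * f_n
  switches$legacy_score <- f_c + f_n - 1
  switches
}

#' Quantify a switch set
#'
#' Convenience wrapper: concordance classification followed by
#' characteristic frequencies.
#'
#' @inheritParams classify_switches
#' @inheritParams switch_frequencies
#' @param tpm TPM [expression_matrix()].
#' @return Fully quantified switch table.
#' @export
quantify_switches <- function(switches, dte, tpm, samples) {
  switch_frequencies(classify_switches(switches, dte), tpm, samples)
}

#' Class membership summary
#'
#' Counts and percentages of each concordance class, per cohort and pooled.
#'
#' @param switches Quantified switch table.
#' @return data.frame with `cohort` (`"all"` for the pooled rows),
#'   `concordance_class`, `n`, `pct`.
#' @export
class_summary <- function(switches) {
  tally <- function(df, label) {
    n <- vapply(CONCORDANCE_CLASSES,
                function(cl) sum(df$concordance_class == cl), integer(1))
    data.frame(cohort = label, concordance_class = CONCORDANCE_CLASSES,
               n = as.integer(n),
               pct = if (nrow(df)) 100 * n / nrow(df) else rep(NA_real_, length(n)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(
    lapply(sort(unique(switches$cohort)),
           function(ch) tally(switches[switches$cohort == ch, ], ch)),
    list(tally(switches, "all"))))
  rownames(out) <- NULL
  out
}

#' Frequency exceedance curves
#'
#' On a 0 to 1 grid (step 0.01), the proportion of switches whose larger
#' characteristic frequency reaches each threshold, and the proportion
#' whose combined frequency does. Both curves are monotone non-increasing.
#'
#' @param switches Quantified switch table.
#' @return data.frame with `threshold`, `prop_max_freq`, `prop_combined`;
#'   empty when no switches are supplied.
#' @export
frequency_curve <- function(switches) {
  if (nrow(switches) == 0) {
    return(data.frame(threshold = numeric(0), prop_max_freq = numeric(0),
                      prop_combined = numeric(0)))
  }
  grid <- seq(0, 1, by = 0.01)
  mx <- pmax(switches$f_cancer, switches$f_normal)
  data.frame(threshold = grid,
             prop_max_freq = vapply(grid, function(t) mean(mx >= t), numeric(1)),
             prop_combined = vapply(grid, function(t) mean(switches$combined_freq >= t),
                                    numeric(1)))
}

#' Per-transcript role table for a switch set
#'
#' Expands a quantified switch table into one row per (cohort, transcript,
#' role), where the role is `cancer` for up-used and `normal` for down-used
#' members; each transcript is counted once per cohort and role even when
#' it takes part in several switches.
#'
#' @param switches Quantified switch table.
#' @return data.frame with `cohort`, `transcript_id`, `role`, `dIF`,
#'   `log2fc`.
#' @export
transcript_roles <- function(switches) {
  cc <- data.frame(cohort = switches$cohort,
                   transcript_id = switches$cancer_tx, role = "cancer",
                   dIF = switches$dIF_cancer, log2fc = switches$log2fc_cancer,
                   stringsAsFactors = FALSE)
  nn <- data.frame(cohort = switches$cohort,
                   transcript_id = switches$normal_tx, role = "normal",
                   dIF = switches$dIF_normal, log2fc = switches$log2fc_normal,
                   stringsAsFactors = FALSE)
  out <- rbind(cc, nn)
  out <- out[!duplicated(out[, c("cohort", "transcript_id", "role")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

mean_normal_tpm <- function(roles, tpm, samples) {
  vapply(seq_len(nrow(roles)), function(i) {
    sub <- cohort_samples(align_samples(tpm, samples), roles$cohort[i])
    ns <- sub$sample_id[sub$condition == "normal"]
    mean(unclass(tpm)[roles$transcript_id[i], ns])
  }, numeric(1))
}

#' Stratify switch transcripts by baseline expression
#'
#' Splits the cancer-role and normal-role transcripts into lowly and highly
#' expressed groups by their mean TPM in normal samples (changes are
#' measured relative to the normal condition) and compares the
#' distributions of dIF and of log2 fold change between the groups with
#' two-sided rank-sum tests, BH-adjusted over the battery. Comparisons with
#' an empty group are skipped with a warning.
#'
#' @param switches Quantified switch table.
#' @param tpm TPM [expression_matrix()].
#' @param samples Sample sheet.
#' @param threshold_tpm Expression threshold in TPM. Default 1.
#' @return data.frame with `role`, `measure`, `n_low`, `n_high`,
#'   `median_diff` (high minus low), `p`, `adj_p`.
#' @export
stratify_by_expression <- function(switches, tpm, samples, threshold_tpm = 1.0) {
  roles <- transcript_roles(switches)
  roles$mean_normal_tpm <- mean_normal_tpm(roles, tpm, samples)
  roles$group <- ifelse(roles$mean_normal_tpm < threshold_tpm, "low", "high")
  rows <- list()
  for (role in c("cancer", "normal")) {
    sub <- roles[roles$role == role, , drop = FALSE]
    for (measure in c("dIF", "log2fc")) {
      lo <- sub[[measure]][sub$group == "low"]
      hi <- sub[[measure]][sub$group == "high"]
      if (!length(lo) || !length(hi)) {
        warning(sprintf("skipping %s/%s: empty %s-expression group",
                        role, measure, if (length(lo)) "high" else "low"))
        next
      }
      rows[[paste(role, measure)]] <- data.frame(
        role = role, measure = measure,
        n_low = length(lo), n_high = length(hi),
        median_diff = stats::median(hi) - stats::median(lo),
        p = rank_sum_test(hi, lo), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(role = character(), measure = character(), n_low = integer(),
               n_high = integer(), median_diff = numeric(), p = numeric())
  }
  out$adj_p <- adjust_global(out$p)
  rownames(out) <- NULL
  out
}

#' Correlation of baseline expression with effect sizes
#'
#' Spearman rank correlation (midrank ties) between each switch
#' transcript's mean TPM in normal samples and its dIF or log2 fold change,
#' per role. Undefined correlations (constant input) are reported as `NA`.
#'
#' @inheritParams stratify_by_expression
#' @return data.frame with `role`, `measure`, `rho`, `n`.
#' @export
expression_effect_correlation <- function(switches, tpm, samples) {
  roles <- transcript_roles(switches)
  roles$mean_normal_tpm <- mean_normal_tpm(roles, tpm, samples)
  rows <- list()
  for (role in c("cancer", "normal")) {
    sub <- roles[roles$role == role, , drop = FALSE]
    for (measure in c("dIF", "log2fc")) {
      rho <- if (nrow(sub) < 3 ||
                 stats::var(sub$mean_normal_tpm) == 0 ||
                 stats::var(sub[[measure]]) == 0) NA_real_
             else stats::cor(sub$mean_normal_tpm, sub[[measure]],
                             method = "spearman")
      rows[[paste(role, measure)]] <- data.frame(
        role = role, measure = measure, rho = rho, n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Paired signed-rank test with a p = 1 convention when every pair ties.
signed_rank_test <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[is.finite(d)]
  if (length(d) == 0 || all(d == 0)) return(1)
  stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                     exact = FALSE, correct = TRUE)$p.value
}

#' Cross-cohort and within-class statistical battery
#'
#' Reproduces the summary comparisons run on a multi-cohort switch catalog:
#'
#' * Kruskal-Wallis tests across cohorts on dIF and on log2 fold change,
#'   separately for cancer-role and normal-role transcripts (each
#'   transcript counted once per cohort); skipped with fewer than two
#'   cohorts.
#' * Per cohort, a paired two-sided signed-rank test of |dIF| of the cancer
#'   transcript against |dIF| of the normal transcript over switches.
#' * Pooled over cohorts, one-sided paired signed-rank tests within the
#'   `both_down` and `both_up` classes of the alternative that the normal
#'   transcript's expression change is the more negative of the pair
#'   (log2fc_cancer - log2fc_normal > 0).
#'
#' All p-values are BH-adjusted together.
#'
#' @param switches Quantified switch table.
#' @return data.frame with `test`, `scope`, `n`, `p`, `adj_p`.
#' @export
cohort_comparisons <- function(switches) {
  rows <- list()
  roles <- transcript_roles(switches)
  n_cohorts <- length(unique(switches$cohort))
  if (n_cohorts >= 2) {
    for (role in c("cancer", "normal")) {
      sub <- roles[roles$role == role, , drop = FALSE]
      for (measure in c("dIF", "log2fc")) {
        kw <- stats::kruskal.test(sub[[measure]], factor(sub$cohort))
        rows[[paste("kw", role, measure)]] <- data.frame(
          test = sprintf("kruskal_wallis_%s_%s", measure, role),
          scope = "across_cohorts", n = nrow(sub), p = kw$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (ch in sort(unique(switches$cohort))) {
    sub <- switches[switches$cohort == ch, , drop = FALSE]
    rows[[paste("absdif", ch)]] <- data.frame(
      test = "signed_rank_abs_dIF_cancer_vs_normal", scope = ch,
      n = nrow(sub),
      p = signed_rank_test(abs(sub$dIF_cancer), abs(sub$dIF_normal)),
      stringsAsFactors = FALSE)
  }
  for (cl in c("both_down", "both_up")) {
    sub <- switches[switches$concordance_class == cl, , drop = FALSE]
    if (nrow(sub) == 0) next
    rows[[paste("lfc", cl)]] <- data.frame(
      test = sprintf("signed_rank_lfc_normal_below_cancer_%s", cl),
      scope = "pooled", n = nrow(sub),
      p = signed_rank_test(sub$log2fc_cancer, sub$log2fc_normal,
                           alternative = "greater"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(test = character(), scope = character(), n = integer(),
               p = numeric())
  }
  out$adj_p <- adjust_global(out$p)
  rownames(out) <- NULL
  out
}
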