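# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg step-up, written directly from the procedure's
# definition: sort p ascending, q_i = p_i * m / i, enforce monotonicity from
# the largest rank down, cap at 1.
bf_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Switch pairing by explicit double loop over all transcript pairs.
bf_identify_switches <- function(dtu, dif_threshold = 0.1, alpha = 0.05) {
  rows <- list()
  for (ch in unique(dtu$cohort)) {
    d <- dtu[dtu$cohort == ch, ]
    for (g in unique(d$gene_id)) {
      dg <- d[d$gene_id == g, ]
      for (i in seq_len(nrow(dg))) for (j in seq_len(nrow(dg))) {
        if (i == j) next
        up <- dg$dIF[i] > dif_threshold && dg$adj_p[i] < alpha
        dn <- dg$dIF[j] < -dif_threshold && dg$adj_p[j] < alpha
        if (up && dn) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, cohort = ch,
            cancer_tx = dg$transcript_id[i], normal_tx = dg$transcript_id[j],
            dIF_cancer = dg$dIF[i], dIF_normal = dg$dIF[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), cohort = character(),
                      cancer_tx = character(), normal_tx = character(),
                      dIF_cancer = numeric(), dIF_normal = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cohort, out$gene_id, out$cancer_tx, out$normal_tx), ]
  rownames(out) <- NULL
  out
}

# Characteristic frequencies by explicit per-sample counting loops.
bf_frequencies <- function(values, cancer_tx, normal_tx, cancer_samples,
                           normal_samples) {
  nc <- 0
  for (s in cancer_samples) {
    if (values[cancer_tx, s] > values[normal_tx, s]) nc <- nc + 1
  }
  nn <- 0
  for (s in normal_samples) {
    if (values[normal_tx, s] > values[cancer_tx, s]) nn <- nn + 1
  }
  f_c <- nc / length(cancer_samples)
  f_n <- nn / length(normal_samples)
  c(f_cancer = f_c, f_normal = f_n, combined = f_c * f_n,
    legacy = f_c + f_n - 1)
}

# Filter chain as one monolithic predicate evaluation.
bf_filter_chain <- function(sw, min_combined = 0.5, lfc = NULL) {
  keep <- sw$concordance_class == "concordant" & sw$combined_freq > 0 &
    sw$combined_freq > min_combined
  if (!is.null(lfc)) {
    keep <- keep & pmin(abs(sw$log2fc_cancer), abs(sw$log2fc_normal)) > lfc
  }
  out <- sw[keep, , drop = FALSE]
  out <- out[order(-out$combined_freq, out$gene_id, out$cancer_tx,
                   out$normal_tx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tiny deterministic expression fixture: two genes, four transcripts,
# four samples (2 normal + 2 cancer) in cohort "FX".
make_fixture <- function() {
  tpm <- matrix(c(30, 28, 29, 5, 4, 6,
                  10, 12, 11, 35, 30, 33,
                  8, 9, 8, 2, 1, 2,
                  1, 2, 1, 8, 9, 8),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("G1.T1", "G1.T2", "G2.T1", "G2.T2"),
                                c("N1", "N2", "N3", "C1", "C2", "C3")))
  list(
    tpm = expression_matrix(tpm, "tpm"),
    counts = expression_matrix(tpm * 10, "counts"),
    annotation = data.frame(transcript_id = rownames(tpm),
                            gene_id = c("G1", "G1", "G2", "G2"),
                            stringsAsFactors = FALSE),
    samples = suppressWarnings(validate_sample_sheet(data.frame(
      sample_id = colnames(tpm),
      condition = rep(c("normal", "cancer"), each = 3),
      cohort = "FX", stringsAsFactors = FALSE))))
}

# Random small cohort (plain matrices, no planted structure) for property
# tests over arbitrary data.
random_cohort <- function(n_genes = 10, n_per_gene = 2, n_normal = 4,
                          n_cancer = 4, cohort = "RND") {
  genes <- sprintf("g%02d", seq_len(n_genes))
  tx <- unlist(lapply(genes, function(g) paste0(g, ".t", seq_len(n_per_gene))))
  smp <- c(sprintf("n%02d", seq_len(n_normal)), sprintf("c%02d", seq_len(n_cancer)))
  vals <- matrix(stats::rexp(length(tx) * length(smp), rate = 0.1),
                 nrow = length(tx), dimnames = list(tx, smp))
  list(
    tpm = expression_matrix(vals, "tpm"),
    counts = expression_matrix(round(vals * 20), "counts"),
    annotation = data.frame(transcript_id = tx,
                            gene_id = rep(genes, each = n_per_gene),
                            stringsAsFactors = FALSE),
    samples = suppressWarnings(validate_sample_sheet(data.frame(
      sample_id = smp,
      condition = rep(c("normal", "cancer"), c(n_normal, n_cancer)),
      cohort = cohort, stringsAsFactors = FALSE))))
}

# Random DTU-like result table for pairing-oracle tests.
random_dtu_table <- function(n_genes = 8, max_tx = 4, cohorts = c("A", "B")) {
  rows <- list()
  for (ch in cohorts) for (g in seq_len(n_genes)) {
    k <- sample(2:max_tx, 1)
    gid <- sprintf("g%02d", g)
    rows[[paste(ch, g)]] <- data.frame(
      transcript_id = sprintf("%s.t%d", gid, seq_len(k)),
      gene_id = gid, cohort = ch,
      dIF = stats::runif(k, -0.5, 0.5),
      adj_p = stats::runif(k, 0, 0.2), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Random quantified-switch-like table for filter-chain oracle tests.
random_switch_table <- function(n = 40) {
  f_c <- stats::runif(n); f_n <- stats::runif(n)
  data.frame(
    gene_id = sprintf("g%02d", sample(20, n, TRUE)), cohort = rep("A", n),
    cancer_tx = sprintf("tC%03d", seq_len(n)),
    normal_tx = sprintf("tN%03d", seq_len(n)),
    dIF_cancer = stats::runif(n, 0.1, 0.5),
    dIF_normal = stats::runif(n, -0.5, -0.1),
    log2fc_cancer = stats::rnorm(n, 0, 2),
    log2fc_normal = stats::rnorm(n, 0, 2),
    concordance_class = sample(c("concordant", "both_down", "cancer_not_de"),
                               n, TRUE),
    f_cancer = f_c, f_normal = f_n,
    combined_freq = f_c * f_n, legacy_score = f_c + f_n - 1,
    stringsAsFactors = FALSE)
}
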