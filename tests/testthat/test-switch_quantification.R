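mk_switch <- function(ctx = "A", ntx = "B", gene = "g1", cohort = "X") {
  data.frame(gene_id = gene, cohort = cohort, cancer_tx = ctx,
             normal_tx = ntx, dIF_cancer = 0.3, dIF_normal = -0.3,
             stringsAsFactors = FALSE)
}

mk_dte <- function(tx, dir, lfc, cohort = "X") {
  data.frame(transcript_id = tx, cohort = cohort, log2fc = lfc,
             de_flag = dir != "none", expr_direction = dir,
             stringsAsFactors = FALSE)
}

test_that("concordance classification follows the truth table", {
  sw <- mk_switch()
  case <- function(dir_c, lfc_c, dir_n, lfc_n) {
    classify_switches(sw, rbind(mk_dte("A", dir_c, lfc_c),
                                mk_dte("B", dir_n, lfc_n)))$concordance_class
  }
  expect_identical(case("up", 1.2, "down", -0.8), "concordant")
  expect_identical(case("none", 0.1, "down", -1.0), "cancer_not_de")
  expect_identical(case("up", 0.6, "none", -0.1), "normal_not_de")
  expect_identical(case("down", -0.4, "down", -2.0), "both_down")
  expect_identical(case("up", 0.4, "up", 2.0), "both_up")
  expect_identical(case("down", -0.4, "up", 2.0), "reverse")
  expect_identical(case("none", 0, "none", 0), "both_not_de")
  expect_error(classify_switches(sw, mk_dte("A", "up", 1)),
               "no differential-expression result.*B")
})

test_that("classification is a partition and the summary adds up", {
  set.seed(19)
  sw <- random_switch_table(30)
  cs <- class_summary(sw)
  pooled <- cs[cs$cohort == "all", ]
  expect_equal(sum(pooled$n), nrow(sw))
  expect_equal(sum(pooled$pct), 100, tolerance = 1e-9)
  expect_true(all(sw$concordance_class %in% CONCORDANCE_CLASSES))
})

test_that("characteristic frequencies count strict prevalence per sample", {
  tpm <- expression_matrix(
    matrix(c(1, 2, 6, 5, 4, 3,       # cancer_tx
             5, 1, 1, 1, 2, 6),      # normal_tx
           nrow = 2, byrow = TRUE,
           dimnames = list(c("A", "B"),
                           c("n1", "n2", "n3", "c1", "c2", "c3"))), "tpm")
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = colnames(tpm),
    condition = rep(c("normal", "cancer"), each = 3), cohort = "X")))
  q <- switch_frequencies(mk_switch(), tpm, samples)
  expect_equal(q$f_cancer, 2 / 3)   # cancer samples: 5>1, 4>2, 3<6
  expect_equal(q$f_normal, 1 / 3)   # normal samples: 5>1 only
  expect_equal(q$combined_freq, q$f_cancer * q$f_normal)
  expect_equal(q$legacy_score, q$f_cancer + q$f_normal - 1)

  # ties count toward neither frequency
  tpm2 <- unclass(tpm); tpm2["A", ] <- tpm2["B", ]
  q2 <- switch_frequencies(mk_switch(), expression_matrix(tpm2, "tpm"), samples)
  expect_equal(q2$f_cancer, 0)
  expect_equal(q2$f_normal, 0)
})

test_that("combined and legacy scores behave as designed, incl. the degeneracy", {
  combined <- function(fc, fn) fc * fn
  legacy <- function(fc, fn) fc + fn - 1
  expect_equal(legacy(1, 0), legacy(0.5, 0.5))       # legacy cannot separate
  expect_equal(combined(1, 0), 0)
  expect_equal(combined(0.5, 0.5), 0.25)             # product can
  set.seed(4)
  sw <- random_switch_table(50)
  expect_true(all(sw$combined_freq >= 0 & sw$combined_freq <= 1))
  expect_true(all(sw$legacy_score >= -1 & sw$legacy_score <= 1))
})

test_that("frequencies agree between TPM and usage where genes are expressed", {
  set.seed(23)
  for (i in 1:3) {
    rc <- random_cohort(n_genes = 6, n_per_gene = 3)
    vals <- unclass(rc$tpm) + 0.5   # strictly positive gene expression
    tpm <- expression_matrix(vals, "tpm")
    usage <- compute_usage(tpm, rc$annotation)
    sw <- do.call(rbind, lapply(sprintf("g%02d", 1:6), function(g) {
      mk_switch(paste0(g, ".t1"), paste0(g, ".t2"), g, "RND")
    }))
    a <- switch_frequencies(sw, tpm, rc$samples)
    b <- switch_frequencies(sw, usage, rc$samples)
    expect_identical(a[, c("f_cancer", "f_normal", "combined_freq")],
                     b[, c("f_cancer", "f_normal", "combined_freq")])
  }
})

test_that("frequencies match the brute-force counting oracle", {
  set.seed(29)
  rc <- random_cohort(n_genes = 5, n_per_gene = 2)
  sw <- do.call(rbind, lapply(sprintf("g%02d", 1:5), function(g) {
    mk_switch(paste0(g, ".t1"), paste0(g, ".t2"), g, "RND")
  }))
  got <- switch_frequencies(sw, rc$tpm, rc$samples)
  ns <- rc$samples$sample_id[rc$samples$condition == "normal"]
  cs <- rc$samples$sample_id[rc$samples$condition == "cancer"]
  for (i in seq_len(nrow(sw))) {
    ref <- bf_frequencies(unclass(rc$tpm), sw$cancer_tx[i], sw$normal_tx[i],
                          cs, ns)
    expect_equal(got$f_cancer[i], unname(ref["f_cancer"]))
    expect_equal(got$f_normal[i], unname(ref["f_normal"]))
    expect_equal(got$combined_freq[i], unname(ref["combined"]))
  }
})

test_that("frequency exceedance curves are monotone and match counting", {
  sw <- random_switch_table(25)
  fc <- frequency_curve(sw)
  expect_equal(nrow(fc), 101)
  expect_true(all(diff(fc$prop_max_freq) <= 0))
  expect_true(all(diff(fc$prop_combined) <= 0))
  i70 <- which(abs(fc$threshold - 0.7) < 1e-9)
  expect_equal(fc$prop_max_freq[i70],
               mean(pmax(sw$f_cancer, sw$f_normal) >= 0.7))
  one <- random_switch_table(1)
  one$f_cancer <- 0.6; one$f_normal <- 0.8
  one$combined_freq <- 0.48
  fc1 <- frequency_curve(one)
  expect_equal(fc1$prop_max_freq[abs(fc1$threshold - 0.7) < 1e-9], 1)
  expect_equal(fc1$prop_max_freq[abs(fc1$threshold - 0.9) < 1e-9], 0)
  expect_equal(nrow(frequency_curve(random_switch_table(0))), 0)
})

test_that("expression stratification compares low vs high baseline groups", {
  set.seed(41)
  spec <- scenario_spec(n_genes = 40,
                        planted = plant_switches(c(concordant = 8)),
                        dispersion = 30, seed = 51)
  gen <- generate_cohort(spec)
  dtu <- analyze_dtu(gen$tpm, gen$counts, gen$annotation, gen$samples)
  dte <- analyze_dte(gen$tpm, gen$counts, gen$annotation, gen$samples)
  q <- quantify_switches(identify_switches(dtu), dte, gen$tpm, gen$samples)
  strat <- suppressWarnings(
    stratify_by_expression(q, gen$tpm, gen$samples, threshold_tpm = 1))
  expect_true(all(strat$adj_p >= strat$p - 1e-12))
  # threshold 0 puts everything in the high group -> all comparisons skipped
  w <- capture_warnings(s0 <- stratify_by_expression(q, gen$tpm, gen$samples, 0))
  expect_true(all(grepl("empty low-expression group", w)))
  expect_equal(nrow(s0), 0)

  rho <- expression_effect_correlation(q, gen$tpm, gen$samples)
  expect_equal(nrow(rho), 4)
  expect_true(all(is.na(rho$rho) | abs(rho$rho) <= 1))
})

test_that("spearman correlation oracle: monotone pairs give rho = 1", {
  x <- c(1, 5, 9, 20); y <- c(0.1, 0.4, 0.9, 3)
  expect_equal(stats::cor(x, y, method = "spearman"), 1)
  # midrank-tie correlation equals rank-then-pearson
  set.seed(6)
  a <- sample(1:5, 30, TRUE); b <- sample(1:5, 30, TRUE)
  expect_equal(stats::cor(a, b, method = "spearman"),
               stats::cor(rank(a), rank(b)), tolerance = 1e-12)
})

test_that("cohort comparison battery honours conventions and sidedness", {
  set.seed(55)
  sw <- random_switch_table(60)
  sw$cohort <- rep(c("A", "B"), 30)
  out <- cohort_comparisons(sw)
  expect_true(any(grepl("kruskal_wallis", out$test)))
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_equal(out$adj_p, bf_bh(out$p), tolerance = 1e-12)

  # paired all-equal values give p = 1 by convention
  tied <- sw[sw$cohort == "A", ]
  tied$dIF_normal <- -tied$dIF_cancer
  out2 <- cohort_comparisons(tied)
  expect_equal(out2$p[out2$test == "signed_rank_abs_dIF_cancer_vs_normal"], 1)

  # planted stronger decrease of the normal transcript is detected one-sided
  bd <- random_switch_table(50)
  bd$concordance_class <- "both_down"
  bd$log2fc_cancer <- stats::rnorm(50, -0.5, 0.2)
  bd$log2fc_normal <- bd$log2fc_cancer - abs(stats::rnorm(50, 1, 0.2))
  out3 <- cohort_comparisons(bd)
  expect_lt(out3$p[out3$test == "signed_rank_lfc_normal_below_cancer_both_down"],
            0.05)
})
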