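test_that("usage is transcript TPM over gene TPM with an all-zero rule", {
  tpm <- expression_matrix(matrix(c(3, 0,
                                    1, 0,
                                    7, 5), nrow = 3, byrow = TRUE,
                                  dimnames = list(c("G1.T1", "G1.T2", "G2.T1"),
                                                  c("S1", "S2"))),
                           "tpm")
  ann <- data.frame(transcript_id = rownames(tpm),
                    gene_id = c("G1", "G1", "G2"))
  u <- compute_usage(tpm, ann)
  expect_equal(u["G1.T1", "S1"], 0.75)
  expect_equal(u["G1.T2", "S1"], 0.25)
  expect_equal(unname(u[c("G1.T1", "G1.T2"), "S2"]), c(0, 0))  # gene off
  expect_equal(unname(u["G2.T1", ]), c(1, 1))                  # single isoform
  expect_error(compute_usage(expression_matrix(unclass(tpm), "counts"), ann),
               "TPM")
})

test_that("per-gene usage sums are 1 or all-zero on random cohorts", {
  set.seed(42)
  for (i in 1:5) {
    rc <- random_cohort(n_genes = 8, n_per_gene = 3)
    vals <- unclass(rc$tpm)
    vals[sample(length(vals), 10)] <- 0
    u <- compute_usage(expression_matrix(vals, "tpm"), rc$annotation)
    sums <- rowsum(unclass(u), attr(u, "gene"))
    expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  }
})

test_that("dIF equals brute-force per-sample mean difference and is antisymmetric", {
  set.seed(7)
  rc <- random_cohort()
  u <- compute_usage(rc$tpm, rc$annotation)
  mu <- mean_usage_change(u, rc$samples, "RND")
  ns <- rc$samples$sample_id[rc$samples$condition == "normal"]
  cs <- rc$samples$sample_id[rc$samples$condition == "cancer"]
  for (t in sample(rownames(u), 5)) {
    i <- match(t, mu$transcript_id)
    expect_equal(mu$dIF[i],
                 sum(u[t, cs]) / length(cs) - sum(u[t, ns]) / length(ns),
                 tolerance = 1e-12)
  }
  flipped <- rc$samples
  flipped$condition <- factor(ifelse(flipped$condition == "normal",
                                     "cancer", "normal"),
                              levels = c("normal", "cancer"))
  mu2 <- mean_usage_change(u, flipped, "RND")
  expect_equal(mu2$dIF, -mu$dIF, tolerance = 0)
})

test_that("hand-worked mean usage example", {
  u <- matrix(c(0.2, 0.4, 0.6, 0.8), nrow = 1,
              dimnames = list("t", c("n1", "n2", "c1", "c2")))
  u <- structure(u, gene = "g", class = c("usage_matrix", "matrix", "array"))
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = colnames(u),
    condition = c("normal", "normal", "cancer", "cancer"), cohort = "X")))
  expect_equal(mean_usage_change(u, samples, "X")$dIF, 0.4)
})

test_that("expression filter applies the CPM and total-count rules", {
  n <- 6
  counts <- matrix(0, nrow = 3, ncol = n,
                   dimnames = list(c("zero", "high", "low"), paste0("s", 1:n)))
  counts["high", ] <- 100
  counts["low", ] <- c(1, 1, 1, 1, 1, 1)
  # library sizes ~1e6 via a filler transcript
  counts <- rbind(counts, filler = 1e6 - colSums(counts))
  cm <- expression_matrix(counts, "counts")
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = paste0("s", 1:n),
    condition = rep(c("normal", "cancer"), each = 3), cohort = "X")))
  kept <- filter_transcripts(cm, samples, "X")
  expect_true("high" %in% kept)       # CPM 100 >= 10, total 600 >= 15
  expect_false("zero" %in% kept)
  expect_false("low" %in% kept)       # CPM 1 < 10
  expect_setequal(filter_transcripts(cm, samples, "X", min_count = 0,
                                     min_total = 0),
                  rownames(counts))
  expect_error(filter_transcripts(cm, samples, "X", min_count = 1e9),
               "every transcript")
})

test_that("rank-sum test matches exhaustive enumeration on small groups", {
  # complete separation with within-group ties: minimum two-sided p for 3v3
  expect_equal(rank_sum_test(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1)), 0.1)
  # identical groups: convention p = 1
  expect_equal(rank_sum_test(c(0.5, 0.5), c(0.5, 0.5)), 1)
  # tie-free small samples agree with the exact wilcoxon distribution
  set.seed(13)
  for (i in 1:20) {
    x <- stats::rnorm(4); y <- stats::rnorm(5)
    expect_equal(rank_sum_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # one-sided orientation: 'greater' means first group tends larger
  expect_lt(rank_sum_test(6:9, 1:4, "greater"),
            rank_sum_test(6:9, 1:4, "less"))
})

test_that("null rank-sum p-values are approximately uniform", {
  set.seed(99)
  p <- replicate(400, rank_sum_test(stats::rnorm(25), stats::rnorm(25)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p < 0.5), 0.4)
})

test_that("global BH adjustment matches the hand step-up procedure", {
  expect_equal(adjust_global(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_global(0.04), 0.04)
  expect_identical(adjust_global(numeric(0)), numeric(0))
  set.seed(3)
  for (i in 1:10) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(adjust_global(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("external DTU adapter validates, re-adjusts and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tcohort\tp", "T1\tA\t0.01", "T2\tA\t0.5"), path)
  ext <- load_external_dtu(path)
  expect_equal(nrow(ext), 2)
  expect_equal(ext$adj_p, bf_bh(c(0.01, 0.5)))
  writeLines(c("transcript_id\tcohort", "T1\tA"), path)
  expect_error(load_external_dtu(path), "lacks column")

  # exporting the built-in results and re-importing them changes nothing
  fx <- make_fixture()
  dtu <- analyze_dtu(fx$tpm, fx$counts, fx$annotation, fx$samples,
                     filter = FALSE)
  write_tsv(dtu[, c("transcript_id", "cohort", "p", "adj_p")], path)
  dtu2 <- apply_external_dtu(dtu, load_external_dtu(path))
  expect_equal(dtu2, dtu)
})

test_that("built-in DTU stage flags the engineered switch in the fixture", {
  fx <- make_fixture()
  dtu <- analyze_dtu(fx$tpm, fx$counts, fx$annotation, fx$samples,
                     config = analysis_config(alpha = 0.2), filter = FALSE)
  expect_true(all(c("dIF", "adj_p", "usage_direction") %in% names(dtu)))
  expect_equal(dtu$dIF,
               dtu$mean_usage_cancer - dtu$mean_usage_normal,
               tolerance = 1e-12)
  g1 <- dtu[dtu$gene_id == "G1", ]
  expect_true(g1$dIF[g1$transcript_id == "G1.T2"] > 0.1)
  expect_true(g1$dIF[g1$transcript_id == "G1.T1"] < -0.1)
})
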