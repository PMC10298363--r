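test_that("filter chain applies the staged rules and ranks survivors", {
  sw <- data.frame(
    gene_id = c("g1", "g2", "g3"), cohort = "X",
    cancer_tx = c("a1", "a2", "a3"), normal_tx = c("b1", "b2", "b3"),
    dIF_cancer = 0.3, dIF_normal = -0.3,
    log2fc_cancer = c(1.5, 2, 0.5), log2fc_normal = c(-1.2, -2, -0.5),
    concordance_class = c("concordant", "concordant", "both_down"),
    f_cancer = c(0.9, 1.0, 0.9), f_normal = c(0.9, 0.0, 0.9),
    stringsAsFactors = FALSE)
  sw$combined_freq <- sw$f_cancer * sw$f_normal
  sw$legacy_score <- sw$f_cancer + sw$f_normal - 1

  rep <- filter_chain(sw, analysis_config())
  expect_equal(rep$stages$n_in[1], 3)
  expect_equal(rep$stages$n_out, c(2, 1, 1))  # class, zero-freq, min-freq
  expect_equal(rep$switches$gene_id, "g1")
  expect_equal(rep$switches$rank, 1)
  # (1.0, 0.0) pair removed exactly at the zero-combined-frequency stage
  expect_equal(rep$stages$n_in[2] - rep$stages$n_out[2], 1)

  with_lfc <- filter_chain(sw, analysis_config(lfc_filter = 1.3),
                           apply_lfc = TRUE)
  expect_equal(nrow(with_lfc$switches), 0)    # g1 fails min |lfc| 1.2 > 1.3
})

test_that("chain accounting is internally consistent and idempotent", {
  set.seed(61)
  for (i in 1:5) {
    sw <- random_switch_table(40)
    rep <- filter_chain(sw, analysis_config(), apply_lfc = TRUE)
    st <- rep$stages
    expect_true(all(st$n_out <= st$n_in))
    expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
    # re-applying the chain to its own output changes nothing
    again <- filter_chain(rep$switches, analysis_config(), apply_lfc = TRUE)
    expect_equal(again$switches$cancer_tx, rep$switches$cancer_tx)
    expect_true(all(again$stages$n_in == again$stages$n_out))
  }
})

test_that("chain output equals the brute-force predicate oracle", {
  set.seed(67)
  for (i in 1:10) {
    sw <- random_switch_table(50)
    got <- filter_chain(sw, analysis_config(), apply_lfc = TRUE)$switches
    ref <- bf_filter_chain(sw, min_combined = 0.5, lfc = 1)
    expect_equal(got$cancer_tx, ref$cancer_tx)
    expect_equal(got$combined_freq, ref$combined_freq, tolerance = 1e-12)
  }
})

test_that("anticorrelation filter keeps complementary two-isoform usage", {
  set.seed(71)
  u_vals <- stats::runif(10, 0.2, 0.8)
  usage <- structure(
    rbind(A = u_vals, B = 1 - u_vals,
          C = stats::runif(10), D = stats::runif(10)),
    class = c("usage_matrix", "matrix", "array"))
  colnames(usage) <- sprintf("s%02d", 1:10)
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = colnames(usage),
    condition = rep(c("normal", "cancer"), each = 5), cohort = "X")))
  sw <- data.frame(gene_id = c("g1", "g2"), cohort = "X",
                   cancer_tx = c("A", "C"), normal_tx = c("B", "D"),
                   stringsAsFactors = FALSE)
  kept <- anticorrelation_filter(sw, usage, samples)
  expect_equal(kept$gene_id, "g1")            # u vs 1-u has rho exactly -1

  # vacuous threshold keeps everything with a defined correlation
  expect_equal(nrow(anticorrelation_filter(sw, usage, samples,
                                           rho_threshold = 1.01)), 2)
  # constant vector: dropped with a warning
  usage["C", ] <- 0.5
  expect_warning(k2 <- anticorrelation_filter(sw, usage, samples),
                 "constant usage")
  expect_equal(k2$gene_id, "g1")
})

test_that("independent usage vectors are almost always filtered out", {
  set.seed(73)
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = sprintf("s%02d", 1:50),
    condition = rep(c("normal", "cancer"), each = 25), cohort = "X")))
  dropped <- vapply(1:50, function(i) {
    usage <- structure(rbind(A = stats::runif(50), B = stats::runif(50)),
                       class = c("usage_matrix", "matrix", "array"))
    colnames(usage) <- samples$sample_id
    sw <- data.frame(gene_id = "g", cohort = "X", cancer_tx = "A",
                     normal_tx = "B", stringsAsFactors = FALSE)
    nrow(anticorrelation_filter(sw, usage, samples)) == 0
  }, logical(1))
  expect_gte(mean(dropped), 0.99)
})

test_that("expression floor keeps transcripts clearing 1 TPM in either condition", {
  tpm <- expression_matrix(
    matrix(c(5, 5, 5, 5,       # well expressed
             0.1, 0.1, 0.1, 0.1,  # low everywhere
             1.0, 1.0, 1.0, 1.0), # exactly at the floor
           nrow = 3, byrow = TRUE,
           dimnames = list(c("hi", "lo", "edge"), c("n1", "n2", "c1", "c2"))),
    "tpm")
  samples <- suppressWarnings(validate_sample_sheet(data.frame(
    sample_id = colnames(tpm),
    condition = c("normal", "normal", "cancer", "cancer"), cohort = "X")))
  sw <- data.frame(gene_id = c("g1", "g2", "g3"), cohort = "X",
                   cancer_tx = c("hi", "hi", "edge"),
                   normal_tx = c("hi", "lo", "hi"),
                   stringsAsFactors = FALSE)
  kept <- expression_floor_filter(sw, tpm, samples)
  expect_equal(kept$gene_id, c("g1", "g3"))   # boundary mean 1.0 passes
})
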