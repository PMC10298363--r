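#' Describe a planted isoform switch
#'
#' A planted switch designates two isoforms of one gene whose usage is
#' shifted between conditions by `delta_if` (mass moved from the
#' normal-condition-dominant transcript to the cancer transcript in cancer
#' samples), together with the expression scenario the pair should realize:
#'
#' * `concordant` — cancer transcript's expected expression rises, normal
#'   transcript's falls (usage and expression move together);
#' * `cancer_not_de` — the cancer transcript's expected expression is held
#'   exactly equal across conditions (its usage gain comes entirely from the
#'   normal transcript's loss);
#' * `normal_not_de` — the normal transcript's expected expression is held
#'   equal, the cancer transcript's rises;
#' * `both_down` — total gene expression drops enough that both transcripts'
#'   expected expression falls, the normal transcript's more steeply;
#' * `both_up` — total gene expression rises enough that both transcripts'
#'   expected expression rises, the cancer transcript's more steeply.
#'
#' @param gene_id Gene to plant the switch in.
#' @param expression_class One of `concordant`, `cancer_not_de`,
#'   `normal_not_de`, `both_down`, `both_up`.
#' @param delta_if Intended shift in usage, in (0, 1). Default 0.3.
#' @param gene_fold Condition-wise multiplier on total gene expression.
#'   Defaults per class: 1 (`concordant`), 0.5 (`both_down`), 2 (`both_up`);
#'   ignored for the `*_not_de` classes where the fold is algebraically
#'   determined by the equality constraint.
#' @param cancer_tx,normal_tx Optional transcript ids; when `NA` the
#'   generator designates the gene's two major isoforms.
#' @return A list of class `planted_switch`.
#' @export
planted_switch <- function(gene_id, expression_class, delta_if = 0.3,
                           gene_fold = NULL,
                           cancer_tx = NA_character_,
                           normal_tx = NA_character_) {
  classes <- c("concordant", "cancer_not_de", "normal_not_de",
               "both_down", "both_up")
  expression_class <- match.arg(expression_class, classes)
  if (!is.finite(delta_if) || delta_if <= 0 || delta_if >= 1) {
    stop("delta_if must lie strictly inside (0, 1); a usage shift of 0 ",
         "cannot realize any differential-usage scenario")
  }
  if (is.null(gene_fold)) {
    gene_fold <- switch(expression_class,
                        both_down = 0.5, both_up = 2, 1)
  }
  if (expression_class == "both_down" && gene_fold >= 1) {
    stop("both_down requires gene_fold < 1: the cancer transcript's expected ",
         "expression changes by gene_fold (relative to its usage-driven ",
         "gain), which must fall below 1 for both transcripts to decrease")
  }
  if (expression_class == "both_up" && gene_fold <= 1) {
    stop("both_up requires gene_fold > 1: the normal transcript's expected ",
         "expression changes by gene_fold (relative to its usage-driven ",
         "loss), which must exceed 1 for both transcripts to increase")
  }
  structure(list(gene_id = gene_id, expression_class = expression_class,
                 delta_if = delta_if, gene_fold = gene_fold,
                 cancer_tx = cancer_tx, normal_tx = normal_tx),
            class = "planted_switch")
}

#' Build a list of planted switches over sequentially numbered genes
#'
#' Convenience constructor: plants `n` switches of each requested class in
#' genes `G0001`, `G0002`, ... in order.
#'
#' @param classes Named integer vector, e.g.
#'   `c(concordant = 10, both_down = 10)`.
#' @param delta_if,gene_fold Passed to [planted_switch()].
#' @return List of `planted_switch` objects.
#' @export
plant_switches <- function(classes, delta_if = 0.3, gene_fold = NULL) {
  stopifnot(length(classes) > 0, !is.null(names(classes)))
  cls <- rep(names(classes), times = classes)
  lapply(seq_along(cls), function(i) {
    planted_switch(sprintf("G%04d", i), cls[i], delta_if = delta_if,
                   gene_fold = gene_fold)
  })
}

#' Scenario specification for the synthetic cohort generator
#'
#' @param n_genes Number of multi-isoform genes to simulate.
#' @param isoforms_min,isoforms_max Range of isoforms per gene (uniformly
#'   sampled). Defaults 2-5.
#' @param n_normal,n_cancer Samples per condition. Defaults 25 and 25, the
#'   smallest cohort the pipeline is designed around.
#' @param planted List of [planted_switch()] objects (may be empty).
#' @param dispersion Negative-binomial size parameter for counts; larger
#'   means less noise. `Inf` switches the generator to its deterministic
#'   mode in which counts equal their expected values exactly. Default 10.
#' @param mean_gene_tpm_log_mu,mean_gene_tpm_log_sigma Natural-log mean and
#'   sd of the log-normal distribution of expected gene-level TPM.
#'   Defaults 4 and 1.
#' @param library_size Expected total counts per sample. Default 2e6.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_genes = 100, isoforms_min = 2, isoforms_max = 5,
                          n_normal = 25, n_cancer = 25, planted = list(),
                          dispersion = 10, mean_gene_tpm_log_mu = 4,
                          mean_gene_tpm_log_sigma = 1,
                          library_size = 2e6, seed = 1L) {
  stopifnot(n_genes >= 1, isoforms_min >= 1, isoforms_max >= isoforms_min,
            n_normal >= 1, n_cancer >= 1, dispersion > 0, library_size > 0,
            mean_gene_tpm_log_sigma >= 0)
  planted <- lapply(planted, function(p) {
    if (!inherits(p, "planted_switch")) do.call(planted_switch, p) else p
  })
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  pg <- vapply(planted, `[[`, "", "gene_id")
  if (anyDuplicated(pg)) stop("at most one planted switch per gene")
  if (length(pg) && !all(pg %in% gene_ids)) {
    stop("planted gene(s) outside the generated gene set: ",
         paste(setdiff(pg, gene_ids), collapse = ", "))
  }
  structure(list(n_genes = n_genes, isoforms_min = isoforms_min,
                 isoforms_max = isoforms_max, n_normal = n_normal,
                 n_cancer = n_cancer, planted = planted,
                 dispersion = dispersion,
                 mean_gene_tpm_log_mu = mean_gene_tpm_log_mu,
                 mean_gene_tpm_log_sigma = mean_gene_tpm_log_sigma,
                 library_size = library_size, seed = as.integer(seed)),
            class = "scenario_spec")
}

rdirichlet1 <- function(k, alpha = 2) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Baseline usage for a planted gene: symmetric Dirichlet(2) conditioned on
# feasibility of the delta_if shift (the designated normal transcript must
# hold at least delta_if + margin mass, the cancer transcript must stay
# below 1 - margin after the shift). Rejection sampling with a deterministic
# fallback for extreme shifts.
draw_planted_usage <- function(k, d, margin = 0.05, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    p <- sort(rdirichlet1(k), decreasing = TRUE)
    if (p[1] >= d + margin && p[2] + d <= 1 - margin && p[2] >= 0.02) {
      return(p)
    }
  }
  pn <- min(d + margin, 0.9)
  pc <- min(0.25, (1 - pn) * 0.8, (1 - margin) - d)
  rest <- 1 - pn - pc
  p <- c(pn, pc, if (k > 2) rep(rest / (k - 2), k - 2))
  if (k == 2) p <- c(pn, 1 - pn)
  p
}

# Target measured (post-normalization) gene-level fold for a planted gene,
# given the baseline usages of the pair. The *_not_de classes pin one
# transcript's expected expression to equality across conditions; both_down /
# both_up scale relative to the fold that would pin it.
planted_gene_fold <- function(plant, pi_c, pi_n) {
  d <- plant$delta_if
  if (pi_n - d <= 0) stop("infeasible plant: baseline usage of the normal ",
                          "transcript does not cover delta_if")
  pin_cancer <- pi_c / (pi_c + d)   # fold keeping cancer_tx expression flat
  pin_normal <- pi_n / (pi_n - d)   # fold keeping normal_tx expression flat
  f <- switch(plant$expression_class,
              concordant    = plant$gene_fold,
              cancer_not_de = pin_cancer,
              normal_not_de = pin_normal,
              both_down     = plant$gene_fold * pin_cancer,
              both_up       = plant$gene_fold * pin_normal)
  if (plant$expression_class == "concordant" &&
      (f <= pin_cancer || f >= pin_normal)) {
    stop(sprintf(paste0("infeasible concordant plant: gene_fold must lie in ",
                        "(%.4f, %.4f) so that the cancer transcript rises and ",
                        "the normal transcript falls"), pin_cancer, pin_normal))
  }
  f
}

classify_expected_folds <- function(fold_cancer, fold_normal, tol = 1e-9) {
  flat_c <- abs(fold_cancer - 1) <= tol
  flat_n <- abs(fold_normal - 1) <= tol
  if (flat_c && flat_n) return("both_not_de")
  if (flat_c) return("cancer_not_de")
  if (flat_n) return("normal_not_de")
  if (fold_cancer > 1 && fold_normal < 1) return("concordant")
  if (fold_cancer < 1 && fold_normal > 1) return("reverse")
  if (fold_cancer < 1) return("both_down")
  "both_up"
}

#' Concordance class implied by a planted switch's expected expressions
#'
#' Analytical oracle used to verify classification recovery: from the
#' baseline usages of the pair it computes the expected expression fold of
#' each transcript and maps the fold signs onto the concordance taxonomy.
#'
#' @param plant A [planted_switch()].
#' @param pi_cancer_tx,pi_normal_tx Baseline (normal-condition) usages of the
#'   cancer and normal transcript. Defaults are representative mid-range
#'   values.
#' @return A concordance class label.
#' @export
expected_class <- function(plant, pi_cancer_tx = 0.25, pi_normal_tx = 0.45) {
  f <- planted_gene_fold(plant, pi_cancer_tx, pi_normal_tx)
  d <- plant$delta_if
  classify_expected_folds(f * (pi_cancer_tx + d) / pi_cancer_tx,
                          f * (pi_normal_tx - d) / pi_normal_tx)
}

#' Generate a synthetic two-condition transcript-level cohort
#'
#' Emulates a tumor-vs-normal transcript quantification experiment: each
#' gene carries 2-5 isoforms with baseline usage drawn from a symmetric
#' Dirichlet(2); expected gene TPM is log-normal; in the cancer condition,
#' planted genes move `delta_if` usage mass from the normal transcript to
#' the cancer transcript and scale total gene expression according to the
#' planted expression class. Per-sample counts are negative binomial around
#' expected counts (expected TPM times the library share, unit transcript
#' lengths), and TPM is recomputed from counts by column normalization to
#' 1e6 — so usage and expression noise propagate exactly as they would
#' through a real quantifier's output.
#'
#' A single-isoform ballast transcript absorbs the net change in total
#' expected abundance introduced by the planted folds, keeping the
#' per-condition totals equal. Without it, within-sample TPM normalization
#' would impose a spurious global fold change on every unplanted gene.
#'
#' When `cohorts` has several labels, the gene universe, baseline usages and
#' planted effects are shared and each cohort receives independent samples,
#' mimicking several cancer types profiled against the same annotation.
#'
#' @param spec A [scenario_spec()].
#' @param cohorts Character vector of cohort labels. Default `"SIM"`.
#' @return A list with elements `counts` and `tpm`
#'   ([expression_matrix()]s), `annotation` (tx2gene data.frame), `samples`
#'   (sample sheet data.frame) and `truth` (one row per planted switch per
#'   cohort, carrying the intended shift, the expected expression folds of
#'   both transcripts and the analytically expected concordance class and
#'   characteristic frequencies).
#' @export
generate_cohort <- function(spec, cohorts = "SIM") {
  stopifnot(inherits(spec, "scenario_spec"), length(cohorts) >= 1,
            !anyDuplicated(cohorts))
  set.seed(spec$seed)

  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  k <- sample(spec$isoforms_min:spec$isoforms_max, spec$n_genes, replace = TRUE)
  names(k) <- gene_ids
  planted_genes <- vapply(spec$planted, `[[`, "", "gene_id")
  k[planted_genes] <- pmax(k[planted_genes], 2L)

  tx_gene <- rep(gene_ids, times = k)
  tx_ids <- unlist(lapply(seq_len(spec$n_genes), function(i) {
    sprintf("%s.T%d", gene_ids[i], seq_len(k[i]))
  }), use.names = FALSE)

  gene_tpm <- stats::rlnorm(spec$n_genes, spec$mean_gene_tpm_log_mu,
                            spec$mean_gene_tpm_log_sigma)
  names(gene_tpm) <- gene_ids

  plant_of <- setNames(spec$planted, planted_genes)
  usage_normal <- numeric(length(tx_ids))
  usage_cancer <- numeric(length(tx_ids))
  names(usage_normal) <- names(usage_cancer) <- tx_ids

  truth_rows <- list()
  offset <- 0L
  for (i in seq_len(spec$n_genes)) {
    g <- gene_ids[i]
    idx <- offset + seq_len(k[i])
    offset <- offset + k[i]
    plant <- plant_of[[g]]
    if (is.null(plant)) {
      p <- rdirichlet1(k[i])
      usage_normal[idx] <- p
      usage_cancer[idx] <- p
      next
    }
    d <- plant$delta_if
    p <- draw_planted_usage(k[i], d)      # sorted: p[1] -> normal_tx
    i_n <- 1L; i_c <- 2L
    ntx <- if (is.na(plant$normal_tx)) tx_ids[idx][i_n] else plant$normal_tx
    ctx <- if (is.na(plant$cancer_tx)) tx_ids[idx][i_c] else plant$cancer_tx
    if (!is.na(plant$normal_tx) || !is.na(plant$cancer_tx)) {
      i_n <- match(ntx, tx_ids[idx]); i_c <- match(ctx, tx_ids[idx])
      if (anyNA(c(i_n, i_c)) || i_n == i_c) {
        stop("planted pair for gene ", g,
             " must name two distinct isoforms of that gene")
      }
      # put largest mass on normal_tx, second largest on cancer_tx
      srt <- sort(p, decreasing = TRUE)
      p <- rep(NA_real_, k[i])
      p[i_n] <- srt[1]; p[i_c] <- srt[2]
      p[is.na(p)] <- srt[-(1:2)]
    }
    q <- p
    q[i_n] <- p[i_n] - d
    q[i_c] <- p[i_c] + d
    usage_normal[idx] <- p
    usage_cancer[idx] <- q
    fold <- planted_gene_fold(plant, p[i_c], p[i_n])
    fc <- fold * q[i_c] / p[i_c]
    fn <- fold * q[i_n] / p[i_n]
    truth_rows[[g]] <- data.frame(
      gene_id = g, cancer_tx = tx_ids[idx][i_c], normal_tx = tx_ids[idx][i_n],
      delta_if = d, expression_class = plant$expression_class,
      gene_fold = plant$gene_fold, measured_gene_fold = fold,
      usage_cancer_tx = p[i_c], usage_normal_tx = p[i_n],
      fold_cancer_tx = fc, fold_normal_tx = fn,
      expected_class = classify_expected_folds(fc, fn),
      expected_f_cancer = as.numeric(q[i_c] > q[i_n]),
      expected_f_normal = as.numeric(p[i_n] > p[i_c]),
      stringsAsFactors = FALSE)
  }

  # Expected abundances on a common scale; measured gene fold in cancer.
  meas_fold <- rep(1, spec$n_genes)
  names(meas_fold) <- gene_ids
  for (g in names(truth_rows)) meas_fold[g] <- truth_rows[[g]]$measured_gene_fold

  abund_normal <- gene_tpm[tx_gene] * usage_normal
  abund_cancer <- gene_tpm[tx_gene] * meas_fold[tx_gene] * usage_cancer

  # Ballast transcript equalizes per-condition totals so that column
  # normalization does not distort unplanted genes' folds.
  delta <- sum(abund_cancer) - sum(abund_normal)
  ballast <- max(2 * abs(delta), 0.05 * sum(abund_normal))
  tx_ids <- c(tx_ids, "BALLAST.T1")
  tx_gene <- c(tx_gene, "BALLAST")
  abund_normal <- c(abund_normal, ballast)
  abund_cancer <- c(abund_cancer, ballast - delta)

  total <- sum(abund_normal)
  exp_tpm <- cbind(normal = abund_normal, cancer = abund_cancer) / total * 1e6

  n_n <- spec$n_normal; n_c <- spec$n_cancer
  sample_ids <- unlist(lapply(cohorts, function(ch) {
    c(sprintf("%s_N%03d", ch, seq_len(n_n)), sprintf("%s_C%03d", ch, seq_len(n_c)))
  }), use.names = FALSE)
  cond <- rep(rep(c("normal", "cancer"), c(n_n, n_c)), length(cohorts))
  cohort_col <- rep(cohorts, each = n_n + n_c)

  mu <- exp_tpm[, ifelse(cond == "normal", 1L, 2L), drop = FALSE] *
    (spec$library_size / 1e6)
  dimnames(mu) <- list(tx_ids, sample_ids)
  if (is.finite(spec$dispersion)) {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = spec$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    counts <- counts * 1.0
  } else {
    counts <- mu   # deterministic mode: counts equal their expectations
  }
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  tpm <- sweep(counts, 2, cs, "/") * 1e6

  truth <- if (length(truth_rows)) {
    one <- do.call(rbind, truth_rows[order(names(truth_rows))])
    do.call(rbind, lapply(cohorts, function(ch) {
      cbind(cohort = ch, one, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cohort = character(), gene_id = character(),
               cancer_tx = character(), normal_tx = character(),
               delta_if = numeric(), expression_class = character(),
               gene_fold = numeric(), measured_gene_fold = numeric(),
               usage_cancer_tx = numeric(), usage_normal_tx = numeric(),
               fold_cancer_tx = numeric(), fold_normal_tx = numeric(),
               expected_class = character(), expected_f_cancer = numeric(),
               expected_f_normal = numeric(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL

  samples <- data.frame(sample_id = sample_ids,
                        condition = factor(cond, levels = c("normal", "cancer")),
                        cohort = cohort_col, stringsAsFactors = FALSE)
  list(counts = expression_matrix(counts, "counts"),
       tpm = expression_matrix(tpm, "tpm"),
       annotation = data.frame(transcript_id = tx_ids, gene_id = tx_gene,
                               stringsAsFactors = FALSE),
       samples = samples,
       truth = truth)
}
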