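#' Run the whole isoform-switch analysis end to end
#'
#' Orchestrates every stage: (optional) cohort simulation or input loading,
#' usage computation, expression filtering, differential usage and
#' expression testing with one global BH correction each, switch pairing,
#' concordance classification, frequency scoring, the summary statistics
#' battery, and the prioritization chain. Each stage's table is written to
#' `outdir` before the next stage begins, and a JSON run manifest records
#' the configuration, seed, file digests and per-stage row counts; built-in
#' stages are pure functions of (inputs, configuration, seed), so a rerun
#' with the same manifest reproduces the tables byte for byte.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' blocks `analysis` (see [analysis_config()]), either `simulate` (see
#' [scenario_spec()]; fields `planted` and `cohorts` as in
#' [generate_cohort()]) or `inputs` (paths `tpm`, `counts`, `tx2gene`,
#' `samples`, optional `tx2gene_format`), optional `external` (paths `dtu`,
#' `dte` to adapter tables) and optional `prioritize` (logicals
#' `apply_min_combined`, `apply_lfc`, `anticorrelation`, numeric
#' `tpm_floor`).
#'
#' @param config Path to a YAML configuration or a nested list.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(analysis_config,
                 config$analysis %||% list())
  log_stage <- function(fmt, ...) message(sprintf(paste0("[switchquant] ", fmt), ...))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cohorts <- sim$cohorts %||% "SIM"
    sim$cohorts <- NULL
    if (!is.null(sim$planted)) {
      sim$planted <- lapply(sim$planted, function(p) do.call(planted_switch, p))
    }
    if (is.null(sim$seed)) sim$seed <- cfg$seed
    spec <- do.call(scenario_spec, sim)
    log_stage("simulating cohort(s) %s (seed %d)",
              paste(cohorts, collapse = ","), spec$seed)
    gen <- generate_cohort(spec, cohorts)
    tpm <- gen$tpm; counts <- gen$counts
    annotation <- gen$annotation; samples <- gen$samples; truth <- gen$truth
    write_expression_matrix(counts, file.path(outdir, "counts.tsv"))
    write_expression_matrix(tpm, file.path(outdir, "tpm.tsv"))
    write_tsv(annotation, file.path(outdir, "tx2gene.tsv"))
    write_sample_sheet(samples, file.path(outdir, "samples.tsv"))
    write_tsv(truth, file.path(outdir, "truth.tsv"))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    need <- c("tpm", "counts", "tx2gene", "samples")
    miss <- setdiff(need, names(inp))
    if (length(miss)) stop("config inputs block lacks: ", paste(miss, collapse = ", "))
    log_stage("loading inputs")
    tpm <- read_expression_matrix(inp$tpm, "tpm")
    counts <- read_expression_matrix(inp$counts, "counts")
    annotation <- read_tx2gene(inp$tx2gene, inp$tx2gene_format %||% "tsv")
    samples <- read_sample_sheet(inp$samples)
  } else {
    stop("config must contain either a 'simulate' or an 'inputs' block")
  }
  check_matching_keys(counts, tpm)
  check_annotation_total(tpm, annotation)

  log_stage("differential transcript usage (%d cohorts)",
            length(unique(samples$cohort)))
  dtu <- analyze_dtu(tpm, counts, annotation, samples, cfg)
  if (!is.null(config$external$dtu)) {
    dtu <- apply_external_dtu(dtu, load_external_dtu(config$external$dtu), cfg)
  }
  write_tsv(dtu, file.path(outdir, "dtu_results.tsv"))
  log_stage("DTU: %d tests, %d significant directions", nrow(dtu),
            sum(dtu$usage_direction != "none"))

  dte <- analyze_dte(tpm, counts, annotation, samples, cfg)
  if (!is.null(config$external$dte)) {
    dte <- apply_external_dte(dte, load_external_dte(config$external$dte), cfg)
  }
  write_tsv(dte, file.path(outdir, "dte_results.tsv"))
  log_stage("DTE: %d tests, %d DE calls", nrow(dte), sum(dte$de_flag))

  switches <- identify_switches(dtu, cfg)
  write_tsv(switches, file.path(outdir, "switches.tsv"))
  cnt <- count_switches(switches)
  log_stage("switches: %d events, %d genes, %d unique pairs",
            cnt$n_switches, cnt$n_genes, cnt$n_pairs)

  quantified <- quantify_switches(switches, dte, tpm, samples)
  write_tsv(quantified, file.path(outdir, "switches_quantified.tsv"))
  write_tsv(class_summary(quantified), file.path(outdir, "class_summary.tsv"))
  write_tsv(frequency_curve(quantified), file.path(outdir, "frequency_curve.tsv"))
  battery <- if (nrow(quantified)) cohort_comparisons(quantified) else NULL
  if (!is.null(battery)) write_tsv(battery, file.path(outdir, "stats_battery.tsv"))

  usage <- compute_usage(tpm, annotation)
  pri_cfg <- config$prioritize %||% list()
  report <- filter_chain(quantified, cfg,
                         apply_min_combined = pri_cfg$apply_min_combined %||% TRUE,
                         apply_lfc = pri_cfg$apply_lfc %||% FALSE)
  pri <- report$switches
  if (isTRUE(pri_cfg$anticorrelation)) {
    pri <- anticorrelation_filter(pri, usage, samples, cfg$rho_threshold)
  }
  if (!is.null(pri_cfg$tpm_floor)) {
    pri <- expression_floor_filter(pri, tpm, samples, pri_cfg$tpm_floor)
  }
  write_tsv(pri, file.path(outdir, "prioritized.tsv"))
  jsonlite::write_json(list(stages = report$stages, n_retained = nrow(pri)),
                       file.path(outdir, "filter_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_stage("prioritization: %d switch(es) retained", nrow(pri))

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate_against_truth(quantified, truth)
    write_tsv(evaluation, file.path(outdir, "evaluation.tsv"))
  }

  tables <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    tool = "switchquant",
    version = as.character(utils::packageVersion("switchquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = config,
    digests = as.list(tools::md5sum(sort(tables))),
    rows = list(dtu = nrow(dtu), dte = nrow(dte), switches = nrow(switches),
                prioritized = nrow(pri)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = cfg, tpm = tpm, counts = counts,
                 annotation = annotation, samples = samples, truth = truth,
                 dtu = dtu, dte = dte, switches = switches,
                 quantified = quantified, battery = battery,
                 filter_report = report, prioritized = pri,
                 evaluation = evaluation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark a detected switch set against the generator's ground truth
#'
#' Detected switches are matched to planted switches by
#' (cohort, gene, cancer transcript, normal transcript).
#'
#' @param switches Quantified switch table.
#' @param truth Truth table from [generate_cohort()].
#' @return One-row data.frame: `n_planted`, `n_detected`, `n_matched`,
#'   `sensitivity` (matched / planted, `NA` with nothing planted),
#'   `fdr` (unmatched / detected, 0 when nothing was detected),
#'   `class_accuracy` (share of matched switches assigned their expected
#'   concordance class) and `freq_rmse` (root-mean-square difference
#'   between the observed combined frequency and the one implied by the
#'   generator's expected expression ordering).
#' @export
evaluate_against_truth <- function(switches, truth) {
  key <- function(df, ctx, ntx) paste(df$cohort, df$gene_id, df[[ctx]], df[[ntx]])
  det <- key(switches, "cancer_tx", "normal_tx")
  pla <- key(truth, "cancer_tx", "normal_tx")
  hit <- match(det, pla)
  n_matched <- sum(!is.na(hit))
  matched <- switches[!is.na(hit), , drop = FALSE]
  mtruth <- truth[hit[!is.na(hit)], , drop = FALSE]
  class_acc <- if (n_matched && "concordance_class" %in% names(matched)) {
    mean(matched$concordance_class == mtruth$expected_class)
  } else NA_real_
  freq_rmse <- if (n_matched && "combined_freq" %in% names(matched)) {
    sqrt(mean((matched$combined_freq -
                 mtruth$expected_f_cancer * mtruth$expected_f_normal)^2))
  } else NA_real_
  data.frame(
    n_planted = nrow(truth), n_detected = nrow(switches),
    n_matched = n_matched,
    sensitivity = if (nrow(truth)) n_matched / nrow(truth) else NA_real_,
    fdr = if (nrow(switches)) (nrow(switches) - n_matched) / nrow(switches) else 0,
    class_accuracy = class_acc, freq_rmse = freq_rmse)
}
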