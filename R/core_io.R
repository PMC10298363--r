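#' Construct an expression matrix
#'
#' An expression matrix holds non-negative transcript-level values
#' (transcripts as rows, samples as columns) tagged with the unit they are
#' measured in: `"tpm"` (transcripts per million) or `"counts"` (raw
#' estimated counts). All downstream joins are keyed by the row and column
#' names, never by position.
#'
#' @param values Numeric matrix with unique, non-empty rownames (transcript
#'   identifiers) and colnames (sample identifiers). Missing values are not
#'   allowed; absence of expression must be encoded as 0.
#' @param kind Either `"tpm"` or `"counts"`.
#' @return A numeric matrix of class `expression_matrix` with attribute
#'   `kind`.
#' @export
expression_matrix <- function(values, kind = c("tpm", "counts")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  tx <- rownames(values)
  smp <- colnames(values)
  if (is.null(tx) || is.null(smp) || any(!nzchar(tx)) || any(!nzchar(smp))) {
    stop("`values` must have non-empty rownames (transcripts) and colnames (samples)")
  }
  if (anyDuplicated(tx)) {
    stop("duplicated transcript id(s): ",
         paste(unique(tx[duplicated(tx)]), collapse = ", "))
  }
  if (anyDuplicated(smp)) {
    stop("duplicated sample id(s): ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at transcript '%s', sample '%s'",
                 tx[bad[1]], smp[bad[2]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at transcript '%s', sample '%s'",
                 tx[bad[1]], smp[bad[2]]))
  }
  structure(values, kind = kind, class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d transcripts x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Kind ("tpm" or "counts") of an expression matrix
#' @param x An `expression_matrix`.
#' @return `"tpm"` or `"counts"`.
#' @export
matrix_kind <- function(x) attr(x, "kind")

#' Read a transcript-by-sample expression matrix from TSV
#'
#' The file must be tab-delimited with a header row of sample identifiers and
#' a first column of transcript identifiers. Duplicated identifiers, missing
#' cells, non-numeric cells and negative values are hard errors.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, kind = c("tpm", "counts")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression matrix needs an id column plus >=1 sample column")
  tx <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing cell at transcript '%s', column '%s'",
                 tx[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  dimnames(num) <- list(tx, colnames(vals))
  expression_matrix(num, kind)
}

#' Write an expression matrix to TSV
#'
#' Values are written with up to 10 significant digits so that a write/read
#' round trip reproduces them bit-identically at that precision.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(transcript_id = rownames(x),
                   format(unclass(x), digits = 10, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene map
#'
#' Accepts either a two-column TSV (`transcript_id`, `gene_id`, with header)
#' or a GTF file in the GENCODE attribute dialect, from which only
#' feature-type `transcript` records are used. A transcript mapped to two
#' distinct genes is a hard error.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gtf"`.
#' @return A data.frame with columns `transcript_id` and `gene_id`.
#' @export
read_tx2gene <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) < 2) stop("tx2gene TSV needs columns transcript_id, gene_id")
    map <- data.frame(transcript_id = df[[1]], gene_id = df[[2]],
                      stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF annotation requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "transcript"]
    if (length(gr) == 0) stop("GTF contains no transcript-typed records")
    tx <- gr$transcript_id
    gn <- gr$gene_id
    if (is.null(tx) || anyNA(tx) || any(!nzchar(tx))) {
      stop("GTF transcript feature lacking a transcript_id attribute")
    }
    if (is.null(gn) || anyNA(gn) || any(!nzchar(gn))) {
      stop("GTF transcript feature lacking a gene_id attribute")
    }
    map <- unique(data.frame(transcript_id = as.character(tx),
                             gene_id = as.character(gn),
                             stringsAsFactors = FALSE))
  }
  validate_tx2gene(map)
}

validate_tx2gene <- function(map) {
  dup <- unique(map$transcript_id[duplicated(map$transcript_id)])
  if (length(dup)) {
    # duplicates pointing at the same gene collapse; distinct genes are fatal
    map <- unique(map)
    dup <- unique(map$transcript_id[duplicated(map$transcript_id)])
    if (length(dup)) {
      stop("transcript(s) mapped to more than one gene: ",
           paste(dup, collapse = ", "))
    }
  }
  rownames(map) <- NULL
  map
}

#' Read a sample sheet
#'
#' The TSV must carry columns `sample_id`, `condition` and `cohort`.
#' Condition values are normalized case-insensitively to `normal` / `cancer`;
#' anything else is a hard error. A warning is emitted for any cohort with
#' fewer than 25 samples in either condition, the minimum cohort size the
#' pipeline is designed around.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `sample_id`, `condition` (factor with
#'   levels `normal`, `cancer`) and `cohort`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("sample_id", "condition", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no samples in sample sheet")
  validate_sample_sheet(df[, need])
}

validate_sample_sheet <- function(df) {
  if (nrow(df) == 0) stop("no samples in sample sheet")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  cond <- tolower(trimws(df$condition))
  bad <- setdiff(unique(cond), c("normal", "cancer"))
  if (length(bad)) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "),
         "; allowed values are 'normal' and 'cancer'")
  }
  out <- data.frame(sample_id = df$sample_id,
                    condition = factor(cond, levels = c("normal", "cancer")),
                    cohort = as.character(df$cohort),
                    stringsAsFactors = FALSE)
  tab <- table(out$cohort, out$condition)
  if (any(tab == 0)) {
    lack <- rownames(tab)[apply(tab == 0, 1, any)]
    stop("cohort(s) missing a condition: ", paste(lack, collapse = ", "))
  }
  if (any(tab < 25)) {
    small <- rownames(tab)[apply(tab < 25, 1, any)]
    warning("cohort(s) with fewer than 25 samples per condition: ",
            paste(small, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Write a sample sheet to TSV
#' @param samples A validated sample sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- samples
  out$condition <- as.character(out$condition)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#'
#' @param dif_threshold Minimum absolute change in mean transcript usage
#'   (isoform fraction) for a transcript to count as up- or down-used.
#'   Default 0.1.
#' @param alpha Significance level applied to globally adjusted p-values of
#'   both the usage and the expression tests. Default 0.05.
#' @param low_expression_tpm Mean-TPM threshold (in normal samples)
#'   separating lowly from highly expressed transcripts. Default 1.
#' @param lfc_filter Optional minimum absolute log2 fold change required of
#'   both transcripts in the prioritization chain. Default 1.
#' @param min_combined_freq Optional minimum combined frequency (strictly
#'   greater than) for the prioritization chain. Default 0.5.
#' @param rho_threshold Spearman correlation ceiling for the usage
#'   anticorrelation filter; switches are kept when the correlation of the
#'   two transcripts' usage vectors falls below it. Default -0.8.
#' @param pseudocount Pseudocount added to mean TPM before taking log2 fold
#'   changes. Default 0.01.
#' @param seed Integer seed recorded in run manifests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(dif_threshold = 0.1, alpha = 0.05,
                            low_expression_tpm = 1.0, lfc_filter = 1.0,
                            min_combined_freq = 0.5, rho_threshold = -0.8,
                            pseudocount = 0.01, seed = 1L) {
  stopifnot(dif_threshold > 0, alpha > 0, alpha < 1, pseudocount > 0,
            low_expression_tpm >= 0)
  structure(list(dif_threshold = dif_threshold, alpha = alpha,
                 low_expression_tpm = low_expression_tpm,
                 lfc_filter = lfc_filter,
                 min_combined_freq = min_combined_freq,
                 rho_threshold = rho_threshold, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path Path to the YAML file.
#' @return For `read_analysis_config`, an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw[intersect(names(raw), names(formals(analysis_config)))])
}

#' @rdname read_analysis_config
#' @param config An [analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Check that a tx2gene map covers every transcript of a matrix.
check_annotation_total <- function(x, annotation) {
  miss <- setdiff(rownames(x), annotation$transcript_id)
  if (length(miss)) {
    stop("transcripts absent from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  invisible(TRUE)
}

# Check that counts and TPM matrices share identical keys.
check_matching_keys <- function(counts, tpm) {
  if (!identical(rownames(counts), rownames(tpm)) ||
      !identical(colnames(counts), colnames(tpm))) {
    stop("counts and TPM matrices must share identical transcript and sample keys")
  }
  invisible(TRUE)
}

# Align a sample sheet with a matrix, warning about sheet samples the
# matrix lacks and dropping matrix columns the sheet does not describe.
align_samples <- function(x, samples) {
  miss <- setdiff(samples$sample_id, colnames(x))
  if (length(miss)) {
    warning("sample(s) in sheet absent from matrix: ",
            paste(miss, collapse = ", "))
    samples <- samples[samples$sample_id %in% colnames(x), , drop = FALSE]
  }
  samples
}

cohort_samples <- function(samples, cohort) {
  sub <- samples[samples$cohort == cohort, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown cohort: ", cohort)
  sub
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
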