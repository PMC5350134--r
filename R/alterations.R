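# Expression-alteration calling: z-statistics of each patient's
# expression against a designated reference (diploid/normal) sample
# pool, thresholded at |z| > 1.96 (outside the 95% confidence interval).

#' Construct an expression matrix with a designated reference pool
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param reference_samples character vector of column names forming the
#'   reference (diploid/normal) pool against which z-statistics are
#'   computed; the remaining columns are the patients.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, reference_samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample ids in expression matrix")
  reference_samples <- as.character(reference_samples)
  missing_ref <- setdiff(reference_samples, colnames(values))
  if (length(missing_ref))
    stop_format("reference sample(s) absent from matrix: %s",
                paste(missing_ref, collapse = ", "))
  if (length(reference_samples) < 2L)
    stop_format("at least 2 reference samples are required")
  structure(list(values = values, reference_samples = reference_samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d reference, %d patient)\n",
              nrow(x$values), ncol(x$values), length(x$reference_samples),
              ncol(x$values) - length(x$reference_samples)))
  invisible(x)
}

#' Read an expression TSV (first column gene id, then one column per sample)
#'
#' @param path expression TSV path.
#' @param reference_samples character vector of reference sample ids, or
#'   the path of a one-id-per-line file.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, reference_samples) {
  if (length(reference_samples) == 1L && file.exists(reference_samples))
    reference_samples <- readLines(reference_samples)
  reference_samples <- trimws(reference_samples)
  reference_samples <- reference_samples[nzchar(reference_samples)]
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tab[[1L]])
  expression_matrix(vals, reference_samples)
}

#' Per-patient z-statistics against the reference pool
#'
#' For each gene g and non-reference sample p,
#' `z[g, p] = (x[g, p] - mean_ref[g]) / sd_ref[g]`, with mean and sd
#' taken over the reference samples of gene g (sample sd, n - 1
#' denominator). A gene whose reference pool has zero or inestimable
#' standard deviation yields an all-missing row and a warning naming it.
#'
#' @param em an [expression_matrix()].
#' @return numeric matrix of z-statistics, genes x patients.
#' @export
compute_zscores <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  ref <- em$values[, em$reference_samples, drop = FALSE]
  patients <- setdiff(colnames(em$values), em$reference_samples)
  if (length(patients) == 0L) stop_format("no non-reference samples present")
  x <- em$values[, patients, drop = FALSE]
  m <- rowMeans(ref, na.rm = TRUE)
  s <- apply(ref, 1L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(s) | s <= 0 | !is.finite(m)
  if (any(bad)) {
    warning(sprintf("zero or inestimable reference sd for gene(s): %s",
                    paste(rownames(x)[bad], collapse = ", ")))
    s[bad] <- NA_real_
  }
  (x - m) / s
}

#' Call expression alterations from z-statistics
#'
#' A call is positive iff `|z| > threshold` (strict inequality; the
#' default 1.96 marks values outside the central 95% of the reference
#' distribution). Missing z-statistics give a negative call and are
#' tracked in the `missing` slot so downstream stratification can
#' exclude patients with no usable measurement.
#'
#' @param zscores genes x patients z matrix from [compute_zscores()].
#' @param threshold positive alteration threshold (default 1.96).
#' @return an object of class `alteration_matrix`: `list(calls, zscores,
#'   missing, threshold)`, all matrices genes x patients.
#' @export
call_alterations <- function(zscores, threshold = 1.96) {
  check_positive_scalar(threshold, "threshold")
  stopifnot(is.matrix(zscores))
  miss <- is.na(zscores)
  calls <- abs(zscores) > threshold
  calls[miss] <- FALSE
  structure(list(calls = calls, zscores = zscores, missing = miss,
                 threshold = threshold),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf(
    "alteration_matrix: %d genes x %d patients, |z| > %g; %d call(s), %d missing value(s)\n",
    nrow(x$calls), ncol(x$calls), x$threshold, sum(x$calls), sum(x$missing)))
  invisible(x)
}

#' Per-patient positivity for a gene subset
#'
#' A patient is positive for a subset iff ANY subset gene carries an
#' alteration call ("any or all of the genes" rule). A patient whose
#' z-statistics are missing for every subset gene is neither positive
#' nor negative: the returned value is `NA`, and such patients are
#' excluded from that subset's survival stratification.
#'
#' @param am an [call_alterations()] result.
#' @param subset non-empty character vector of gene symbols, all present
#'   in `rownames(am$calls)`.
#' @return named logical vector over patients (`NA` = no usable data).
#' @export
subset_positivity <- function(am, subset) {
  stopifnot(inherits(am, "alteration_matrix"))
  if (length(subset) == 0L) stop_format("'subset' must be non-empty")
  unknown <- setdiff(subset, rownames(am$calls))
  if (length(unknown))
    stop_format("gene(s) not in alteration matrix: %s",
                paste(unknown, collapse = ", "))
  calls <- am$calls[subset, , drop = FALSE]
  miss <- am$missing[subset, , drop = FALSE]
  pos <- colSums(calls) > 0L
  pos[colSums(!miss) == 0L] <- NA
  pos
}

#' Write alteration calls and their z-score twin as TSVs
#'
#' @param am an `alteration_matrix`.
#' @param calls_path,zscores_path output paths (gene rows, patient
#'   columns; calls as 0/1, missing z as NA).
#' @return invisibly, the two paths.
#' @export
write_alterations <- function(am, calls_path, zscores_path) {
  stopifnot(inherits(am, "alteration_matrix"))
  wr <- function(m, path) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  calls <- am$calls * 1L
  calls[am$missing] <- NA_integer_
  wr(calls, calls_path)
  wr(round(am$zscores, 6L), zscores_path)
  invisible(c(calls_path, zscores_path))
}
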