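# Exhaustive subset ranking: enumerate every non-empty subset of the
# core gene set, stratify patients by any-gene alteration positivity,
# and rank subsets by the two-group log-rank p-value against
# disease-free survival, producing the DFS landscape and the optimal
# gene set (OGS).

#' Number of non-empty subsets of an n-element set
#'
#' @param n set size (non-negative integer).
#' @return `2^n - 1` (the size of the power set minus the empty set).
#' @export
count_nonempty_subsets <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop_format("'n' must be a single non-negative integer")
  if (n > 52) stop_format("2^n - 1 exceeds exact double precision for n > 52")
  2^n - 1
}

#' Number of k-element subsets of an n-element set
#'
#' @param n set size; @param k subset size, `0 <= k <= n`.
#' @return the binomial coefficient `C(n, k)` as an exact integer-valued
#'   double.
#' @export
count_k_subsets <- function(n, k) {
  if (!is.numeric(n) || !is.numeric(k) || length(n) != 1L || length(k) != 1L ||
      n < 0 || k < 0 || n != floor(n) || k != floor(k))
    stop_format("'n' and 'k' must be single non-negative integers")
  if (k > n) stop_format("'k' must not exceed 'n'")
  round(choose(n, k))
}

#' Lazily enumerate gene subsets
#'
#' In `powerset` mode yields every non-empty subset exactly once in
#' ascending-bitmask order (bit i = gene i of the input order); in
#' `ksubsets` mode yields all `C(n, k)` subsets of size `k` in
#' lexicographic index order. Enumeration is lazy: each call to `$nxt()`
#' returns the next subset (a character vector) or `NULL` when
#' exhausted, holding O(n) state.
#'
#' @param genes duplicate-free character vector.
#' @param mode "powerset" or "ksubsets".
#' @param k subset size (ksubsets mode only).
#' @param allow_large powerset mode refuses n > 25 (an exponential
#'   blowup guard) unless this is TRUE.
#' @return an object of class `subset_iterator` with elements `nxt`
#'   (function), `length`, `genes`, `mode`. Use [subset_list()] to
#'   materialize all subsets.
#' @export
enumerate_subsets <- function(genes, mode = c("powerset", "ksubsets"),
                              k = NULL, allow_large = FALSE) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_format("'genes' must be non-empty")
  if (anyDuplicated(genes))
    stop_format("duplicate gene(s): %s",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
  n <- length(genes)
  if (mode == "powerset") {
    if (n > 25 && !allow_large)
      stop_format("powerset over %d genes is 2^%d - 1 subsets; pass allow_large = TRUE to proceed", n, n)
    total <- count_nonempty_subsets(n)
    mask <- 0
    nxt <- function() {
      if (mask >= total) return(NULL)
      mask <<- mask + 1
      genes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    }
  } else {
    if (is.null(k)) stop_format("'k' is required in ksubsets mode")
    total <- count_k_subsets(n, k)
    idx <- NULL
    nxt <- function() {
      if (k == 0L) return(NULL)
      if (is.null(idx)) {
        idx <<- seq_len(k)
        return(genes[idx])
      }
      # advance the rightmost index that can still move
      j <- k
      while (j >= 1L && idx[j] == n - k + j) j <- j - 1L
      if (j < 1L) return(NULL)
      idx[j] <<- idx[j] + 1L
      if (j < k) idx[(j + 1L):k] <<- idx[j] + seq_len(k - j)
      genes[idx]
    }
  }
  structure(list(nxt = nxt, length = total, genes = genes, mode = mode),
            class = "subset_iterator")
}

#' Materialize a subset iterator into a list
#' @param it a [enumerate_subsets()] iterator.
#' @return list of character vectors, in enumeration order.
#' @export
subset_list <- function(it) {
  stopifnot(inherits(it, "subset_iterator"))
  out <- vector("list", it$length)
  i <- 0L
  while (!is.null(s <- it$nxt())) {
    i <- i + 1L
    out[[i]] <- s
  }
  out[seq_len(i)]
}

#' Rank gene subsets by log-rank association with disease-free survival
#'
#' For every candidate subset, patients are stratified by subset
#' positivity (altered in ANY member gene); the two strata are compared
#' with the Mantel-Haenszel log-rank test on DFS. Subsets are ranked by
#' ascending p-value, ties broken by smaller subset then ascending
#' bitmask (parsimony first). Degenerate stratifications (every usable
#' patient in one stratum) receive sentinel p = 1 and sort after all
#' tested subsets. Raw p-values are the ranking key, as in the original
#' procedure; Bonferroni and Benjamini-Hochberg columns are carried as
#' extensions for reference only.
#'
#' @param am an [call_alterations()] alteration matrix.
#' @param clinical clinical data.frame (see [read_clinical()]) with
#'   `patient_id`, `dfs_months`, `event`.
#' @param subsets subsets to evaluate: a [enumerate_subsets()] iterator,
#'   a list of character vectors, or NULL (default) for the full power
#'   set of the alteration matrix's genes.
#' @param alpha significance level for flagging (default 0.05).
#' @param min_group strata smaller than this are flagged underpowered
#'   but still tested (default 5).
#' @return an object of class `landscape_ranking`: `results` data.frame
#'   (one row per subset, in rank order), `ogs` (the rank-1 subset),
#'   `significant` (rows with p < alpha, non-degenerate), `alpha`,
#'   `genes`, `n_patients_used`.
#' @export
rank_subsets <- function(am, clinical, subsets = NULL, alpha = 0.05,
                         min_group = 5L) {
  stopifnot(inherits(am, "alteration_matrix"))
  if (!is.data.frame(clinical) ||
      !all(c("dfs_months", "event") %in% names(clinical)))
    stop_format("clinical table lacks 'dfs_months'/'event' columns")
  if (!"patient_id" %in% names(clinical))
    clinical$patient_id <- as.character(seq_len(nrow(clinical)))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_format("'alpha' must lie in (0, 1)")

  patients <- intersect(colnames(am$calls), clinical$patient_id)
  if (length(patients) == 0L)
    stop_format("no patient ids shared between alteration matrix and clinical table")
  n_drop <- (ncol(am$calls) - length(patients)) +
    (nrow(clinical) - length(patients))
  if (n_drop > 0L)
    message(sprintf("dropped %d subject(s) outside the id intersection", n_drop))
  clin <- clinical[match(patients, clinical$patient_id), , drop = FALSE]
  times <- as.numeric(clin$dfs_months)
  events <- as.logical(clin$event)
  calls <- am$calls[, patients, drop = FALSE]
  usable <- !am$missing[, patients, drop = FALSE]  # per gene x patient

  genes <- rownames(calls)
  if (is.null(subsets))
    subsets <- enumerate_subsets(genes, "powerset")
  if (inherits(subsets, "subset_iterator")) subsets <- subset_list(subsets)
  m <- length(subsets)
  if (m == 0L) stop_format("no subsets to rank")

  bit <- stats::setNames(2^(seq_along(genes) - 1L), genes)
  res <- data.frame(
    genes = character(m), subset_size = integer(m), bitmask = numeric(m),
    n_positive = integer(m), n_negative = integer(m), n_excluded = integer(m),
    logrank_chisq = numeric(m), p_value = numeric(m),
    median_pos = numeric(m), median_neg = numeric(m),
    degenerate = logical(m), underpowered = logical(m),
    stringsAsFactors = FALSE)

  for (i in seq_len(m)) {
    sub <- subsets[[i]]
    unknown <- setdiff(sub, genes)
    if (length(unknown))
      stop_format("subset gene(s) not in alteration matrix: %s",
                  paste(unknown, collapse = ", "))
    idx <- match(sub, genes)
    pos <- colSums(calls[idx, , drop = FALSE]) > 0L
    excl <- colSums(usable[idx, , drop = FALSE]) == 0L
    keep <- !excl
    np <- sum(pos & keep); nn <- sum(!pos & keep)
    res$genes[i] <- paste(sort(sub), collapse = ";")
    res$subset_size[i] <- length(sub)
    res$bitmask[i] <- sum(bit[sub])
    res$n_positive[i] <- np
    res$n_negative[i] <- nn
    res$n_excluded[i] <- sum(excl)
    if (np == 0L || nn == 0L) {
      res$degenerate[i] <- TRUE
      res$logrank_chisq[i] <- NA_real_
      res$p_value[i] <- 1
      res$median_pos[i] <- if (np > 0L)
        median_survival(times[keep & pos], events[keep & pos]) else NA_real_
      res$median_neg[i] <- if (nn > 0L)
        median_survival(times[keep & !pos], events[keep & !pos]) else NA_real_
      next
    }
    lr <- logrank_core(times[keep], events[keep], pos[keep])
    res$logrank_chisq[i] <- lr$stat
    res$p_value[i] <- if (lr$v > 0)
      stats::pchisq(lr$stat, df = 1L, lower.tail = FALSE) else 1
    res$median_pos[i] <- median_survival(times[keep & pos], events[keep & pos])
    res$median_neg[i] <- median_survival(times[keep & !pos], events[keep & !pos])
    res$underpowered[i] <- min(np, nn) < min_group
  }

  tested <- !res$degenerate
  res$p_bonferroni <- ifelse(tested, pmin(1, res$p_value * m), NA_real_)
  res$p_bh <- NA_real_
  res$p_bh[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res$significant <- tested & res$p_value < alpha

  ord <- order(res$degenerate, res$p_value, res$subset_size, res$bitmask)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(m)
  rownames(res) <- NULL
  res <- res[, c("rank", setdiff(names(res), "rank"))]

  ogs_genes <- strsplit(res$genes[1L], ";", fixed = TRUE)[[1L]]
  if (res$degenerate[1L])
    warning("every subset is degenerate; the optimal gene set is unreliable")
  structure(list(results = res,
                 ogs = list(genes = ogs_genes, row = res[1L, , drop = FALSE],
                            reliable = !res$degenerate[1L]),
                 significant = res[res$significant, , drop = FALSE],
                 alpha = alpha, genes = genes,
                 n_patients_used = length(patients)),
            class = "landscape_ranking")
}

#' @export
print.landscape_ranking <- function(x, ...) {
  cat(sprintf("DFS landscape: %d subset(s) of %d gene(s), %d patient(s)\n",
              nrow(x$results), length(x$genes), x$n_patients_used))
  cat(sprintf("  significant at alpha = %g: %d subset(s)\n",
              x$alpha, nrow(x$significant)))
  r <- x$ogs$row
  cat(sprintf("  optimal gene set: {%s}  logrank p = %.4g  (n+ = %d, n- = %d)%s\n",
              paste(x$ogs$genes, collapse = ", "), r$p_value,
              r$n_positive, r$n_negative,
              if (x$ogs$reliable) "" else "  [degenerate]"))
  invisible(x)
}

#' Export the DFS landscape as a TSV
#'
#' One row per subset, in rank order; the tabular twin of the landscape
#' plot. Medians that are never reached are written as `NR`.
#'
#' @param ranking a [rank_subsets()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
landscape_export <- function(ranking, path) {
  stopifnot(inherits(ranking, "landscape_ranking"))
  res <- ranking$results
  if (nrow(res) == 0L) stop_format("empty ranking")
  out <- data.frame(
    rank = res$rank, genes = res$genes, subset_size = res$subset_size,
    n_positive = res$n_positive, n_negative = res$n_negative,
    n_excluded = res$n_excluded,
    logrank_chisq = sprintf("%.10g", res$logrank_chisq),
    p_value = sprintf("%.10g", res$p_value),
    median_pos = ifelse(is.na(res$median_pos), "NR",
                        sprintf("%.10g", res$median_pos)),
    median_neg = ifelse(is.na(res$median_neg), "NR",
                        sprintf("%.10g", res$median_neg)),
    significant_flag = as.integer(res$significant),
    degenerate_flag = as.integer(res$degenerate),
    underpowered_flag = as.integer(res$underpowered),
    p_bonferroni = sprintf("%.10g", res$p_bonferroni),
    p_bh = sprintf("%.10g", res$p_bh),
    stringsAsFactors = FALSE)
  out$logrank_chisq[is.na(res$logrank_chisq)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
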