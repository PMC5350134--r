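# Seeded synthetic cohorts: an expression matrix with a planted altered
# risk gene set and exponential proportional-hazards survival, so every
# pipeline stage is testable without controlled-access clinical data.
# Defaults emulate the scale of a typical early-prostate-cancer DFS
# cohort: ~491 patients, ~19% relapse events, a 2-gene risk set with
# hazard ratio ~2.2.

#' Configuration for the synthetic-cohort generator
#'
#' @param n_patients number of tumor samples (default 491).
#' @param n_reference number of reference (diploid/normal pool) samples
#'   (default 50).
#' @param genes gene symbols (default 11 placeholder symbols).
#' @param planted_set subset of `genes` whose alteration multiplies the
#'   relapse hazard (default the first 2 genes).
#' @param hazard_ratio hazard multiplier for planted-set-positive
#'   patients (default 2.2).
#' @param baseline_hazard events per month for planted-set-negative
#'   patients (default 0.0022, giving ~19% observed events under the
#'   default censoring).
#' @param alteration_prob per-gene probability that a patient carries a
#'   planted alteration (default 0.15).
#' @param alteration_shift displacement of altered expression values, in
#'   reference-sd units, with random sign (default 3; must exceed the
#'   1.96 call threshold to be detectable).
#' @param censor_time administrative censoring horizon in months
#'   (default 150); censoring is `min(censor_time, U)` with
#'   `U ~ Uniform(0, censor_time)`.
#' @param seed RNG seed (NULL = use the current RNG state).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 491L,
                             n_reference = 50L,
                             genes = sprintf("GENE%02d", 1:11),
                             planted_set = genes[1:2],
                             hazard_ratio = 2.2,
                             baseline_hazard = 0.0022,
                             alteration_prob = 0.15,
                             alteration_shift = 3,
                             censor_time = 150,
                             seed = NULL) {
  if (n_reference < 2L) stop_format("'n_reference' must be >= 2")
  if (n_patients < 1L) stop_format("'n_patients' must be >= 1")
  if (anyDuplicated(genes)) stop_format("'genes' must be duplicate-free")
  if (!all(planted_set %in% genes))
    stop_format("'planted_set' must be a subset of 'genes'")
  check_positive_scalar(hazard_ratio, "hazard_ratio")
  check_positive_scalar(baseline_hazard, "baseline_hazard")
  check_positive_scalar(censor_time, "censor_time")
  if (alteration_prob < 0 || alteration_prob > 1)
    stop_format("'alteration_prob' must lie in [0, 1]")
  check_positive_scalar(alteration_shift, "alteration_shift")
  if (alteration_shift <= 1.96)
    warning("alteration_shift <= 1.96: planted alterations are barely detectable")
  structure(list(n_patients = as.integer(n_patients),
                 n_reference = as.integer(n_reference),
                 genes = as.character(genes),
                 planted_set = as.character(planted_set),
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 alteration_prob = alteration_prob,
                 alteration_shift = alteration_shift,
                 censor_time = censor_time,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic expression + clinical cohort with planted risk set
#'
#' Reference samples are drawn per gene from `Normal(mu_g, sigma_g)`
#' (gene-level `mu_g ~ Normal(8, 2)`, `sigma_g ~ Uniform(0.5, 2)`, drawn
#' once). Each patient is independently altered per gene with
#' probability `alteration_prob`; altered values are displaced by
#' `alteration_shift * sigma_g` with random sign (over- and
#' under-expression both count, since calling uses |z|). A patient is
#' truly positive when altered in ANY planted-set gene; relapse times
#' are exponential with rate `baseline_hazard * hazard_ratio^positive`
#' (an exactly proportional-hazards generator), censored at
#' `min(censor_time, Uniform(0, censor_time))`. Clinical covariates
#' (Gleason category, age, lymph nodes, PSA) are drawn independently of
#' the hazard.
#'
#' @param config a [synthetic_config()].
#' @return `list(expression, clinical, truth)`: an [expression_matrix()],
#'   a clinical data.frame (`patient_id`, `dfs_months`, `event`,
#'   `gleason_category`, `age`, `lymph_nodes`, `psa`), and a truth list
#'   (`positive` per patient, `alterations` gene x patient indicator
#'   matrix, `hazard_ratio`, `config`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ng <- length(config$genes)
  np <- config$n_patients
  nr <- config$n_reference
  pat_ids <- sprintf("P%04d", seq_len(np))
  ref_ids <- sprintf("REF%03d", seq_len(nr))

  mu <- stats::rnorm(ng, mean = 8, sd = 2)
  sigma <- stats::runif(ng, 0.5, 2)

  ref <- matrix(stats::rnorm(ng * nr, mean = mu, sd = sigma), nrow = ng)
  base <- matrix(stats::rnorm(ng * np, mean = mu, sd = sigma), nrow = ng)
  altered <- matrix(stats::runif(ng * np) < config$alteration_prob, nrow = ng)
  sign <- matrix(sample(c(-1, 1), ng * np, replace = TRUE), nrow = ng)
  vals <- base + altered * sign * config$alteration_shift * sigma

  values <- cbind(ref, vals)
  rownames(values) <- config$genes
  colnames(values) <- c(ref_ids, pat_ids)
  em <- expression_matrix(values, ref_ids)

  planted_idx <- match(config$planted_set, config$genes)
  positive <- if (length(planted_idx))
    colSums(altered[planted_idx, , drop = FALSE]) > 0L
  else rep(FALSE, np)
  names(positive) <- pat_ids

  rate <- config$baseline_hazard * config$hazard_ratio^positive
  t_event <- stats::rexp(np, rate = rate)
  censor <- if (is.finite(config$censor_time))
    pmin(config$censor_time, stats::runif(np, 0, config$censor_time))
  else rep(Inf, np)  # censor_time = Inf: complete follow-up
  dfs <- pmin(t_event, censor)
  event <- as.integer(t_event <= censor)

  clinical <- data.frame(
    patient_id = pat_ids,
    dfs_months = round(dfs, 3L),
    event = event,
    gleason_category = sample(1:5, np, replace = TRUE,
                              prob = c(0.30, 0.30, 0.20, 0.12, 0.08)),
    age = round(stats::rnorm(np, 61, 6.9), 1L),
    lymph_nodes = stats::rpois(np, 11),
    psa = round(abs(stats::rnorm(np, 1, 2)), 2L),
    stringsAsFactors = FALSE)

  dimnames(altered) <- list(config$genes, pat_ids)
  list(expression = em,
       clinical = clinical,
       truth = list(positive = positive, alterations = altered,
                    hazard_ratio = config$hazard_ratio, config = config))
}

#' Observed event rate of a clinical table, in percent
#'
#' @param clinical data.frame with an `event` column (0/1).
#' @return `100 * events / patients`, rounded to one decimal.
#' @export
event_rate <- function(clinical) {
  if (!is.data.frame(clinical) || nrow(clinical) == 0L)
    stop_format("'clinical' must be a non-empty data.frame")
  if (!"event" %in% names(clinical))
    stop_format("'clinical' lacks an 'event' column")
  round(100 * sum(clinical$event) / nrow(clinical), 1L)
}

#' Write a synthetic cohort as plain-text artifacts
#'
#' Writes `<prefix>expression.tsv`, `<prefix>reference_samples.txt`,
#' `<prefix>clinical.tsv` and `<prefix>truth.tsv` (per-patient planted
#' positivity).
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_prefix path prefix (directories must exist).
#' @return invisibly, the four paths written.
#' @export
write_cohort <- function(cohort, out_prefix) {
  em <- cohort$expression
  p_expr <- paste0(out_prefix, "expression.tsv")
  p_ref <- paste0(out_prefix, "reference_samples.txt")
  p_clin <- paste0(out_prefix, "clinical.tsv")
  p_truth <- paste0(out_prefix, "truth.tsv")
  df <- data.frame(gene = rownames(em$values), round(em$values, 6L),
                   check.names = FALSE)
  utils::write.table(df, p_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(em$reference_samples, p_ref)
  utils::write.table(cohort$clinical, p_clin, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(patient_id = names(cohort$truth$positive),
               planted_positive = as.integer(cohort$truth$positive)),
    p_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_expr, p_ref, p_clin, p_truth))
}
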