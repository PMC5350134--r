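# End-to-end orchestration: network contraction -> alteration calling
# -> exhaustive subset ranking -> OGS validation (stratified KM summary,
# univariate Cox, optional Gleason + OGS multivariable Cox with
# nested-model ANOVA), with all intermediate artifacts written as TSVs.

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values that parse as numbers become numeric; comma-separated
#' values become vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop_format("unparseable config line: '%s'", ln)
    val <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Per-stratum Kaplan-Meier report for a positivity split
#'
#' Summarizes DFS per stratum (n, events, KM median) and, when both
#' strata are populated, adds the two-group log-rank test and the Cox
#' hazard ratio with 95% CI for the positivity contrast.
#'
#' @param clinical clinical data.frame (`patient_id`, `dfs_months`,
#'   `event`).
#' @param positivity named logical over patient ids (`NA` = excluded).
#' @return an object of class `km_report`: `strata` data.frame,
#'   `logrank` ([logrank_test()] result or NULL), `cox` ([cox_fit()]
#'   or NULL), `n_excluded`.
#' @export
km_report <- function(clinical, positivity) {
  ids <- intersect(names(positivity), clinical$patient_id)
  if (length(ids) == 0L) stop_format("no patient ids shared with 'positivity'")
  clin <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  pos <- positivity[ids]
  keep <- !is.na(pos)
  n_excluded <- sum(!keep)
  clin <- clin[keep, , drop = FALSE]
  pos <- pos[keep]
  strat <- lapply(c(positive = TRUE, negative = FALSE), function(v) {
    sel <- pos == v
    data.frame(stratum = if (v) "positive" else "negative",
               n = sum(sel), events = sum(clin$event[sel]),
               km_median = if (sum(sel))
                 median_survival(clin$dfs_months[sel], clin$event[sel])
               else NA_real_)
  })
  strata <- do.call(rbind, strat)
  rownames(strata) <- NULL
  lr <- cox <- NULL
  if (all(strata$n > 0L)) {
    lr <- logrank_test(clin$dfs_months, clin$event, pos)
    cox <- cox_fit(clin$dfs_months, clin$event,
                   data.frame(positive = pos))
  } else {
    warning("single stratum: no log-rank test or Cox contrast computed")
  }
  structure(list(strata = strata, logrank = lr, cox = cox,
                 n_excluded = n_excluded),
            class = "km_report")
}

#' @export
print.km_report <- function(x, ...) {
  s <- x$strata
  s$km_median <- ifelse(is.na(s$km_median), "not reached",
                        format(s$km_median))
  print(s, row.names = FALSE)
  if (!is.null(x$logrank))
    cat(sprintf("log-rank p = %.4g; HR = %.3f (95%% CI %.3f-%.3f)\n",
                x$logrank$p_value, x$cox$hazard_ratios[1L],
                x$cox$ci95_low[1L], x$cox$ci95_high[1L]))
  if (x$n_excluded > 0L)
    cat(sprintf("%d patient(s) excluded (no usable measurement)\n",
                x$n_excluded))
  invisible(x)
}

#' Run the full combinatorial screening pipeline
#'
#' Executes, in order: (1) network contraction to the core gene set, if
#' interaction inputs are configured, else the configured `genes` are
#' used directly; (2) z-score alteration calling on the expression
#' matrix; (3) exhaustive power-set ranking against DFS; (4) for the
#' optimal gene set, a stratified KM report with univariate Cox, and --
#' when the clinical table has a usable Gleason category -- a
#' multivariable Gleason + OGS Cox model compared to Gleason-only by
#' nested-model ANOVA. All intermediate artifacts are written under
#' `out_dir` together with a MANIFEST; a failing stage aborts with the
#' stage name and leaves the MANIFEST marked incomplete.
#'
#' @param config named list (or path to a [read_config()] file) with
#'   keys: `out_dir` (required); either `genes` or network inputs
#'   `partner_file` + `seed_gene` (+ `biogrid_file`, `string_file`,
#'   `string_id_map`); `expression_file` + `reference_file` (or in-memory
#'   `expression` as an [expression_matrix()]); `clinical_file` (or
#'   in-memory `clinical` data.frame); optional `min_channels` (2),
#'   `string_threshold` (400), `z_threshold` (1.96), `alpha` (0.05),
#'   `min_group` (5), `seed`.
#' @return an object of class `run_report`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  defaults <- list(min_channels = 2, string_threshold = 400,
                   z_threshold = 1.96, alpha = 0.05, min_group = 5)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config[["out_dir"]])) stop_format("config lacks 'out_dir'")
  out_dir <- config[["out_dir"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config[["seed"]])) set.seed(config[["seed"]])

  warnings_seen <- character()
  counts <- list()
  manifest <- character()
  note <- function(path) manifest <<- c(manifest, path)
  write_manifest <- function(status) {
    writeLines(c(sprintf("status\t%s", status),
                 paste0("artifact\t", manifest)),
               file.path(out_dir, "MANIFEST"))
  }
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        write_manifest(sprintf("incomplete (failed at stage '%s')", name))
        stop_format("stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  need_file <- function(key) {
    p <- config[[key]]
    if (is.null(p)) stop_format("config lacks '%s'", key)
    if (!file.exists(p)) stop_format("'%s' file not found: %s", key, p)
    p
  }

  # -- stage: core gene set ------------------------------------------------
  core <- NULL
  genes <- config[["genes"]]
  if (!is.null(config[["partner_file"]])) {
    core <- run_stage("contract", {
      partners <- load_partner_list(need_file("partner_file"))
      edges <- list()
      if (!is.null(config[["biogrid_file"]]))
        edges <- c(edges, list(parse_biogrid(need_file("biogrid_file"),
                                             config[["seed_gene"]],
                                             partners$symbol)))
      if (!is.null(config[["string_file"]]))
        edges <- c(edges, list(parse_string_links(
          need_file("string_file"), config[["seed_gene"]], partners$symbol,
          channel_threshold = config[["string_threshold"]],
          id_map = config[["string_id_map"]])))
      if (length(edges) == 0L)
        stop_format("no interaction tables configured")
      all_edges <- do.call(rbind, edges)
      attr(all_edges, "seed") <- canonical_symbol(config[["seed_gene"]])
      core <- contract_network(merge_evidence(all_edges),
                               min_channels = config[["min_channels"]])
      write_provenance(core, file.path(out_dir, "provenance.tsv"))
      note("provenance.tsv")
      core
    })
    genes <- core$genes
    counts$core_genes <- length(genes)
  }
  if (is.null(genes) || length(genes) == 0L) {
    write_manifest("incomplete (no genes)")
    stop_format("no genes to screen: configure 'genes' or network inputs")
  }

  # -- stage: alteration calling ------------------------------------------
  am <- run_stage("call-alterations", {
    em <- if (!is.null(config[["expression"]])) config[["expression"]]
          else read_expression(need_file("expression_file"),
                               need_file("reference_file"))
    missing_genes <- setdiff(genes, rownames(em$values))
    if (length(missing_genes)) {
      warning(sprintf("gene(s) absent from expression matrix dropped: %s",
                      paste(missing_genes, collapse = ", ")))
      genes <- intersect(genes, rownames(em$values))
    }
    em$values <- em$values[genes, , drop = FALSE]
    z <- compute_zscores(em)
    am <- call_alterations(z, threshold = config[["z_threshold"]])
    write_alterations(am, file.path(out_dir, "calls.tsv"),
                      file.path(out_dir, "zscores.tsv"))
    note("calls.tsv"); note("zscores.tsv")
    am
  })
  counts$genes_screened <- nrow(am$calls)
  counts$patients_expression <- ncol(am$calls)
  counts$alteration_calls <- sum(am$calls)

  # -- stage: clinical -----------------------------------------------------
  clinical <- run_stage("clinical", {
    if (!is.null(config[["clinical"]])) config[["clinical"]]
    else read_clinical(need_file("clinical_file"))
  })
  counts$patients_clinical <- nrow(clinical)

  # -- stage: ranking ------------------------------------------------------
  ranking <- run_stage("rank", {
    rk <- rank_subsets(am, clinical, alpha = config[["alpha"]],
                       min_group = config[["min_group"]])
    landscape_export(rk, file.path(out_dir, "landscape.tsv"))
    note("landscape.tsv")
    rk
  })
  counts$subsets_ranked <- nrow(ranking$results)
  counts$subsets_significant <- nrow(ranking$significant)

  # -- stage: OGS validation ----------------------------------------------
  ogs <- ranking$ogs
  validation <- run_stage("report", {
    pos <- subset_positivity(am, ogs$genes)
    rep <- km_report(clinical, pos)
    utils::write.table(rep$strata, file.path(out_dir, "ogs_km_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("ogs_km_report.tsv")
    anova <- NULL
    if ("gleason_category" %in% names(clinical)) {
      ids <- intersect(names(pos), clinical$patient_id)
      clin <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
      p <- pos[ids]
      cc <- !is.na(p) & !is.na(clin$gleason_category)
      gl <- factor(clin$gleason_category[cc], levels = sort(unique(
        clin$gleason_category[cc])))
      if (nlevels(gl) >= 2L && sum(clin$event[cc]) > 0L) {
        reduced <- cox_fit(clin$dfs_months[cc], clin$event[cc],
                           data.frame(gleason = gl))
        full <- cox_fit(clin$dfs_months[cc], clin$event[cc],
                        data.frame(gleason = gl, ogs = p[cc]))
        anova <- nested_anova(reduced, full)
      }
    }
    list(km = rep, anova = anova)
  })

  # out_dir is not an analytic parameter: leave it out of the echoed
  # config so the provenance hash depends only on what shaped the result
  cfg_echo <- config[!vapply(config, is.object, logical(1L)) &
                     !names(config) %in% c("expression", "clinical", "out_dir")]
  cfg_lines <- vapply(names(cfg_echo), function(k)
    sprintf("%s = %s", k, paste(format(cfg_echo[[k]]), collapse = ",")),
    character(1L))
  cfg_file <- file.path(out_dir, "config_echo.txt")
  writeLines(sort(cfg_lines), cfg_file)
  note("config_echo.txt")
  cfg_hash <- unname(tools::md5sum(cfg_file))

  report <- structure(
    list(package_version = as.character(utils::packageVersion("ogscreen")),
         config = cfg_echo, config_hash = cfg_hash,
         seed = config[["seed"]], counts = counts,
         warnings = warnings_seen,
         core = core, ranking = ranking,
         ogs = list(genes = ogs$genes,
                    p_value = ogs$row$p_value,
                    hr = if (!is.null(validation$km$cox))
                      unname(validation$km$cox$hazard_ratios[1L]) else NA_real_,
                    ci95 = if (!is.null(validation$km$cox))
                      c(unname(validation$km$cox$ci95_low[1L]),
                        unname(validation$km$cox$ci95_high[1L]))
                      else c(NA_real_, NA_real_),
                    median_positive = ogs$row$median_pos,
                    median_negative = ogs$row$median_neg),
         km_report = validation$km,
         anova = validation$anova,
         out_dir = out_dir),
    class = "run_report")

  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  note("report.txt")
  write_manifest("complete")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("ogscreen run report (package %s)\n", x$package_version))
  cat(sprintf("config hash: %s; seed: %s\n", x$config_hash,
              if (is.null(x$seed)) "none" else format(x$seed)))
  cat("stage counts:\n")
  for (k in names(x$counts))
    cat(sprintf("  %-24s %s\n", k, format(x$counts[[k]])))
  fmt_med <- function(m) if (is.na(m)) "not reached" else sprintf("%.1f", m)
  cat(sprintf("optimal gene set: {%s}\n", paste(x$ogs$genes, collapse = ", ")))
  cat(sprintf("  log-rank p = %.4g; HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$ogs$p_value, x$ogs$hr, x$ogs$ci95[1L], x$ogs$ci95[2L]))
  cat(sprintf("  median DFS: positive %s, negative %s months\n",
              fmt_med(x$ogs$median_positive), fmt_med(x$ogs$median_negative)))
  if (!is.null(x$anova))
    cat(sprintf("nested ANOVA (Gleason vs Gleason + OGS): chisq = %.3f on %d df, p = %.4g\n",
                x$anova$chi_square, x$anova$df, x$anova$p_value))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
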