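# Survival primitives used by the ranking and validation stages:
# product-limit (Kaplan-Meier) estimation, the two-group Mantel-Haenszel
# log-rank test (implemented directly -- it is the inner loop of the
# exhaustive subset scan), Cox proportional-hazards fitting via the
# survival package, nested-model ANOVA, and Welch's t-test from summary
# statistics for cohort comparability tables.

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings at the same time are handled
#' events-first (the standard convention: censored subjects at time t
#' are still at risk for events at t).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return an object of class `km_curve`: `list(event_times, survival,
#'   at_risk, n_events, median)`; `median` is the smallest event time
#'   with survival <= 0.5, or `NA` ("not reached") when the curve never
#'   crosses 0.5.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) == 0L || length(times) != length(events))
    stop_format("'times' and 'events' must be non-empty and equal-length")
  if (any(is.na(times)) || any(is.na(events)) || any(times < 0))
    stop_format("times must be non-negative and complete")
  n <- length(times)
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  dt <- unique(t_s[e_s])
  if (length(dt) == 0L) {
    return(structure(list(event_times = numeric(), survival = numeric(),
                          at_risk = integer(), n_events = integer(),
                          median = NA_real_), class = "km_curve"))
  }
  at_risk <- n - findInterval(dt, t_s, left.open = TRUE)  # subjects with t >= dt
  d <- as.integer(rowsum(as.integer(e_s), t_s)[as.character(dt), 1L])
  surv <- cumprod(1 - d / at_risk)
  med <- if (any(surv <= 0.5)) dt[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(event_times = dt, survival = surv, at_risk = at_risk,
                 n_events = d, median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event time(s); median %s\n",
              length(x$event_times),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Median survival time (product-limit convention)
#'
#' @inheritParams km_estimate
#' @return smallest event time with S(t) <= 0.5, or `NA` if not reached.
#' @export
median_survival <- function(times, events) km_estimate(times, events)$median

# Core two-group log-rank computation on raw vectors; `group` is logical
# (TRUE = group 1). Returns the chi-square statistic and per-group
# observed/expected sums. Kept free of validation so the subset scan can
# call it 2^n - 1 times cheaply.
logrank_core <- function(times, events, group) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- group[ord]
  n <- length(t_s)
  n1 <- sum(g_s)
  dt <- unique(t_s[e_s])
  if (length(dt) == 0L)
    return(list(stat = 0, o1 = 0, e1 = 0, o2 = 0, e2 = 0, v = 0))
  at_risk <- n - findInterval(dt, t_s, left.open = TRUE)
  t1 <- t_s[g_s]
  at_risk1 <- n1 - findInterval(dt, t1, left.open = TRUE)
  key <- as.character(dt)
  d <- as.integer(rowsum(as.integer(e_s), t_s)[key, 1L])
  d1 <- if (n1 > 0L) {
    dd <- rowsum(as.integer(e_s & g_s), t_s)[key, 1L]
    as.integer(dd)
  } else integer(length(dt))
  p1 <- at_risk1 / at_risk
  e1 <- d * p1
  v <- ifelse(at_risk > 1L,
              d * p1 * (1 - p1) * (at_risk - d) / (at_risk - 1L), 0)
  sv <- sum(v)
  stat <- if (sv > 0) (sum(d1) - sum(e1))^2 / sv else 0
  list(stat = stat, o1 = sum(d1), e1 = sum(e1),
       o2 = sum(d) - sum(d1), e2 = sum(d) - sum(e1), v = sv)
}

#' Two-group Mantel-Haenszel log-rank test
#'
#' Sums, over distinct event times, the group-1 observed-minus-expected
#' event counts under the conditional hypergeometric distribution; the
#' statistic `(sum(O1 - E1))^2 / sum(V1)` is referred to the upper tail
#' of a chi-square distribution on 1 degree of freedom.
#'
#' @inheritParams km_estimate
#' @param group vector with exactly two distinct values (each present at
#'   least once) assigning subjects to groups.
#' @return an object of class `logrank_result`: statistic, p_value,
#'   per-group sizes and observed/expected event counts. With no events
#'   at all the statistic is 0 and p = 1, with a warning.
#' @export
logrank_test <- function(times, events, group) {
  times <- as.numeric(times); events <- as.logical(events)
  if (length(times) != length(events) || length(times) != length(group))
    stop_format("'times', 'events' and 'group' must have equal length")
  keep <- !is.na(group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop_format("log-rank test needs exactly 2 groups, got %d", length(lev))
  g <- group == lev[2L]
  res <- logrank_core(times, events, g)
  if (sum(events) == 0L) warning("no events observed; log-rank p set to 1")
  p <- if (res$v > 0) stats::pchisq(res$stat, df = 1L, lower.tail = FALSE) else 1
  structure(list(statistic = res$stat, p_value = p,
                 n_group = c(sum(!g), sum(g)),
                 observed = c(res$o2, res$o1), expected = c(res$e2, res$e1),
                 groups = lev),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on 1 df, p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  groups (%s / %s): n = %d / %d, observed events %.3g / %.3g, expected %.3g / %.3g\n",
              format(x$groups[1L]), format(x$groups[2L]),
              x$n_group[1L], x$n_group[2L],
              x$observed[1L], x$observed[2L],
              x$expected[1L], x$expected[2L]))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default,
#' via the survival package) and reports hazard ratios with 95% Wald
#' confidence intervals `exp(beta +/- 1.96 se)`.
#'
#' @inheritParams km_estimate
#' @param covariates numeric matrix or data.frame (one column per
#'   covariate; factors allowed in a data.frame).
#' @param tie_method "efron" (default) or "breslow".
#' @return an object of class `cox_fit`: coefficients, hazard_ratios,
#'   ci95_low/high, se, p (Wald), loglik (null and fitted log partial
#'   likelihood), df, n, n_events, converged, and the covariate names.
#' @export
cox_fit <- function(times, events, covariates, tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  times <- as.numeric(times); events <- as.logical(events)
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  if (length(times) != nrow(covariates) || length(times) != length(events))
    stop_format("covariates and survival vectors disagree in length")
  cc <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  n_dropped <- sum(!cc)
  if (n_dropped > 0L)
    message(sprintf("complete-case deletion dropped %d subject(s)", n_dropped))
  times <- times[cc]; events <- events[cc]
  covariates <- covariates[cc, , drop = FALSE]
  if (nrow(covariates) < ncol(covariates) + 1L)
    stop_format("too few subjects (%d) for %d covariate(s)",
                nrow(covariates), ncol(covariates))
  if (sum(events) == 0L) stop_format("no events observed; Cox model undefined")
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2L,
                  logical(1L))
  if (any(const))
    stop_format("constant covariate(s): %s",
                paste(names(covariates)[const], collapse = ", "))
  fit <- survival::coxph(
    survival::Surv(times, events) ~ .,
    data = covariates, ties = tie_method,
    control = survival::coxph.control(eps = 1e-9, iter.max = 50L))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- is.null(fit$info) || fit$iter < 50L
  mono <- any(abs(beta) > 15)
  if (mono || !converged) {
    warning("possible monotone likelihood (perfect separation); estimates unreliable")
    converged <- FALSE
  }
  z975 <- stats::qnorm(0.975)
  structure(list(covariates = names(beta),
                 coefficients = beta,
                 hazard_ratios = exp(beta),
                 ci95_low = exp(beta - z975 * se),
                 ci95_high = exp(beta + z975 * se),
                 se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik_null = fit$loglik[1L],
                 loglik = fit$loglik[2L],
                 df = length(beta),
                 n = fit$n, n_events = fit$nevent,
                 n_dropped = n_dropped,
                 converged = converged,
                 tie_method = tie_method),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$tie_method, x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    `CI95.low` = x$ci95_low, `CI95.high` = x$ci95_high,
                    p = x$p, row.names = x$covariates, check.names = FALSE)
  print(round(tab, 4L))
  cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
              x$loglik, x$loglik_null))
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The chi-square statistic is twice the gain in log partial likelihood
#' of the full model over the reduced model, on degrees of freedom equal
#' to the difference in parameter counts.
#'
#' @param fit_reduced,fit_full two [cox_fit()] objects on the same
#'   subjects, the reduced model's covariates a strict subset of the
#'   full model's. `fit_reduced = NULL` compares the full model against
#'   the covariate-free null model (its own null log partial likelihood).
#' @return an object of class `nested_anova_result`: loglik_reduced,
#'   loglik_full, chi_square, df, p_value.
#' @export
nested_anova <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_full, "cox_fit"))
  if (is.null(fit_reduced)) {
    fit_reduced <- structure(list(covariates = character(),
                                  loglik = fit_full$loglik_null, df = 0L,
                                  n = fit_full$n,
                                  n_events = fit_full$n_events),
                             class = "cox_fit")
  }
  stopifnot(inherits(fit_reduced, "cox_fit"))
  if (!all(fit_reduced$covariates %in% fit_full$covariates))
    stop_format("models are not nested: reduced covariates must be a subset of the full model's")
  if (fit_reduced$n != fit_full$n || fit_reduced$n_events != fit_full$n_events)
    stop_format("models were fit on different subjects")
  df <- fit_full$df - fit_reduced$df
  if (df < 1L) stop_format("full model must add at least one parameter")
  chi <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (chi < -1e-6)
    stop_format("negative likelihood gain (%.3g): a model failed to converge", chi)
  chi <- max(chi, 0)
  structure(list(loglik_reduced = fit_reduced$loglik,
                 loglik_full = fit_full$loglik,
                 chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df = df, lower.tail = FALSE)),
            class = "nested_anova_result")
}

#' @export
print.nested_anova_result <- function(x, ...) {
  cat(sprintf("Nested Cox model ANOVA: chisq = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  log likelihood: reduced %.3f, full %.3f\n",
              x$loglik_reduced, x$loglik_full))
  invisible(x)
}

#' Welch's heteroscedastic t-test from summary statistics
#'
#' Unpaired two-sample t-test without the equal-variance assumption,
#' computed from per-group mean, standard deviation and size, with
#' Welch-Satterthwaite degrees of freedom -- the form needed when only a
#' cohort-characteristics table is available.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (sd > 0, n >= 2).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return `list(t, df, p_value)` with a two-sided p-value.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_format("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_format("standard deviations must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df = df))
}

#' Read a clinical table
#'
#' Expects at minimum a follow-up time column (months) and an event
#' indicator column; optional covariate columns (Gleason category on the
#' 5-level scale, age, examined lymph-node count, most recent PSA) are
#' carried through when present. `col_map` renames nonstandard headers,
#' e.g. `c(dfs_months = "DFS_MONTHS", event = "DFS_STATUS")`.
#'
#' @param path TSV path with a header row.
#' @param col_map named character vector mapping standard names
#'   (patient_id, dfs_months, event, gleason_category, age, lymph_nodes,
#'   psa) to the file's column names.
#' @return data.frame with standardized column names; `event` coerced to
#'   0/1, `dfs_months` numeric and non-negative.
#' @export
read_clinical <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(tab))
        stop_format("clinical table lacks column '%s'", col_map[[std]])
      names(tab)[names(tab) == col_map[[std]]] <- std
    }
  }
  for (req in c("dfs_months", "event"))
    if (!req %in% names(tab))
      stop_format("clinical table lacks required column '%s'", req)
  tab$dfs_months <- as.numeric(tab$dfs_months)
  tab$event <- as.integer(as.logical(as.numeric(tab$event)))
  if (any(is.na(tab$dfs_months)) || any(tab$dfs_months < 0))
    stop_format("'dfs_months' must be non-negative and complete")
  if (!"patient_id" %in% names(tab))
    tab$patient_id <- as.character(seq_len(nrow(tab)))
  tab$patient_id <- as.character(tab$patient_id)
  tab
}
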