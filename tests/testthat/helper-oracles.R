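# Independent oracles and fixture builders. These deliberately use
# naive loops / generic optimizers so they share no code with the
# implementations they check.

# Naive two-group log-rank statistic: explicit loop over distinct event
# times, hypergeometric expectation and variance per 2x2 table.
naive_logrank_stat <- function(time, event, group) {
  dt <- sort(unique(time[event]))
  num <- 0
  den <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group)
    num <- num + (d1 - d * n1 / n)
    if (n > 1) den <- den + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  num^2 / den
}

# Cox log partial likelihood for a single covariate with no tied event
# times (Efron and Breslow coincide), evaluated by explicit risk-set
# summation.
cox_partial_loglik <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

# Oracle beta-hat: golden-section maximization of the partial likelihood.
grid_cox_beta <- function(time, event, x) {
  stats::optimize(cox_partial_loglik, c(-20, 20), maximum = TRUE,
                  time = time, event = event, x = x,
                  tol = 1e-10)$maximum
}

# Independent recursive power-set enumeration (non-empty subsets).
recursive_powerset <- function(genes) {
  if (length(genes) == 0L) return(list())
  rest <- recursive_powerset(genes[-1L])
  c(list(genes[1L]), rest, lapply(rest, function(s) c(genes[1L], s)))
}

# A small deterministic survival fixture.
random_survival_fixture <- function(n, p_event = 0.7) {
  list(time = round(rexp(n, rate = 0.1), 3L),
       event = runif(n) < p_event,
       group = runif(n) < 0.5)
}

# Deterministic alteration matrix from a 0/1 gene x patient matrix.
am_from_calls <- function(calls) {
  z <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  z[calls == 1] <- 3
  call_alterations(z, 1.96)
}

extdata <- function(f) system.file("extdata", f, package = "ogscreen")
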