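# Independent brute-force oracles and small fixture builders used across tests.

# AUC by exhaustive enumeration of all case-control score comparisons:
# concordant pairs count 1, ties count 1/2.
brute_force_auc <- function(values, labels) {
  case <- values[labels == "case"]
  ctrl <- values[labels == "control"]
  tot <- 0
  for (x in case) for (y in ctrl) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(case) * length(ctrl))
}

brute_force_U <- function(values, labels) {
  brute_force_auc(values, labels) *
    sum(labels == "case") * sum(labels == "control")
}

# small ct_matrix built directly from a matrix of Ct values
make_ct <- function(ct, cohort, censored = NULL, max_cycles = 40) {
  if (is.null(colnames(ct)))
    colnames(ct) <- sprintf("miR-t%02d", seq_len(ncol(ct)))
  if (is.null(rownames(ct)))
    rownames(ct) <- sprintf("S%03d", seq_len(nrow(ct)))
  ct_matrix(ct, cohort = cohort, censored = censored, max_cycles = max_cycles)
}

# two-cohort Gaussian ct_matrix without the full generator: n1 cases with
# per-assay shifts `delta`, shared per-sample offset sd `tau`
make_gaussian_ct <- function(n1 = 30, n0 = 30, n_assays = 6, delta = 0,
                             sigma = 1, tau = 1.5, mu = 28, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  delta <- rep_len(delta, n_assays)
  sigma <- rep_len(sigma, n_assays)
  mu <- rep_len(mu, n_assays)
  cohort <- rep(c("case", "control"), c(n1, n0))
  u <- rnorm(n, 0, tau)
  ct <- matrix(mu, n, n_assays, byrow = TRUE) +
    outer(as.numeric(cohort == "case"), delta) + u +
    matrix(rnorm(n * n_assays), n, n_assays) %*% diag(sigma, n_assays)
  ct <- pmin(ct, 40)
  make_ct(ct, cohort, censored = ct >= 40)
}

write_long_ct <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
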