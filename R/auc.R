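#' Rank-based ROC AUC
#'
#' AUC is computed by the midrank (Mann-Whitney) method: the probability that
#' a random case scores above a random control, counting ties as one half.
#' This equals the trapezoidal area under the empirical ROC curve over all
#' thresholds. ROC points are returned as (1 - specificity, sensitivity),
#' anchored at (0,0) and (1,1).
#'
#' @param values numeric scores, higher = more case-like
#' @param labels cohort labels (`"case"`/`"control"`, factor or character)
#' @return list of class `roc_auc` with `auc`, `roc` (data frame `fpr`,
#'   `tpr`, `threshold`), `n_case`, `n_control`
#' @export
roc_auc <- function(values, labels) {
  labels <- as_cohort(labels)
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  if (any(!is.finite(values))) stop("scores must be finite")
  n1 <- sum(labels == "case")
  n0 <- sum(labels == "control")
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")

  auc <- auc_midrank(values, labels == "case")

  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(values >= t & labels == "case") / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(values >= t & labels == "control") / n0,
                numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  structure(list(auc = auc, roc = roc, n_case = n1, n_control = n0),
            class = "roc_auc")
}

# midrank AUC; `case` logical
auc_midrank <- function(values, case) {
  r <- rank(values)
  n1 <- sum(case)
  n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC / Mann-Whitney U equivalence
#'
#' Computes the Mann-Whitney U statistic (number of case-control score pairs
#' where the case wins, ties counting one half) and the midrank AUC, and
#' verifies the identity `AUC = U / (n_case * n_control)` to machine
#' precision. The identity is what licenses reading AUC as a two-sample
#' rank statistic.
#'
#' @inheritParams roc_auc
#' @return list with `U`, `auc`, `n_case`, `n_control`, `max_abs_diff`
#'   (|AUC - U/(n1 n0)|, numerically zero)
#' @export
mann_whitney_auc <- function(values, labels) {
  labels <- as_cohort(labels)
  case <- labels == "case"
  n1 <- sum(case)
  n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  if (any(!is.finite(values))) stop("scores must be finite")
  r <- rank(values)
  U <- sum(r[case]) - n1 * (n1 + 1) / 2
  auc <- auc_midrank(values, case)
  d <- abs(auc - U / (n1 * n0))
  if (d > 1e-10)
    stop("AUC / U identity violated (diff ", format(d), ")")
  list(U = U, auc = auc, n_case = n1, n_control = n0, max_abs_diff = d)
}

# two-sided Mann-Whitney p-value: exact when the product of group sizes is
# small and there are no ties, otherwise tie-corrected normal approximation
mw_p_value <- function(values, labels, exact_max_product = 400) {
  labels <- as_cohort(labels)
  case <- labels == "case"
  n1 <- sum(case)
  n0 <- sum(!case)
  want_exact <- n1 * n0 <= exact_max_product && !anyDuplicated(values)
  suppressWarnings(
    stats::wilcox.test(values[case], values[!case],
                       exact = want_exact, correct = !want_exact)$p.value
  )
}

#' Confidence interval for an AUC
#'
#' DeLong's asymptotic variance-based interval (default) or a stratified
#' bootstrap percentile interval. Both are truncated to \[0, 1\]. A
#' perfectly separating score has zero DeLong variance; the degenerate
#' zero-width interval is returned with a `degenerate` attribute.
#'
#' @inheritParams roc_auc
#' @param method `"delong"` or `"bootstrap"`
#' @param level confidence level (default 0.95)
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed integer seed for the bootstrap (required for reproducible
#'   bootstrap intervals; ignored for DeLong)
#' @return numeric vector `c(low, high)` with attributes `auc`, `method`,
#'   `level`, and `degenerate` (logical)
#' @export
auc_ci <- function(values, labels, method = c("delong", "bootstrap"),
                   level = 0.95, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  labels <- as_cohort(labels)
  if (!all(table(labels) > 0)) stop("need both classes")
  if (any(!is.finite(values))) stop("scores must be finite")
  auc <- auc_midrank(values, labels == "case")

  if (method == "delong") {
    r <- pROC::roc(response = labels, predictor = values,
                   levels = c("control", "case"), direction = "<",
                   quiet = TRUE)
    ci <- suppressWarnings(
      as.numeric(pROC::ci.auc(r, method = "delong", conf.level = level)))
    low <- max(0, ci[1])
    high <- min(1, ci[3])
  } else {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    ic <- which(labels == "case")
    i0 <- which(labels == "control")
    stat <- vapply(seq_len(n_boot), function(i) {
      bi <- c(sample(ic, replace = TRUE), sample(i0, replace = TRUE))
      auc_midrank(values[bi], labels[bi] == "case")
    }, numeric(1))
    q <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 7)
    low <- max(0, q[1])
    high <- min(1, q[2])
  }
  structure(c(low = low, high = high), auc = auc, method = method,
            level = level, degenerate = (high - low) == 0)
}
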