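#' Fit a single-pair binary classifier
#'
#' Evaluates one ratio feature as a case/control classifier, mirroring the
#' exploratory screening design: a maximum-likelihood logistic regression of
#' cohort on the log2 ratio, with sensitivity, specificity and accuracy read
#' off in-sample at the p = 0.5 probability threshold (p >= 0.5 classifies as
#' case), the midrank AUC oriented to be >= 0.5 (the flip is recorded), a
#' confidence interval for the AUC, and a two-sided Mann-Whitney test.
#' Evaluation is in-sample by design — estimates are optimistic and meant for
#' screening, not validation.
#'
#' Perfectly separable features make the logistic MLE diverge; the fit then
#' falls back to the ROC-optimal (Youden) step rule and is flagged
#' `separable`. A constant feature yields a flagged degenerate result with
#' AUC 0.5 and slope 0.
#'
#' @param feature a [pair_feature()] object, or a numeric vector of scores
#' @param labels cohort labels; taken from the feature if omitted
#' @param ci_method `"delong"` (default) or `"bootstrap"`
#' @param level confidence level for the AUC interval
#' @param exclude_censored drop samples where either pair member was censored
#'   (only meaningful when `feature` is a `pair_feature`); default `FALSE`,
#'   i.e. ceiling-imputed values are used
#' @param boot_seed seed for the bootstrap interval (if selected)
#' @return an object of class `pair_classifier`
#' @export
fit_pair_classifier <- function(feature, labels = NULL,
                                ci_method = c("delong", "bootstrap"),
                                level = 0.95, exclude_censored = FALSE,
                                boot_seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (inherits(feature, "pair_feature")) {
    x <- feature$log2_ratio
    if (is.null(labels)) labels <- feature$cohort
    pair_id <- feature$pair_id
    mirna_a <- feature$mirna_a
    mirna_b <- feature$mirna_b
    if (exclude_censored) {
      keep <- !feature$any_censored
      x <- x[keep]
      labels <- labels[keep]
    }
  } else {
    x <- as.numeric(feature)
    if (is.null(labels)) stop("labels required when feature is a plain vector")
    pair_id <- "feature"
    mirna_a <- mirna_b <- NA_character_
  }
  labels <- as_cohort(labels)
  y <- as.integer(labels == "case")
  n1 <- sum(y)
  n0 <- sum(1 - y)
  if (n1 < 2 || n0 < 2) stop("need at least 2 samples per class")

  degenerate <- stats::sd(x) == 0
  auc_raw <- if (degenerate) 0.5 else auc_midrank(x, y == 1)
  orientation <- if (auc_raw >= 0.5) 1L else -1L
  oriented <- orientation * x
  auc <- max(auc_raw, 1 - auc_raw)

  separable <- FALSE
  if (degenerate) {
    coefs <- c(intercept = stats::qlogis(max(min(mean(y), 1 - 1e-12), 1e-12)),
               slope = 0)
    pred_case <- rep(mean(y) >= 0.5, length(y))
  } else {
    sep_warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    separable <- sep_warned || max(abs(fit$coefficients[2])) > 1e3
    if (separable) {
      # ROC-optimal deterministic step rule on the oriented feature
      thr <- youden_threshold(oriented, y == 1)
      coefs <- c(intercept = NA_real_, slope = NA_real_)
      pred_case <- oriented >= thr
      attr(coefs, "step_threshold") <- thr
    } else {
      coefs <- c(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]))
      pred_case <- fit$fitted.values >= 0.5
    }
  }

  tp <- sum(pred_case & y == 1)
  tn <- sum(!pred_case & y == 0)
  sens <- tp / n1
  spec <- tn / n0
  acc <- (tp + tn) / (n1 + n0)

  if (degenerate) {
    ci <- structure(c(low = 0.5, high = 0.5), degenerate = TRUE)
  } else {
    ci <- auc_ci(oriented, labels, method = ci_method, level = level,
                 seed = boot_seed)
  }
  mw_p <- if (degenerate) 1 else mw_p_value(x, labels)

  structure(list(
    pair_id = pair_id, mirna_a = mirna_a, mirna_b = mirna_b,
    orientation = orientation,
    coefficients = coefs,
    sensitivity = sens, specificity = spec, accuracy = acc,
    auc = auc, auc_ci_low = unname(ci[1]), auc_ci_high = unname(ci[2]),
    ci_method = ci_method, ci_level = level,
    mw_p = mw_p,
    n_case = n1, n_control = n0,
    degenerate = degenerate, separable = separable,
    feature = x, labels = labels
  ), class = "pair_classifier")
}

# threshold on the oriented score maximizing sensitivity + specificity;
# deterministic midpoint between adjacent distinct scores
youden_threshold <- function(score, case) {
  s <- sort(unique(score))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(t) {
    mean(score[case] >= t) + mean(score[!case] < t)
  }, numeric(1))
  cand[which.max(j)]
}

#' @export
coef.pair_classifier <- function(object, ...) object$coefficients

#' @export
print.pair_classifier <- function(x, ...) {
  cat(sprintf("<pair_classifier> %s%s\n", x$pair_id,
              if (x$orientation < 0) " (orientation flipped)" else ""))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f, %s)  sens %.2f  spec %.2f  acc %.2f\n",
              x$auc, round(100 * x$ci_level), x$auc_ci_low, x$auc_ci_high,
              x$ci_method, x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  Mann-Whitney p = %.3g  (n = %d case / %d control)\n",
              x$mw_p, x$n_case, x$n_control))
  if (x$degenerate) cat("  [degenerate constant feature]\n")
  if (x$separable) cat("  [perfect separation: step-rule fallback]\n")
  invisible(x)
}

#' @export
summary.pair_classifier <- function(object, ...) print(object, ...)

#' Predict case probabilities from a fitted pair classifier
#' @param object a `pair_classifier`
#' @param newdata numeric vector of log2 ratio values (defaults to the
#'   training feature)
#' @param ... ignored
#' @return numeric vector of case probabilities
#' @export
predict.pair_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$feature
  x <- as.numeric(newdata)
  if (object$separable) {
    thr <- attr(object$coefficients, "step_threshold")
    return(as.numeric(object$orientation * x >= thr))
  }
  if (object$degenerate)
    return(rep(stats::plogis(object$coefficients[["intercept"]]), length(x)))
  stats::plogis(object$coefficients[["intercept"]] +
                  object$coefficients[["slope"]] * x)
}

#' @export
plot.pair_classifier <- function(x, ...) {
  r <- roc_auc(x$orientation * x$feature, x$labels)
  plot(r$roc$fpr, r$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s (AUC %.3f)", x$pair_id, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Screen every pair as a classifier
#'
#' Runs [fit_pair_classifier()] over all (or the given) pairs of a Ct matrix
#' and collects one row of metrics per pair — the exhaustive single-pair
#' stage of the discovery pipeline. A Benjamini-Hochberg adjusted
#' Mann-Whitney q-value column is included for reference but is never used
#' for gating (the screening design deliberately applies no multiple-testing
#' correction).
#'
#' @param ct a `ct_matrix` with cohort labels
#' @param pairs pair table from [enumerate_pairs()]; default all pairs
#' @param ci_method,level,exclude_censored,boot_seed passed to
#'   [fit_pair_classifier()]
#' @return object of class `pair_screen`: list with `results` (one row per
#'   pair), `ci_method`, `n_case`, `n_control`
#' @export
screen_pairs <- function(ct, pairs = NULL, ci_method = c("delong", "bootstrap"),
                         level = 0.95, exclude_censored = FALSE,
                         boot_seed = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  ci_method <- match.arg(ci_method)
  if (is.null(pairs)) pairs <- enumerate_pairs(ct)
  labels <- ct$samples$cohort
  fm <- pair_feature_matrix(ct, pairs)
  cen <- attr(fm, "censored")

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- fm[, i]
    lab <- labels
    if (exclude_censored) {
      keep <- !cen[, i]
      x <- x[keep]
      lab <- lab[keep]
    }
    fit <- fit_pair_classifier(x, lab, ci_method = ci_method, level = level,
                               boot_seed = boot_seed)
    data.frame(pair_id = pairs$pair_id[i],
               mirna_a = pairs$mirna_a[i], mirna_b = pairs$mirna_b[i],
               orientation = fit$orientation,
               intercept = fit$coefficients[["intercept"]],
               slope = fit$coefficients[["slope"]],
               sensitivity = fit$sensitivity, specificity = fit$specificity,
               accuracy = fit$accuracy,
               auc = fit$auc, auc_ci_low = fit$auc_ci_low,
               auc_ci_high = fit$auc_ci_high,
               mw_p = fit$mw_p,
               n_case = fit$n_case, n_control = fit$n_control,
               degenerate = fit$degenerate, separable = fit$separable,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$mw_q <- stats::p.adjust(results$mw_p, method = "BH")
  structure(list(results = results, ci_method = ci_method,
                 n_case = results$n_case[1], n_control = results$n_control[1]),
            class = "pair_screen")
}

#' @export
print.pair_screen <- function(x, ...) {
  cat(sprintf("<pair_screen> %d pairs, %d case / %d control (CI: %s)\n",
              nrow(x$results), x$n_case, x$n_control, x$ci_method))
  top <- utils::head(x$results[order(-x$results$auc, x$results$pair_id), ], 5)
  cat("  top pairs by AUC:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-28s AUC %.3f  acc %.2f\n",
                top$pair_id[i], top$auc[i], top$accuracy[i]))
  invisible(x)
}

#' Gate pairs on AUC
#'
#' Selects pairs whose in-sample AUC meets the gate (inclusive threshold,
#' default 0.8 — conventional "good discrimination"), sorted by AUC
#' descending then pair id. No multiple-testing adjustment is applied to the
#' gate; the BH q-values travel along for reference only.
#'
#' @param screen a `pair_screen` (or its `results` data frame)
#' @param auc_min inclusive AUC gate (default 0.8)
#' @return data frame of class `pair_selection` (possibly 0 rows), columns as
#'   in the screen results
#' @export
select_pairs <- function(screen, auc_min = 0.8) {
  results <- if (inherits(screen, "pair_screen")) screen$results else screen
  sel <- results[results$auc >= auc_min, , drop = FALSE]
  sel <- sel[order(-sel$auc, sel$pair_id), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "auc_min") <- auc_min
  class(sel) <- c("pair_selection", "data.frame")
  sel
}
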