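#' Build an equal-weight k-pair combination classifier
#'
#' Combines k ratio features into one score with equal weights and maps it
#' through a sigmoid, `P(case) = 1 / (1 + exp(-score))`, thresholded at
#' p = 0.5 (p >= 0.5 classifies as case).
#'
#' Two score constructions ship:
#' \describe{
#'   \item{`standardized_log` (default)}{each member's oriented log2 feature
#'     is centered at the midpoint between its class means and scaled to unit
#'     pooled within-class SD before averaging, so score 0 (p = 0.5) is a
#'     meaningful decision boundary between the cohorts.}
#'   \item{`raw_ratio`}{the literal mean of the positive 2^dCt ratios through
#'     the sigmoid. Because every ratio is positive, the score is positive
#'     and *every* sample is classified as a case (specificity 0); the
#'     classifier carries a `caveat` flag documenting this internal
#'     inconsistency of the literal formula. Provided for fidelity, not use.}
#' }
#'
#' @param features samples-by-pairs log2 feature matrix from
#'   [pair_feature_matrix()]
#' @param members the k member pairs: a character vector of pair ids or a
#'   [select_pairs()] selection (whose recorded orientations are then used)
#' @param labels cohort labels for the training samples
#' @param mode `"standardized_log"` or `"raw_ratio"`
#' @param orientations optional +1/-1 per member; default: from `members` if
#'   it is a selection, otherwise derived from the training data (sign of the
#'   case-minus-control mean)
#' @return object of class `combo_classifier`
#' @export
build_combo <- function(features, members, labels,
                        mode = c("standardized_log", "raw_ratio"),
                        orientations = NULL) {
  mode <- match.arg(mode)
  if (inherits(members, "pair_selection") || is.data.frame(members)) {
    if (is.null(orientations)) orientations <- members$orientation
    members <- members$pair_id
  }
  members <- as.character(members)
  k <- length(members)
  if (k == 0) stop("a combination needs at least one member pair")
  if (anyDuplicated(members))
    stop("duplicate member pair(s): ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  miss <- setdiff(members, colnames(features))
  if (length(miss))
    stop("member pair(s) missing from feature matrix: ",
         paste(miss, collapse = ", "))
  labels <- as_cohort(labels, n = nrow(features))
  case <- labels == "case"
  if (!any(case) || all(case)) stop("need both classes")

  x <- features[, members, drop = FALSE]

  if (mode == "raw_ratio") {
    score <- rowMeans(2 ^ x)
    centers <- rep(0, k)
    scales <- rep(1, k)
    orientations <- rep(1L, k)
    caveat <- TRUE
  } else {
    if (is.null(orientations)) {
      orientations <- ifelse(colMeans(x[case, , drop = FALSE]) >=
                               colMeans(x[!case, , drop = FALSE]), 1L, -1L)
    }
    if (length(orientations) != k) stop("need one orientation per member")
    xo <- sweep(x, 2, orientations, `*`)
    m1 <- colMeans(xo[case, , drop = FALSE])
    m0 <- colMeans(xo[!case, , drop = FALSE])
    centers <- (m1 + m0) / 2
    scales <- pooled_sd(xo, case)
    scales[scales == 0] <- 1
    z <- sweep(sweep(xo, 2, centers), 2, scales, `/`)
    score <- rowMeans(z)
    caveat <- FALSE
  }
  names(centers) <- names(scales) <- members
  probability <- stats::plogis(score)
  metrics <- score_metrics(score, case)

  structure(c(list(
    members = members, k = k, mode = mode,
    orientations = stats::setNames(as.integer(orientations), members),
    centers = centers, scales = scales,
    score = unname(score), probability = unname(probability),
    labels = labels, caveat = caveat
  ), metrics), class = "combo_classifier")
}

pooled_sd <- function(x, case) {
  n1 <- sum(case)
  n0 <- sum(!case)
  v1 <- apply(x[case, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!case, , drop = FALSE], 2, stats::var)
  sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
}

# sens/spec/acc at score >= 0 (p >= 0.5) plus midrank AUC
score_metrics <- function(score, case) {
  pred <- score >= 0
  n1 <- sum(case)
  n0 <- sum(!case)
  tp <- sum(pred & case)
  tn <- sum(!pred & !case)
  list(sensitivity = tp / n1, specificity = tn / n0,
       accuracy = (tp + tn) / (n1 + n0),
       auc = auc_midrank(score, case))
}

#' Re-evaluate a combination classifier
#'
#' Recomputes sensitivity, specificity, accuracy (at the p = 0.5 rule) and
#' AUC of a built combination against a label vector.
#'
#' @param combo a `combo_classifier`
#' @param labels cohort labels (default: the training labels)
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc`
#' @export
evaluate_combo <- function(combo, labels = NULL) {
  stopifnot(inherits(combo, "combo_classifier"))
  if (is.null(labels)) labels <- combo$labels
  labels <- as_cohort(labels, n = length(combo$score))
  case <- labels == "case"
  if (!any(case) || all(case)) stop("need both classes")
  score_metrics(combo$score, case)
}

#' Predict from a combination classifier
#' @param object a `combo_classifier`
#' @param newdata samples-by-pairs log2 feature matrix containing the member
#'   columns (default: training scores are returned)
#' @param type `"probability"`, `"score"` or `"class"`
#' @param ... ignored
#' @return numeric vector (or factor for `"class"`)
#' @export
predict.combo_classifier <- function(object, newdata = NULL,
                                     type = c("probability", "score", "class"),
                                     ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    score <- object$score
  } else {
    x <- newdata[, object$members, drop = FALSE]
    if (object$mode == "raw_ratio") {
      score <- rowMeans(2 ^ x)
    } else {
      xo <- sweep(x, 2, object$orientations, `*`)
      z <- sweep(sweep(xo, 2, object$centers), 2, object$scales, `/`)
      score <- rowMeans(z)
    }
    score <- unname(score)
  }
  switch(type,
         score = score,
         probability = stats::plogis(score),
         class = factor(ifelse(stats::plogis(score) >= 0.5, "case", "control"),
                        levels = c("control", "case")))
}

#' @export
print.combo_classifier <- function(x, ...) {
  cat(sprintf("<combo_classifier> k=%d, mode=%s\n  members: %s\n",
              x$k, x$mode, paste(x$members, collapse = " + ")))
  cat(sprintf("  AUC %.3f  sens %.2f  spec %.2f  acc %.2f (p >= 0.5 rule)\n",
              x$auc, x$sensitivity, x$specificity, x$accuracy))
  if (x$caveat)
    cat("  CAVEAT: raw_ratio scores are strictly positive; every sample is\n",
        "         classified as case. Mode kept for documentation only.\n")
  invisible(x)
}

#' @export
summary.combo_classifier <- function(object, ...) print(object, ...)

#' @export
plot.combo_classifier <- function(x, ...) {
  r <- roc_auc(x$score, x$labels)
  plot(r$roc$fpr, r$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%d-pair combination (AUC %.3f)", x$k, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Exhaustive search over k-pair combinations
#'
#' Evaluates *every* k-combination of the gated pairs as an equal-weight
#' standardized-log combination classifier — no greedy shortcuts — and
#' returns those meeting the criteria, ranked by AUC (descending), ties
#' broken by accuracy then by the lexicographic member-id string. The search
#' has no randomness: identical inputs give identical rankings, and the
#' result is invariant under reordering of the gated pairs.
#'
#' @param gated a [select_pairs()] selection (or data frame with `pair_id`
#'   and `orientation` columns); must contain at least `k` pairs
#' @param features samples-by-pairs log2 feature matrix covering the gated
#'   pairs
#' @param labels cohort labels
#' @param k members per combination (default 3, configurable 1-4)
#' @param criteria list of inclusive floors `min_sens`, `min_spec`,
#'   `min_auc` applied to the evaluated combinations (all default 0, i.e. no
#'   filtering; any selection criteria are a reporting choice, not a claim)
#' @return object of class `combo_search`: list with `results` (ranked data
#'   frame: `member_1..k`, `combo_id`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`), `n_evaluated`, `k`, `criteria`
#' @export
combo_search <- function(gated, features, labels, k = 3,
                         criteria = list(min_sens = 0, min_spec = 0,
                                         min_auc = 0)) {
  if (is.character(gated))
    gated <- data.frame(pair_id = gated, orientation = NA_integer_,
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(gated), k >= 1, k <= 4)
  if (nrow(gated) < k)
    stop("need at least k = ", k, " gated pairs, have ", nrow(gated))
  if (anyDuplicated(gated$pair_id)) stop("gated pair ids must be unique")
  criteria <- utils::modifyList(list(min_sens = 0, min_spec = 0, min_auc = 0),
                                as.list(criteria))
  labels <- as_cohort(labels, n = nrow(features))
  case <- labels == "case"

  # canonical order makes the search invariant to input ordering
  ord <- order(gated$pair_id)
  ids <- gated$pair_id[ord]
  ori <- gated$orientation[ord]
  x <- features[, ids, drop = FALSE]
  if (anyNA(ori)) {
    ori <- ifelse(colMeans(x[case, , drop = FALSE]) >=
                    colMeans(x[!case, , drop = FALSE]), 1L, -1L)
  }
  xo <- sweep(x, 2, ori, `*`)
  m1 <- colMeans(xo[case, , drop = FALSE])
  m0 <- colMeans(xo[!case, , drop = FALSE])
  sds <- pooled_sd(xo, case)
  sds[sds == 0] <- 1
  z <- sweep(sweep(xo, 2, (m1 + m0) / 2), 2, sds, `/`)

  combos <- utils::combn(length(ids), k)
  n_eval <- ncol(combos)
  n1 <- sum(case)
  n0 <- sum(!case)
  sens <- spec <- acc <- auc <- numeric(n_eval)
  for (i in seq_len(n_eval)) {
    s <- rowMeans(z[, combos[, i], drop = FALSE])
    pred <- s >= 0
    tp <- sum(pred & case)
    tn <- sum(!pred & !case)
    sens[i] <- tp / n1
    spec[i] <- tn / n0
    acc[i] <- (tp + tn) / (n1 + n0)
    auc[i] <- auc_midrank(s, case)
  }

  member_mat <- matrix(ids[combos], nrow = n_eval, byrow = TRUE)
  colnames(member_mat) <- paste0("member_", seq_len(k))
  results <- data.frame(member_mat, stringsAsFactors = FALSE)
  results$combo_id <- apply(member_mat, 1, paste, collapse = " + ")
  results$sensitivity <- sens
  results$specificity <- spec
  results$accuracy <- acc
  results$auc <- auc

  keep <- sens >= criteria$min_sens & spec >= criteria$min_spec &
    auc >= criteria$min_auc
  results <- results[keep, , drop = FALSE]
  results <- results[order(-results$auc, -results$accuracy,
                           results$combo_id), , drop = FALSE]
  rownames(results) <- NULL

  structure(list(results = results, n_evaluated = n_eval, k = k,
                 criteria = criteria),
            class = "combo_search")
}

#' @export
print.combo_search <- function(x, ...) {
  cat(sprintf("<combo_search> %d combinations of k=%d evaluated, %d meet criteria\n",
              x$n_evaluated, x$k, nrow(x$results)))
  top <- utils::head(x$results, 6)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. %s  AUC %.3f  sens %.2f  spec %.2f  acc %.2f\n",
                i, top$combo_id[i], top$auc[i], top$sensitivity[i],
                top$specificity[i], top$accuracy[i]))
  invisible(x)
}
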