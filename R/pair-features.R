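#' Enumerate all unordered assay pairs
#'
#' For an n-assay panel there are n(n-1)/2 unordered pairs; each is a
#' candidate ratio biomarker. Pairs are returned in deterministic
#' lexicographic order of the panel's assay ordering (first member always
#' precedes the second).
#'
#' @param x a `mirna_panel`, a `ct_matrix`, or a character vector of assay ids
#' @return data frame with columns `mirna_a`, `mirna_b`, `pair_id`
#'   (`"a/b"`), one row per unordered pair
#' @export
enumerate_pairs <- function(x) {
  assays <- if (inherits(x, "ct_matrix")) x$assays
  else if (is.data.frame(x)) x$mirna_id
  else as.character(x)
  if (anyDuplicated(assays)) stop("assay ids must be unique")
  n <- length(assays)
  if (n < 2) stop("need at least 2 assays to form pairs")
  idx <- utils::combn(n, 2)
  out <- data.frame(mirna_a = assays[idx[1, ]],
                    mirna_b = assays[idx[2, ]],
                    stringsAsFactors = FALSE)
  out$pair_id <- paste(out$mirna_a, out$mirna_b, sep = "/")
  out
}

#' Compute the ratio feature for one miRNA pair
#'
#' Within each sample, the pair ratio is `2^(Ct_a - Ct_b)` and its log2 value
#' is `Ct_a - Ct_b`. Because any additive per-sample technical offset (input
#' amount, extraction or RT efficiency) shifts both Ct values equally, it
#' cancels exactly in the difference — the panel's internal normalization.
#' Samples where either member is censored still receive a value (from the
#' ceiling imputation) but are flagged.
#'
#' @param ct a `ct_matrix`
#' @param a,b assay ids (must differ and be present in `ct`)
#' @return object of class `pair_feature`: list with `mirna_a`, `mirna_b`,
#'   `pair_id`, per-sample `log2_ratio` and `ratio`, `any_censored` flags,
#'   `cohort`, `sample_id`
#' @export
pair_feature <- function(ct, a, b) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (identical(a, b)) stop("pair members must differ: ", a)
  miss <- setdiff(c(a, b), ct$assays)
  if (length(miss)) stop("assay(s) not in matrix: ", paste(miss, collapse = ", "))
  l2 <- ct$ct[, a] - ct$ct[, b]
  structure(list(
    mirna_a = a, mirna_b = b,
    pair_id = paste(a, b, sep = "/"),
    log2_ratio = unname(l2),
    ratio = unname(2 ^ l2),
    any_censored = unname(ct$censored[, a] | ct$censored[, b]),
    cohort = ct$samples$cohort,
    sample_id = ct$samples$sample_id
  ), class = "pair_feature")
}

#' @export
print.pair_feature <- function(x, ...) {
  cat(sprintf("<pair_feature> %s: n=%d (%d flagged censored)\n",
              x$pair_id, length(x$log2_ratio), sum(x$any_censored)))
  invisible(x)
}

#' Samples-by-pairs feature matrix
#'
#' Computes the log2 ratio feature (`Ct_a - Ct_b`) for every requested pair
#' in one pass; the workhorse behind the exhaustive screens.
#'
#' @param ct a `ct_matrix`
#' @param pairs a pair table from [enumerate_pairs()]; defaults to all pairs
#'   of `ct`'s assays
#' @param value `"log2"` (default, working scale) or `"ratio"` (2^ scale)
#' @return numeric matrix, samples x pairs, with `pair_id` column names and a
#'   `"censored"` attribute (logical matrix: either member censored)
#' @export
pair_feature_matrix <- function(ct, pairs = NULL, value = c("log2", "ratio")) {
  stopifnot(inherits(ct, "ct_matrix"))
  value <- match.arg(value)
  if (is.null(pairs)) pairs <- enumerate_pairs(ct)
  ia <- match(pairs$mirna_a, ct$assays)
  ib <- match(pairs$mirna_b, ct$assays)
  if (anyNA(ia) || anyNA(ib)) stop("pair table references assays not in matrix")
  m <- ct$ct[, ia, drop = FALSE] - ct$ct[, ib, drop = FALSE]
  cen <- ct$censored[, ia, drop = FALSE] | ct$censored[, ib, drop = FALSE]
  colnames(m) <- colnames(cen) <- pairs$pair_id
  rownames(m) <- rownames(cen) <- ct$samples$sample_id
  if (value == "ratio") m <- 2 ^ m
  attr(m, "censored") <- cen
  m
}
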