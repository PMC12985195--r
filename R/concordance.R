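#' Plasma vs tissue expression-profile concordance
#'
#' Quantifies how similar two per-assay mean Ct profiles are — e.g. plasma
#' versus matched tumor tissue across a panel. Per-assay mean Ct is computed
#' over uncensored wells in each matrix; the summary reports the mean Ct
#' shift (second minus first: negative when the second matrix amplifies
#' earlier, i.e. expresses higher), Spearman and Pearson correlations of the
#' two profiles, and a detectability cross-table (assays with at least one
#' uncensored well in both / one / neither matrix). The choice of rank plus
#' linear correlation on mean profiles is this package's quantification of
#' "pattern similarity"; it is labeled as such in the output.
#'
#' @param a,b `ct_matrix` objects (e.g. plasma and tissue); assays are
#'   aligned via [align_profiles()] first
#' @return object of class `concordance`: list with `n_assays`, `shift`
#'   (mean Ct, b minus a), `spearman`, `pearson`, `detectability` (2x2
#'   table), and `profile` (per-assay data frame)
#' @export
profile_concordance <- function(a, b) {
  al <- align_profiles(a, b)
  a <- al$a
  b <- al$b
  mean_unc <- function(x) {
    vapply(seq_along(x$assays), function(j) {
      v <- x$ct[!x$censored[, j], j]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  ma <- mean_unc(a)
  mb <- mean_unc(b)
  ok <- !is.na(ma) & !is.na(mb)
  if (sum(ok) < 3)
    stop("fewer than 3 shared assays with uncensored values; correlation undefined")

  det_a <- colSums(!a$censored) > 0
  det_b <- colSums(!b$censored) > 0
  detectability <- table(factor(ifelse(det_a, "detected", "undetected"),
                                levels = c("detected", "undetected")),
                         factor(ifelse(det_b, "detected", "undetected"),
                                levels = c("detected", "undetected")),
                         dnn = c("a", "b"))

  profile <- data.frame(mirna_id = a$assays, mean_ct_a = ma, mean_ct_b = mb,
                        shift = mb - ma, stringsAsFactors = FALSE)
  structure(list(
    n_assays = sum(ok),
    shift = mean(mb[ok] - ma[ok]),
    spearman = stats::cor(ma[ok], mb[ok], method = "spearman"),
    pearson = stats::cor(ma[ok], mb[ok], method = "pearson"),
    detectability = detectability,
    profile = profile
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d assays compared\n", x$n_assays))
  cat(sprintf("  mean Ct shift (b - a): %+.2f cycles\n", x$shift))
  cat(sprintf("  profile correlation: Spearman %.3f, Pearson %.3f\n",
              x$spearman, x$pearson))
  invisible(x)
}
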