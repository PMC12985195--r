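#' Construct a two-cohort Ct matrix
#'
#' The central container of the package: a samples-by-assays matrix of qPCR
#' cycle-threshold (Ct) values together with cohort labels, sample type and a
#' censoring mask. Wells that never amplified within `max_cycles` cycles
#' ("Undetermined" exports) are imputed at `max_cycles` and flagged censored
#' rather than dropped, so downstream QC filters decide their fate.
#'
#' @param ct numeric matrix, samples in rows, assays in columns. Row names are
#'   sample ids, column names assay (miRNA) ids.
#' @param cohort character/factor of length `nrow(ct)` with values `"case"`
#'   or `"control"`.
#' @param censored logical matrix of the same shape as `ct`, `TRUE` where no
#'   amplification occurred. Defaults to all-`FALSE`.
#' @param sample_type `"plasma"` or `"tissue"`, recycled to the sample count.
#' @param max_cycles cycling ceiling of the qPCR program (default 40).
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `censored`, `samples` (data frame with `sample_id`, `cohort`,
#'   `sample_type`), `assays`, `max_cycles`.
#' @export
ct_matrix <- function(ct, cohort, censored = NULL, sample_type = "plasma",
                      max_cycles = 40) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x assays)")
  if (is.null(rownames(ct)))
    rownames(ct) <- sprintf("S%03d", seq_len(nrow(ct)))
  if (is.null(colnames(ct)))
    stop("`ct` must have assay ids as column names")
  if (anyDuplicated(colnames(ct)))
    stop("duplicated assay ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  if (!identical(dim(censored), dim(ct)))
    stop("`censored` must have the same dimensions as `ct`")
  storage.mode(censored) <- "logical"
  dimnames(censored) <- dimnames(ct)
  cohort <- as_cohort(cohort, n = nrow(ct))
  sample_type <- rep_len(as.character(sample_type), nrow(ct))
  if (!all(sample_type %in% c("plasma", "tissue")))
    stop("sample_type must be 'plasma' or 'tissue'")

  if (any(!is.finite(ct)))
    stop("all Ct values must be finite; encode missing wells as censored")
  if (any(ct[censored] != max_cycles))
    stop("censored wells must carry ct = max_cycles (", max_cycles, ")")
  unc <- ct[!censored]
  if (length(unc) && (any(unc <= 0) || any(unc > max_cycles)))
    stop("uncensored Ct values must lie in (0, max_cycles]")

  structure(
    list(
      ct = ct,
      censored = censored,
      samples = data.frame(
        sample_id = rownames(ct),
        cohort = cohort,
        sample_type = sample_type,
        stringsAsFactors = FALSE
      ),
      assays = colnames(ct),
      max_cycles = max_cycles
    ),
    class = "ct_matrix"
  )
}

# canonical cohort factor: control is the reference level, case the positive
as_cohort <- function(x, n = NULL) {
  x <- as.character(x)
  if (!is.null(n) && length(x) != n)
    stop("cohort labels must match the number of samples")
  bad <- setdiff(unique(x), c("case", "control"))
  if (length(bad))
    stop("cohort labels must be 'case' or 'control'; saw: ",
         paste(bad, collapse = ", "))
  factor(x, levels = c("control", "case"))
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Number of samples / assays in a `ct_matrix`
#' @param x a `ct_matrix`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$ct)

#' @rdname n_samples
#' @export
n_assays <- function(x) ncol(x$ct)

#' Subset a Ct matrix by samples and/or assays
#'
#' @param x a `ct_matrix`
#' @param i sample index (integer, logical or sample ids)
#' @param j assay index (integer, logical or assay ids)
#' @param ... ignored
#' @return a `ct_matrix` restricted to the selection
#' @export
`[.ct_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$ct))
  if (missing(j)) j <- seq_len(ncol(x$ct))
  ct <- x$ct[i, j, drop = FALSE]
  cen <- x$censored[i, j, drop = FALSE]
  smp <- x$samples[match(rownames(ct), x$samples$sample_id), , drop = FALSE]
  ct_matrix(ct, cohort = smp$cohort, censored = cen,
            sample_type = smp$sample_type, max_cycles = x$max_cycles)
}

#' @export
print.ct_matrix <- function(x, ...) {
  tab <- table(x$samples$cohort)
  cat(sprintf("<ct_matrix> %d samples x %d assays (%d case / %d control, %s)\n",
              nrow(x$ct), ncol(x$ct), tab[["case"]], tab[["control"]],
              paste(unique(x$samples$sample_type), collapse = "+")))
  cat(sprintf("  censored wells: %d (%.1f%%); Ct ceiling %d cycles\n",
              sum(x$censored), 100 * mean(x$censored), x$max_cycles))
  invisible(x)
}

#' Write a Ct matrix as a long-format delimited table
#'
#' Emits the package's canonical long CSV dialect
#' (`sample_id,cohort,sample_type,assay,ct`), with censored wells written as
#' `"Undetermined"` so that [read_ct_table()] round-trips values and flags
#' bit-exactly.
#'
#' @param x a `ct_matrix`
#' @param path output file path
#' @param sep field separator (default comma)
#' @return `path`, invisibly
#' @export
write_ct_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ct_matrix"))
  long <- data.frame(
    sample_id = rep(x$samples$sample_id, times = ncol(x$ct)),
    cohort = rep(as.character(x$samples$cohort), times = ncol(x$ct)),
    sample_type = rep(x$samples$sample_type, times = ncol(x$ct)),
    assay = rep(x$assays, each = nrow(x$ct)),
    ct = ifelse(as.vector(x$censored), "Undetermined",
                format(as.vector(x$ct), digits = 17, trim = TRUE,
                       scientific = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
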