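#' Assay and run-control QC thresholds
#'
#' The elimination stage drops assays with poor detectability, excessive
#' variability or failed run controls. No community-standard numeric cutoffs
#' exist for custom plasma panels, so the defaults below are stated
#' conventions, echoed in every [assess_assays()] report:
#' \itemize{
#'   \item `min_detect_rate` (0.8): an assay must amplify (uncensored) in at
#'     least this fraction of samples in *each* cohort;
#'   \item `max_assay_sd` (3 Ct): within-cohort SD of uncensored Ct values
#'     must not exceed this in any cohort;
#'   \item `ntc_max_ct_margin` (5 Ct): a no-template control must sit at
#'     least this many cycles above the plate's sample Ct median (or be
#'     censored), else the plate is flagged for contamination;
#'   \item `spikein_sd_max` (2 Ct): spike-in Ct SD across plates above this
#'     flags the batch for processing drift.
#' }
#'
#' @param min_detect_rate fraction in \[0, 1\]
#' @param max_assay_sd Ct cycles
#' @param ntc_max_ct_margin Ct cycles
#' @param spikein_sd_max Ct cycles
#' @return a list of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_detect_rate = 0.8, max_assay_sd = 3.0,
                          ntc_max_ct_margin = 5.0, spikein_sd_max = 2.0) {
  stopifnot(min_detect_rate >= 0, min_detect_rate <= 1,
            max_assay_sd >= 0, ntc_max_ct_margin >= 0, spikein_sd_max >= 0)
  structure(list(min_detect_rate = min_detect_rate,
                 max_assay_sd = max_assay_sd,
                 ntc_max_ct_margin = ntc_max_ct_margin,
                 spikein_sd_max = spikein_sd_max),
            class = "qc_thresholds")
}

#' Assess assays for elimination
#'
#' Computes per-assay, per-cohort detection rates (fraction of uncensored
#' wells) and Ct standard deviations (over uncensored wells), and fails an
#' assay that undershoots the detection-rate floor or overshoots the SD
#' ceiling in either cohort.
#'
#' @param ct a `ct_matrix` with at least 2 samples per cohort
#' @param thresholds a [qc_thresholds()] object
#' @return an object of class `qc_report`: list with `assays` (per-assay data
#'   frame with rates, SDs, `pass`, `reason`), `eliminated_assays`, and the
#'   `thresholds` in force
#' @export
assess_assays <- function(ct, thresholds = qc_thresholds()) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(thresholds, "qc_thresholds"))
  coh <- ct$samples$cohort
  if (any(table(coh) < 2))
    stop("each cohort needs at least 2 samples for QC assessment")

  per_cohort <- function(fun) {
    vapply(c(control = "control", case = "case"), function(g) {
      idx <- which(coh == g)
      vapply(seq_along(ct$assays), function(j) {
        fun(ct$ct[idx, j], ct$censored[idx, j])
      }, numeric(1))
    }, numeric(length(ct$assays)))
  }
  detect <- per_cohort(function(v, cen) mean(!cen))
  sds <- per_cohort(function(v, cen) {
    u <- v[!cen]
    if (length(u) >= 2) stats::sd(u) else NA_real_
  })

  fail_detect <- detect[, "control"] < thresholds$min_detect_rate |
    detect[, "case"] < thresholds$min_detect_rate
  fail_sd <- (!is.na(sds[, "control"]) & sds[, "control"] > thresholds$max_assay_sd) |
    (!is.na(sds[, "case"]) & sds[, "case"] > thresholds$max_assay_sd)

  reason <- character(length(ct$assays))
  reason[fail_sd] <- "variability"
  reason[fail_detect] <- ifelse(fail_sd[fail_detect],
                                "detectability,variability", "detectability")
  assays <- data.frame(
    mirna_id = ct$assays,
    detect_rate_control = detect[, "control"],
    detect_rate_case = detect[, "case"],
    sd_control = sds[, "control"],
    sd_case = sds[, "case"],
    pass = !(fail_detect | fail_sd),
    reason = reason,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(assays = assays,
                 eliminated_assays = assays$mirna_id[!assays$pass],
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d assays assessed, %d eliminated\n",
              nrow(x$assays), length(x$eliminated_assays)))
  if (length(x$eliminated_assays)) {
    cat("  eliminated:", paste(x$eliminated_assays, collapse = ", "), "\n")
  }
  th <- x$thresholds
  cat(sprintf("  thresholds: detect rate >= %.2f per cohort, assay SD <= %.1f Ct\n",
              th$min_detect_rate, th$max_assay_sd))
  invisible(x)
}

#' Check plate and batch run controls
#'
#' NTC wells that amplify within `ntc_max_ct_margin` cycles of the plate's
#' sample Ct median indicate contamination and flag the plate. Spike-in
#' (UniSp3/UniSp6) Ct variation across plates above `spikein_sd_max` flags
#' the whole batch for processing drift. Spike-ins are used only as flags,
#' never for normalization (pair ratios normalize by construction).
#'
#' @param controls a [control_wells()] data frame
#' @param thresholds a [qc_thresholds()] object
#' @param sample_median plate-level sample Ct median(s): a single number or a
#'   named vector keyed by `plate_id`. If `NULL`, the NTC proximity rule is
#'   skipped with a warning.
#' @return list of class `run_control_report`: `plates` (per-plate NTC
#'   verdicts), `spikeins` (per-control-type across-plate SD and verdict),
#'   `flagged_plates`, `batch_flagged`
#' @export
check_run_controls <- function(controls, thresholds = qc_thresholds(),
                               sample_median = NULL) {
  stopifnot(inherits(controls, "control_wells"))
  if (nrow(controls) == 0) stop("`controls` is empty")

  plates <- unique(controls$plate_id)
  ntc_pass <- rep(TRUE, length(plates))
  names(ntc_pass) <- plates
  ntc <- controls[controls$control_type == "NTC", , drop = FALSE]
  if (nrow(ntc)) {
    if (is.null(sample_median)) {
      warning("no sample_median supplied; NTC proximity check skipped")
    } else {
      med <- if (length(sample_median) == 1 && is.null(names(sample_median)))
        stats::setNames(rep(sample_median, length(plates)), plates)
      else sample_median
      for (i in seq_len(nrow(ntc))) {
        p <- ntc$plate_id[i]
        if (!ntc$censored[i] && p %in% names(med) &&
            (ntc$ct[i] - med[[p]]) < thresholds$ntc_max_ct_margin) {
          ntc_pass[p] <- FALSE
        }
      }
    }
  }

  spike <- controls[controls$control_type %in% c("UniSp3", "UniSp6"), ,
                    drop = FALSE]
  spikeins <- do.call(rbind, lapply(split(spike, spike$control_type), function(d) {
    u <- d$ct[!d$censored]
    s <- if (length(u) >= 2) stats::sd(u) else NA_real_
    data.frame(control_type = d$control_type[1], n_plates = nrow(d), sd = s,
               pass = is.na(s) || s <= thresholds$spikein_sd_max,
               stringsAsFactors = FALSE)
  }))
  rownames(spikeins) <- NULL
  if (is.null(spikeins))
    spikeins <- data.frame(control_type = character(), n_plates = integer(),
                           sd = numeric(), pass = logical())

  structure(list(
    plates = data.frame(plate_id = plates, ntc_pass = unname(ntc_pass),
                        stringsAsFactors = FALSE),
    spikeins = spikeins,
    flagged_plates = plates[!ntc_pass],
    batch_flagged = any(!spikeins$pass)
  ), class = "run_control_report")
}

#' Apply an elimination report to a Ct matrix
#'
#' Restricts the matrix to assays that passed QC; retained Ct values and the
#' sample set are untouched, so the operation is idempotent.
#'
#' @param ct a `ct_matrix`
#' @param report a `qc_report` produced from the same assay set
#' @return a `ct_matrix` with only passing assays
#' @export
apply_elimination <- function(ct, report) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(report, "qc_report"))
  if (!all(ct$assays %in% report$assays$mirna_id))
    stop("QC report was produced from a different assay set")
  keep <- intersect(ct$assays,
                    report$assays$mirna_id[report$assays$pass])
  if (!length(keep))
    stop("all assays eliminated; nothing survives QC")
  ct[, keep]
}
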