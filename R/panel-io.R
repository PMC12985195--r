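#' Canonicalize miRNA assay identifiers
#'
#' Vendors and publications use slightly different names for the same mature
#' miRNA (e.g. "miR-451a" vs "miR-451a-5p"). A packaged synonym table maps
#' known aliases onto one canonical miRBase-style id so that panel
#' definitions, Ct exports and classifier reports resolve against each other.
#'
#' @param x character vector of assay ids
#' @param synonyms data frame with columns `alias`, `canonical`; defaults to
#'   the packaged table.
#' @return character vector of canonical ids
#' @export
normalize_mirna_id <- function(x, synonyms = mirna_synonyms()) {
  x <- trimws(as.character(x))
  hit <- match(x, synonyms$alias)
  x[!is.na(hit)] <- synonyms$canonical[hit[!is.na(hit)]]
  x
}

#' Packaged miRNA synonym table
#' @return data frame with columns `alias`, `canonical`
#' @export
mirna_synonyms <- function() {
  path <- system.file("extdata", "mirna_synonyms.csv", package = "mirpair")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

panel_roles <- c("oncomiR", "tumor_suppressor", "context_dependent")

normalize_role <- function(x) {
  key <- gsub("[^a-z]", "_", tolower(trimws(x)))
  map <- c(oncomir = "oncomiR",
           tumor_suppressor = "tumor_suppressor",
           context_dependent = "context_dependent")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unknown role token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected oncomiR / tumor_suppressor / context_dependent)")
  out
}

#' Read a panel definition
#'
#' A panel definition is a delimited text file with a header row and columns
#' `mirna_id`, `role` (oncomiR / tumor_suppressor / context_dependent) and
#' `brain_enriched` (logical, or "+"/"-"). Assay ids are canonicalized via
#' the packaged synonym table; duplicates are a hard error.
#'
#' @param path file path (TSV or CSV; separator sniffed from the header)
#' @return data frame of class `mirna_panel` with columns `mirna_id`, `role`,
#'   `brain_enriched`, in file order
#' @export
read_panel <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("mirna_id", "role", "brain_enriched")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("panel file has no assay rows")
  df$mirna_id <- normalize_mirna_id(df$mirna_id)
  dup <- unique(df$mirna_id[duplicated(df$mirna_id)])
  if (length(dup))
    stop("duplicated assay id(s) in panel: ", paste(dup, collapse = ", "))
  df$role <- normalize_role(df$role)
  be <- df$brain_enriched
  if (!is.logical(be)) {
    be <- trimws(as.character(be))
    be <- ifelse(be %in% c("+", "TRUE", "true", "1", "yes"), TRUE,
                 ifelse(be %in% c("-", "FALSE", "false", "0", "no"), FALSE, NA))
    if (anyNA(be)) stop("brain_enriched must be logical or '+'/'-'")
  }
  df$brain_enriched <- be
  out <- df[, need]
  class(out) <- c("mirna_panel", "data.frame")
  out
}

#' The packaged 48-miRNA glioblastoma panel
#'
#' Curated panel of 48 miRNAs relevant to glioblastoma and brain health
#' (oncomiRs, tumor suppressors and context-dependent miRNAs, most
#' brain-enriched), shipped as a plain-text fixture.
#'
#' @return a `mirna_panel` data frame with 48 rows
#' @export
gbm_panel <- function() {
  read_panel(system.file("extdata", "gbm_panel_48.tsv", package = "mirpair"))
}

ct_censor_tokens <- c("Undetermined", "undetermined", "NA", "")

#' Read a Ct table into a `ct_matrix`
#'
#' Long layout expects columns `sample_id`, `cohort`, `assay`, `ct` (optional
#' `sample_type`, `plate`, `well`); wide layout expects one row per sample
#' with `sample_id`, `cohort` (optional `sample_type`) followed by one column
#' per assay. `"Undetermined"`, `"NA"` and empty cells are parsed as censored
#' wells at the Ct ceiling. Replicate wells for the same (sample, assay) are
#' collapsed by the median of their uncensored values; a cell whose wells are
#' all censored stays censored.
#'
#' @param path delimited text file (separator sniffed from the header)
#' @param layout `"long"` (canonical) or `"wide"`
#' @param panel a `mirna_panel`; assay names not in the panel are an error
#' @param max_cycles Ct ceiling used for censored wells (default 40)
#' @return a `ct_matrix` with assays ordered as in `panel`
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), panel,
                          max_cycles = 40) {
  layout <- match.arg(layout)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          colClasses = "character", check.names = FALSE)
  if (layout == "wide") df <- wide_to_long(df)
  need <- c("sample_id", "cohort", "assay", "ct")
  if (!all(need %in% names(df)))
    stop("long Ct table must have columns: ", paste(need, collapse = ", "))
  if (!"sample_type" %in% names(df)) df$sample_type <- "plasma"

  df$assay <- normalize_mirna_id(df$assay)
  unknown <- setdiff(unique(df$assay), panel$mirna_id)
  if (length(unknown))
    stop("assay(s) not in panel: ", paste(unknown, collapse = ", "))

  all_ids <- unique(df$sample_id)
  raw <- trimws(df$ct)
  censored <- raw %in% ct_censor_tokens | is.na(raw)
  val <- suppressWarnings(as.numeric(raw))
  parseable <- censored | !is.na(val)
  if (any(!parseable)) {
    warning("dropping ", sum(!parseable), " unparseable Ct cell(s)")
    df <- df[parseable, , drop = FALSE]
    censored <- censored[parseable]
    val <- val[parseable]
  }
  empty <- setdiff(all_ids, df$sample_id)
  if (length(empty) || nrow(df) == 0)
    stop("sample(s) with zero parseable wells: ",
         paste(if (length(empty)) empty else all_ids, collapse = ", "))
  val[censored] <- max_cycles

  samples <- unique(df[, c("sample_id", "cohort", "sample_type")])
  if (anyDuplicated(samples$sample_id))
    stop("inconsistent cohort/sample_type annotation for: ",
         paste(samples$sample_id[duplicated(samples$sample_id)], collapse = ", "))
  assays <- panel$mirna_id[panel$mirna_id %in% df$assay]

  ct <- matrix(NA_real_, nrow(samples), length(assays),
               dimnames = list(samples$sample_id, assays))
  cen <- matrix(TRUE, nrow(samples), length(assays),
                dimnames = list(samples$sample_id, assays))
  key <- split(seq_len(nrow(df)), list(df$sample_id, df$assay), drop = TRUE)
  for (k in names(key)) {
    idx <- key[[k]]
    s <- df$sample_id[idx[1]]
    a <- df$assay[idx[1]]
    unc <- idx[!censored[idx]]
    if (length(unc)) {
      ct[s, a] <- stats::median(val[unc])
      cen[s, a] <- FALSE
    } else {
      ct[s, a] <- max_cycles
      cen[s, a] <- TRUE
    }
  }
  if (anyNA(ct)) {
    # wells never observed for a (sample, assay) combination: censored ceiling
    cen[is.na(ct)] <- TRUE
    ct[is.na(ct)] <- max_cycles
  }
  ct_matrix(ct, cohort = samples$cohort, censored = cen,
            sample_type = samples$sample_type, max_cycles = max_cycles)
}

wide_to_long <- function(df) {
  meta <- intersect(c("sample_id", "cohort", "sample_type"), names(df))
  if (!all(c("sample_id", "cohort") %in% meta))
    stop("wide Ct table must have sample_id and cohort columns")
  assay_cols <- setdiff(names(df), meta)
  if (!length(assay_cols)) stop("wide Ct table has no assay columns")
  out <- do.call(rbind, lapply(assay_cols, function(a) {
    cbind(df[, meta, drop = FALSE],
          data.frame(assay = a, ct = df[[a]], stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Restrict two Ct matrices to their shared assays
#'
#' Prerequisite for profile comparisons (e.g. plasma vs tumor tissue): both
#' matrices are restricted to the intersection of their assay sets, in
#' identical order.
#'
#' @param a,b `ct_matrix` objects
#' @return a list with elements `a` and `b`, both restricted to the shared
#'   assays
#' @export
align_profiles <- function(a, b) {
  stopifnot(inherits(a, "ct_matrix"), inherits(b, "ct_matrix"))
  shared <- intersect(a$assays, b$assays)
  if (length(shared) < 2)
    stop("matrices share fewer than 2 assays (", length(shared), ")")
  list(a = a[, shared], b = b[, shared])
}

control_types <- c("UniSp3", "UniSp6", "BlankSpot", "NTC", "PosCtrl")

#' Construct a run-control well table
#'
#' Run controls monitor the wet-lab process: `UniSp3`/`UniSp6` spike-ins
#' (extraction/RT/qPCR efficiency), `BlankSpot` empty wells, `NTC`
#' no-template contamination sentinels, and `PosCtrl` synthetic-oligo
#' positive controls.
#'
#' @param control_type one of UniSp3, UniSp6, BlankSpot, NTC, PosCtrl
#' @param plate_id plate identifier
#' @param ct numeric Ct, or `NA` for a censored (non-amplifying) well
#' @param max_cycles Ct ceiling (default 40)
#' @return data frame of class `control_wells` with columns `control_type`,
#'   `plate_id`, `ct`, `censored`
#' @export
control_wells <- function(control_type, plate_id, ct, max_cycles = 40) {
  control_type <- as.character(control_type)
  bad <- setdiff(unique(control_type), control_types)
  if (length(bad))
    stop("unknown control_type(s): ", paste(bad, collapse = ", "))
  ct <- as.numeric(ct)
  censored <- is.na(ct) | ct >= max_cycles
  ct[censored] <- max_cycles
  out <- data.frame(control_type = control_type,
                    plate_id = as.character(plate_id),
                    ct = ct, censored = censored,
                    stringsAsFactors = FALSE)
  class(out) <- c("control_wells", "data.frame")
  out
}

#' Read control wells from a CSV
#' @param path CSV with columns `control_type`, `plate_id`, `ct`
#'   ("Undetermined"/"NA"/empty parse as censored)
#' @param max_cycles Ct ceiling (default 40)
#' @return a `control_wells` data frame
#' @export
read_control_wells <- function(path, max_cycles = 40) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  raw <- trimws(df$ct)
  ct <- suppressWarnings(as.numeric(raw))
  ct[raw %in% ct_censor_tokens] <- NA
  control_wells(df$control_type, df$plate_id, ct, max_cycles = max_cycles)
}
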