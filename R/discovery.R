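#' Resolved configuration for a discovery run
#'
#' Bundles every setting of the end-to-end pipeline so a run is fully
#' reproducible from its serialized config. Either pass an in-memory
#' `ct_matrix` or paths to a panel definition and Ct table.
#'
#' @param ct a `ct_matrix` (takes precedence over paths)
#' @param ct_path,panel_path,layout input files for [read_ct_table()]
#' @param qc a [qc_thresholds()] object
#' @param auc_min inclusive AUC gate for pair selection (default 0.8)
#' @param ci_method `"delong"` or `"bootstrap"`
#' @param k combination size (default 3)
#' @param combo_mode `"standardized_log"` or `"raw_ratio"`
#' @param criteria combination floors, see [combo_search()]
#' @param exclude_censored drop censor-flagged samples per pair
#' @param out_dir output directory (created if needed); `NULL` for an
#'   in-memory run with no artifacts
#' @param seed integer seed recorded in the log and used for any seeded step
#' @return list of class `discovery_config`
#' @export
discovery_config <- function(ct = NULL, ct_path = NULL, panel_path = NULL,
                             layout = "long", qc = qc_thresholds(),
                             auc_min = 0.8,
                             ci_method = c("delong", "bootstrap"), k = 3,
                             combo_mode = c("standardized_log", "raw_ratio"),
                             criteria = list(min_sens = 0, min_spec = 0,
                                             min_auc = 0),
                             exclude_censored = FALSE,
                             out_dir = NULL, seed = 1L) {
  ci_method <- match.arg(ci_method)
  combo_mode <- match.arg(combo_mode)
  if (is.null(ct) && is.null(ct_path))
    stop("provide either `ct` or `ct_path`")
  structure(list(ct = ct, ct_path = ct_path, panel_path = panel_path,
                 layout = layout, qc = qc, auc_min = auc_min,
                 ci_method = ci_method, k = k, combo_mode = combo_mode,
                 criteria = criteria, exclude_censored = exclude_censored,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "discovery_config")
}

# tiny polynomial rolling hash for config provenance lines in the log
config_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_json <- function(config) {
  ser <- config[setdiff(names(config), "ct")]
  ser$qc <- unclass(ser$qc)
  ser$ct <- if (is.null(config$ct)) NULL else
    sprintf("<in-memory ct_matrix %dx%d>", nrow(config$ct$ct),
            ncol(config$ct$ct))
  jsonlite::toJSON(ser, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Run the discovery pipeline end to end
#'
#' Executes panel/Ct ingestion, QC elimination, pair-feature construction,
#' the exhaustive single-pair screen, the AUC gate and the exhaustive k-pair
#' combination search, writing plot-ready artifacts to `out_dir`: the
#' per-pair results TSV, the ranked-combination TSV, ROC point CSVs for the
#' top combinations, per-pair group-distribution summaries for the top
#' pairs, the QC report JSON, the resolved config and a run log. Any stage
#' failure aborts with a stage-named error and removes partial outputs. A
#' rerun with an identical config reproduces the tables byte for byte (the
#' pipeline itself is deterministic).
#'
#' @param config a [discovery_config()]
#' @return object of class `discovery_bundle`: list with `config`, `qc`,
#'   `screen`, `selection`, `search` (`NULL` when the gate is empty),
#'   `files`, `log`
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "discovery_config"))
  out_dir <- config$out_dir
  written <- character()
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  cfg_json <- config_json(config)
  say("mirpair %s | seed %d | config %s",
      as.character(utils::packageVersion("mirpair")), config$seed,
      config_hash(cfg_json))

  ct <- stage("panel_io", {
    if (!is.null(config$ct)) config$ct
    else {
      panel <- if (is.null(config$panel_path)) gbm_panel()
      else read_panel(config$panel_path)
      read_ct_table(config$ct_path, layout = config$layout, panel = panel)
    }
  })
  say("input: %d samples x %d assays", nrow(ct$ct), ncol(ct$ct))

  qc <- stage("qc_filtering", assess_assays(ct, config$qc))
  ct_f <- stage("qc_filtering", apply_elimination(ct, qc))
  say("qc: %d assays eliminated, %d retained",
      length(qc$eliminated_assays), ncol(ct_f$ct))
  emit("qc_report.json", function(p)
    jsonlite::write_json(list(thresholds = unclass(qc$thresholds),
                              assays = qc$assays,
                              eliminated = qc$eliminated_assays),
                         p, auto_unbox = TRUE, digits = NA))

  screen <- stage("single_pair_eval",
                  screen_pairs(ct_f, ci_method = config$ci_method,
                               exclude_censored = config$exclude_censored,
                               boot_seed = config$seed))
  say("screen: %d pairs evaluated (CI: %s)", nrow(screen$results),
      config$ci_method)
  emit("pair_results.tsv", function(p)
    utils::write.table(screen$results, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))

  selection <- stage("single_pair_eval", select_pairs(screen, config$auc_min))
  say("gate: %d pairs with AUC >= %.2f", nrow(selection), config$auc_min)

  fm <- pair_feature_matrix(ct_f)
  labels <- ct_f$samples$cohort

  # Fig 2-style per-cohort distribution summaries for the top pairs
  emit("top_pair_distributions.csv", function(p) {
    top <- utils::head(selection, 5)
    if (nrow(top) == 0)
      top <- utils::head(screen$results[order(-screen$results$auc), ], 5)
    rows <- do.call(rbind, lapply(top$pair_id, function(id) {
      do.call(rbind, lapply(c("control", "case"), function(g) {
        v <- fm[labels == g, id]
        q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
        data.frame(pair_id = id, cohort = g, min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
      }))
    }))
    utils::write.table(rows, p, sep = ",", row.names = FALSE, quote = FALSE)
  })

  search <- NULL
  if (nrow(selection) >= config$k) {
    search <- stage("combo_search", {
      if (config$combo_mode == "raw_ratio") {
        say("combo: raw_ratio mode — literal ratio-mean score; every sample")
        say("       is classified case (see documentation caveat)")
      }
      combo_search(selection, fm, labels, k = config$k,
                   criteria = config$criteria)
    })
    say("combo: %d combinations of k=%d evaluated, %d meet criteria",
        search$n_evaluated, config$k, nrow(search$results))
    emit("combo_results.tsv", function(p)
      utils::write.table(search$results, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
    emit("top_combo_roc.csv", function(p) {
      top <- utils::head(search$results, 3)
      rows <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
        cb <- build_combo(fm, unlist(top[i, grep("^member_", names(top))]),
                          labels, mode = config$combo_mode,
                          orientations = NULL)
        r <- roc_auc(cb$score, labels)
        data.frame(rank = i, combo_id = top$combo_id[i], r$roc)
      }))
      utils::write.table(rows, p, sep = ",", row.names = FALSE, quote = FALSE)
    })
  } else {
    say("combo: stage skipped — gate has %d pair(s), fewer than k=%d",
        nrow(selection), config$k)
  }

  emit("resolved_config.json", function(p) writeLines(cfg_json, p))
  emit("run.log", function(p) writeLines(log_lines, p))

  structure(list(config = config, qc = qc, screen = screen,
                 selection = selection, search = search,
                 files = written, log = log_lines),
            class = "discovery_bundle")
}

#' @export
print.discovery_bundle <- function(x, ...) {
  cat("<discovery_bundle>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Human-readable report from a discovery bundle
#'
#' Formats the bundle's numbers — top pairs, top combinations, QC summary
#' and every setting in force — into a plain-text report. Numbers are read
#' from the bundle, never recomputed, so the report cannot drift from the
#' table artifacts.
#'
#' @param bundle a `discovery_bundle`
#' @param path optional file to write the report to
#' @return character vector of report lines (invisibly if written)
#' @export
make_report <- function(bundle, path = NULL) {
  need <- c("config", "qc", "screen", "selection", "log")
  miss <- need[!vapply(need, function(n) !is.null(bundle[[n]]), logical(1))]
  if (length(miss))
    stop("bundle is missing member(s): ", paste(miss, collapse = ", "))
  cfg <- bundle$config
  out <- c(
    "== miRNA pair-ratio discovery report ==",
    "",
    sprintf("Samples: %d case / %d control | CI method: %s | AUC gate: >= %.2f",
            bundle$screen$n_case, bundle$screen$n_control,
            bundle$screen$ci_method, cfg$auc_min),
    "",
    sprintf("QC: %d assays assessed, %d eliminated (detect rate >= %.2f, SD <= %.1f Ct)",
            nrow(bundle$qc$assays), length(bundle$qc$eliminated_assays),
            bundle$qc$thresholds$min_detect_rate,
            bundle$qc$thresholds$max_assay_sd)
  )
  if (length(bundle$qc$eliminated_assays))
    out <- c(out, paste("  eliminated:",
                        paste(bundle$qc$eliminated_assays, collapse = ", ")))
  out <- c(out, "", "Top 5 pairs by AUC:")
  top <- utils::head(
    bundle$screen$results[order(-bundle$screen$results$auc,
                                bundle$screen$results$pair_id), ], 5)
  for (i in seq_len(nrow(top)))
    out <- c(out, sprintf(
      "  %d. %-28s AUC %.3f (%.3f-%.3f)  sens %.2f  spec %.2f  acc %.2f  MW p %.3g",
      i, top$pair_id[i], top$auc[i], top$auc_ci_low[i], top$auc_ci_high[i],
      top$sensitivity[i], top$specificity[i], top$accuracy[i], top$mw_p[i]))
  if (!is.null(bundle$search)) {
    out <- c(out, "", sprintf("Top combinations (k=%d, %d evaluated):",
                              bundle$search$k, bundle$search$n_evaluated))
    tc <- utils::head(bundle$search$results, 6)
    for (i in seq_len(nrow(tc)))
      out <- c(out, sprintf(
        "  %d. %s  AUC %.3f  sens %.2f  spec %.2f  acc %.2f",
        i, tc$combo_id[i], tc$auc[i], tc$sensitivity[i], tc$specificity[i],
        tc$accuracy[i]))
  } else {
    out <- c(out, "", "Combination stage skipped (gate smaller than k).")
  }
  if (identical(cfg$combo_mode, "raw_ratio"))
    out <- c(out, "",
             "CAVEAT: raw_ratio mode scores are strictly positive, so the p >= 0.5",
             "rule classifies every sample as case (specificity 0). This mode",
             "documents the literal ratio-mean formula; use standardized_log for",
             "meaningful classification.")
  out <- c(out, "", "Settings in force:",
           sprintf("  seed %d | k %d | combo_mode %s | exclude_censored %s",
                   cfg$seed, cfg$k, cfg$combo_mode, cfg$exclude_censored),
           sprintf("  criteria: min_sens %.2f, min_spec %.2f, min_auc %.2f",
                   cfg$criteria$min_sens %||% 0, cfg$criteria$min_spec %||% 0,
                   cfg$criteria$min_auc %||% 0),
           "  evaluation is in-sample by design (screening, not validation)")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
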