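#' Load a reference violation-count table
#'
#' CSV with an `id` column and one column per reference source (e.g.
#' `swissadme`, `molinspiration`, `manual`). Empty cells and `NaN` mark
#' molecules a platform could not process (large structures with long
#' SMILES are a known failure mode); they are preserved as missing, never
#' coerced to zero.
#'
#' @param path CSV file path.
#' @return data.frame with `id` and one integer-or-NA column per source.
#' @export
load_reference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "NaN", "nan", ""))
  if (!"id" %in% names(df)) {
    stop("reference table '", path, "' has no 'id' column", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id '", df$id[duplicated(df$id)][1],
         "' in reference table", call. = FALSE)
  }
  sources <- setdiff(names(df), "id")
  if (length(sources) == 0L) {
    stop("reference table has no source columns", call. = FALSE)
  }
  for (s in sources) {
    x <- suppressWarnings(as.numeric(df[[s]]))
    bad <- !is.na(df[[s]]) & is.na(x)
    if (any(bad)) {
      stop("non-numeric reference value '", df[[s]][bad][1],
           "' in column '", s, "'", call. = FALSE)
    }
    df[[s]] <- as.integer(x)
  }
  df$id <- as.character(df$id)
  df
}

#' Compare model predictions against reference violation counts
#'
#' Joins a prediction table to reference counts and accounts for
#' per-molecule agreement: signed deltas (prediction minus reference),
#' exact matches, off-by-one cases and missing references. Molecules
#' without a reference from a source are excluded from that source's
#' denominator rather than imputed. The signed-delta histogram surfaces
#' systematic +/-1 biases between a counter implementation and a platform.
#'
#' @param preds data.frame with an `id` column and one or more integer
#'   prediction columns (one per model configuration, e.g. `cls_10`).
#' @param refs reference table from [load_reference_table()].
#' @param rule rule name, recorded in the report.
#' @return a `dl_comparison`: list with `rule`, `rows` (per-molecule wide
#'   table with `delta_` and `match_` columns), `summary` (one row per
#'   (prediction, source) pair: `n_compared`, `n_exact`, `n_off_by_one`,
#'   `n_missing`) and `delta_hist` (signed-delta counts per pair).
#' @export
compare_predictions <- function(preds, refs, rule) {
  if (!"id" %in% names(preds)) stop("'preds' needs an 'id' column",
                                    call. = FALSE)
  pred_cols <- setdiff(names(preds), "id")
  if (length(pred_cols) == 0L) stop("'preds' has no prediction columns",
                                    call. = FALSE)
  if (anyDuplicated(preds$id)) stop("duplicate id in predictions",
                                    call. = FALSE)
  sources <- setdiff(names(refs), "id")
  rows <- merge(preds, refs, by = "id", all.x = TRUE, sort = FALSE)
  rows <- rows[match(preds$id, rows$id), , drop = FALSE]

  summary_rows <- list()
  hist_rows <- list()
  for (p in pred_cols) {
    for (s in sources) {
      delta <- rows[[p]] - rows[[s]]
      rows[[paste0("delta_", p, "_", s)]] <- delta
      rows[[paste0("match_", p, "_", s)]] <- delta == 0L
      present <- !is.na(delta)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        prediction = p, source = s,
        n_compared = sum(present),
        n_exact = sum(delta == 0L, na.rm = TRUE),
        n_off_by_one = sum(abs(delta) == 1L, na.rm = TRUE),
        n_missing = sum(!present),
        stringsAsFactors = FALSE)
      if (any(present)) {
        tb <- table(delta[present])
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          prediction = p, source = s,
          delta = as.integer(names(tb)), count = as.integer(tb),
          stringsAsFactors = FALSE)
      }
    }
  }
  rownames(rows) <- NULL
  structure(list(rule = rule, rows = rows,
                 summary = do.call(rbind, summary_rows),
                 delta_hist = do.call(rbind, hist_rows)),
            class = "dl_comparison")
}

#' @export
print.dl_comparison <- function(x, ...) {
  cat("<comparison report> rule ", x$rule, ", ", nrow(x$rows),
      " molecules\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Per-molecule rows go to `<prefix>_rows.csv`; the per-source summaries
#' and delta histogram to `<prefix>_summary.json`.
#'
#' @param report a `dl_comparison`.
#' @param prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
write_comparison <- function(report, prefix) {
  stopifnot(inherits(report, "dl_comparison"))
  rows_path <- paste0(prefix, "_rows.csv")
  json_path <- paste0(prefix, "_summary.json")
  utils::write.csv(report$rows, rows_path, row.names = FALSE)
  jsonlite::write_json(list(rule = report$rule, summary = report$summary,
                            delta_hist = report$delta_hist),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(rows_path, json_path))
}
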