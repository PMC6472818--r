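ct_table_cols <- c("tech_id", "panel_id", "member_id", "aliquot_index",
                   "pcr_rep_index", "target", "ct")

#' Write / read a replicate-level Ct table
#'
#' The canonical on-disk form is a long-format, comma-delimited, UTF-8 table
#' with one row per PCR replicate and columns tech_id, panel_id, member_id,
#' aliquot_index, pcr_rep_index, target, ct. Ct is written to one decimal
#' place; undetected replicates are written as the token `ND`. On read, `ND`,
#' empty cells and Ct values beyond `max_cycles` are all normalized to
#' not-detected (`NA`); any other non-numeric Ct is rejected with its line
#' number, as are duplicate replicate keys.
#'
#' @param records Tibble of Ct records (as from [generate_study()]).
#' @param path File path.
#' @param max_cycles Detection cutoff used to censor read values (default 45).
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()` a
#'   tibble of records.
#' @export
write_ct_table <- function(records, path) {
  stopifnot(all(ct_table_cols %in% names(records)))
  out <- records[, ct_table_cols]
  out$ct <- ifelse(is.na(out$ct), "ND",
                   format(round_half_up(out$ct, 1), nsmall = 1, trim = TRUE))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path, max_cycles = 45) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(ct_table_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ct_chr <- trimws(raw$ct %||% "")
  nd <- is.na(ct_chr) | ct_chr == "" | toupper(ct_chr) == "ND"
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad <- !nd & is.na(ct)
  if (any(bad)) {
    abort(paste0("Non-numeric Ct value(s) other than the ND token at line(s) ",
                 paste(which(bad) + 1L, collapse = ", "), "."))
  }
  ct[nd] <- NA_real_
  ct[!is.na(ct) & ct > max_cycles] <- NA_real_
  if (any(!is.na(ct) & ct <= 0)) {
    abort(paste0("Nonpositive Ct at line(s) ",
                 paste(which(!is.na(ct) & ct <= 0) + 1L, collapse = ", "), "."))
  }
  key <- paste(raw$tech_id, raw$member_id, raw$aliquot_index,
               raw$pcr_rep_index, raw$target)
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    abort(paste0("Duplicate replicate key(s) at lines ",
                 paste(dup + 1L, collapse = ", "), "."))
  }
  tibble::tibble(
    tech_id = raw$tech_id, panel_id = raw$panel_id, member_id = raw$member_id,
    aliquot_index = as.integer(raw$aliquot_index),
    pcr_rep_index = as.integer(raw$pcr_rep_index),
    target = raw$target, ct = ct
  )
}

#' Blind or unblind a Ct table
#'
#' Blinding replaces the (panel, member, aliquot) identity of each record with
#' its four-digit code; unblinding restores it. The two operations are exact
#' inverses under the same map. An unknown code (or member/aliquot) signals a
#' mislabeled sample and is an error.
#'
#' @param records Ct records; blinded records carry a `code` column instead of
#'   panel_id/member_id/aliquot_index.
#' @param map Blinding map, as from [blinding_map()].
#' @param direction `"blind"` or `"unblind"`.
#' @return The transformed records tibble.
#' @export
apply_blinding <- function(records, map, direction = c("blind", "unblind")) {
  direction <- match.arg(direction)
  if (direction == "blind") {
    out <- dplyr::left_join(records, map,
                            by = c("panel_id", "member_id", "aliquot_index"))
    if (anyNA(out$code)) {
      missing_ids <- unique(paste0(records$member_id, "#",
                                   records$aliquot_index)[is.na(out$code)])
      abort(paste0("No blinding code for aliquot(s): ",
                   paste(missing_ids, collapse = ", ")))
    }
    out[, c("tech_id", "code", "pcr_rep_index", "target", "ct")]
  } else {
    if (!"code" %in% names(records)) {
      abort("Unblinding requires a `code` column.")
    }
    out <- dplyr::left_join(records, map, by = "code")
    if (anyNA(out$member_id)) {
      bad <- unique(records$code[is.na(out$member_id)])
      abort(paste0("Unknown blinding code(s) (possible mislabeled sample): ",
                   paste(bad, collapse = ", ")))
    }
    out[, ct_table_cols]
  }
}

workflow_metric_cols <- c("tech_id", "panel_id", "input_volume",
                          "provided_volume", "elution_volume", "pcr_aliquot",
                          "turnaround_min", "manual_steps", "cost_usd")

#' Read or validate per-technology workflow metrics
#'
#' One row per (technology, panel): specimen input volume out of the provided
#' volume, eluate volume, PCR aliquot, turnaround time, manual step count and
#' cost per extraction. Invariants (`input <= provided`,
#' `pcr_aliquot <= elution`, positivity) are checked row by row.
#'
#' @param path CSV file with the columns listed above.
#' @return Tibble of validated workflow metrics.
#' @export
read_workflow_metrics <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  m <- readr::read_csv(path, col_types = readr::cols(
    tech_id = "c", panel_id = "c", .default = "d"), progress = FALSE)
  missing_cols <- setdiff(workflow_metric_cols, names(m))
  if (length(missing_cols) > 0) {
    abort(paste0("Workflow metrics missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_workflow_metrics(m)
}

#' @rdname read_workflow_metrics
#' @param metrics A workflow-metrics data frame to validate in place.
#' @export
validate_workflow_metrics <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  for (i in seq_len(nrow(metrics))) {
    r <- metrics[i, ]
    label <- paste0("(", r$tech_id, ", ", r$panel_id, ")")
    if (r$input_volume <= 0 || r$input_volume > r$provided_volume) {
      abort(paste0("Row ", label, ": input_volume must be in (0, provided_volume]."))
    }
    if (r$pcr_aliquot <= 0 || r$pcr_aliquot > r$elution_volume) {
      abort(paste0("Row ", label, ": pcr_aliquot must be in (0, elution_volume]."))
    }
    if (r$turnaround_min <= 0 || r$manual_steps <= 0 || r$cost_usd < 0) {
      abort(paste0("Row ", label, ": turnaround, steps and cost must be positive."))
    }
  }
  metrics
}

#' @rdname read_workflow_metrics
#' @param metrics A workflow-metrics tibble.
#' @export
write_workflow_metrics <- function(metrics, path) {
  readr::write_csv(metrics[, workflow_metric_cols], path, progress = FALSE)
  invisible(path)
}
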