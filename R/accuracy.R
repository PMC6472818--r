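#' Classify an RT-PCR replicate call
#'
#' A replicate is detected iff a Ct was recorded and it does not exceed the
#' cycle cutoff (45, the protocol's cycle count; a call exactly at the cutoff
#' counts as detected).
#'
#' @param ct Numeric Ct vector, `NA` for not detected.
#' @param cutoff Detection cutoff in cycles (default 45).
#' @return Logical vector.
#' @export
classify_replicate <- function(ct, cutoff = 45) {
  !is.na(ct) & ct <= cutoff
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Equal-tailed exact interval for a binomial proportion, via the standard
#' beta-quantile form: lower = qbeta(alpha/2; k, n-k+1) (0 when k = 0), upper
#' = qbeta(1-alpha/2; k+1, n-k) (1 when k = n). Values are returned unrounded;
#' the study's tables print them half-up to 2 decimals.
#'
#' @param k Successes (vectorized).
#' @param n Trials (vectorized).
#' @param confidence Two-sided confidence level (default 0.95).
#' @return Tibble with columns `lower` and `upper`.
#' @examples
#' round_half_up(clopper_pearson(27, 36), 2)  # 0.58, 0.88
#' @export
clopper_pearson <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n.")
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1).")
  alpha <- 1 - confidence
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(lower = lower, upper = upper)
}

#' Reconstruct a replicate count from a printed proportion
#'
#' Finds the success count `k` whose proportion rounds (half-up, 2 dp) to a
#' printed value. Returns `NA` when no or several counts are compatible
#' (ambiguous cells cannot be used in regression checks).
#'
#' @param p Printed proportion (2 decimal places).
#' @param n Number of trials.
#' @return Integer `k` or `NA`.
#' @export
reconstruct_successes <- function(p, n) {
  ks <- which(round_half_up(0:n / n, 2) == round_half_up(p, 2)) - 1L
  if (length(ks) == 1) ks else NA_integer_
}

#' Summarise one technology x member x target cell
#'
#' Mean Ct over detected replicates only (absent when none detected), with
#' the table's footnote flags: `"a"` marks a spiked member with at least one
#' undetected replicate among >= 1 detections (partial false negatives);
#' `"b"` marks an unspiked member with >= 1 detection (false positives).
#'
#' @param records Ct records for a single technology x member x target.
#' @param truth `"spiked"` or `"unspiked"`.
#' @param cutoff Detection cutoff in cycles.
#' @return One-row tibble: tech_id, member_id, target, n_replicates,
#'   n_detected, mean_ct, flag.
#' @export
summarize_member <- function(records, truth = c("spiked", "unspiked"),
                             cutoff = 45) {
  truth <- match.arg(truth)
  if (nrow(records) == 0) abort("`records` must contain at least one row.")
  if (length(unique(records$member_id)) > 1 ||
      length(unique(records$target)) > 1 ||
      length(unique(records$tech_id)) > 1) {
    abort("`records` must cover exactly one technology x member x target.")
  }
  det <- classify_replicate(records$ct, cutoff)
  n_det <- sum(det)
  flag <- "none"
  if (truth == "spiked" && n_det >= 1 && n_det < nrow(records)) flag <- "a"
  if (truth == "unspiked" && n_det >= 1) flag <- "b"
  tibble::tibble(
    tech_id = records$tech_id[1], member_id = records$member_id[1],
    target = records$target[1], truth = truth,
    n_replicates = nrow(records), n_detected = n_det,
    mean_ct = if (n_det >= 1) mean(records$ct[det]) else NA_real_,
    flag = flag
  )
}

#' Member-level summary table
#'
#' Applies [summarize_member()] to every technology x member x target cell in
#' a Ct table, using the design's ground truth. Records that reference
#' excluded members are skipped with a warning.
#'
#' @param records Unblinded Ct records.
#' @param design A qualified `panel_design`.
#' @param cutoff Detection cutoff in cycles.
#' @return Tibble of member summaries with panel_id and truth attached.
#' @export
member_summaries <- function(records, design, cutoff = 45) {
  truth <- design_truth(design)
  excluded <- design$members$member_id[design$members$excluded]
  if (any(records$member_id %in% excluded)) {
    warn(paste0("Dropping records for excluded member(s): ",
                paste(intersect(records$member_id, excluded), collapse = ", ")))
    records <- records[!records$member_id %in% excluded, ]
  }
  joined <- dplyr::inner_join(
    records, truth[, c("member_id", "target", "tier", "spiked")],
    by = c("member_id", "target")
  )
  grp <- dplyr::group_by(joined, .data$tech_id, .data$panel_id,
                         .data$member_id, .data$target, .data$spiked)
  out <- dplyr::summarise(
    grp,
    n_replicates = dplyr::n(),
    n_detected = sum(classify_replicate(.data$ct, cutoff)),
    mean_ct = ifelse(.data$n_detected >= 1,
                     mean(.data$ct[classify_replicate(.data$ct, cutoff)]),
                     NA_real_),
    .groups = "drop"
  )
  out$truth <- ifelse(out$spiked, "spiked", "unspiked")
  out$flag <- dplyr::case_when(
    out$spiked & out$n_detected >= 1 & out$n_detected < out$n_replicates ~ "a",
    !out$spiked & out$n_detected >= 1 ~ "b",
    TRUE ~ "none"
  )
  out[, c("tech_id", "panel_id", "member_id", "target", "truth",
          "n_replicates", "n_detected", "mean_ct", "flag")]
}

#' Study deviations to the full replicate grid
#'
#' The two deviations recorded in the study: developer E shipped only two of
#' the three ST3 and ST6 aliquots (both targets lost), and one SP3 extract
#' from developer C had insufficient eluate to test M. tuberculosis (that
#' target only). Each missing aliquot removes one extract, i.e. all of its
#' PCR replicates, from the corresponding denominators.
#'
#' @return Tibble: tech_id, panel_id, member_id, n_missing, target (`NA` =
#'   both targets).
#' @export
reference_deviations <- function() {
  tibble::tibble(
    tech_id = c("C", "E", "E"),
    panel_id = c("SP", "ST", "ST"),
    member_id = c("SP3", "ST3", "ST6"),
    n_missing = 1L,
    target = c("M. tuberculosis", NA, NA)
  )
}

#' Expected replicate denominators per technology x target
#'
#' The replicate totals implied by the qualified design: 3 PCR replicates x 3
#' aliquots = 9 data points per member, summed over spiked (positive total)
#' and unspiked (negative total) members, minus replicates lost to recorded
#' deviations.
#'
#' @param design A qualified `panel_design`.
#' @param tech_ids Technology identifiers to expand over.
#' @param deviations Optional deviations tibble (see [reference_deviations()]).
#' @param pcr_replicates PCR replicates per extract (default 3).
#' @return Tibble: tech_id, panel_id, target, n_pos, n_neg.
#' @export
replicate_totals <- function(design, tech_ids, deviations = NULL,
                             pcr_replicates = 3) {
  truth <- design_truth(design)
  base <- dplyr::summarise(
    dplyr::group_by(truth, .data$panel_id, .data$target),
    n_pos = sum(.data$aliquot_count[.data$spiked]) * pcr_replicates,
    n_neg = sum(.data$aliquot_count[!.data$spiked]) * pcr_replicates,
    .groups = "drop"
  )
  out <- tidyr::crossing(tech_id = tech_ids, base)
  if (!is.null(deviations)) {
    truth_key <- truth[, c("member_id", "target", "spiked")]
    for (i in seq_len(nrow(deviations))) {
      d <- deviations[i, ]
      hit <- truth_key[truth_key$member_id == d$member_id, ]
      if (!is.na(d$target)) hit <- hit[hit$target == d$target, ]
      for (j in seq_len(nrow(hit))) {
        sel <- out$tech_id == d$tech_id & out$panel_id == d$panel_id &
          out$target == hit$target[j]
        lost <- d$n_missing * pcr_replicates
        if (hit$spiked[j]) {
          out$n_pos[sel] <- out$n_pos[sel] - lost
        } else {
          out$n_neg[sel] <- out$n_neg[sel] - lost
        }
      }
    }
  }
  out
}

#' Replicate-level 2x2 counts
#'
#' Tabulates true/false positives and negatives over all replicates of
#' non-excluded members, per technology x panel x target.
#'
#' @param records Unblinded Ct records.
#' @param design A qualified `panel_design`.
#' @param cutoff Detection cutoff in cycles.
#' @return Tibble: tech_id, panel_id, target, tp, fn, tn, fp.
#' @export
tabulate_counts <- function(records, design, cutoff = 45) {
  ms <- member_summaries(records, design, cutoff)
  dplyr::summarise(
    dplyr::group_by(ms, .data$tech_id, .data$panel_id, .data$target),
    tp = sum(.data$n_detected[.data$truth == "spiked"]),
    fn = sum((.data$n_replicates - .data$n_detected)[.data$truth == "spiked"]),
    tn = sum((.data$n_replicates - .data$n_detected)[.data$truth == "unspiked"]),
    fp = sum(.data$n_detected[.data$truth == "unspiked"]),
    .groups = "drop"
  )
}

#' Diagnostic accuracy table
#'
#' Replicate-level sensitivity and specificity per technology x target, with
#' exact 95% confidence intervals, a pooled score `(sens + spec) / 2`
#' computed on unrounded proportions, and a per-target competition rank.
#'
#' @param records Unblinded Ct records.
#' @param design A qualified `panel_design`.
#' @param deviations Optional deviations tibble; when supplied, the realised
#'   replicate totals are checked against the expected ones and a warning is
#'   raised on mismatch.
#' @param cutoff Detection cutoff in cycles.
#' @param confidence Confidence level for the intervals.
#' @return Tibble of accuracy summaries (one row per tech x panel x target).
#' @export
accuracy_table <- function(records, design, deviations = NULL, cutoff = 45,
                           confidence = 0.95) {
  counts <- tabulate_counts(records, design, cutoff)
  if (!is.null(deviations)) {
    expected <- replicate_totals(design, unique(counts$tech_id), deviations)
    chk <- dplyr::left_join(counts, expected,
                            by = c("tech_id", "panel_id", "target"))
    off <- chk$tp + chk$fn != chk$n_pos | chk$tn + chk$fp != chk$n_neg
    if (any(off)) {
      warn(paste0("Replicate totals differ from design expectation for: ",
                  paste(unique(paste(chk$tech_id, chk$target)[off]),
                        collapse = "; ")))
    }
  }
  out <- accuracy_from_counts(counts, confidence)
  rank_per_target(out)
}

#' Accuracy summaries from 2x2 counts
#'
#' @param counts Tibble with tech_id, panel_id, target, tp, fn, tn, fp.
#' @param confidence Confidence level.
#' @return Tibble with sensitivity, specificity, CI bounds and score columns.
#' @export
accuracy_from_counts <- function(counts, confidence = 0.95) {
  out <- tibble::as_tibble(counts)
  out$sensitivity <- out$tp / (out$tp + out$fn)
  out$specificity <- out$tn / (out$tn + out$fp)
  sci <- clopper_pearson(out$tp, out$tp + out$fn, confidence)
  pci <- clopper_pearson(out$tn, out$tn + out$fp, confidence)
  out$sens_lower <- sci$lower
  out$sens_upper <- sci$upper
  out$spec_lower <- pci$lower
  out$spec_upper <- pci$upper
  out$score <- (out$sensitivity + out$specificity) / 2
  out
}

#' Score a table of published accuracy rates
#'
#' Attaches the pooled score `(sensitivity + specificity) / 2` to a table of
#' (possibly printed, 2-dp) sensitivity/specificity values so that the
#' ranking operations can run on published numbers as well as on recomputed
#' ones.
#'
#' @param rates Tibble with tech_id, panel_id, target, sensitivity,
#'   specificity.
#' @return `rates` with a `score` column.
#' @export
accuracy_from_published <- function(rates) {
  out <- tibble::as_tibble(rates)
  out$score <- (out$sensitivity + out$specificity) / 2
  out
}

#' Per-target competition ranking
#'
#' Ranks technologies within each panel x target by score, descending, with
#' competition (minimum-shared) tie handling.
#'
#' @param summaries Accuracy summaries with tech_id, panel_id, target, score.
#' @return `summaries` with a `rank` column.
#' @export
rank_per_target <- function(summaries) {
  grp <- dplyr::group_by(summaries, .data$panel_id, .data$target)
  dplyr::ungroup(dplyr::mutate(grp, rank = competition_rank(.data$score)))
}

#' Pooled performance ranking
#'
#' Averages each technology's per-target scores over a scope (one panel, or
#' all panels) and applies competition ranking to the pooled means. Every
#' technology must have a score for every target in scope.
#'
#' @param summaries Accuracy summaries with tech_id, panel_id, target, score.
#' @param scope `"overall"` or a panel_id (`"SP"`, `"BL"`, `"ST"`).
#' @return Tibble: tech_id, scope, pooled_score, rank.
#' @export
rank_pooled <- function(summaries, scope = "overall") {
  s <- tibble::as_tibble(summaries)
  if (!identical(scope, "overall")) {
    s <- s[s$panel_id %in% scope, ]
    if (nrow(s) == 0) abort(paste0("No summaries in scope ", scope, "."))
  }
  n_targets <- length(unique(paste(s$panel_id, s$target)))
  counts <- table(s$tech_id)
  if (any(counts != n_targets)) {
    abort(paste0("Incomplete score set: every technology needs all ",
                 n_targets, " target(s) in scope."))
  }
  pooled <- dplyr::summarise(dplyr::group_by(s, .data$tech_id),
                             pooled_score = mean(.data$score), .groups = "drop")
  pooled$scope <- paste(scope, collapse = "+")
  pooled$rank <- competition_rank(pooled$pooled_score)
  pooled[, c("tech_id", "scope", "pooled_score", "rank")]
}
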