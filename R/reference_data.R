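ref_csv <- function(name, col_types) {
  path <- system.file("extdata", name, package = "assurbench", mustWork = TRUE)
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Published reference tables
#'
#' The study's printed result tables, shipped with the package so the
#' regression analyses run offline:
#' \itemize{
#'   \item `reference_accuracy()` — per technology x target sensitivity,
#'     specificity, their printed 95% CI bounds (2 dp) and per-target rank.
#'   \item `reference_volumes()` — per group x specimen input / provided /
#'     elution volumes and the three printed derived percentage columns
#'     (includes the two reference laboratories alongside developers A-F).
#'   \item `reference_assur()` — per technology x target ASSUR mean scores
#'     (2 dp).
#'   \item `reference_assur_ranks()` — printed per-panel and overall ASSUR
#'     ranks with the performance-only ranks shown in parentheses in the
#'     source (the printed three-way overall tie "3=" is stored as rank 3).
#' }
#'
#' @return A tibble (see above for columns).
#' @export
reference_accuracy <- function() {
  ref_csv("table2_accuracy.csv", readr::cols(
    panel_id = "c", target = "c", tech_id = "c", rank = "i", .default = "d"))
}

#' @rdname reference_accuracy
#' @export
reference_volumes <- function() {
  ref_csv("table3_volumes.csv", readr::cols(
    group = "c", panel_id = "c", specimen = "c", na_extracted = "c",
    .default = "d"))
}

#' @rdname reference_accuracy
#' @export
reference_assur <- function() {
  ref_csv("table4_assur.csv", readr::cols(
    tech_id = "c", panel_id = "c", target = "c", mean_score = "d"))
}

#' @rdname reference_accuracy
#' @export
reference_assur_ranks <- function() {
  ref_csv("table4_ranks.csv", readr::cols(
    tech_id = "c", scope = "c", assur_rank = "i", perf_rank = "i"))
}

#' Replicate denominators of the published accuracy table
#'
#' Convenience wrapper: the qualified realized design (SP6 removed), the two
#' recorded deviations, and 9 replicates per member give the positive and
#' negative replicate totals behind each printed sensitivity/specificity.
#'
#' @return Tibble: tech_id, panel_id, target, n_pos, n_neg.
#' @export
reference_replicate_totals <- function() {
  design <- qualify_panel(
    build_reference_design(seed = 1L, layout = "realized"),
    list(SP6 = "M. tuberculosis")
  )
  replicate_totals(design, tech_ids = LETTERS[1:6],
                   deviations = reference_deviations())
}
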