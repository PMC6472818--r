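#' Volumetric efficiency metrics
#'
#' Three derived quantities relate how much of a specimen each extraction
#' workflow actually interrogates per PCR reaction:
#' \itemize{
#'   \item `pct_of_total()`: percent of the provided specimen processed,
#'     printed as a whole percent;
#'   \item `pct_eluate_per_pcr()`: percent of the eluate pipetted into one
#'     reaction (5 uL aliquot), printed to 1 decimal;
#'   \item `pct_sample_per_pcr()`: their product — percent of the original
#'     specimen represented in one reaction, printed to 1 decimal.
#' }
#' All rounding is half-up, matching the published table (e.g. 25% of 5.0%
#' prints as 1.3). The product is taken over the printed-precision
#' percentages, which is the chain the published derived column follows.
#'
#' @param input_volume Specimen volume processed (uL; stool mg are treated as
#'   uL-equivalents of homogenate).
#' @param provided_volume Specimen volume provided (uL).
#' @return Percentage (numeric), rounded as printed.
#' @examples
#' pct_of_total(225.8, 1000)      # 23
#' pct_eluate_per_pcr(105)        # 4.8
#' pct_sample_per_pcr(25, 5.0)    # 1.3
#' @export
pct_of_total <- function(input_volume, provided_volume) {
  if (any(input_volume <= 0)) abort("`input_volume` must be positive.")
  if (any(input_volume > provided_volume)) {
    abort("`input_volume` cannot exceed `provided_volume`.")
  }
  round_half_up(100 * input_volume / provided_volume, 0)
}

#' @rdname pct_of_total
#' @param elution_volume Eluate volume (uL).
#' @param pcr_aliquot Eluate volume per reaction (uL, default 5).
#' @export
pct_eluate_per_pcr <- function(elution_volume, pcr_aliquot = 5) {
  if (any(elution_volume <= 0)) abort("`elution_volume` must be positive.")
  if (any(pcr_aliquot > elution_volume)) {
    abort("`pcr_aliquot` cannot exceed `elution_volume`.")
  }
  round_half_up(100 * pcr_aliquot / elution_volume, 1)
}

#' @rdname pct_of_total
#' @param pct_total Percent of total sample used (as printed).
#' @param pct_eluate Percent of eluate per reaction (as printed).
#' @export
pct_sample_per_pcr <- function(pct_total, pct_eluate) {
  if (any(pct_total < 0 | pct_total > 100) ||
      any(pct_eluate < 0 | pct_eluate > 100)) {
    abort("Percentages must be in [0, 100].")
  }
  round_half_up(pct_total * pct_eluate / 100, 1)
}

#' Volumetric summary table
#'
#' Recomputes the three derived volumetric columns from raw input, provided
#' and elution volumes for every (technology, panel) row of a workflow
#' metrics table.
#'
#' @param metrics Workflow metrics tibble (see [read_workflow_metrics()]).
#' @return `metrics` with pct_of_total_sample, pct_eluate_per_pcr and
#'   pct_sample_per_pcr columns appended.
#' @export
volumetric_table <- function(metrics) {
  m <- tibble::as_tibble(metrics)
  m$pct_of_total_sample <- pct_of_total(m$input_volume, m$provided_volume)
  m$pct_eluate_per_pcr <- pct_eluate_per_pcr(m$elution_volume, m$pcr_aliquot)
  m$pct_sample_per_pcr <- pct_sample_per_pcr(m$pct_of_total_sample,
                                             m$pct_eluate_per_pcr)
  m
}
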