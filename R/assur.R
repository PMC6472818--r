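#' Direction-aware min-max normalization of an attribute
#'
#' Maps a peer group's attribute values onto [0, 1] with 1.0 the most optimal
#' observed value: `(x - min) / (max - min)` for benefit attributes
#' (sensitivity, specificity) and `(max - x) / (max - min)` for cost
#' attributes (price, manual steps, turnaround). When all peers share one
#' value the attribute cannot discriminate and every technology is scored
#' 1.0 (all equally optimal) — the convention the uniform $2-per-extraction
#' affordability score requires.
#'
#' @param values Non-negative numeric vector (one value per technology).
#' @param direction `"benefit"` (higher is better) or `"cost"`.
#' @return Normalized values in [0, 1].
#' @examples
#' normalize_attribute(c(55, 15, 35), "cost")  # 0.0 1.0 0.5
#' @export
normalize_attribute <- function(values, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  if (any(values < 0)) abort("Attribute values must be non-negative.")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1, length(values)))
  if (direction == "benefit") {
    (values - rng[1]) / (rng[2] - rng[1])
  } else {
    (rng[2] - values) / (rng[2] - rng[1])
  }
}

assur_attributes <- c("affordable", "sensitive", "specific",
                      "user_friendly", "rapid")

#' ASSUR scores per technology x target
#'
#' Builds the five-attribute ASSUR score (Affordable, Sensitive, Specific,
#' User-friendly, Rapid) for every technology x target. Sensitivity and
#' specificity are normalized across technologies within each panel x target;
#' cost, manual steps and turnaround are normalized within each panel (they
#' are properties of the workflow on that specimen type). The score is the
#' weighted mean of the five normalized attributes, equally weighted by
#' default.
#'
#' @param accuracy Accuracy summaries with tech_id, panel_id, target,
#'   sensitivity, specificity (e.g. from [accuracy_table()]).
#' @param metrics Workflow metrics with tech_id, panel_id, turnaround_min,
#'   manual_steps, cost_usd (see [read_workflow_metrics()]).
#' @param weights Five weights in ASSUR order (affordable, sensitive,
#'   specific, user_friendly, rapid); normalized to sum to one.
#' @return Tibble: tech_id, panel_id, target, the five normalized attributes,
#'   mean_score.
#' @export
assur_scores <- function(accuracy, metrics, weights = rep(1, 5)) {
  if (length(weights) != 5 || any(weights < 0) || sum(weights) == 0) {
    abort("`weights` must be five non-negative values, not all zero.")
  }
  weights <- weights / sum(weights)
  acc <- tibble::as_tibble(accuracy)
  met <- tibble::as_tibble(metrics)
  need <- dplyr::distinct(acc[, c("tech_id", "panel_id")])
  have <- dplyr::distinct(met[, c("tech_id", "panel_id")])
  gap <- dplyr::anti_join(need, have, by = c("tech_id", "panel_id"))
  if (nrow(gap) > 0) {
    abort(paste0("Missing workflow metrics for: ",
                 paste(paste0("(", gap$tech_id, ", ", gap$panel_id, ")"),
                       collapse = ", ")))
  }
  met <- dplyr::group_by(met, .data$panel_id)
  met <- dplyr::ungroup(dplyr::mutate(
    met,
    affordable = normalize_attribute(.data$cost_usd, "cost"),
    user_friendly = normalize_attribute(.data$manual_steps, "cost"),
    rapid = normalize_attribute(.data$turnaround_min, "cost")
  ))
  acc <- dplyr::group_by(acc, .data$panel_id, .data$target)
  acc <- dplyr::ungroup(dplyr::mutate(
    acc,
    sensitive = normalize_attribute(.data$sensitivity, "benefit"),
    specific = normalize_attribute(.data$specificity, "benefit")
  ))
  out <- dplyr::left_join(
    acc[, c("tech_id", "panel_id", "target", "sensitive", "specific")],
    met[, c("tech_id", "panel_id", "affordable", "user_friendly", "rapid")],
    by = c("tech_id", "panel_id")
  )
  mat <- as.matrix(out[, assur_attributes])
  out$mean_score <- as.numeric(mat %*% weights)
  out[, c("tech_id", "panel_id", "target", assur_attributes, "mean_score")]
}

#' Pooled ASSUR ranking
#'
#' Averages per-target ASSUR mean scores over a scope (a panel, or overall)
#' and ranks technologies by competition ranking, descending.
#'
#' @param scores Tibble with tech_id, panel_id, target, mean_score (from
#'   [assur_scores()], or per-target values supplied directly).
#' @param scope `"overall"` or panel_id(s).
#' @return Tibble: tech_id, scope, pooled_score, rank.
#' @export
rank_assur <- function(scores, scope = "overall") {
  s <- tibble::as_tibble(scores)
  if (!identical(scope, "overall")) {
    s <- s[s$panel_id %in% scope, ]
    if (nrow(s) == 0) abort(paste0("No scores in scope ", scope, "."))
  }
  n_targets <- length(unique(paste(s$panel_id, s$target)))
  counts <- table(s$tech_id)
  if (any(counts != n_targets)) {
    abort("Incomplete score set: every technology needs every target in scope.")
  }
  pooled <- dplyr::summarise(dplyr::group_by(s, .data$tech_id),
                             pooled_score = mean(.data$mean_score),
                             .groups = "drop")
  pooled$scope <- paste(scope, collapse = "+")
  pooled$rank <- competition_rank(pooled$pooled_score)
  pooled[, c("tech_id", "scope", "pooled_score", "rank")]
}

#' Radar-plot coordinates of ASSUR scores
#'
#' Emits plain polygon coordinates for any plotting backend: five axes at 72
#' degree spacing, read clockwise from 12 o'clock in the order A, S
#' (sensitive), S (specific), U, R; the vertex radius is the normalized
#' attribute value.
#'
#' @param scores Tibble from [assur_scores()] (or any tibble carrying the
#'   five attribute columns plus tech_id, panel_id, target).
#' @return Tibble: tech_id, panel_id, target, attribute, axis_order,
#'   angle_deg (mathematical convention, counterclockwise from east), radius,
#'   x, y.
#' @export
radar_coordinates <- function(scores) {
  s <- tibble::as_tibble(scores)
  long <- tidyr::pivot_longer(
    s[, c("tech_id", "panel_id", "target", assur_attributes)],
    cols = dplyr::all_of(assur_attributes),
    names_to = "attribute", values_to = "radius"
  )
  long$axis_order <- match(long$attribute, assur_attributes)
  long$angle_deg <- (90 - 72 * (long$axis_order - 1)) %% 360
  theta <- long$angle_deg * pi / 180
  long$x <- long$radius * cos(theta)
  long$y <- long$radius * sin(theta)
  long[, c("tech_id", "panel_id", "target", "attribute", "axis_order",
           "angle_deg", "radius", "x", "y")]
}
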