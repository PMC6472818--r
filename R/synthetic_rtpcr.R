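#' Assay (standard curve) model for simulated RT-PCR
#'
#' A censored log-linear standard curve: a reaction entered by `m` template
#' copies amplifies at `ct = ct_intercept - ct_slope * log10(m)` plus Gaussian
#' noise, censored to "not detected" beyond `max_cycles` (45 cycles, the
#' thermocycling protocol's limit). The `reference` curve describes the
#' reference extraction + assay used to define the spike tiers; by default it
#' equals the assay curve.
#'
#' @param ct_intercept Cycles at a single template copy per reaction.
#' @param ct_slope Cycles per log10(copies); near 3.32 for ideal doubling.
#' @param ct_noise_sd Replicate-level Ct noise SD (cycles).
#' @param max_cycles Detection cutoff (cycles).
#' @param reference Optional list with `ct_intercept` and `ct_slope` for the
#'   reference curve.
#' @return Object of class `assay_model`.
#' @export
assay_model <- function(ct_intercept = 38, ct_slope = 3.33, ct_noise_sd = 0.75,
                        max_cycles = 45, reference = NULL) {
  if (ct_slope < 3.0 || ct_slope > 3.6) {
    abort("`ct_slope` outside [3.0, 3.6]; amplification efficiency implausible.")
  }
  if (ct_noise_sd < 0) abort("`ct_noise_sd` must be >= 0.")
  if (is.null(reference)) {
    reference <- list(ct_intercept = ct_intercept, ct_slope = ct_slope)
  }
  structure(
    list(ct_intercept = ct_intercept, ct_slope = ct_slope,
         ct_noise_sd = ct_noise_sd, max_cycles = max_cycles,
         reference = reference),
    class = "assay_model"
  )
}

#' Volume of specimen provided per aliquot, by panel
#'
#' Sputum aliquots were 0.5 mL; blood and stool (40% w/v homogenate, mg
#' treated as uL-equivalents) aliquots were 1 mL.
#'
#' @return Named numeric vector (uL) with names SP, BL, ST.
#' @export
provided_volumes <- function() {
  c(SP = 500, BL = 1000, ST = 1000)
}

#' Extraction technology model for the simulator
#'
#' @param tech_id Technology label.
#' @param input_volume Named numeric (uL per extraction) by panel_id
#'   (SP/BL/ST), or a single value recycled.
#' @param elution_volume Eluate volume (uL).
#' @param recovery Fraction of template copies in the processed specimen that
#'   reach the eluate. A single number, a named vector by nucleic-acid class
#'   (`RNA`, `DNA`), or a tibble with columns panel_id, na_class, recovery.
#' @param pcr_aliquot uL of eluate per PCR reaction (5 in the study protocol).
#' @param contamination_rate Per-replicate, per-target probability that a
#'   template-free reaction turns positive anyway. A single number or a named
#'   vector by target with a `.default` element.
#' @param contamination_ct_range Ct range (cycles) of contamination calls.
#' @param missing_extracts Optional tibble with columns member_id, n_missing
#'   and (optionally) target; each row drops `n_missing` aliquot extracts of
#'   that member (restricted to one target if given), emulating shipping
#'   losses and short eluates.
#' @return Object of class `technology_model`.
#' @export
technology_model <- function(tech_id, input_volume, elution_volume,
                             recovery = 1, pcr_aliquot = 5,
                             contamination_rate = 0,
                             contamination_ct_range = c(31, 42),
                             missing_extracts = NULL) {
  if (elution_volume <= 0) abort("`elution_volume` must be positive.")
  if (pcr_aliquot <= 0 || pcr_aliquot > elution_volume) {
    abort("`pcr_aliquot` must be in (0, elution_volume].")
  }
  rec_vals <- if (is.data.frame(recovery)) recovery$recovery else recovery
  if (any(rec_vals <= 0 | rec_vals > 1)) {
    abort("`recovery` fractions must be in (0, 1].")
  }
  if (any(contamination_rate < 0 | contamination_rate >= 1)) {
    abort("`contamination_rate` must be in [0, 1).")
  }
  if (length(input_volume) == 1 && is.null(names(input_volume))) {
    input_volume <- setNames(rep(input_volume, 3), c("SP", "BL", "ST"))
  }
  if (!is.null(missing_extracts)) {
    missing_extracts <- tibble::as_tibble(missing_extracts)
    if (!"target" %in% names(missing_extracts)) {
      missing_extracts$target <- NA_character_
    }
  }
  structure(
    list(tech_id = tech_id, input_volume = input_volume,
         elution_volume = elution_volume, recovery = recovery,
         pcr_aliquot = pcr_aliquot, contamination_rate = contamination_rate,
         contamination_ct_range = contamination_ct_range,
         missing_extracts = missing_extracts),
    class = "technology_model"
  )
}

tech_recovery <- function(tech, panel_id, na_class) {
  r <- tech$recovery
  if (is.data.frame(r)) {
    hit <- r$recovery[r$panel_id == panel_id & r$na_class == na_class]
    if (length(hit) != 1) {
      abort(paste0("No recovery entry for (", panel_id, ", ", na_class,
                   ") in technology ", tech$tech_id, "."))
    }
    return(hit)
  }
  if (!is.null(names(r))) {
    if (!na_class %in% names(r)) {
      abort(paste0("No recovery entry for class ", na_class, "."))
    }
    return(unname(r[na_class]))
  }
  r
}

tech_contamination_rate <- function(tech, target) {
  cr <- tech$contamination_rate
  if (is.null(names(cr))) return(cr[1])
  if (target %in% names(cr)) return(unname(cr[target]))
  unname(cr[".default"] %||% 0)
}

#' Convert a spike tier to a template load
#'
#' Inverts the reference standard curve at the tier's target Ct:
#' `load = 10^((ref_intercept - ct_center) / ref_slope)` copies per reference
#' reaction. Strictly decreasing in `ct_center`, so high > medium > low loads.
#'
#' @param tier A [spike_tier()] or its label.
#' @param assay An [assay_model()] supplying the reference curve.
#' @return Copies per reference reaction (numeric).
#' @examples
#' tier_to_template_load("low", assay_model(ct_intercept = 38, ct_slope = 3.33))
#' @export
tier_to_template_load <- function(tier, assay) {
  if (is.character(tier)) tier <- spike_tier(tier)
  if (tier$label == "none") abort("An unspiked tier has no template load.")
  ref <- assay$reference
  10^((ref$ct_intercept - tier$ct_center) / ref$ct_slope)
}

#' Expected template copies per PCR reaction
#'
#' Chains the dilution/concentration factors between the specimen and a
#' single reaction: the fraction of the provided specimen that the technology
#' processes, its recovery into the eluate, and the fraction of the eluate
#' pipetted into the reaction. Processing more specimen or eluting into less
#' volume concentrates the template.
#'
#' @param load Copies per reference reaction ([tier_to_template_load()]).
#' @param tech A [technology_model()].
#' @param panel_id Panel (SP/BL/ST).
#' @param na_class `"RNA"` or `"DNA"`.
#' @param sample_fraction_used Fraction of the provided specimen processed;
#'   defaults to `input_volume[panel_id] / provided_volumes()[panel_id]`.
#' @return Expected copies per reaction (lambda of the Poisson template draw).
#' @export
expected_pcr_copies <- function(load, tech, panel_id, na_class,
                                sample_fraction_used = NULL) {
  if (is.null(sample_fraction_used)) {
    sample_fraction_used <-
      unname(tech$input_volume[panel_id] / provided_volumes()[panel_id])
  }
  if (any(sample_fraction_used <= 0 | sample_fraction_used > 1)) {
    abort("`sample_fraction_used` must be in (0, 1].")
  }
  load * sample_fraction_used * tech_recovery(tech, panel_id, na_class) *
    tech$pcr_aliquot / tech$elution_volume
}

#' Simulate RT-PCR replicate calls at a fixed expected template load
#'
#' Template copies per reaction are Poisson(`lambda`); a template-free
#' reaction is not detected unless a contamination event injects a spurious
#' Ct drawn uniformly from `contamination_ct_range`; otherwise
#' `ct = intercept - slope * log10(copies) + noise`, censored to not-detected
#' above `max_cycles`.
#'
#' @param n Number of replicate draws.
#' @param lambda Expected copies per reaction (scalar or length-n).
#' @param assay An [assay_model()].
#' @param contamination_rate Per-replicate false-positive probability.
#' @param contamination_ct_range Ct range of contamination calls.
#' @return Numeric vector of length `n`: Ct values, `NA` for not detected.
#' @export
simulate_replicates <- function(n, lambda, assay,
                                contamination_rate = 0,
                                contamination_ct_range = c(31, 42)) {
  if (any(lambda < 0)) abort("`lambda` must be >= 0.")
  lambda <- rep_len(lambda, n)
  templates <- rpois(n, lambda)
  ct <- rep(NA_real_, n)
  pos <- templates > 0
  if (any(pos)) {
    ct[pos] <- assay$ct_intercept - assay$ct_slope * log10(templates[pos]) +
      rnorm(sum(pos), 0, assay$ct_noise_sd)
  }
  zero <- !pos
  if (any(zero) && any(contamination_rate > 0)) {
    rate <- rep_len(contamination_rate, n)[zero]
    contam <- runif(sum(zero)) < rate
    if (any(contam)) {
      ct[which(zero)[contam]] <- runif(sum(contam),
                                       contamination_ct_range[1],
                                       contamination_ct_range[2])
    }
  }
  ct[!is.na(ct) & ct > assay$max_cycles] <- NA_real_
  ct
}

#' Simulation configuration
#'
#' @param design A qualified [build_reference_design()] object.
#' @param technologies List of [technology_model()] objects.
#' @param assay An [assay_model()] shared by all targets, or a named list
#'   keyed `"<panel_id>:<target>"`.
#' @param pcr_replicates PCR replicates per extract (3 in the study).
#' @param seed Integer seed; a fixed seed makes [generate_study()] output
#'   byte-identical across runs.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(design, technologies, assay = assay_model(),
                              pcr_replicates = 3L, seed = 1L) {
  stopifnot(inherits(design, "panel_design"))
  if (pcr_replicates < 1) abort("`pcr_replicates` must be >= 1.")
  if (inherits(technologies, "technology_model")) {
    technologies <- list(technologies)
  }
  known <- design$members$member_id
  for (tech in technologies) {
    if (!is.null(tech$missing_extracts)) {
      unknown <- setdiff(tech$missing_extracts$member_id, known)
      if (length(unknown) > 0) {
        abort(paste0("missing_extracts of ", tech$tech_id,
                     " reference unknown member(s): ",
                     paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(
    list(design = design, technologies = technologies, assay = assay,
         pcr_replicates = as.integer(pcr_replicates), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

config_assay <- function(config, panel_id, target) {
  a <- config$assay
  if (inherits(a, "assay_model")) return(a)
  key <- paste0(panel_id, ":", target)
  if (!key %in% names(a)) abort(paste0("No assay model for ", key, "."))
  a[[key]]
}

#' Generate a full synthetic study
#'
#' One replicate-level Ct record per (technology x non-excluded member x
#' aliquot x PCR replicate x target), honouring each technology's missing
#' extracts. Deterministic for a fixed config seed.
#'
#' @param config A [simulation_config()].
#' @return Tibble of Ct records: tech_id, panel_id, member_id, aliquot_index,
#'   pcr_rep_index, target, ct (NA = not detected).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- design_truth(config$design)
  grid <- purrr::map_dfr(config$technologies, function(tech) {
    g <- tidyr::uncount(truth, weights = .data$aliquot_count,
                        .id = "aliquot_index", .remove = FALSE)
    g <- tidyr::crossing(g, pcr_rep_index = seq_len(config$pcr_replicates))
    g$tech_id <- tech$tech_id
    me <- tech$missing_extracts
    if (!is.null(me) && nrow(me) > 0) {
      for (i in seq_len(nrow(me))) {
        drop_aliquots <- g$member_id == me$member_id[i] &
          g$aliquot_index > (g$aliquot_count - me$n_missing[i])
        if (!is.na(me$target[i])) {
          drop_aliquots <- drop_aliquots & g$target == me$target[i]
        }
        g <- g[!drop_aliquots, ]
      }
    }
    g
  })
  # fixed ordering so draws are reproducible whatever the construction order
  grid <- dplyr::arrange(
    grid,
    .data$tech_id, match(.data$panel_id, c("SP", "BL", "ST")),
    .data$member_num, .data$aliquot_index, .data$target, .data$pcr_rep_index
  )
  tech_by_id <- setNames(config$technologies,
                         purrr::map_chr(config$technologies, "tech_id"))
  key <- paste(grid$tech_id, grid$panel_id, grid$target)
  lambda <- numeric(nrow(grid))
  rate <- numeric(nrow(grid))
  for (k in unique(key)) {
    idx <- which(key == k)
    tech <- tech_by_id[[grid$tech_id[idx[1]]]]
    panel <- grid$panel_id[idx[1]]
    target <- grid$target[idx[1]]
    assay <- config_assay(config, panel, target)
    tiers <- grid$tier[idx]
    lam <- numeric(length(idx))
    for (tl in setdiff(unique(tiers), "none")) {
      load <- tier_to_template_load(tl, assay)
      lam[tiers == tl] <-
        expected_pcr_copies(load, tech, panel, grid$na_class[idx[1]])
    }
    lambda[idx] <- lam
    rate[idx] <- tech_contamination_rate(tech, target)
  }
  set.seed(config$seed)
  ct <- numeric(nrow(grid))
  # draw per (tech, panel, target) block in the sorted order, so each block's
  # assay model (and thus draw count) is applied contiguously
  blocks <- unique(key)
  for (k in blocks) {
    idx <- which(key == k)
    assay <- config_assay(config, grid$panel_id[idx[1]], grid$target[idx[1]])
    tech <- tech_by_id[[grid$tech_id[idx[1]]]]
    ct[idx] <- simulate_replicates(length(idx), lambda[idx], assay,
                                   rate[idx], tech$contamination_ct_range)
  }
  tibble::tibble(
    tech_id = grid$tech_id, panel_id = grid$panel_id,
    member_id = grid$member_id, aliquot_index = as.integer(grid$aliquot_index),
    pcr_rep_index = as.integer(grid$pcr_rep_index), target = grid$target,
    ct = ct
  )
}

#' Example per-technology workflow metrics
#'
#' Synthetic workflow metrics for the six example technologies: volumes follow
#' the published workflow table; turnaround times and manual step counts are
#' illustrative values consistent with the narrative ranges (B/E fastest but
#' step-heavy, A slowest, C few steps except stool, all at $2 per
#' extraction). Real analyses should supply measured values via
#' [read_workflow_metrics()].
#'
#' @return Workflow-metrics tibble (one row per technology x panel).
#' @export
example_workflow_metrics <- function() {
  vols <- tibble::tribble(
    ~tech_id, ~panel_id, ~input_volume, ~elution_volume,
    "A", "SP", 500, 105, "A", "BL", 1000, 105, "A", "ST", 750, 105,
    "B", "SP", 500, 150, "B", "BL", 100, 150, "B", "ST", 250, 150,
    "C", "SP", 150, 50,  "C", "BL", 50, 50,   "C", "ST", 70, 50,
    "D", "SP", 80, 100,  "D", "BL", 80, 100,  "D", "ST", 80, 100,
    "E", "SP", 100, 50,  "E", "BL", 100, 50,  "E", "ST", 77, 50,
    "F", "SP", 500, 100, "F", "BL", 250, 100, "F", "ST", 150, 100
  )
  work <- tibble::tribble(
    ~tech_id, ~panel_id, ~turnaround_min, ~manual_steps,
    "A", "SP", 55, 8,  "A", "BL", 55, 6,  "A", "ST", 60, 10,
    "B", "SP", 15, 10, "B", "BL", 15, 10, "B", "ST", 15, 10,
    "C", "SP", 35, 3,  "C", "BL", 35, 3,  "C", "ST", 60, 8,
    "D", "SP", 40, 10, "D", "BL", 40, 10, "D", "ST", 45, 10,
    "E", "SP", 15, 6,  "E", "BL", 15, 6,  "E", "ST", 20, 8,
    "F", "SP", 25, 4,  "F", "BL", 25, 4,  "F", "ST", 35, 5
  )
  out <- dplyr::inner_join(vols, work, by = c("tech_id", "panel_id"))
  out$provided_volume <- unname(provided_volumes()[out$panel_id])
  out$pcr_aliquot <- 5
  out$cost_usd <- 2
  validate_workflow_metrics(out[, c("tech_id", "panel_id", "input_volume",
                                    "provided_volume", "elution_volume",
                                    "pcr_aliquot", "turnaround_min",
                                    "manual_steps", "cost_usd")])
}

#' Example technology set emulating the six study developers
#'
#' Input/elution volumes follow the study's workflow table; recoveries,
#' contamination rates and missing extracts are illustrative values chosen to
#' mirror the qualitative behaviour of developers A-F (A strong with large
#' inputs; B low recovery with pervasive MS2 carry-over contamination; C a
#' target-restricted short eluate on SP3; D weak; E good recovery, small
#' volumes, two stool aliquots never shipped; F strong with one sporadic
#' contamination channel).
#'
#' @return Named list of six [technology_model()] objects.
#' @export
example_technologies <- function() {
  list(
    A = technology_model(
      "A", c(SP = 500, BL = 1000, ST = 750), 105, recovery = 0.90),
    B = technology_model(
      "B", c(SP = 500, BL = 100, ST = 250), 150, recovery = 0.35,
      contamination_rate = c(MS2 = 0.5, .default = 0)),
    C = technology_model(
      "C", c(SP = 150, BL = 50, ST = 70), 50, recovery = 0.55,
      missing_extracts = tibble::tibble(
        member_id = "SP3", n_missing = 1L, target = "M. tuberculosis")),
    D = technology_model(
      "D", c(SP = 80, BL = 80, ST = 80), 100, recovery = 0.30),
    E = technology_model(
      "E", c(SP = 100, BL = 100, ST = 77), 50, recovery = 0.75,
      missing_extracts = tibble::tibble(
        member_id = c("ST3", "ST6"), n_missing = 1L)),
    F = technology_model(
      "F", c(SP = 500, BL = 250, ST = 150), 100, recovery = 0.85,
      contamination_rate = 0.01)
  )
}
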