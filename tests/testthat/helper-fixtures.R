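# Qualified study design (SP6 removed for trace MTB DNA).
study_design <- function(layout = "realized", seed = 1L) {
  qualify_panel(build_reference_design(seed = seed, layout = layout),
                list(SP6 = "M. tuberculosis"))
}

# Independent Clopper-Pearson oracle: bisects p directly on binomial tail
# sums (dbinom only; no beta-quantile shortcut).
cp_oracle <- function(k, n, confidence = 0.95) {
  a <- (1 - confidence) / 2
  bisect <- function(f) {
    lo <- 0
    hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(function(p) sum(dbinom(k:n, n, p)) - a)
  upper <- if (k == n) 1 else bisect(function(p) a - sum(dbinom(0:k, n, p)))
  c(lower = lower, upper = upper)
}

# A deterministic "perfect technology" configuration: full specimen in, full
# eluate out, no noise, no contamination, and a reference curve placing even
# the low tier far above the Poisson detection floor.
perfect_config <- function(design, seed = 1L) {
  tech <- technology_model("perfect", c(SP = 500, BL = 1000, ST = 1000),
                           elution_volume = 5, pcr_aliquot = 5, recovery = 1)
  assay <- assay_model(ct_intercept = 44, ct_slope = 3.33, ct_noise_sd = 0)
  simulation_config(design, list(tech), assay = assay, seed = seed)
}

# Minimal hand-built Ct record table.
ct_records <- function(tech_id, member_id, target, ct,
                       panel_id = substr(member_id, 1, 2)) {
  n <- length(ct)
  tibble::tibble(
    tech_id = rep_len(tech_id, n), panel_id = rep_len(panel_id, n),
    member_id = rep_len(member_id, n),
    aliquot_index = rep(1:3, length.out = n),
    pcr_rep_index = rep(1:3, each = 3, length.out = n),
    target = rep_len(target, n), ct = ct
  )
}
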