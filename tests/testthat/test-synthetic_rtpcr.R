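test_that("tier loads invert the reference standard curve", {
  a <- assay_model(ct_intercept = 38, ct_slope = 3.33)
  load_low <- tier_to_template_load("low", a)
  expect_equal(load_low, 10^((38 - 35) / 3.33))
  # plugging the load back into the curve recovers the tier Ct
  expect_equal(38 - 3.33 * log10(load_low), 35)
  # a tier centred at the intercept corresponds to a single copy
  a1 <- assay_model(ct_intercept = 35, ct_slope = 3.3)
  expect_equal(tier_to_template_load("low", a1), 1)
  # ratio law between tiers
  expect_equal(tier_to_template_load("high", a) / load_low, 10^((35 - 18) / 3.33))
  expect_error(tier_to_template_load("none", a), "no template load")
})

test_that("expected copies chain dilution and recovery factors", {
  ident <- technology_model("i", c(SP = 500, BL = 1000, ST = 1000),
                            elution_volume = 5, pcr_aliquot = 5, recovery = 1)
  expect_equal(expected_pcr_copies(100, ident, "SP", "DNA"), 100)
  half <- technology_model("h", c(SP = 500, BL = 1000, ST = 1000),
                           elution_volume = 5, pcr_aliquot = 5, recovery = 0.5)
  expect_equal(expected_pcr_copies(100, half, "SP", "DNA"), 50)
  # developer A sputum: full sample, 5 of 105 uL eluate per reaction
  a_tech <- technology_model("A", c(SP = 500, BL = 1000, ST = 750),
                             elution_volume = 105, recovery = 1)
  expect_equal(expected_pcr_copies(100, a_tech, "SP", "DNA"), 100 * 5 / 105)
  expect_error(
    technology_model("z", 500, elution_volume = 0),
    "elution_volume"
  )
  expect_error(expected_pcr_copies(100, ident, "SP", "DNA",
                                   sample_fraction_used = 1.2),
               "sample_fraction_used")
})

test_that("replicate simulation respects its deterministic limits", {
  a <- assay_model(ct_noise_sd = 0)
  set.seed(1)
  expect_true(all(is.na(simulate_replicates(200, 0, a))))
  set.seed(1)
  ct <- simulate_replicates(5, 1e6, a)
  expect_true(all(abs(ct - (38 - 3.33 * log10(1e6))) < 3.33 * 0.01))
  expect_error(simulate_replicates(5, -1, a), "lambda")
})

test_that("detection frequency matches the Poisson zero class", {
  a <- assay_model(ct_noise_sd = 0.5)
  set.seed(99)
  n <- 10000
  ct <- simulate_replicates(n, 1, a)
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(!is.na(ct)) - p), 3 * se)
})

test_that("contamination injects spurious positives within its Ct range", {
  a <- assay_model()
  set.seed(5)
  ct <- simulate_replicates(5000, 0, a, contamination_rate = 0.2,
                            contamination_ct_range = c(31, 42))
  hits <- ct[!is.na(ct)]
  expect_gt(length(hits), 0)
  expect_true(all(hits >= 31 & hits <= 42))
  expect_lt(abs(length(hits) / 5000 - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("generate_study emits the full replicate grid deterministically", {
  d <- study_design()
  tech <- technology_model("T", c(SP = 500, BL = 1000, ST = 1000),
                           elution_volume = 100, recovery = 0.8)
  cfg <- simulation_config(d, list(tech), seed = 7)
  recs <- generate_study(cfg)
  expect_equal(nrow(recs), 87 * 3 * 2)
  expect_identical(generate_study(cfg), recs)
  expect_false(identical(
    generate_study(simulation_config(d, list(tech), seed = 8))$ct, recs$ct))
  # unique replicate keys
  key <- paste(recs$tech_id, recs$member_id, recs$aliquot_index,
               recs$pcr_rep_index, recs$target)
  expect_false(anyDuplicated(key) > 0)
})

test_that("missing extracts drop whole aliquots, optionally per target", {
  d <- study_design()
  tech <- technology_model(
    "E", c(SP = 100, BL = 100, ST = 77), 50, recovery = 0.7,
    missing_extracts = tibble::tibble(member_id = c("ST3", "ST6"),
                                      n_missing = 1L))
  recs <- generate_study(simulation_config(d, list(tech), seed = 1))
  expect_equal(nrow(recs), 522 - 12)
  expect_equal(sum(recs$member_id == "ST3"), 12)  # 2 aliquots x 3 reps x 2 targets
  tech_c <- technology_model(
    "C", c(SP = 150, BL = 50, ST = 70), 50, recovery = 0.5,
    missing_extracts = tibble::tibble(member_id = "SP3", n_missing = 1L,
                                      target = "M. tuberculosis"))
  recs_c <- generate_study(simulation_config(d, list(tech_c), seed = 1))
  expect_equal(nrow(recs_c), 522 - 3)
  sp3 <- recs_c[recs_c$member_id == "SP3", ]
  expect_equal(sum(sp3$target == "M. tuberculosis"), 6)
  expect_equal(sum(sp3$target == "influenza A"), 9)
  expect_error(
    simulation_config(d, list(technology_model(
      "X", 500, 100,
      missing_extracts = tibble::tibble(member_id = "QQ1", n_missing = 1L))),
      seed = 1),
    "unknown member"
  )
})

test_that("perfect technology yields perfect downstream accuracy", {
  d <- study_design()
  recs <- generate_study(perfect_config(d, seed = 1))
  acc <- accuracy_table(recs, d)
  expect_true(all(acc$sensitivity == 1))
  expect_true(all(acc$specificity == 1))
})

test_that("detection probability orders by spike tier", {
  d <- study_design()
  tech <- technology_model("T", c(SP = 500, BL = 1000, ST = 1000),
                           elution_volume = 100, recovery = 0.6)
  assay <- assay_model(ct_intercept = 41, ct_slope = 3.33)
  recs <- generate_study(simulation_config(d, list(tech), assay, seed = 2))
  truth <- design_truth(d)
  joined <- merge(recs, truth[, c("member_id", "target", "tier")],
                  by = c("member_id", "target"))
  rates <- tapply(!is.na(joined$ct), joined$tier, mean)
  expect_gt(rates[["high"]], rates[["medium"]] - 1e-9)
  expect_gt(rates[["medium"]], rates[["low"]])
  expect_gt(rates[["low"]], rates[["none"]])
})

test_that("downstream sensitivity is monotone in recovery under a shared seed", {
  d <- study_design()
  assay <- assay_model(ct_intercept = 41, ct_slope = 3.33)
  sens_at <- function(r) {
    tech <- technology_model("T", c(SP = 500, BL = 1000, ST = 1000),
                             elution_volume = 100, recovery = r)
    recs <- generate_study(simulation_config(d, list(tech), assay, seed = 31))
    acc <- accuracy_table(recs, d)
    mean(acc$sensitivity)
  }
  sens <- vapply(c(0.05, 0.3, 1), sens_at, numeric(1))
  expect_true(all(diff(sens) >= 0))
})
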