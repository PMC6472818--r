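# assurbench

Benchmarking nucleic acid (NA) extraction technologies with blinded,
spiked specimen panels.

Molecular diagnostics for resource-limited settings need an extraction step
that recovers amplifiable pathogen DNA/RNA from difficult matrices — sputum,
whole blood, stool — cheaply and with minimal hands-on work. `assurbench` is
for groups running (or re-analysing) head-to-head evaluations of candidate
extraction technologies: it encodes the panel design and qualification
bookkeeping, a synthetic replicate-level RT-PCR data generator, the
replicate-level diagnostic accuracy statistics, volumetric efficiency
metrics, and the five-attribute ASSUR multi-criteria ranking.

## What it computes

**Panels.** Three ten-member specimen panels (sputum/blood/stool), each
member spiked with an RNA- and/or DNA-based microbe at a tier indexed by
reference Ct — high (Ct 18 ± 1.5), medium (26 ± 1.5), low (35 ± 1.5) — or
left negative. Members ship as three blinded aliquots; qualification
excludes members with detectable target in a supposed-negative channel.

**Accuracy.** Each extract is tested in triplicate RT-PCR per target (nine
replicates per member). With replicate-level 2×2 counts,

- sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
- exact 95% CIs by Clopper–Pearson:
  lower = B(α/2; k, n−k+1), upper = B(1−α/2; k+1, n−k),
- per-target score (Se+Sp)/2, competition-ranked across technologies, and
  pooled per panel / overall as the mean of per-target scores.

**Volumetrics.** % of provided specimen processed, % of eluate per 5 µL PCR
aliquot, and their product — the % of the original specimen interrogated per
reaction — reproduced at printed precision with half-up rounding.

**ASSUR.** Five attributes (Affordable, Sensitive, Specific, User-friendly =
manual steps, Rapid = turnaround) min–max normalized to [0, 1] across
technologies (1.0 = most optimal observed; cost-type attributes reversed;
all-equal attributes score 1.0), equally weighted and averaged per target,
pooled per panel and overall, with radar-plot coordinates exported in
clockwise A-S-S-U-R order.

**Simulator.** Spike tier → template load by inverting a log-linear
standard curve; load → expected copies per reaction λ through sample
fraction × recovery × eluate fraction; Poisson(λ) template counts with
Ct = intercept − slope·log₁₀(copies) + noise, censored at 45 cycles;
optional per-target contamination and missing-extract events.

## Worked example

```r
library(assurbench)

design <- qualify_panel(
  build_reference_design(seed = 1, layout = "realized"),
  list(SP6 = "M. tuberculosis")
)
design
#> <panel_design> 3 panels, 29 active members (1 excluded), 87 shipped aliquots
```

Removing the contaminated sputum member leaves 87 shipped aliquots. A spiked
channel detected in 27 of its 36 replicates gets an exact interval of:

```r
round_half_up(clopper_pearson(27, 36), 2)
#>   lower upper
#> 1  0.58  0.88
```

i.e. sensitivity 0.75 (95% CI 0.58–0.88). Pooling the published per-target
accuracy scores ranks the six (anonymised) technologies on performance:

```r
rank_pooled(accuracy_from_published(reference_accuracy()), "overall")
#>   tech_id scope   pooled_score  rank
#> 1 A       overall        0.954     1
#> 2 B       overall        0.64      6
#> 3 C       overall        0.84      4
#> 4 D       overall        0.68      5
#> 5 E       overall        0.885     3
#> 6 F       overall        0.894     2
```

Technology A leads on raw performance; once workflow attributes enter
through ASSUR pooling, F overtakes it:

```r
rank_assur(reference_assur(), "overall")
#>   tech_id scope   pooled_score  rank
#> 1 A       overall        0.655     3
#> 2 B       overall        0.652     4
#> 3 C       overall        0.7       2
#> 4 D       overall        0.538     6
#> 5 E       overall        0.652     4
#> 6 F       overall        0.77      1
```

## Analysis workflow

The numbered drivers under `analysis/` run the full pipeline and write
tables to `results/`:

1. `01_build_panels.R` — build + qualify the panels, export design and
   blinding map.
2. `02_simulate_study.R` — synthetic six-technology replicate-level Ct
   table with provenance.
3. `03_accuracy.R` — member summaries, accuracy table with exact CIs,
   rankings; regression of the interval machinery against the published
   accuracy table.
4. `04_volumetrics.R` — volumetric efficiency table and its cell-by-cell
   regression.
5. `05_assur.R` — ASSUR scores, radar coordinates, panel/overall rankings.

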