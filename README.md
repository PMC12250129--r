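# radlig

Quantitative evaluation of therapeutic radioligands in preclinical
studies — an R package for the analysis chain used when a beta-emitting,
receptor-targeted radiopharmaceutical (the archetype being a
Lu-177-labelled PSMA ligand in a prostate-cancer model) moves from the
radiochemistry bench to an efficacy and dosimetry readout:

- **Nuclide arithmetic** — physical decay factors, decay correction of
  gamma-counter measurements, molar activity (`decay_factor`,
  `decay_correct`, `molar_activity`; Lu-177 constants shipped).
- **Radiochemical QC** — peak-window integration of iTLC / radio-HPLC
  count profiles for radiochemical purity, and serum-stability tables
  (`window_fraction`, `radiochemical_purity`, `stability_summary`).
- **Binding assays** — cellular uptake per 10⁶ cells, one-site
  saturation fits *B(c) = B·c/(K_d + c)*, one-site competition fits on
  log-concentration, and the Cheng-Prusoff conversion
  *K_i = IC₅₀ / (1 + [L]/K_d)* (`fit_saturation`, `fit_competition`,
  `cheng_prusoff`).
- **Biodistribution** — gamma-counter worksheets to %IA/g (percent
  injected activity per gram, decay-referenced to injection), group
  means ± SD, and tumor-to-normal ratios (`percent_ia_per_gram`,
  `summarize_biodist`, `tn_ratios`).
- **MIRD-style dosimetry** — mouse-to-human relative organ-mass scaling
  *(%IA/organ)ₕ = (%IA/g)ₐ · (kg TB)ₐ · (g organ/kg TB)ₕ*, exponential
  time-activity fits with rates bounded by physical decay, residence
  times τ = Σ cᵢ/rᵢ, the MIRD dose sum *D(t) = Σₛ τₛ·S(t←s)* and the
  ICRP-60 tissue-weighted effective dose (`extrapolate_to_human`,
  `fit_time_activity`, `cumulated_activity`, `organ_doses`,
  `effective_dose`).
- **Survival efficacy** — humane-endpoint eventing (≥ 20% body-weight
  loss), Kaplan–Meier curves, median survival defined as the smallest t
  with S(t) ≤ 0.5, Mantel–Cox log-rank, lifespan increase (`km_curve`,
  `median_survival`, `logrank`, `lifespan_increase`).
- **Synthetic data** — seeded generators for every input (worksheets,
  assays, chromatograms, stability series, survival records) with
  forward models independent of the analysis code, so zero-noise
  round-trips are genuine end-to-end tests (`simulate_*`,
  `biodist_preset_lncap`).

`run_pipeline()` binds the stages into a deterministic end-to-end run
that writes tidy CSV reports, a manifest and a log;
`inst/scripts/run_pipeline.R` is a thin Rscript wrapper.

## Worked example

```r
library(radlig)

# binding affinity from noiseless one-site assay fixtures
a   <- simulate_binding(cfg = sim_config(seed = 42))
sat <- fit_saturation(a$saturation$concentration_nM,
                      a$saturation$total_cpm, a$saturation$nonspecific_cpm)
comp <- fit_competition(a$competition$competitor_nM, a$competition$bound_cpm)
sat$Kd                                          # 4.358 nM
comp$IC50                                       # 17.709 nM
cheng_prusoff(comp$IC50, a$radioligand_nM, sat$Kd)  # 15.10881 nM

# biodistribution: counts -> %IA/g -> tumor-to-normal ratios
sheets <- simulate_worksheet(biodist_preset_lncap(), sim_config(seed = 42))
bt <- summarize_biodist(lapply(sheets, percent_ia_per_gram))
bt[bt$organ == "tumor", ]
#   organ time_h mean_pia_g sd n
#   tumor      1  13.149000  0 3
#   tumor      4  23.310000  0 3
#   tumor     24  12.880000  0 3
#   tumor     48   6.320685  0 3
r <- tn_ratios(bt, "tumor")
r[r$organ %in% c("blood", "muscle") & r$time_h %in% c(1, 24), ]
#    organ time_h ratio
#    blood      1  69.5
#    blood     24 434.4
#   muscle      1  60.2
#   muscle     24 857.4
```

The tumor accumulates to 23.31 %IA/g at 4 h and clears slowly, while
blood and muscle clear fast, so tumor-to-blood rises from 69.5 at 1 h to
434.4 at 24 h and tumor-to-muscle from 60.2 to 857.4 — the
pharmacokinetic signature of a well-retained, receptor-targeted ligand.
K_d ≈ 4.4 nM and IC₅₀ ≈ 17.7 nM characterise high-affinity one-site
binding; the Cheng-Prusoff K_i corrects the IC₅₀ for the 0.75 nM
radioligand used in the competition assay.

```r
# three-arm survival efficacy
subj <- simulate_survival(cfg = sim_config(seed = 42))
es <- efficacy_summary(subj, "control")
es$medians
#          group n median_days
#        control 6          21
#    lu177_37MBq 8          31
#   lu177_111MBq 9          39
es$tests
#          group     chisq            p
#    lu177_37MBq 11.096539 0.0008648897
#   lu177_111MBq  7.594631 0.0058542373
```

Both treated arms separate significantly from control by log-rank
(p < 0.05); medians fluctuate around the generating values (26/34/40
days) at these small group sizes. The exact lifespan-increase arithmetic
on the design medians is `lifespan_increase(34, 26)` = 30.77% and
`lifespan_increase(40, 26)` = 53.85%.

A complete run — QC, binding, biodistribution, dosimetry, survival —
with all reports written to disk:

```r
run_pipeline(default_run_config(seed = 42), "runs/demo")
```

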