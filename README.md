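# rumiflux

Enteric methane quantification by the SF6 tracer technique, with the rumen
fermentation, protozoa, nutrition and archaeome analytics that accompany a
sheep feeding trial — plus a seeded forward simulator so the entire chain
runs and is testable without animal data.

## Who this is for

Ruminant-nutrition and methane-mitigation researchers who run (or review)
SF6 tracer trials: sheep or cattle fitted with an intraruminal permeation
tube releasing sulfur hexafluoride at a calibrated rate, breath sampled into
evacuated canisters, methane and SF6 measured by gas chromatography, and the
outcome interpreted through rumen fermentation stoichiometry, protozoa
counts, digestibility arithmetic and amplicon (16S) archaeal community
summaries.

## The computations

**Tracer flux.** The permeation-tube release rate R_SF6 (mg/day) is the
magnitude of the least-squares slope of weekly tube mass on day
(`calibrate_release_rate`). Measured canister concentrations G_A are
corrected for the sampling and dilution pressure spans,

    G_S = (P_atm − τ_f) / (τ_e − τ_s) × G_A,    P_atm = 90 kPa by default,

(`correct_concentration`), and daily emission follows from the
background-corrected tracer ratio (`methane_emission`):

    R_CH4 = R_SF6 · ([CH4]_M − [CH4]_BG)/([SF6]_M − [SF6]_BG)
            · (MW_CH4 / MW_SF6) · 1000        [g/day]

with CH4 in ppm, SF6 in ppt, MW_CH4 = 16.04, MW_SF6 = 146.06. Methane yield
is emission per kg of dry matter intake (`methane_yield`).

**Fermentation.** VFA from external-standard GC peak areas
(`vfa_concentration`), ammonia-N from microdiffusion titres (`ammonia_n`),
the acetate:propionate ratio, and the stoichiometric metabolic hydrogen
balance (`metabolic_hydrogen`):

    2H = 2·acetate + propionate + 4·butyrate + 3·valerate   [mmol]

(n-acids only; iso-acids arise from protein, not carbohydrate,
fermentation).

**Protozoa.** Hemocytometer enumeration N = n̄·A·D/(a·v) cells/ml from 30
microscope fields per sample (`enumerate_protozoa`), with paired
pre/post-withdrawal comparisons (`compare_withdrawal`).

**Nutrition.** NFE by difference, ME = 0.82·GE, DMI, energy intake,
balance-window digestibility, ADG, and oil-dose economics
(`oil_dose_and_economics`).

**Archaeome.** ASV-table pruning, rarefaction without replacement
(`rarefy_counts`, default depth 31,044), per-10,000 scaling, rank
aggregation, Shannon diversity, prevalence/detection core filtering
(`core_archaeome`, defaults 50% / 0.01) and Bray–Curtis PERMANOVA
(`permanova`, 999 permutations).

**Statistics.** One-way ANOVA (Y_ij = μ + A_i + ε_ij), Tukey–Kramer pairwise
tests with compact letter displays, paired t, Pearson correlation matrices,
Wilcoxon rank-sum (exact for small n) and the D'Agostino–Pearson omnibus
normality screen.

**Simulator.** `generate_trial(trial_config())` forward-simulates a
three-group (control / daily oil / alternating-week oil), 6-animals-per-
group, 180-day trial: latent per-animal traits are drawn with
SD = SEM·√n around configurable group means, and every observable record
(intake, feces, body weights, tube weighings, canisters, GC peaks, titres,
field counts, Dirichlet-multinomial ASV tables) is produced by an explicit
forward model that the pipeline inverts — exactly, when noise is switched
off.

## Worked example

```r
library(rumiflux)

td <- generate_trial(trial_config(seed = 1))   # full synthetic trial
q  <- quantify_trial(td)                       # tubes -> canisters -> g/day
q$emissions$per_group
#>   group n mean_g_day    sem
#> 1   CON 6      17.04 0.9118
#> 2   CTR 6      23.48 0.6837
#> 3   INT 6      19.47 0.5626
q$yield_groups
#>   group n yield_g_kg    sem
#> 1   CON 6      18.71 0.9369
#> 2   CTR 6      26.87 0.4914
#> 3   INT 6      21.34 0.7457
```

At this seed the recovered group means sit where the generator put them:
control sheep emit ~23.5 g CH4/day (yield ~26.9 g/kg DMI) and daily oil
supplementation cuts emission to ~17 g/day — the pipeline recovers the
configured 23.6 / 17.5 / 18.0 g/day structure from raw canister pressures
and GC readings. The reporting layer reproduces the trial-table shape
(means, pooled SEM, F, p, Tukey letters):

```r
rep <- trial_report(td)
rep[rep$attribute %in% c("methane_g_day", "ap_ratio"), ]
#>       attribute    CTR   CON    INT    sem       F         p           letters
#> 1 methane_g_day 23.485 17.04 19.472 0.7338 19.6994 6.365e-05 CTR:b,CON:a,INT:a
#> 2      ap_ratio  4.508  3.85  4.267 0.1659  4.0346 3.962e-02 CTR:b,CON:a,INT:ab
```

Stoichiometry on the trial-table group means reproduces the published
hydrogen balance:

```r
ctr <- vfa_profile(51.9, 11.3, 0.75, 3.49, 0.82, 0.24)
metabolic_hydrogen(ctr)            # 129.78 mmol  (reported: 130)
acetate_propionate_ratio(ctr)      # 4.59
methane_yield(23.6, 884)           # 26.7 g/kg DMI
```

And the archaeome stage:

```r
a <- archaeome_summary(td, rank = "genus")
round(100 * colMeans(a$rel_abund), 2)
#>            Group10            Group12            Group3b             Group9
#>               0.81               4.35               1.43               0.90
#>   Methanobacterium Methanobrevibacter     Methanosarcina     Methanosphaera
#>               2.11              85.14               2.19               3.07
a$core$CTR   # genera >= 1% abundance in >= 50% of control samples
#> [1] "Group12"            "Group3b"            "Methanobacterium"
#> [4] "Methanobrevibacter" "Methanosarcina"     "Methanosphaera"
a$permanova$p
#> [1] 0.113    # no community-level diet effect, as configured
```

## Layout

- `R/` — implementation (gas quantification, fermentation, nutrition,
  protozoa, archaeome, statistics, simulator, pipelines, TSV I/O)
- `tests/testthat/` — unit, property and acceptance suites
- `scripts/acceptance.R` — the acceptance report
- `vignettes/methane-trial-pipeline.Rmd` — the methods vignette
- `inst/cli/rumiflux` — command-line front end
  (`simulate` / `quantify` / `report`)
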