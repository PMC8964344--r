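---
title: "Quantifying enteric methane with the SF6 tracer: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enteric methane with the SF6 tracer: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumiflux)
```

# The measurement problem

Enteric methane from a free-moving animal cannot be metered directly.
The SF6 tracer technique solves this with a ratio argument: a small brass
permeation tube in the rumen releases sulfur hexafluoride at a constant,
gravimetrically calibrated rate; breath sampled continuously into an
evacuated canister then contains CH4 and SF6 mixed in proportion to their
fluxes. If the release rate R_SF6 is known and both gases are measured
against a background canister, the methane flux is

$$R_{CH4} = R_{SF6}\,
  \frac{[CH4]_M - [CH4]_{BG}}{[SF6]_M - [SF6]_{BG}}\,
  \frac{MW_{CH4}}{MW_{SF6}} \times 1000,$$

in g/day with R_SF6 in mg/day, CH4 in ppm and SF6 in ppt. The factor
1000 together with the ppm/ppt mismatch carries the unit bookkeeping; the
package's tests re-derive the constant from an independent molar-flux
formulation (mol SF6/day scaled by the mixing ratio), which pins down both
the arithmetic and the molecular masses used (16.04 and 146.06 g/mol —
named but not valued in trial reports; the worked 20.04 g/day example
confirms them).

This package implements that chain end to end — tube calibration, canister
pressure accounting, emission, yield — together with everything such a
trial reports around it: rumen fermentation stoichiometry, protozoa
enumeration, digestibility and performance arithmetic, archaeal ASV-table
summaries, and the group-comparison statistics.

# Models and their assumptions

## Tube calibration

`calibrate_release_rate()` fits mass-on-day by ordinary least squares and
returns the magnitude of the slope. The model assumes constant release over
the calibration weeks (permeation tubes at constant temperature are
well-described by this). R² is returned as a QC value; a non-decreasing
mass series yields rate 0 with a QC flag rather than a negative rate — a
tube that does not lose mass provides no tracer and must be excluded, not
"corrected".

## Canister pressure correction

Concentrations presented to the GC are diluted by the N2 top-up and depend
on how full the canister was. The field protocol this package implements
corrects as

$$G_S = \frac{P_{atm} - \tau_f}{\tau_e - \tau_s}\, G_A,$$

with the site's atmospheric pressure (default 90 kPa, ~920 m elevation)
rather than sea-level pressure. The numerator is the post-dilution pressure
span while the denominator is the sampling span — dimensionally unusual
(a conventional dilution-only correction would put $P_{atm}-\tau_s$ in the
denominator), but it is the equation as printed in the protocol, so it is
implemented verbatim as the default. The conventional form is available
via `method = "conventional"` in `correct_concentration()`; the two are
**not** interchangeable and no silent substitution is made. The vacuum
readings are treated as gauge-vacuum values exactly as recorded (the
protocol reports canisters evacuated to "> 95 kPa" vacuum at a site where
atmospheric pressure is 90 kPa; the package does not reinterpret them).
Because the synthetic forward model emits raw readings by inverting the
same correction, the round trip is exact by construction whichever form is
chosen, and QC on the dilution factor (2.15–3.0-fold window) is a warning,
not an error.

## Negative deltas and failed canisters

Field datasets routinely contain canisters in which the breath
concentration does not exceed background. A non-positive SF6 delta means
the tracer itself was not recovered: the scalar API raises an error, and
the vectorized `emission_records()` flags the animal-day (`tracer_failure`)
and excludes it. A negative CH4 delta with a valid SF6 delta is truncated
to zero emission with a `negative_delta_ch4` flag. `summarize_emissions()`
averages per animal first and then per group (two-stage averaging), which
matches how per-animal SEMs are constructed in trial tables; animals with
no valid day are dropped with a logged reason.

## Fermentation stoichiometry

Metabolic hydrogen is computed as $2A + P + 4B + 3V$ (mmol). **B and V are
n-butyrate and n-valerate only.** The iso-acids are branched skeletons from
amino-acid deamination, not carbohydrate fermentation; including them would
give 135.2 mmol for the control-group profile where the published balance
is 130, while the n-acid form gives 129.78. The hydrogen-utilization
fraction (`hydrogen_to_methane_fraction()`) deliberately **requires** an
explicit pool/turnover scaling: daily emission is a flux (g/day) while the
VFA-derived 2H is a concentration in one rumen-fluid sample (mmol), and no
printed quantity fixes the conversion. The published 73/54/56% figures are
therefore reproducible only conditionally (calibrate the scale on one
group, propagate to the others — the tests do exactly this as a band
check), and they are not acceptance targets.

The ammonia titration formula is `titre × k` with `k = 1` as printed for
the assay as run; the titrant-normality discrepancy in the source protocol
(0.01 N in the text vs 0.001 N in the formula) is absorbed into the
configurable `k` rather than resolved by guessing.

## Protozoa enumeration

The counting-chamber formula $N = \bar n A D/(a v)$ needs geometry the
protocol does not print. Defaults are config constants: dilution $D = 2$
(the 5 ml + 5 ml formaldehyde fixation; the methyl-green/acetic-acid
solution is a stain stock, not a sample dilution), chamber constants
$A = 9\,mm^2$, $a = 0.01\,mm^2$, $v = 9\times10^{-4}$ ml chosen so that
mean field counts land in the countable 2–50 range at the trial's cell
densities (~9×10⁷ total, ~4×10⁶ Holotrichs per ml). Morphotype
classification (Entodiniomorph vs Holotrich) is an input label — microscopy
is human work; the module only tallies and converts.

## Nutrition arithmetic

NFE closes the proximate analysis by difference; ME is 0.82 × GE (the
gross-energy prediction equation itself is not implemented — it is
attributed to an external reference and not printed, so GE/ME are inputs).
Digestibility over the 10-day balance window uses totals,
$(\sum \text{intake} - \sum \text{excreted})/\sum \text{intake}$, the
standard balance-trial convention that is robust to day-level zeros.
Oil dosing treats 2% w/v as ml = g (density 1.0 g/ml). The alternating
("biweekly") schedule is 7 days on / 7 days off starting **on**; over a
180-day trial that is 91 on-days (13 on-blocks), and it places the last
measurement week half-on/half-off exactly as the emulated trial describes.
Dose *economics*, however, are costed at the long-run 50% duty cycle
(90 days), because that is the convention under which the published totals
(3.24 and 1.61 L; INR 0.72 and 0.36 per day at 40 INR/L) were computed.
The gain side values extra ADG at a configurable mutton price
(default 600 INR/kg).

## Archaeome summaries

The ASV stage mirrors the conventional amplicon workflow: prune
low-abundance ASVs, rarefy once to the lowest retained depth (default
31,044), compute Shannon diversity on the rarefied counts (rarefy →
diversity, natural log), scale to per-10,000, aggregate to a rank, apply
the core filter (prevalence ≥ 50%, detection ≥ 0.01) and test group
separation with PERMANOVA (pseudo-F on among/within sums of squared
distances, $p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$, 999 permutations).
Two choices the source workflow leaves open are made explicit here:
the PERMANOVA distance defaults to Bray–Curtis on the scaled abundances
(configurable), and diversity is computed on single-draw rarefied counts
(an averaged multi-draw variant is available via `n_draws`). Read-level
denoising, chimera removal, taxonomy assignment and negative-binomial
differential abundance are published-tool territory and out of scope; the
simulator emits ASV tables directly.

## Statistics

The reporting layer reproduces the trial-table conventions: one-way ANOVA
($Y_{ij} = \mu + A_i + \varepsilon_{ij}$), Tukey–Kramer studentized-range
pairwise tests with an insert-and-absorb compact letter display (shared
letter ⟺ non-significant pair — an invariant the tests enforce on every
fixture), two-sided paired t, pairwise-complete Pearson matrices, and the
D'Agostino–Pearson omnibus test. The omnibus statistic is undefined at
very small n; where a trial normality-screens n = 6 groups anyway, this
package **flags** (`n_too_small`) instead of reproducing an undefined
test — a documented divergence. The pooled SEM in `group_summary()` is the
residual-mean-square form, $\sqrt{MS_{within}/n}$, and is labeled as such
since trial reports rarely state which SEM they print.

# The synthetic trial: what it emulates, what it does not

`generate_trial()` is a stated world, not a tuning dial. Its defaults are
the emulated trial's published structure: three groups (control, daily oil
at 2% of DMI, alternating-week oil) of six adult sheep for 180 days; group
means and pooled SEMs for intake, digestibility, performance, emission,
fermentation and protozoa taken from the published group tables; permeation
tubes charged with 750 ± 48.18 mg releasing 3.47 ± 0.46 mg/day; a 10-day
measurement window; an archaeal community of 69 ASVs in three families
with the dominant family at 89.8% of reads; library depths of
263,103 ± 38,445 reads truncated at the 31,044 rarefaction depth.

Choices the published tables do not determine, fixed once and documented:

- **SEM → SD.** Animal-level latent traits are drawn with
  SD = SEM·√n (n = 6), the only defensible inversion of a reported SEM.
- **Within-animal day-to-day noise.** A unit-mean lognormal factor with
  CV 10% on intake and emission. No repeatability is published; 10% is a
  realistic day-to-day CV for DMI and SF6-derived emissions. It is a free
  parameter (`within_animal_cv`), not an inference.
- **Measurement noise.** Multiplicative GC noise (5% SD) on canister
  concentrations and VFA peak areas; 3% on fecal collections; 0.1 mg
  balance error on tube weighings. All zeroable — the test suite's
  round-trip properties run in the zero-noise world, where every forward
  model composed with its pipeline inverse is the identity.
- **Dirichlet-multinomial dispersion 1000**, putting the per-sample
  dominant-family proportion at SD ≈ 1%, consistent with the published
  88.6–91.0% range across 18 samples.
- **Background air** at 1.9 ppm CH4 / 30 ppt SF6 (corrected scale), and
  canister vacuum draws constrained to the protocol's dilution window.
- **Protozoa counting noise is Poisson** per field; the zero-noise world
  uses exact expected counts (possibly fractional) so enumeration inverts
  exactly.

A green simulation test therefore establishes that the *pipeline* is
correct and that the *configured* statistical structure is recovered — it
does not establish anything about real animals: the simulator has no
diurnal or seasonal structure, no correlated traits beyond what the group
means induce (e.g. methane and protozoa co-vary across groups but not
within), no tube temperature effects, no true sequencing error model, and
group effects on the archaeal community are deliberately absent (the
emulated trial found none at the family level).

# Numerical choices and degenerate inputs

- Emissions: SF6 delta ≤ 0 → error (scalar) / flagged exclusion
  (vectorized); CH4 delta < 0 → 0 with flag. τ_e = τ_s → explicit
  division-by-zero error naming the canister.
- ANOVA with zero total variance → F = NA with `zero_variance`, and the
  letter display degenerates to p ∈ {0, 1} on mean differences.
- Paired t with zero-variance differences → p ∈ {0, 1} with a flag rather
  than NaN.
- Wilcoxon: exact null distribution when both n ≤ 10 and no ties
  (two-sided = twice the smaller tail, capped at 1); otherwise normal
  approximation with tie and continuity corrections.
- Rarefaction drops samples below depth (logged in an attribute) and is a
  single seeded draw; `rarefy(x, depth = rowSums(x))` is the identity.
- The moment-recovery property test uses a family-wise 0.1% normal
  quantile across its 69 simultaneous checks (23 attributes × 3 groups)
  plus an aggregate bias bound, because a per-check 3σ band is exceeded by
  the family maximum ~20% of the time even for a perfect generator.

# Known limitations

- The hydrogen-utilization percentages are conditional on an unstated
  scaling (see above) — reported with the assumption echoed, never
  silently.
- The as-printed pressure correction is kept verbatim; sites using the
  conventional correction must opt in explicitly.
- Tukey letters use the equal-variance studentized-range model; no
  Welch-type correction.
- The simulator's trial-table blend check (TMR composition vs the 55:45
  ingredient blend) is QC only — analyzed compositions legitimately differ
  from weighted ingredient means.
- PERMANOVA assumes exchangeability under the null; group-size imbalance
  with heteroscedastic dispersion (the betadisper question) is not tested
  here and is out of scope.
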