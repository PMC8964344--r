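#' Default group means and SEMs for the synthetic trial
#'
#' The stated world of the simulator: per-group means and pooled SEMs of the
#' trial attributes (intake, performance, emission, fermentation, protozoa),
#' for a 3-group (control CTR, daily oil CON, intermittent oil INT), 6-per-
#' group, 180-day sheep feeding trial. Protozoa attributes are in units of
#' 1e7 cells/ml (total and Entodiniomorphs) or 1e6 cells/ml (Holotrichs);
#' `_wd` attributes describe the oil-withdrawal re-measurement.
#'
#' @return data frame: `attribute`, `CTR`, `CON`, `INT`, `sem`.
#' @export
default_group_means <- function() {
  tab <- rbind(
    c("dmi",              884,   900,   893,   3.42),
    c("dmi_wd",           967,  1014,   988,  11.0),
    c("initial_bw",       24.1,  24.1,  24.1,  0.273),
    c("adg",              32.7,  49.3,  36.9,  3.07),
    c("methane",          23.6,  17.5,  18.0,  0.918),
    c("methane_wd",       23.3,  22.8,  24.4,  2.06),
    c("dig_dm",           68.8,  67.2,  67.9,  0.29),
    c("dig_om",           69.7,  68.4,  68.7,  0.28),
    c("dig_cp",           67.6,  65.9,  65.6,  0.42),
    c("dig_ndf",          63.1,  61.7,  62.8,  0.34),
    c("dig_adf",          48.3,  48.0,  48.7,  0.48),
    c("dig_ee",           78.6,  87.6,  88.0,  0.46),
    c("ammonia",          19.7,  18.8,  17.9,  0.20),
    c("acetate",          51.9,  50.5,  50.7,  1.03),
    c("propionate",       11.3,  13.0,  12.3,  0.25),
    c("iso_butyrate",     0.75,  0.63,  0.68,  0.04),
    c("butyrate",         3.49,  3.51,  3.58,  0.17),
    c("iso_valerate",     0.82,  0.77,  0.80,  0.04),
    c("valerate",         0.24,  0.23,  0.27,  0.01),
    c("protozoa_ento",    8.87,  6.25,  5.08,  0.275),
    c("protozoa_holo",    3.87,  2.54,  2.19,  0.118),
    c("protozoa_ento_wd", 9.01,  8.40,  8.48,  0.123),
    c("protozoa_holo_wd", 0.73,  0.78,  0.75,  0.031)
  )
  data.frame(attribute = tab[, 1],
             CTR = as.numeric(tab[, 2]),
             CON = as.numeric(tab[, 3]),
             INT = as.numeric(tab[, 4]),
             sem = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

#' Default total mixed ration composition
#'
#' Analyzed composition (g/kg DM) of the 55:45 finger-millet-straw and
#' concentrate total mixed ration fed in the emulated trial, plus its
#' metabolizable energy.
#'
#' @return named numeric vector: `om`, `cp`, `ee`, `ndf`, `adf`, `cf`, `ta`,
#'   `nfe` (g/kg DM) and `me` (MJ/kg DM).
#' @export
default_tmr_composition <- function() {
  c(om = 928, cp = 101, ee = 20.1, ndf = 618, adf = 357, cf = 255,
    ta = 71.7, nfe = 452, me = 11.7)
}

#' Default archaeal community parameters
#'
#' 69 ASVs in three methanogen families with Methanobacteriaceae dominant
#' (89.8 percent of reads in expectation), moderate Dirichlet-multinomial
#' overdispersion, and library depths drawn from the retained-read
#' distribution of a MiSeq archaeal amplicon run (normal, truncated at the
#' rarefaction depth 31,044).
#'
#' @return list of ASV simulation parameters.
#' @export
default_asv_params <- function() {
  list(
    n_asvs = 69,
    family_proportions = c(Methanobacteriaceae = 0.898,
                           Methanomassiliicoccaceae = 0.0797,
                           Methanosarcinaceae = 0.0223),
    dispersion = 1000,
    depth_mean = 263103,
    depth_sd = 38445,
    depth_min = 31044
  )
}

#' Build a synthetic-trial configuration
#'
#' All tunable parameters of the forward simulator. Defaults describe the
#' emulated trial: 18 adult male sheep in three groups of six fed a total
#' mixed ration for 180 days, oil supplemented at 2 percent of DMI either
#' daily (CON) or in alternating 7-day blocks (INT), SF6 permeation tubes
#' charged with 750 mg releasing 3.47 mg/day on average, a 10-day
#' methane/digestibility window on days 171-180, and rumen sampling on the
#' final day.
#'
#' @param n_per_group animals per group (>= 2).
#' @param groups group labels.
#' @param duration_days trial length.
#' @param group_means data frame as [default_group_means()].
#' @param oil_fraction_of_dmi oil dose as fraction of DMI.
#' @param int_block_days alternating block length for the INT schedule.
#' @param within_animal_cv day-to-day (within-animal) lognormal coefficient
#'   of variation applied to intake and emission (default 0.10). Set 0 for
#'   noise-free forward models.
#' @param gc_noise_sd multiplicative GC measurement noise (fractional SD)
#'   on canister concentrations and VFA peak areas (default 0.05).
#' @param fecal_noise_sd multiplicative noise on daily fecal collections
#'   (default 0.03).
#' @param atm_pressure site atmospheric pressure, kPa.
#' @param me_tmr,me_with_oil diet energy densities, MJ/kg DM.
#' @param tube_charge_mg,tube_charge_sd permeation-tube SF6 charge (mg).
#' @param tube_weigh_sd balance error of the weekly tube weighings, mg
#'   (default 0.1, the balance accuracy; set 0 for noise-free forward
#'   models).
#' @param release_rate_mg_day,release_rate_sd between-tube mean and SD of
#'   the true release rate (mg/day).
#' @param background corrected background concentrations,
#'   `c(ch4 = ppm, sf6 = ppt)`.
#' @param measurement_days number of consecutive emission-measurement days.
#' @param refusal_range daily refusal fraction range (uniform).
#' @param composition TMR composition, see [default_tmr_composition()].
#' @param asv_params see [default_asv_params()].
#' @param protozoa_geometry counting-chamber constants: `slide_area` and
#'   `field_area` (mm^2), `dilution`, `chamber_volume` (ml), `n_fields`.
#'   Defaults chosen so mean per-field counts land in the countable 2-50
#'   range at the trial's protozoa densities.
#' @param seed integer seed driving every random draw of the simulator.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(n_per_group = 6,
                         groups = c("CTR", "CON", "INT"),
                         duration_days = 180,
                         group_means = default_group_means(),
                         oil_fraction_of_dmi = 0.02,
                         int_block_days = 7,
                         within_animal_cv = 0.10,
                         gc_noise_sd = 0.05,
                         fecal_noise_sd = 0.03,
                         atm_pressure = 90,
                         me_tmr = 11.7,
                         me_with_oil = 12.24,
                         tube_charge_mg = 750,
                         tube_charge_sd = 48.18,
                         tube_weigh_sd = 0.1,
                         release_rate_mg_day = 3.47,
                         release_rate_sd = 0.46,
                         background = c(ch4 = 1.9, sf6 = 30),
                         measurement_days = 10,
                         refusal_range = c(0.08, 0.16),
                         composition = default_tmr_composition(),
                         asv_params = default_asv_params(),
                         protozoa_geometry = list(slide_area = 9,
                                                  field_area = 0.01,
                                                  dilution = 2,
                                                  chamber_volume = 9e-4,
                                                  n_fields = 30),
                         seed = 1) {
  if (n_per_group < 2) stop("configuration error: n_per_group must be >= 2")
  if (any(group_means$sem < 0)) stop("configuration error: SEMs must be >= 0")
  if (oil_fraction_of_dmi < 0 || oil_fraction_of_dmi > 1) {
    stop("configuration error: oil fraction must be in [0, 1]")
  }
  fp <- asv_params$family_proportions
  if (abs(sum(fp) - 1) > 1e-8) {
    stop("configuration error: family proportions must sum to 1")
  }
  if (asv_params$n_asvs <= 0 || asv_params$depth_min <= 0) {
    stop("configuration error: ASV count and depth must be positive")
  }
  if (asv_params$dispersion <= 0) {
    stop("configuration error: dispersion must be positive")
  }
  missing_groups <- setdiff(groups, names(group_means))
  if (length(missing_groups)) {
    stop("group_means lacks columns for: ",
         paste(missing_groups, collapse = ", "))
  }
  structure(
    list(n_per_group = n_per_group, groups = groups,
         duration_days = duration_days, group_means = group_means,
         oil_fraction_of_dmi = oil_fraction_of_dmi,
         int_block_days = int_block_days,
         within_animal_cv = within_animal_cv, gc_noise_sd = gc_noise_sd,
         fecal_noise_sd = fecal_noise_sd, atm_pressure = atm_pressure,
         me_tmr = me_tmr, me_with_oil = me_with_oil,
         tube_charge_mg = tube_charge_mg, tube_charge_sd = tube_charge_sd,
         tube_weigh_sd = tube_weigh_sd,
         release_rate_mg_day = release_rate_mg_day,
         release_rate_sd = release_rate_sd, background = background,
         measurement_days = measurement_days, refusal_range = refusal_range,
         composition = composition, asv_params = asv_params,
         protozoa_geometry = protozoa_geometry, seed = seed),
    class = "trial_config"
  )
}
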