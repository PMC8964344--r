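# High-level wrappers running whole pipeline stages on a trial dataset.

#' Quantify daily methane emission and yield for a whole trial
#'
#' Calibrates each animal's permeation tube from the weekly weighings,
#' corrects every canister, applies the tracer-ratio equation per
#' animal-day, summarizes to animal and group means, and computes methane
#' yield against the mean DMI over the measurement window.
#'
#' @param dataset a `trial_dataset` (or the list returned by
#'   [read_trial_dataset()], plus a `config`).
#' @param window which canister table to use: `"measurement"` or
#'   `"withdrawal"`.
#' @return list: `release_rates` (per animal, with R^2), `records`
#'   (per animal-day emissions), `emissions` (see [summarize_emissions()]),
#'   `yield` (per animal: mean emission, mean DMI, g/kg DMI),
#'   `yield_groups` (group means of yield with SEM).
#' @export
quantify_trial <- function(dataset, window = c("measurement", "withdrawal")) {
  window <- match.arg(window)
  cfg <- dataset$config
  cal <- lapply(split(dataset$tubes, dataset$tubes$tube_id), function(d) {
    calibrate_release_rate(permeation_tube(d$tube_id[1], d$day, d$mass_mg))
  })
  rates_by_tube <- vapply(cal, `[[`, numeric(1), "rate_mg_day")
  rates <- stats::setNames(
    rates_by_tube[dataset$animals$tube_id], dataset$animals$animal)
  canisters <- if (window == "measurement") dataset$canisters
               else dataset$canisters_wd
  records <- emission_records(canisters, rates,
                              atm_pressure = cfg$atm_pressure)
  groups <- stats::setNames(dataset$animals$group, dataset$animals$animal)
  emissions <- summarize_emissions(records, groups)

  # mean DMI per animal over the measurement window; the withdrawal-window
  # canisters fall after the recorded feeding days, so the last recorded
  # window stands in for DMI there
  meas_days <- sort(unique(canisters$day))
  if (!all(meas_days %in% dataset$intake$day)) {
    meas_days <- seq(cfg$duration_days - cfg$measurement_days + 1,
                     cfg$duration_days)
  }
  w <- dataset$intake[dataset$intake$day %in% meas_days, ]
  dmi_mean <- tapply(dmi(w$offered_g, w$refused_g), w$animal, mean)
  pa <- emissions$per_animal
  pa$dmi_g_day <- unname(dmi_mean[pa$animal])
  pa$yield_g_kg <- methane_yield(pa$mean_g_day, pa$dmi_g_day)
  yg <- do.call(rbind, lapply(split(pa, pa$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               yield_g_kg = mean(d$yield_g_kg),
               sem = stats::sd(d$yield_g_kg) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(yg) <- NULL
  list(release_rates = data.frame(
         animal = dataset$animals$animal,
         tube_id = dataset$animals$tube_id,
         rate_mg_day = unname(rates),
         r_squared = vapply(cal, `[[`, numeric(1),
                            "r_squared")[dataset$animals$tube_id]),
       records = records, emissions = emissions,
       yield = pa, yield_groups = yg)
}

#' Intake, digestibility and performance summary for a whole trial
#'
#' @param dataset a `trial_dataset`.
#' @return list: `per_animal` (DMI, nutrient intakes, energy intake,
#'   digestibility coefficients in percent, initial/final BW, ADG),
#'   `per_group` (one [group_summary()] row per attribute).
#' @export
nutrition_summary <- function(dataset) {
  cfg <- dataset$config
  comp <- cfg$composition
  an <- dataset$animals
  nutr <- c("om", "cp", "ndf", "adf", "ee")

  per_animal <- do.call(rbind, lapply(seq_len(nrow(an)), function(i) {
    a <- an$animal[i]
    it <- dataset$intake[dataset$intake$animal == a, ]
    dmi_day <- dmi(it$offered_g, it$refused_g)
    energy <- energy_intake(dmi_day, cfg$me_tmr, it$oil_day, cfg$me_with_oil)
    fe <- dataset$feces[dataset$feces$animal == a, ]
    wi <- it[it$day %in% fe$day, ]
    wdmi <- dmi(wi$offered_g, wi$refused_g)
    digs <- c(dig_dm = 100 * as.numeric(digestibility_window(wdmi, fe$dm_g)))
    for (nu in nutr) {
      intk <- wdmi * comp[[nu]] / 1000
      if (nu == "ee") intk <- intk + wi$oil_g
      digs[paste0("dig_", nu)] <-
        100 * as.numeric(digestibility_window(intk, fe[[paste0(nu, "_g")]]))
    }
    bw <- dataset$body_weights[dataset$body_weights$animal == a, ]
    bw <- bw[order(bw$day), ]
    gain <- bw$bw_kg[nrow(bw)] - bw$bw_kg[1]
    ni <- nutrient_intakes(mean(dmi_day), comp[setdiff(names(comp), "me")],
                           oil_g_day = mean(it$oil_g))
    data.frame(animal = a, group = an$group[i], dmi_g_day = mean(dmi_day),
               t(ni), energy_mj_day = mean(energy), t(digs),
               initial_bw = bw$bw_kg[1], final_bw = bw$bw_kg[nrow(bw)],
               bw_gain_kg = gain,
               adg_g_day = adg(gain, max(bw$day) - min(bw$day)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_animal) <- NULL
  attrs <- setdiff(names(per_animal), c("animal", "group"))
  per_group <- do.call(rbind, lapply(attrs, function(at) {
    group_summary(split(per_animal[[at]], per_animal$group)[unique(an$group)],
                  attribute = at)
  }))
  list(per_animal = per_animal, per_group = per_group)
}

#' Fermentation summary for a whole trial
#'
#' Runs [fermentation_table()] on the dataset's GC and titration records and
#' attaches group labels.
#'
#' @param dataset a `trial_dataset`.
#' @return data frame per animal: six VFAs, `tvfa`, `ap_ratio`, `h2_mmol`,
#'   `ammonia_mg_dl`, `group`.
#' @export
fermentation_summary <- function(dataset) {
  ft <- fermentation_table(dataset$vfa_gc, dataset$ammonia)
  ft$group <- dataset$animals$group[match(ft$animal, dataset$animals$animal)]
  ft
}

#' Protozoa enumeration summary for a whole trial
#'
#' Applies the counting-chamber formula per animal, period and morphotype.
#' Totals and Entodiniomorphs are reported in 1e7 cells/ml, Holotrichs in
#' 1e6 cells/ml.
#'
#' @param dataset a `trial_dataset`.
#' @return data frame: `animal`, `group`, `period`, `total_1e7`,
#'   `ento_1e7`, `holo_1e6`.
#' @export
protozoa_summary <- function(dataset) {
  geom <- dataset$config$protozoa_geometry
  out <- do.call(rbind, lapply(
    split(dataset$protozoa,
          list(dataset$protozoa$animal, dataset$protozoa$period)),
    function(d) {
      wide <- do.call(cbind, lapply(split(d$count, d$morphotype), identity))
      pc <- protozoa_count(wide, slide_area = geom$slide_area,
                           field_area = geom$field_area,
                           dilution = geom$dilution,
                           chamber_volume = geom$chamber_volume,
                           n_fields = geom$n_fields)
      data.frame(animal = d$animal[1], period = d$period[1],
                 total_1e7 = enumerate_protozoa(pc, "total") / 1e7,
                 ento_1e7 = enumerate_protozoa(pc, "Entodiniomorph") / 1e7,
                 holo_1e6 = enumerate_protozoa(pc, "Holotrich") / 1e6,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out$group <- dataset$animals$group[match(out$animal,
                                           dataset$animals$animal)]
  out[order(out$period, out$animal), ]
}

#' Archaeome summary for a whole trial
#'
#' The ASV-table chain: prune low-abundance ASVs, rarefy to a common depth,
#' compute Shannon diversity on the rarefied counts, scale to per-10,000,
#' aggregate to a rank, run the core-archaeome filter per group and a
#' Bray-Curtis PERMANOVA across groups.
#'
#' @param dataset a `trial_dataset`.
#' @param depth rarefaction depth (default 31044).
#' @param rank rank for aggregation and the core filter (default
#'   `"family"`; the core analysis conventionally uses `"genus"`).
#' @param seed seed for rarefaction and permutations.
#' @param n_perm PERMANOVA permutations.
#' @return list: `rarefied`, `shannon` (per sample), `rel_abund`
#'   (rank x sample relative abundance), `core` (per group), `permanova`.
#' @export
archaeome_summary <- function(dataset, depth = 31044, rank = "family",
                              seed = 1, n_perm = 999) {
  pruned <- prune_low_abundance(dataset$asv_counts)
  rar <- rarefy_counts(pruned, depth = depth, seed = seed)
  groups <- dataset$animals$group[match(rownames(rar),
                                        dataset$animals$animal)]
  sh <- apply(rar, 1, shannon_index)
  scaled <- scale_per_10000(rar)
  rel <- aggregate_rank(scaled, dataset$taxonomy, rank = rank)
  core <- core_archaeome(rel, groups)
  pmv <- permanova(bray_curtis(scaled), groups, n_perm = n_perm,
                   seed = seed)
  list(rarefied = rar,
       shannon = data.frame(sample = rownames(rar), group = groups,
                            shannon = unname(sh), stringsAsFactors = FALSE),
       rel_abund = rel, core = core, permanova = pmv)
}

#' Table-shaped group report across all measured attributes
#'
#' Emits the feeding-trial reporting shape (group means, pooled SEM, F, p,
#' Tukey letters) for emission, yield, fermentation and protozoa attributes
#' computed from the dataset by the pipeline (not from the latent truth).
#'
#' @param dataset a `trial_dataset`.
#' @return data frame, one row per attribute.
#' @export
trial_report <- function(dataset) {
  gorder <- unique(dataset$animals$group)
  q <- quantify_trial(dataset)
  f <- fermentation_summary(dataset)
  p <- protozoa_summary(dataset)
  p <- p[p$period == "supplementation", ]
  rows <- list()
  add <- function(values, groups, attribute) {
    rows[[length(rows) + 1]] <<-
      group_summary(split(values, groups)[gorder], attribute)
  }
  add(q$emissions$per_animal$mean_g_day, q$emissions$per_animal$group,
      "methane_g_day")
  add(q$yield$yield_g_kg, q$yield$group, "methane_yield_g_kg")
  for (at in c("acetate", "propionate", "iso_butyrate", "butyrate",
               "iso_valerate", "valerate", "tvfa", "ap_ratio", "h2_mmol",
               "ammonia_mg_dl")) {
    add(f[[at]], f$group, at)
  }
  add(p$total_1e7, p$group, "protozoa_total_1e7")
  add(p$ento_1e7, p$group, "protozoa_ento_1e7")
  add(p$holo_1e6, p$group, "protozoa_holo_1e6")
  do.call(rbind, rows)
}
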