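# Forward models for the synthetic sheep-trial generator. Every observable
# the pipeline consumes is generated here from latent per-animal traits, so
# the pipeline's inversions can be checked against known truth.

# unit-mean lognormal factors with coefficient of variation `cv`
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# multiplicative measurement noise, truncated away from zero
meas_noise <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  pmax(1 + stats::rnorm(n, 0, sd), 0.05)
}

# Draw canister vacuum readings consistent with the invariants
# tau_e > tau_s >= tau_f >= 0 and a dilution factor inside [2.15, 3.0].
draw_taus <- function(atm_pressure = 90) {
  tau_e <- stats::runif(1, 95.5, 97.5)
  tau_s <- stats::runif(1, 55, 65)
  dil_max <- min(2.9, 0.98 * atm_pressure / (atm_pressure - tau_s))
  dil <- stats::runif(1, 2.2, max(2.2, dil_max))
  tau_f <- atm_pressure - dil * (atm_pressure - tau_s)
  c(tau_e = tau_e, tau_s = tau_s, tau_f = max(tau_f, 0))
}

# Given true field concentrations (corrected scale), emit the raw canister
# record the GC would produce: G_A = G_S * (tau_e - tau_s)/(atm - tau_f),
# times multiplicative measurement noise.
forward_canister <- function(true_ch4_ppm, true_sf6_ppt, kind,
                             noise_sd = 0, atm_pressure = 90) {
  tau <- draw_taus(atm_pressure)
  inv <- (tau[["tau_e"]] - tau[["tau_s"]]) / (atm_pressure - tau[["tau_f"]])
  noise <- meas_noise(2, noise_sd)
  canister_sample(kind = kind,
                  tau_e = tau[["tau_e"]], tau_s = tau[["tau_s"]],
                  tau_f = tau[["tau_f"]],
                  ch4_ppm = true_ch4_ppm * inv * noise[1],
                  sf6_ppt = true_sf6_ppt * inv * noise[2],
                  atm_pressure = atm_pressure)
}

#' Forward-simulate one day's breath and background canisters
#'
#' Inversion target of the tracer-ratio emission equation: given the true
#' daily methane emission and the tube's SF6 release rate, emits a breath
#' canister and a matched background canister whose vacuum readings and GC
#' concentrations, pushed through [correct_concentration()] and
#' [methane_emission()], recover the true emission (exactly when
#' `noise_sd = 0`).
#'
#' @param true_emission_g_day true methane emission, g/day (>= 0).
#' @param release_rate_mg_day SF6 release rate, mg/day (> 0).
#' @param background corrected background concentrations,
#'   `c(ch4 = ppm, sf6 = ppt)`.
#' @param noise_sd fractional SD of multiplicative GC measurement noise.
#' @param atm_pressure site pressure, kPa.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_trial()]).
#' @return list with elements `breath` and `background`, both
#'   [canister_sample()] objects.
#' @export
forward_emission <- function(true_emission_g_day, release_rate_mg_day,
                             background = c(ch4 = 1.9, sf6 = 30),
                             noise_sd = 0, atm_pressure = 90, seed = NULL) {
  if (true_emission_g_day < 0) stop("true emission must be non-negative")
  if (release_rate_mg_day <= 0) stop("release rate must be positive")
  gen <- function() {
    delta_sf6 <- stats::runif(1, 900, 1400)  # corrected ppt above background
    delta_ch4 <- true_emission_g_day /
      (release_rate_mg_day * (MW_CH4 / MW_SF6) * 1000) * delta_sf6
    list(
      breath = forward_canister(background[["ch4"]] + delta_ch4,
                                background[["sf6"]] + delta_sf6,
                                "breath", noise_sd, atm_pressure),
      background = forward_canister(background[["ch4"]], background[["sf6"]],
                                    "background", noise_sd, atm_pressure)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Invert a forward-simulated canister pair back to an emission
#'
#' Convenience wrapper for round-trip checks: corrects both canisters and
#' applies the tracer-ratio equation.
#'
#' @param pair output of [forward_emission()].
#' @param release_rate_mg_day SF6 release rate used in the forward model.
#' @return Emission in g/day.
#' @export
recover_emission <- function(pair, release_rate_mg_day) {
  as.numeric(methane_emission(
    release_rate_mg_day,
    ch4_m = correct_concentration(pair$breath, "CH4"),
    ch4_bg = correct_concentration(pair$background, "CH4"),
    sf6_m = correct_concentration(pair$breath, "SF6"),
    sf6_bg = correct_concentration(pair$background, "SF6")))
}

#' Forward-simulate GC peak areas for a VFA profile
#'
#' Emits the peak areas the external-standard calibration would produce for
#' given true concentrations; [vfa_concentration()] inverts it exactly at
#' zero noise.
#'
#' @param conc named vector of true concentrations (mmol), names being the
#'   six acids of [vfa_profile()].
#' @param peak_area_standard,standard_conc,dilution calibration constants.
#' @param noise_sd fractional SD of multiplicative peak-area noise.
#' @return data frame: `acid`, `peak_area_sample`, `peak_area_standard`,
#'   `standard_conc`, `dilution`.
#' @export
forward_vfa_gc <- function(conc, peak_area_standard = 25000,
                           standard_conc = 10, dilution = 1, noise_sd = 0) {
  area <- conc * peak_area_standard / (standard_conc * dilution) *
    meas_noise(length(conc), noise_sd)
  data.frame(acid = names(conc), peak_area_sample = unname(area),
             peak_area_standard = peak_area_standard,
             standard_conc = standard_conc, dilution = dilution,
             stringsAsFactors = FALSE)
}

#' Forward-simulate hemocytometer field counts
#'
#' Given a true concentration (cells/ml) and the counting-chamber geometry,
#' the expected count per microscopic field is
#' `n = N * a * v / (A * D)`. Fields are Poisson draws around that
#' expectation; with `poisson = FALSE` every field equals the expectation
#' exactly (possibly fractional), making [enumerate_protozoa()] an exact
#' inverse.
#'
#' @param cells_ml true concentration, cells/ml.
#' @param geometry list with `slide_area`, `field_area`, `dilution`,
#'   `chamber_volume`, `n_fields` (see [protozoa_count()]).
#' @param poisson draw Poisson counting noise?
#' @return numeric vector of `n_fields` field counts.
#' @export
forward_protozoa_fields <- function(cells_ml, geometry, poisson = TRUE) {
  n_bar <- cells_ml * geometry$field_area * geometry$chamber_volume /
    (geometry$slide_area * geometry$dilution)
  if (poisson) stats::rpois(geometry$n_fields, n_bar)
  else rep(n_bar, geometry$n_fields)
}

# Allocate `n_asvs` ASVs across the archaeal taxonomy scheme and split each
# species' expected proportion among its ASVs with geometric weights.
build_asv_scheme <- function(asv_params) {
  fp <- asv_params$family_proportions
  dominant <- names(fp)[which.max(fp)]
  # within-family genus/species structure of a sheep rumen archaeome:
  # Methanobrevibacter (gottschalkii dominant) >> Methanosphaera,
  # Methanobacterium; Methanomassiliicoccaceae split over Group* lineages;
  # Methanosarcinaceae minor.
  species <- data.frame(
    order = c(rep("Methanobacteriales", 6),
              rep("Methanomassiliicoccales", 4),
              "Methanosarcinales"),
    family = c(rep("Methanobacteriaceae", 6),
               rep("Methanomassiliicoccaceae", 4),
               "Methanosarcinaceae"),
    genus = c("Methanobrevibacter", "Methanobrevibacter",
              "Methanobrevibacter", "Methanobrevibacter",
              "Methanosphaera", "Methanobacterium",
              "Group12", "Group9", "Group10", "Group3b",
              "Methanosarcina"),
    species = c("Methanobrevibacter gottschalkii clade",
                "Methanobrevibacter millerae",
                "Methanobrevibacter ruminantium clade",
                "Methanobrevibacter wolinii",
                "Methanosphaera ISO3-F5",
                "Methanobacterium sp.",
                "Group12 sp. ISO4-H5", "Group9 sp.", "Group10 sp.",
                "Group3b sp.", "Methanosarcina sp."),
    within_family = c(0.60, 0.12, 0.09, 0.035, 0.032, 0.021,
                      0.045, 0.0107, 0.009, 0.015,
                      0.0223) / c(rep(0.898, 6), rep(0.0797, 4), 0.0223),
    stringsAsFactors = FALSE
  )
  species$prop <- species$within_family * fp[species$family]
  species$prop <- species$prop / sum(species$prop)
  # largest-remainder allocation of ASVs to species, at least 1 each
  n <- asv_params$n_asvs
  if (n < nrow(species)) stop("need at least ", nrow(species), " ASVs")
  raw <- species$prop * (n - nrow(species))
  n_per <- 1 + floor(raw)
  rem <- n - sum(n_per)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1
  }
  tax <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    m <- n_per[i]
    w <- 0.5^(seq_len(m) - 1)
    data.frame(species[i, c("order", "family", "genus", "species")],
               prop = species$prop[i] * w / sum(w),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  tax <- data.frame(asv_id = sprintf("ASV%03d", seq_len(nrow(tax))), tax,
                    stringsAsFactors = FALSE)
  tax
}

#' Generate a synthetic archaeal ASV table
#'
#' Per-sample counts are Dirichlet-multinomial: sample proportions are drawn
#' from a Dirichlet with mean equal to the configured ASV proportions and
#' concentration `dispersion` (larger = closer to the mean; `Inf` collapses
#' to a plain multinomial), then reads are drawn multinomially at a depth
#' sampled from the configured library-size distribution. The taxonomy map
#' assigns each ASV order/family/genus/species labels honoring the
#' configured family proportions in expectation.
#'
#' @param asv_params list as [default_asv_params()].
#' @param sample_names character vector of sample (animal) ids.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list: `counts` (samples x ASVs integer matrix), `taxonomy`
#'   (data frame: asv_id, order, family, genus, species, prop).
#' @export
generate_asv_table <- function(asv_params = default_asv_params(),
                               sample_names, seed = NULL) {
  if (asv_params$dispersion <= 0) stop("dispersion must be positive")
  if (!is.null(asv_params$proportions)) {
    # explicit per-ASV expected proportions override the taxonomy scheme
    p <- asv_params$proportions
    if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
    ids <- if (is.null(names(p))) sprintf("ASV%03d", seq_along(p))
           else names(p)
    tax <- data.frame(asv_id = ids, order = "unclassified",
                      family = "unclassified", genus = "unclassified",
                      species = "unclassified", prop = unname(p),
                      stringsAsFactors = FALSE)
  } else {
    tax <- build_asv_scheme(asv_params)
  }
  p <- tax$prop
  gen <- function() {
    counts <- t(vapply(sample_names, function(s) {
      depth <- max(asv_params$depth_min,
                   round(stats::rnorm(1, asv_params$depth_mean,
                                      asv_params$depth_sd)))
      prop <- if (is.finite(asv_params$dispersion)) {
        alpha <- asv_params$dispersion * p
        theta <- ifelse(alpha > 0, stats::rgamma(length(alpha), alpha), 0)
        if (sum(theta) == 0) p else theta / sum(theta)
      } else p
      as.integer(stats::rmultinom(1, depth, prop))
    }, integer(nrow(tax))))
    dimnames(counts) <- list(sample_names, tax$asv_id)
    counts
  }
  counts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  list(counts = counts, taxonomy = tax)
}

#' Forward-simulate a complete sheep feeding trial
#'
#' The hub of the synthetic-data module. Per-animal latent traits are drawn
#' from Normal(group mean, SD) with `SD = SEM * sqrt(n_per_group)` (the only
#' defensible inversion of a reported SEM), then every observable record the
#' pipeline consumes is generated by the forward models: daily feed offered
#' and refused, fecal collections over the digestibility window, monthly
#' body weights, weekly permeation-tube weighings, breath and background
#' canisters for the measurement window (and the post-withdrawal window),
#' VFA peak areas, ammonia titres, protozoa field counts (supplementation
#' and withdrawal periods), and a Dirichlet-multinomial archaeal ASV table.
#' All randomness flows through one generator seeded from `config$seed`, so
#' equal configs give identical datasets.
#'
#' @param config a [trial_config()].
#' @return Object of class `trial_dataset`: list with `animals`, `latents`
#'   (per-animal ground-truth traits, for testing), `intake`, `feces`,
#'   `body_weights`, `tubes`, `canisters`, `canisters_wd`, `vfa_gc`,
#'   `ammonia`, `protozoa`, `asv_counts`, `taxonomy`, `config`.
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  withr::with_seed(config$seed, generate_trial_impl(config))
}

generate_trial_impl <- function(cfg) {
  n_g <- cfg$n_per_group
  groups <- rep(cfg$groups, each = n_g)
  n <- length(groups)
  animal <- sprintf("S%02d", seq_len(n))
  animals <- data.frame(animal = animal, group = groups,
                        tube_id = paste0("T", animal),
                        stringsAsFactors = FALSE)

  gm <- cfg$group_means
  latents <- sapply(seq_len(nrow(gm)), function(i) {
    mu <- unlist(gm[i, cfg$groups])[match(groups, cfg$groups)]
    pmax(stats::rnorm(n, mu, gm$sem[i] * sqrt(n_g)), 0)
  })
  colnames(latents) <- gm$attribute
  rownames(latents) <- animal
  lat <- as.data.frame(latents)

  days <- seq_len(cfg$duration_days)
  meas_days <- seq(cfg$duration_days - cfg$measurement_days + 1,
                   cfg$duration_days)

  # --- daily intake (offered / refused), oil schedule ---
  oil_on <- list(CTR = rep(FALSE, cfg$duration_days),
                 CON = oil_schedule(cfg$duration_days, "daily"),
                 INT = oil_schedule(cfg$duration_days, "biweekly",
                                    cfg$int_block_days))
  intake <- do.call(rbind, lapply(seq_len(n), function(i) {
    dmi_day <- lat$dmi[i] * lnorm_factor(cfg$duration_days,
                                         cfg$within_animal_cv)
    rf <- stats::runif(cfg$duration_days, cfg$refusal_range[1],
                       cfg$refusal_range[2])
    offered <- dmi_day / (1 - rf)
    on <- if (groups[i] %in% names(oil_on)) oil_on[[groups[i]]]
          else rep(FALSE, cfg$duration_days)
    data.frame(animal = animal[i], day = days, offered_g = offered,
               refused_g = offered - dmi_day, oil_day = on,
               oil_g = ifelse(on, cfg$oil_fraction_of_dmi * dmi_day, 0),
               stringsAsFactors = FALSE)
  }))

  # --- fecal collections over the digestibility window ---
  comp <- cfg$composition
  nutr <- c("dm", "om", "cp", "ndf", "adf", "ee")
  feces <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- intake[intake$animal == animal[i] & intake$day %in% meas_days, ]
    dmi_day <- w$offered_g - w$refused_g
    out <- data.frame(animal = animal[i], day = w$day,
                      stringsAsFactors = FALSE)
    for (nu in nutr) {
      intk <- if (nu == "dm") dmi_day else dmi_day * comp[[nu]] / 1000
      if (nu == "ee") intk <- intk + w$oil_g
      d <- lat[[paste0("dig_", nu)]][i] / 100
      out[[paste0(nu, "_g")]] <- intk * (1 - d) *
        meas_noise(nrow(w), cfg$fecal_noise_sd)
    }
    out
  }))

  # --- body weights at monthly intervals ---
  bw_days <- seq(0, cfg$duration_days, by = 30)
  body_weights <- do.call(rbind, lapply(seq_len(n), function(i) {
    bw <- lat$initial_bw[i] + lat$adg[i] * bw_days / 1000
    interior <- bw_days > 0 & bw_days < cfg$duration_days
    bw[interior] <- bw[interior] + stats::rnorm(sum(interior), 0, 0.15)
    data.frame(animal = animal[i], day = bw_days, bw_kg = bw,
               stringsAsFactors = FALSE)
  }))

  # --- permeation tubes: true rates and weekly weighings ---
  true_rate <- pmax(stats::rnorm(n, cfg$release_rate_mg_day,
                                 cfg$release_rate_sd), 0.5)
  week_days <- seq(0, 49, by = 7)
  tubes <- do.call(rbind, lapply(seq_len(n), function(i) {
    charge <- stats::rnorm(1, cfg$tube_charge_mg, cfg$tube_charge_sd)
    mass <- charge - true_rate[i] * week_days +
      stats::rnorm(length(week_days), 0, cfg$tube_weigh_sd)
    data.frame(tube_id = animals$tube_id[i], day = week_days,
               mass_mg = cummin(mass), stringsAsFactors = FALSE)
  }))

  # --- canister samples: measurement window and withdrawal window ---
  make_canisters <- function(emission_attr, day_offset = 0) {
    do.call(rbind, lapply(meas_days, function(d) {
      rows <- vector("list", n + 1)
      day_factor <- lnorm_factor(n, cfg$within_animal_cv)
      bg_pair <- NULL
      for (i in seq_len(n)) {
        pair <- forward_emission(lat[[emission_attr]][i] * day_factor[i],
                                 true_rate[i], cfg$background,
                                 cfg$gc_noise_sd, cfg$atm_pressure)
        if (i == 1) bg_pair <- pair$background
        b <- pair$breath
        rows[[i]] <- data.frame(animal = animal[i], day = d + day_offset,
                                kind = "breath", tau_e = b$tau_e,
                                tau_s = b$tau_s, tau_f = b$tau_f,
                                ch4_ppm = b$ch4_ppm, sf6_ppt = b$sf6_ppt,
                                stringsAsFactors = FALSE)
      }
      rows[[n + 1]] <- data.frame(animal = "BG", day = d + day_offset,
                                  kind = "background",
                                  tau_e = bg_pair$tau_e,
                                  tau_s = bg_pair$tau_s,
                                  tau_f = bg_pair$tau_f,
                                  ch4_ppm = bg_pair$ch4_ppm,
                                  sf6_ppt = bg_pair$sf6_ppt,
                                  stringsAsFactors = FALSE)
      do.call(rbind, rows)
    }))
  }
  canisters <- make_canisters("methane")
  canisters_wd <- make_canisters("methane_wd", day_offset = 40)

  # --- VFA peak areas and ammonia titres ---
  acids <- c("acetate", "propionate", "iso_butyrate", "butyrate",
             "iso_valerate", "valerate")
  vfa_gc <- do.call(rbind, lapply(seq_len(n), function(i) {
    conc <- stats::setNames(unlist(lat[i, acids]), acids)
    data.frame(animal = animal[i],
               forward_vfa_gc(conc, noise_sd = cfg$gc_noise_sd),
               stringsAsFactors = FALSE)
  }))
  ammonia <- data.frame(animal = animal, titre_ml = lat$ammonia,
                        stringsAsFactors = FALSE)

  # --- protozoa field counts, both enumeration periods ---
  geom <- cfg$protozoa_geometry
  poisson <- cfg$within_animal_cv > 0
  protozoa <- do.call(rbind, lapply(seq_len(n), function(i) {
    per_period <- function(period, ento_1e7, holo_1e6) {
      do.call(rbind, lapply(
        list(c("Entodiniomorph", ento_1e7 * 1e7),
             c("Holotrich", holo_1e6 * 1e6)),
        function(m) {
          data.frame(animal = animal[i], period = period,
                     field = seq_len(geom$n_fields), morphotype = m[1],
                     count = forward_protozoa_fields(as.numeric(m[2]),
                                                     geom, poisson),
                     stringsAsFactors = FALSE)
        }))
    }
    rbind(per_period("supplementation", lat$protozoa_ento[i],
                     lat$protozoa_holo[i]),
          per_period("withdrawal", lat$protozoa_ento_wd[i],
                     lat$protozoa_holo_wd[i]))
  }))

  # --- archaeal ASV table ---
  asv <- generate_asv_table(cfg$asv_params, animal)

  structure(
    list(animals = animals, latents = lat, intake = intake, feces = feces,
         body_weights = body_weights, tubes = tubes, canisters = canisters,
         canisters_wd = canisters_wd, vfa_gc = vfa_gc, ammonia = ammonia,
         protozoa = protozoa, asv_counts = asv$counts,
         taxonomy = asv$taxonomy, config = cfg),
    class = "trial_dataset"
  )
}
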