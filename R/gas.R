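#' Molecular weights used in the tracer flux calculation
#'
#' Standard 4-digit molecular masses of methane and sulfur hexafluoride
#' (g/mol). Exposed so that the emission equation is auditable.
#' @keywords internal
MW_CH4 <- 16.04
#' @rdname MW_CH4
#' @keywords internal
MW_SF6 <- 146.06

#' Construct a permeation-tube calibration record
#'
#' A permeation tube is a sealed intraruminal device releasing SF6 at an
#' approximately constant rate. It is calibrated gravimetrically: the tube is
#' weighed repeatedly (here weekly) and the release rate is the magnitude of
#' the least-squares slope of mass against time.
#'
#' @param tube_id character scalar identifying the tube.
#' @param days numeric vector of weighing days (strictly increasing).
#' @param mass_mg tube masses (mg) at those days.
#' @param charge_mg initial SF6 charge (mg), default 750.
#' @return An object of class `permeation_tube`.
#' @export
permeation_tube <- function(tube_id, days, mass_mg, charge_mg = 750) {
  stopifnot(length(days) == length(mass_mg))
  if (length(days) < 2) {
    stop("permeation tube '", tube_id, "': at least 2 weighings are required")
  }
  if (any(diff(days) <= 0)) {
    stop("permeation tube '", tube_id, "': weighing days must be strictly increasing")
  }
  if (any(mass_mg < 0) || charge_mg <= 0) {
    stop("permeation tube '", tube_id, "': masses must be non-negative and charge positive")
  }
  structure(
    list(tube_id = as.character(tube_id), days = as.numeric(days),
         mass_mg = as.numeric(mass_mg), charge_mg = charge_mg),
    class = "permeation_tube"
  )
}

#' Calibrate the SF6 release rate of a permeation tube
#'
#' Ordinary least-squares regression of tube mass (mg) on day; the release
#' rate is the magnitude of the fitted slope (mg/day). The coefficient of
#' determination is returned as a quality-control value, and a
#' non-decreasing mass trend (slope >= 0) raises a QC flag since a tube that
#' does not lose mass releases no tracer.
#'
#' @param tube a [permeation_tube()].
#' @return A list with `rate_mg_day`, `r_squared`, `qc_flags` (character
#'   vector, empty when clean) and `tube_id`.
#' @export
calibrate_release_rate <- function(tube) {
  stopifnot(inherits(tube, "permeation_tube"))
  x <- tube$days
  y <- tube$mass_mg
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fitted <- mean(y) + slope * (x - mean(x))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((y - fitted)^2) / ss_tot
  qc <- character()
  if (slope >= 0) qc <- c(qc, "non_decreasing_mass")
  list(tube_id = tube$tube_id,
       rate_mg_day = if (slope >= 0) 0 else abs(slope),
       r_squared = r2,
       qc_flags = qc)
}

#' Construct a canister sample record
#'
#' One breath or background collection: the vacuum of the evacuated canister
#' (`tau_e`, kPa), the post-sampling vacuum (`tau_s`), the vacuum after
#' dilution with high-purity N2 (`tau_f`), and the gas-chromatograph
#' concentrations presented to the detector (CH4 in ppm, SF6 in ppt).
#'
#' @param kind `"breath"` or `"background"`.
#' @param tau_e,tau_s,tau_f vacuum readings (kPa); a filled canister has
#'   `tau_e > tau_s >= tau_f >= 0`.
#' @param ch4_ppm,sf6_ppt measured concentrations (non-negative).
#' @param atm_pressure local atmospheric pressure in kPa (default 90,
#'   appropriate for a site at roughly 920 m elevation).
#' @param id optional sample identifier used in error messages.
#' @return An object of class `canister_sample`.
#' @export
canister_sample <- function(kind = c("breath", "background"),
                            tau_e, tau_s, tau_f,
                            ch4_ppm = NA_real_, sf6_ppt = NA_real_,
                            atm_pressure = 90, id = NULL) {
  kind <- match.arg(kind)
  if (tau_e < tau_s) {
    stop("canister ", if (is.null(id)) "" else paste0("'", id, "' "),
         "must satisfy tau_e >= tau_s (got tau_e = ", tau_e,
         ", tau_s = ", tau_s, ")")
  }
  if (tau_s < tau_f || tau_f < 0) {
    stop("canister ", if (is.null(id)) "" else paste0("'", id, "' "),
         "must satisfy tau_s >= tau_f >= 0")
  }
  if ((!is.na(ch4_ppm) && ch4_ppm < 0) || (!is.na(sf6_ppt) && sf6_ppt < 0)) {
    stop("concentrations must be non-negative")
  }
  structure(
    list(kind = kind, tau_e = tau_e, tau_s = tau_s, tau_f = tau_f,
         ch4_ppm = ch4_ppm, sf6_ppt = sf6_ppt,
         atm_pressure = atm_pressure, id = id),
    class = "canister_sample"
  )
}

#' Correct a measured concentration for canister pressures
#'
#' Converts the concentration presented to the gas chromatograph (G_A) into
#' the field concentration (G_S) using the canister vacuum readings:
#'
#' \deqn{G_S = \frac{P_{atm} - \tau_f}{\tau_e - \tau_s} \times G_A}
#'
#' with `P_atm` defaulting to 90 kPa. This is the site-adjusted form of the
#' standard canister-pressure correction; its numerator uses the
#' post-dilution span while the denominator uses the sampling span, exactly
#' as used in the field protocol this package implements. A conventional
#' dilution-only correction, `G_A * (P_atm - tau_f) / (P_atm - tau_s)`, is
#' available via `method = "conventional"` for comparison; the two are not
#' interchangeable and the printed-protocol form is the default everywhere.
#'
#' @param sample a [canister_sample()].
#' @param channel `"CH4"` (ppm) or `"SF6"` (ppt).
#' @param method `"as_printed"` (default) or `"conventional"`.
#' @return Corrected concentration (same units as the input channel).
#' @export
correct_concentration <- function(sample, channel = c("CH4", "SF6"),
                                  method = c("as_printed", "conventional")) {
  stopifnot(inherits(sample, "canister_sample"))
  channel <- match.arg(channel)
  method <- match.arg(method)
  ga <- switch(channel, CH4 = sample$ch4_ppm, SF6 = sample$sf6_ppt)
  if (is.na(ga)) stop("channel ", channel, " was not measured for this canister")
  if (sample$tau_e == sample$tau_s) {
    stop("canister ", if (is.null(sample$id)) "" else paste0("'", sample$id, "' "),
         "has tau_e == tau_s: pressure correction undefined")
  }
  factor <- switch(method,
    as_printed  = (sample$atm_pressure - sample$tau_f) / (sample$tau_e - sample$tau_s),
    conventional = (sample$atm_pressure - sample$tau_f) / (sample$atm_pressure - sample$tau_s)
  )
  factor * ga
}

#' N2 dilution factor of a canister
#'
#' The fold-dilution applied when the canister is topped up with high-purity
#' nitrogen before GC analysis, computed from the pressure spans:
#' `(P_atm - tau_f) / (P_atm - tau_s)`. The field protocol targets 2.15- to
#' 3.0-fold dilution; values outside that window are flagged (QC warning,
#' not an error).
#'
#' @inheritParams correct_concentration
#' @param range acceptable dilution window, default `c(2.15, 3.0)`.
#' @return Numeric dilution factor with attribute `qc_flags`.
#' @export
dilution_factor <- function(sample, range = c(2.15, 3.0)) {
  stopifnot(inherits(sample, "canister_sample"))
  if (sample$tau_s >= sample$atm_pressure) {
    stop("canister ", if (is.null(sample$id)) "" else paste0("'", sample$id, "' "),
         ": post-sampling vacuum at or above atmospheric pressure")
  }
  f <- (sample$atm_pressure - sample$tau_f) / (sample$atm_pressure - sample$tau_s)
  qc <- character()
  if (f < range[1] || f > range[2]) qc <- "dilution_out_of_range"
  structure(f, qc_flags = qc)
}

#' Daily enteric methane emission from the SF6 tracer ratio
#'
#' The tracer-ratio equation: with a known SF6 release rate from the
#' intraruminal permeation tube, the methane flux follows from the
#' background-corrected concentration ratio in breath samples,
#'
#' \deqn{R_{CH4} = R_{SF6} \cdot
#'   \frac{[CH4]_M - [CH4]_{BG}}{[SF6]_M - [SF6]_{BG}} \cdot
#'   \frac{MW_{CH4}}{MW_{SF6}} \cdot 1000}
#'
#' with `R_SF6` in mg/day, CH4 concentrations in ppm, SF6 in ppt, and the
#' result in g/day (the 1000 carries the mg-to-g and ppm/ppt unit bookkeeping;
#' the molar-flux derivation gives the identical constant).
#'
#' A negative CH4 delta (background above breath) is truncated to 0 g/day
#' with QC flag `"negative_delta_ch4"` rather than propagated: failed
#' canisters occur routinely in the field. A non-positive SF6 delta means the
#' tracer was not detected above background and is a hard error; use
#' [emission_records()] for a vectorized, flag-instead-of-fail version.
#'
#' @param r_sf6 SF6 release rate, mg/day (> 0).
#' @param ch4_m,ch4_bg corrected breath and background CH4 (ppm).
#' @param sf6_m,sf6_bg corrected breath and background SF6 (ppt).
#' @param mw_ch4,mw_sf6 molecular masses (g/mol).
#' @return Emission in g/day, with attribute `qc_flags`.
#' @export
methane_emission <- function(r_sf6, ch4_m, ch4_bg, sf6_m, sf6_bg,
                             mw_ch4 = MW_CH4, mw_sf6 = MW_SF6) {
  if (any(r_sf6 <= 0)) stop("SF6 release rate must be positive")
  d_ch4 <- ch4_m - ch4_bg
  d_sf6 <- sf6_m - sf6_bg
  if (any(d_sf6 <= 0)) {
    stop("tracer failure: breath SF6 does not exceed background (delta = ",
         paste(signif(d_sf6[d_sf6 <= 0], 4), collapse = ", "), " ppt)")
  }
  qc <- character()
  if (any(d_ch4 < 0)) qc <- "negative_delta_ch4"
  d_ch4 <- pmax(d_ch4, 0)
  structure(r_sf6 * (d_ch4 / d_sf6) * (mw_ch4 / mw_sf6) * 1000, qc_flags = qc)
}

#' Methane yield per unit of dry matter intake
#'
#' Daily emission (g/day) divided by dry matter intake expressed in kg/day.
#'
#' @param emission_g_day methane emission, g/day.
#' @param dmi_g_day dry matter intake, g/day (> 0).
#' @return Methane yield, g CH4 per kg DMI.
#' @export
methane_yield <- function(emission_g_day, dmi_g_day) {
  if (any(dmi_g_day <= 0)) stop("DMI must be positive")
  emission_g_day / (dmi_g_day / 1000)
}

#' Build per-animal-day emission records from canister tables
#'
#' Vectorized pipeline step: applies the canister pressure correction to each
#' breath sample and its same-day background, then the tracer-ratio emission
#' equation. Rows where the tracer fails (SF6 delta <= 0) or the CH4 delta is
#' negative are QC-flagged instead of raising, so a whole trial can be
#' processed at once.
#'
#' @param canisters data frame with columns `animal`, `day`, `kind`
#'   (`"breath"`/`"background"`), `tau_e`, `tau_s`, `tau_f`, `ch4_ppm`,
#'   `sf6_ppt`. Exactly one background row per day is expected.
#' @param release_rates named numeric vector of per-animal SF6 release rates
#'   (mg/day), or a single value recycled to all animals.
#' @param atm_pressure atmospheric pressure, kPa.
#' @param method pressure-correction form, see [correct_concentration()].
#' @return data frame: `animal`, `day`, `r_sf6`, `ch4_m`, `ch4_bg`, `sf6_m`,
#'   `sf6_bg`, `delta_ch4`, `delta_sf6`, `r_ch4`, `qc_flags`.
#' @export
emission_records <- function(canisters, release_rates, atm_pressure = 90,
                             method = "as_printed") {
  need <- c("animal", "day", "kind", "tau_e", "tau_s", "tau_f", "ch4_ppm", "sf6_ppt")
  if (!all(need %in% names(canisters))) {
    stop("canister table must have columns: ", paste(need, collapse = ", "))
  }
  corr <- function(ga, tau_e, tau_s, tau_f) {
    if (method == "conventional") {
      (atm_pressure - tau_f) / (atm_pressure - tau_s) * ga
    } else {
      (atm_pressure - tau_f) / (tau_e - tau_s) * ga
    }
  }
  cc <- canisters
  cc$ch4_c <- corr(cc$ch4_ppm, cc$tau_e, cc$tau_s, cc$tau_f)
  cc$sf6_c <- corr(cc$sf6_ppt, cc$tau_e, cc$tau_s, cc$tau_f)
  bg <- cc[cc$kind == "background", c("day", "ch4_c", "sf6_c")]
  if (anyDuplicated(bg$day)) stop("more than one background canister on a day")
  br <- cc[cc$kind == "breath", , drop = FALSE]
  i <- match(br$day, bg$day)
  if (anyNA(i)) stop("missing background canister for day(s): ",
                     paste(unique(br$day[is.na(i)]), collapse = ", "))
  if (length(release_rates) == 1 && is.null(names(release_rates))) {
    r_sf6 <- rep(release_rates, nrow(br))
  } else {
    r_sf6 <- unname(release_rates[as.character(br$animal)])
    if (anyNA(r_sf6)) stop("missing release rate for some animals")
  }
  d_ch4 <- br$ch4_c - bg$ch4_c[i]
  d_sf6 <- br$sf6_c - bg$sf6_c[i]
  qc <- character(nrow(br))
  qc[d_ch4 < 0] <- "negative_delta_ch4"
  qc[d_sf6 <= 0] <- "tracer_failure"
  r_ch4 <- ifelse(d_sf6 > 0,
                  r_sf6 * pmax(d_ch4, 0) / d_sf6 * (MW_CH4 / MW_SF6) * 1000,
                  NA_real_)
  data.frame(animal = br$animal, day = br$day, r_sf6 = r_sf6,
             ch4_m = br$ch4_c, ch4_bg = bg$ch4_c[i],
             sf6_m = br$sf6_c, sf6_bg = bg$sf6_c[i],
             delta_ch4 = d_ch4, delta_sf6 = d_sf6,
             r_ch4 = r_ch4, qc_flags = qc,
             stringsAsFactors = FALSE)
}

#' Summarize emission records to animal and group means
#'
#' Two-stage averaging matching how per-animal SEMs are reported in feeding
#' trials: first the mean over an animal's valid measurement days, then the
#' group mean of animal means with its standard error over animals.
#' QC-flagged days are excluded and reported; an animal with no valid day is
#' dropped with a logged reason.
#'
#' @param records output of [emission_records()].
#' @param groups named character vector mapping animal id to group label.
#' @return list with `per_animal` (animal, group, n_days, mean_g_day),
#'   `per_group` (group, n, mean_g_day, sem), `excluded` (flagged rows) and
#'   `dropped_animals`.
#' @export
summarize_emissions <- function(records, groups) {
  valid <- records$qc_flags == "" & !is.na(records$r_ch4)
  excluded <- records[!valid, , drop = FALSE]
  ok <- records[valid, , drop = FALSE]
  all_animals <- unique(records$animal)
  per_animal <- do.call(rbind, lapply(split(ok, ok$animal), function(d) {
    data.frame(animal = d$animal[1], n_days = nrow(d),
               mean_g_day = mean(d$r_ch4), stringsAsFactors = FALSE)
  }))
  rownames(per_animal) <- NULL
  dropped <- setdiff(all_animals, per_animal$animal)
  per_animal$group <- unname(groups[as.character(per_animal$animal)])
  if (anyNA(per_animal$group)) stop("missing group label for some animals")
  per_group <- do.call(rbind, lapply(split(per_animal, per_animal$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_g_day = mean(d$mean_g_day),
               sem = stats::sd(d$mean_g_day) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_animal = per_animal[, c("animal", "group", "n_days", "mean_g_day")],
       per_group = per_group,
       excluded = excluded,
       dropped_animals = if (length(dropped)) {
         paste0(dropped, ": no valid measurement day")
       } else character())
}
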