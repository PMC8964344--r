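test_that("release-rate calibration recovers the slope of the weighing series", {
  # exact line: slope -3.47 mg/day
  tube <- permeation_tube("T1", days = c(0, 7, 14),
                          mass_mg = c(750.00, 725.71, 701.42))
  cal <- calibrate_release_rate(tube)
  expect_equal(cal$rate_mg_day, 3.47)
  expect_equal(cal$r_squared, 1)
  expect_length(cal$qc_flags, 0)

  # constant mass: zero rate, QC flagged
  flat <- calibrate_release_rate(
    permeation_tube("T2", days = c(0, 7, 14), mass_mg = rep(750, 3)))
  expect_equal(flat$rate_mg_day, 0)
  expect_true("non_decreasing_mass" %in% flat$qc_flags)

  # jittered weekly weighings vs an independent closed-form OLS slope
  days <- seq(0, 49, by = 7)
  set.seed(11)
  mass <- 750 - 3.47 * days + rnorm(8, 0, 0.5)
  cal <- calibrate_release_rate(permeation_tube("T3", days, mass))
  ols <- -sum((days - mean(days)) * (mass - mean(mass))) /
    sum((days - mean(days))^2)
  expect_equal(cal$rate_mg_day, ols, tolerance = 1e-12)
  expect_lt(abs(cal$rate_mg_day - 3.47), 0.1)
})

test_that("permeation tube construction enforces its invariants", {
  expect_error(permeation_tube("T1", days = 0, mass_mg = 750),
               "at least 2 weighings")
  expect_error(permeation_tube("T1", days = c(0, 0), mass_mg = c(750, 740)),
               "strictly increasing")
})

test_that("concentration correction applies the pressure-span factor", {
  s <- canister_sample("breath", tau_e = 95, tau_s = 65, tau_f = 40,
                       ch4_ppm = 100, atm_pressure = 90)
  expect_equal(correct_concentration(s, "CH4"), (90 - 40) / (95 - 65) * 100)

  # linear through the origin
  s0 <- canister_sample("breath", 95, 65, 40, ch4_ppm = 0)
  expect_equal(correct_concentration(s0, "CH4"), 0)

  # identity-factor case: numerator span equals denominator span
  si <- canister_sample("breath", tau_e = 96, tau_s = 66, tau_f = 60,
                        ch4_ppm = 57.3, atm_pressure = 90)
  expect_equal(correct_concentration(si, "CH4"), 57.3)

  # linear in G_A at fixed pressures (property over random pressures)
  set.seed(4)
  for (i in 1:20) {
    tau_s <- runif(1, 40, 70)
    s1 <- canister_sample("breath", tau_e = tau_s + runif(1, 10, 40),
                          tau_s = tau_s, tau_f = runif(1, 0, tau_s),
                          ch4_ppm = 1, atm_pressure = 90)
    ga <- runif(1, 1, 500)
    s2 <- s1; s2$ch4_ppm <- ga
    expect_equal(correct_concentration(s2, "CH4"),
                 ga * correct_concentration(s1, "CH4"), tolerance = 1e-12)
  }

  # degenerate pressure span is a division-by-zero error naming the canister
  sz <- canister_sample("breath", tau_e = 65, tau_s = 65, tau_f = 40,
                        ch4_ppm = 10, id = "C042")
  expect_error(correct_concentration(sz, "CH4"), "C042")
})

test_that("dilution factor reports the N2 top-up and flags the window", {
  s <- canister_sample("breath", 96, 65, 25, ch4_ppm = 1)
  d <- dilution_factor(s)
  expect_equal(as.numeric(d), 65 / 25)
  expect_length(attr(d, "qc_flags"), 0)

  # tau_f == tau_s: no dilution, out of the 2.15-3.0 window
  s1 <- canister_sample("breath", 96, 65, 65, ch4_ppm = 1)
  d1 <- dilution_factor(s1)
  expect_equal(as.numeric(d1), 1)
  expect_equal(attr(d1, "qc_flags"), "dilution_out_of_range")

  # boundary 3.0 accepted
  s2 <- canister_sample("breath", 96, 60, 0, ch4_ppm = 1)
  d2 <- dilution_factor(s2)
  expect_equal(as.numeric(d2), 3.0)
  expect_length(attr(d2, "qc_flags"), 0)

  s3 <- canister_sample("breath", 96, 92, 20, ch4_ppm = 1)
  expect_error(dilution_factor(s3), "atmospheric")
})

test_that("tracer-ratio emission equation matches the molar-flux oracle", {
  # independent oracle: mol SF6/day scaled by the ppm/ppt mixing ratio
  molar <- function(r_sf6, d_ch4, d_sf6) {
    n_sf6 <- r_sf6 / 1000 / 146.06            # mol/day
    n_ch4 <- n_sf6 * (d_ch4 * 1e-6) / (d_sf6 * 1e-12)
    n_ch4 * 16.04                             # g/day
  }
  e <- methane_emission(3.47, ch4_m = 54.5, ch4_bg = 1.9,
                        sf6_m = 1030, sf6_bg = 30)
  expect_equal(as.numeric(e), molar(3.47, 52.6, 1000), tolerance = 1e-12)
  expect_equal(as.numeric(e), 20.04, tolerance = 1e-3)

  # zero numerator
  expect_equal(as.numeric(methane_emission(3.47, 2, 2, 1030, 30)), 0)

  # ratio invariance: doubling both deltas changes nothing
  e2 <- methane_emission(3.47, 2 * 52.6 + 1.9, 1.9, 2 * 1000 + 30, 30)
  expect_equal(as.numeric(e2), as.numeric(e), tolerance = 1e-12)

  # linear in the release rate
  e3 <- methane_emission(2 * 3.47, 54.5, 1.9, 1030, 30)
  expect_equal(as.numeric(e3), 2 * as.numeric(e), tolerance = 1e-12)

  # background above breath: truncated to zero and QC flagged
  eneg <- methane_emission(3.47, 1.0, 1.9, 1030, 30)
  expect_equal(as.numeric(eneg), 0)
  expect_equal(attr(eneg, "qc_flags"), "negative_delta_ch4")

  # tracer failure is a hard error in the scalar interface
  expect_error(methane_emission(3.47, 54.5, 1.9, 30, 30), "tracer failure")
})

test_that("methane yield is emission per kg of intake", {
  expect_equal(methane_yield(23.6, 884), 26.7, tolerance = 1e-2)
  expect_equal(methane_yield(0, 884), 0)
  expect_equal(methane_yield(17.5, 900), 19.4, tolerance = 1e-2)
  expect_error(methane_yield(10, 0), "positive")
  # consistency: yield * dmi/1000 recovers the emission
  set.seed(5)
  e <- runif(20, 1, 40); d <- runif(20, 300, 1500)
  expect_equal(methane_yield(e, d) * d / 1000, e, tolerance = 1e-12)
})

test_that("emission summaries use two-stage averaging and report exclusions", {
  groups <- c(A1 = "G1", A2 = "G1", A3 = "G2", A4 = "G2")
  rec <- expand.grid(animal = names(groups), day = 1:3,
                     stringsAsFactors = FALSE)
  rec$r_ch4 <- 23.6
  rec$qc_flags <- ""
  s <- summarize_emissions(rec, groups)
  expect_equal(s$per_group$mean_g_day, c(23.6, 23.6))
  expect_equal(s$per_group$sem, c(0, 0))

  # one animal all tracer failures: dropped with a logged reason
  rec2 <- rec
  rec2$qc_flags[rec2$animal == "A3"] <- "tracer_failure"
  rec2$r_ch4[rec2$animal == "A3"] <- NA
  s2 <- summarize_emissions(rec2, groups)
  expect_equal(s2$per_group$n[s2$per_group$group == "G2"], 1)
  expect_match(s2$dropped_animals, "A3")
  expect_equal(nrow(s2$excluded), 3)
})
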