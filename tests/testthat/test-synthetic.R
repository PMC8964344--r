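test_that("the generator is deterministic and honors degenerate noise", {
  cfg <- light_config(seed = 42)
  expect_identical(generate_trial(cfg), generate_trial(cfg))

  # all SEMs zero: every latent trait equals its group mean exactly
  gm <- default_group_means()
  gm$sem <- 0
  td <- generate_trial(light_config(seed = 3, group_means = gm))
  for (g in c("CTR", "CON", "INT")) {
    idx <- td$animals$group == g
    for (i in seq_len(nrow(gm))) {
      expect_equal(unname(td$latents[idx, gm$attribute[i]]),
                   rep(gm[[g]][i], sum(idx)))
    }
  }
})

test_that("latent group means sit near the configured table at seed 1", {
  td <- generate_trial(trial_config(seed = 1))
  ctr <- td$animals$animal[td$animals$group == "CTR"]
  # the mean of 6 latents drawn with SD = SEM*sqrt(6) has SE = SEM
  expect_lt(abs(mean(td$latents[ctr, "dmi"]) - 884), 2 * 3.42)
})

test_that("latent moments are recovered over many seeds", {
  n_seeds <- 100
  gm <- default_group_means()
  sums <- matrix(0, nrow(gm), 3,
                 dimnames = list(gm$attribute, c("CTR", "CON", "INT")))
  for (s in seq_len(n_seeds)) {
    td <- generate_trial(light_config(seed = s))
    for (g in colnames(sums)) {
      idx <- td$animals$group == g
      sums[, g] <- sums[, g] + colMeans(td$latents[idx, gm$attribute])
    }
  }
  means <- sums / n_seeds
  # 69 simultaneous unbiased checks (23 attributes x 3 groups): a per-check
  # 3-sigma band is exceeded by the family maximum about one time in five
  # under the null, so the per-check bound uses the family-wise 0.1% normal
  # quantile; an aggregate bias check caps the mean |z| as well.
  z_crit <- qnorm(1 - 0.001 / (2 * 69))
  zs <- NULL
  for (g in colnames(means)) {
    z <- abs(means[, g] - gm[[g]]) / (gm$sem / sqrt(n_seeds))
    zs <- c(zs, z)
    expect_true(all(z <= z_crit), info = paste("group", g))
  }
  expect_lt(mean(zs), 1.5)
})

test_that("forward emission inverts exactly at zero noise", {
  set.seed(71)
  for (i in 1:25) {
    true <- runif(1, 0.5, 40)
    rate <- runif(1, 2, 5)
    pair <- forward_emission(true, rate, noise_sd = 0)
    expect_equal(recover_emission(pair, rate), true, tolerance = 1e-9)
  }
  # the worked round trip
  pair <- forward_emission(20, 3.47, noise_sd = 0, seed = 1)
  expect_equal(recover_emission(pair, 3.47), 20, tolerance = 1e-9)

  # zero flux: corrected breath CH4 equals corrected background CH4
  z <- forward_emission(0, 3.47, noise_sd = 0, seed = 2)
  expect_equal(correct_concentration(z$breath, "CH4"),
               correct_concentration(z$background, "CH4"),
               tolerance = 1e-12)
  expect_error(forward_emission(-1, 3.47), "non-negative")
  expect_error(forward_emission(10, 0), "positive")
})

test_that("noisy forward/inverse emission pair is unbiased (Monte Carlo)", {
  true <- 23.6
  set.seed(73)
  means <- replicate(200, {
    mean(replicate(10, {
      pair <- forward_emission(true, 3.47, noise_sd = 0.05)
      recover_emission(pair, 3.47)
    }))
  })
  expect_lt(abs(mean(means) - true) / true, 0.01)
})

test_that("synthetic ASV tables honor the configured composition", {
  # pooled dominant-family relative abundance across 50 seeds
  pooled <- vapply(1:50, function(s) {
    a <- generate_asv_table(
      within(default_asv_params(), {
        depth_mean <- 5000; depth_sd <- 500; depth_min <- 2000
      }),
      paste0("S", 1:6), seed = s)
    fam <- aggregate_rank(a$counts, a$taxonomy, "family", relative = FALSE)
    sum(fam[, "Methanobacteriaceae"]) / sum(fam)
  }, numeric(1))
  expect_gt(mean(pooled), 0.85)
  expect_lt(mean(pooled), 0.93)

  # dispersion -> Inf: per-sample proportions collapse to the means
  pars <- default_asv_params()
  pars$dispersion <- Inf
  a <- generate_asv_table(pars, paste0("S", 1:6), seed = 4)
  fam <- aggregate_rank(a$counts, a$taxonomy, "family")
  expect_true(all(abs(fam[, "Methanobacteriaceae"] - 0.898) < 0.01))

  # an ASV carrying proportion 1 receives every count
  pars1 <- default_asv_params()
  pars1$proportions <- c(A = 1, B = 0, C = 0)
  pars1$depth_mean <- 1000; pars1$depth_sd <- 0; pars1$depth_min <- 1000
  a1 <- generate_asv_table(pars1, paste0("S", 1:3), seed = 5)
  expect_true(all(a1$counts[, "A"] == rowSums(a1$counts)))

  pars2 <- default_asv_params()
  pars2$dispersion <- 0
  expect_error(generate_asv_table(pars2, "S1", seed = 1), "dispersion")
  expect_error(trial_config(asv_params = pars2), "dispersion")
})

test_that("zero-noise pipeline round trips are exact", {
  td <- generate_trial(noise_free_config(seed = 11))

  # emission: recovered per-animal means equal the latent truth
  q <- quantify_trial(td)
  pa <- q$emissions$per_animal
  expect_equal(pa$mean_g_day, unname(td$latents[pa$animal, "methane"]),
               tolerance = 1e-6)

  # digestibility: window totals recover the latent coefficient exactly
  ns <- nutrition_summary(td)
  expect_equal(ns$per_animal$dig_dm,
               unname(td$latents[ns$per_animal$animal, "dig_dm"]),
               tolerance = 1e-9)

  # VFA: GC inversion recovers latent concentrations
  f <- fermentation_summary(td)
  expect_equal(f$acetate, unname(td$latents[f$animal, "acetate"]),
               tolerance = 1e-9)

  # protozoa: noise-free fields make enumeration exact
  p <- protozoa_summary(td)
  p <- p[p$period == "supplementation", ]
  expect_equal(p$ento_1e7, unname(td$latents[p$animal, "protozoa_ento"]),
               tolerance = 1e-9)
})

test_that("trial datasets survive a TSV write/read round trip", {
  td <- generate_trial(light_config(seed = 8))
  dir <- withr::local_tempdir()
  write_trial_dataset(td, dir)
  expect_true(file.exists(file.path(dir, "canisters.tsv")))
  back <- read_trial_dataset(dir)
  expect_equal(back$animals, td$animals)
  expect_equal(back$canisters$ch4_ppm, td$canisters$ch4_ppm,
               tolerance = 1e-10)
  expect_equal(back$asv_counts[rownames(td$asv_counts),
                               colnames(td$asv_counts)[
                                 colSums(td$asv_counts) > 0]],
               td$asv_counts[, colSums(td$asv_counts) > 0])
  skip_if_not_installed("Matrix")
  mtx <- file.path(dir, "asv.mtx")
  export_asv_mtx(td$asv_counts, mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  expect_equal(unname(m), unname(td$asv_counts))
})

test_that("trial invariants hold on a default dataset", {
  td <- generate_trial(trial_config(seed = 6))
  expect_true(all(td$intake$refused_g <= td$intake$offered_g))
  expect_true(all(td$intake$offered_g >= 0))
  # tube weights non-increasing within each tube
  for (d in split(td$tubes, td$tubes$tube_id)) {
    expect_true(all(diff(d$mass_mg) <= 0))
  }
  expect_true(all(table(td$animals$animal) == 1))
  expect_true(all(td$protozoa$count >= 0))
  # one background canister per measurement day
  bg <- td$canisters[td$canisters$kind == "background", ]
  expect_equal(nrow(bg), td$config$measurement_days)
})
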