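rand_table <- function(n = 8, m = 12, seed = 101, lambda = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n * m, lambda), n, m,
                   dimnames = list(paste0("S", seq_len(n)),
                                   paste0("ASV", seq_len(m))))
  counts
}

test_that("pruning matches a brute-force filter", {
  x <- rand_table(lambda = 1.5)
  for (mt in c(0, 2, 5)) {
    for (mp in c(0, 0.25, 0.6)) {
      got <- prune_low_abundance(x, min_total = mt, min_prevalence = mp)
      keep <- vapply(seq_len(ncol(x)), function(j) {
        sum(x[, j]) >= mt && mean(x[, j] > 0) >= mp
      }, logical(1))
      expect_identical(got, x[, keep, drop = FALSE])
    }
  }
  expect_identical(prune_low_abundance(x, 0, 0), x)
  # a singleton ASV is dropped at min_total = 2
  y <- x; y[, 1] <- 0; y[1, 1] <- 1
  expect_false("ASV1" %in% colnames(prune_low_abundance(y, min_total = 2)))
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  x <- rand_table(lambda = 50)
  r <- rarefy_counts(x, depth = 300, seed = 9)
  expect_true(all(rowSums(r) == 300))
  expect_true(all(r <= x))
  expect_identical(rarefy_counts(x, depth = 300, seed = 9), r)
  # depth equal to the sample total leaves the sample unchanged
  xr <- x[1, , drop = FALSE]
  expect_equal(rarefy_counts(xr, depth = sum(xr), seed = 1)[1, ], x[1, ])
  # shallow samples are dropped and logged
  y <- x; y[2, ] <- 0; y[2, 1] <- 10
  r2 <- rarefy_counts(y, depth = 300, seed = 9)
  expect_equal(attr(r2, "dropped_samples"), "S2")
  expect_equal(nrow(r2), nrow(x) - 1)
})

test_that("rarefaction marginals match the hypergeometric expectation", {
  x <- rand_table(n = 1, m = 6, seed = 7, lambda = 80)
  depth <- 200
  total <- sum(x)
  n_seeds <- 200
  draws <- vapply(seq_len(n_seeds), function(s) {
    rarefy_counts(x, depth = depth, seed = s)[1, ]
  }, numeric(ncol(x)))
  means <- rowMeans(draws)
  expected <- depth * x[1, ] / total
  # hypergeometric SD of each marginal, shrunk by the number of draws
  sd_h <- sqrt(depth * (x[1, ] / total) * (1 - x[1, ] / total) *
                 (total - depth) / (total - 1))
  expect_true(all(abs(means - expected) <= 3 * sd_h / sqrt(n_seeds)))
})

test_that("per-10,000 scaling normalizes rows", {
  x <- rand_table()
  s <- scale_per_10000(x)
  expect_equal(unname(rowSums(s)), rep(10000, nrow(x)))
  expect_equal(unname(scale_per_10000(matrix(c(3, 3), 1, 2,
    dimnames = list("a", c("x", "y"))))[1, ]), c(5000, 5000))
  y <- x; y[1, ] <- 0
  expect_error(scale_per_10000(y), "empty")
})

test_that("rank aggregation sums members and respects the hierarchy", {
  x <- rand_table(m = 6)
  tax <- data.frame(asv_id = colnames(x),
                    order = c("O1", "O1", "O1", "O1", "O2", "O2"),
                    family = c("F1", "F1", "F2", "F2", "F3", "F3"),
                    genus = paste0("G", 1:6),
                    species = paste0("sp", 1:6))
  fam <- aggregate_rank(x, tax, "family")
  expect_equal(unname(rowSums(fam)), rep(1, nrow(x)))
  # order-level sums equal family-level sums grouped upward
  ord <- aggregate_rank(x, tax, "order")
  expect_equal(ord[, "O1"], fam[, "F1"] + fam[, "F2"], tolerance = 1e-12)
  expect_equal(ord[, "O2"], fam[, "F3"], tolerance = 1e-12)
  # one family covering every ASV has relative abundance 1
  tax1 <- tax; tax1$family <- "F1"
  expect_equal(unname(aggregate_rank(x, tax1, "family")[, "F1"]),
               rep(1, nrow(x)))
})

test_that("Shannon index equals direct summation", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  set.seed(13)
  for (i in 1:25) {
    v <- c(rpois(15, 8), 0, 0)
    p <- v[v > 0] / sum(v)
    expect_equal(shannon_index(v), -sum(p * log(p)), tolerance = 1e-12)
  }
})

test_that("core filter applies prevalence and detection thresholds", {
  rel <- matrix(0.02, 6, 1, dimnames = list(paste0("S", 1:6), "T1"))
  expect_equal(core_archaeome(rel)$all, "T1")
  rel2 <- rel; rel2[3:6, 1] <- 0.001
  expect_equal(length(core_archaeome(rel2)$all), 0)
  # monotone non-increasing in both thresholds
  set.seed(17)
  rel3 <- matrix(runif(60, 0, 0.05), 6, 10,
                 dimnames = list(paste0("S", 1:6), paste0("T", 1:10)))
  prev_grid <- c(0.2, 0.5, 0.8)
  det_grid <- c(0.005, 0.01, 0.02)
  for (d in det_grid) {
    sets <- lapply(prev_grid, function(pv) {
      core_archaeome(rel3, prevalence = pv, detection = d)$all
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
  for (pv in prev_grid) {
    sets <- lapply(det_grid, function(d) {
      core_archaeome(rel3, prevalence = pv, detection = d)$all
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("PERMANOVA: extreme separation, relabeling invariance", {
  set.seed(19)
  # three fully separated clusters: virtually no permutation preserves the
  # partition, so p attains its minimum 1/(n_perm + 1)
  x <- rbind(matrix(rpois(5 * 5, 40), 5, 5),
             matrix(rpois(5 * 5, 40), 5, 5) + 500,
             matrix(rpois(5 * 5, 40), 5, 5) + 2000)
  rownames(x) <- paste0("S", 1:15)
  colnames(x) <- paste0("T", 1:5)
  g <- rep(c("A", "B", "C"), each = 5)
  pm <- permanova(bray_curtis(x), g, n_perm = 999, seed = 3)
  expect_equal(pm$p, 1 / 1000)

  # permuting samples together with labels leaves F unchanged
  ord <- sample(15)
  pm2 <- permanova(bray_curtis(x[ord, ]), g[ord], n_perm = 99, seed = 3)
  expect_equal(pm2$F, pm$F, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum: exact p matches full enumeration at 6 vs 6", {
  a <- c(3.1, 4.2, 1.7, 5.5, 2.9, 4.8)
  b <- c(8.3, 7.1, 9.9, 6.6, 10.2, 7.7)
  got <- wilcoxon_rank_sum(a, b)
  expect_equal(got$method, "exact")

  # enumeration oracle: all C(12,6) assignments of the pooled ranks
  r <- rank(c(a, b))
  u_obs <- sum(r[1:6]) - 6 * 7 / 2
  combos <- utils::combn(12, 6)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - 21)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  expect_equal(got$p, min(1, 2 * min(p_low, p_high)), tolerance = 1e-12)
  # disjoint ranges attain the minimum exact two-sided p
  expect_equal(got$p, 2 / choose(12, 6))

  # label swap leaves p unchanged
  expect_equal(wilcoxon_rank_sum(b, a)$p, got$p)
  # identical samples (all ties): p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 1, 2, 2), c(1, 1, 2, 2))$p, 1)
})

test_that("archaeome pipeline runs end to end on a synthetic trial", {
  td <- generate_trial(light_config(seed = 5))
  a <- archaeome_summary(td, depth = 2000, rank = "family", seed = 2,
                         n_perm = 199)
  expect_true(all(rowSums(a$rarefied) == 2000))
  expect_true(all(a$shannon$shannon > 0))
  expect_true("Methanobacteriaceae" %in% colnames(a$rel_abund))
  expect_true(all(vapply(a$core, function(s)
    "Methanobacteriaceae" %in% s, logical(1))))
  expect_true(a$permanova$p > 0 && a$permanova$p <= 1)
})
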