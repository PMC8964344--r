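#' Validate an ASV count matrix
#'
#' The archaeome stage works on a plain samples x ASVs matrix of
#' non-negative integer counts with sample names as row names and ASV ids as
#' column names.
#' @param counts matrix-like, samples x ASVs.
#' @return the validated integer-mode matrix.
#' @keywords internal
as_asv_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("ASV table needs sample row names and ASV column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("ASV counts must be non-negative integers")
  }
  counts
}

#' Prune low-abundance ASVs
#'
#' Drops ASVs whose total count across samples falls below `min_total` or
#' whose prevalence (fraction of samples where the ASV is observed) falls
#' below `min_prevalence`. The sample set is unchanged.
#'
#' @param counts samples x ASVs count matrix.
#' @param min_total minimum total count across samples (default 2: removes
#'   singletons).
#' @param min_prevalence minimum fraction of samples with a nonzero count
#'   (default 0: no prevalence filter).
#' @return The filtered count matrix.
#' @export
prune_low_abundance <- function(counts, min_total = 2, min_prevalence = 0) {
  counts <- as_asv_matrix(counts)
  if (min_total < 0 || min_prevalence < 0) stop("thresholds must be >= 0")
  keep <- colSums(counts) >= min_total &
    colMeans(counts > 0) >= min_prevalence
  counts[, keep, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (one seeded draw, as in single-rarefaction workflows; average over
#' repeated draws with `n_draws > 1` if a smoothed table is wanted). Samples
#' whose total falls below `depth` are dropped, with the drop recorded in
#' attribute `dropped_samples`.
#'
#' @param counts samples x ASVs count matrix.
#' @param depth target depth (default 31044).
#' @param seed integer seed; required for reproducibility.
#' @param n_draws number of rarefaction draws to average (default 1).
#' @return Rarefied count matrix (every row sums to `depth`; real-valued if
#'   `n_draws > 1`) with attribute `dropped_samples`.
#' @export
rarefy_counts <- function(counts, depth = 31044, seed = 1, n_draws = 1) {
  counts <- as_asv_matrix(counts)
  if (depth <= 0) stop("depth must be positive")
  totals <- rowSums(counts)
  drop <- totals < depth
  kept <- counts[!drop, , drop = FALSE]
  out <- withr::with_seed(seed, {
    draws <- lapply(seq_len(n_draws), function(r) {
      t(apply(kept, 1, rarefy_one, depth = depth))
    })
    Reduce(`+`, draws) / n_draws
  })
  dimnames(out) <- dimnames(kept)
  structure(out, dropped_samples = rownames(counts)[drop])
}

# Draw `depth` reads without replacement from one sample's count vector.
rarefy_one <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(x)
  idx <- sample.int(total, depth)                 # which reads survive
  breaks <- cumsum(x)
  tabulate(findInterval(idx, breaks, left.open = TRUE) + 1L,
           nbins = length(x))
}

#' Scale each sample to 10,000 sequences
#'
#' Real-valued library-size normalization: every sample row is rescaled to
#' sum to 10,000.
#'
#' @param counts samples x ASVs matrix (counts or rarefied counts).
#' @return Matrix of the same shape with all row sums equal to 10,000.
#' @export
scale_per_10000 <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("cannot scale empty sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  counts / totals * 10000
}

#' Aggregate an ASV table to a taxonomic rank
#'
#' Sums member-ASV counts per rank label and converts to per-sample relative
#' abundance. ASVs missing from the taxonomy map are an error; unclassified
#' ASVs should carry an explicit "unclassified" label.
#'
#' @param counts samples x ASVs matrix (raw, rarefied or scaled).
#' @param taxonomy data frame with column `asv_id` plus rank columns
#'   (`order`, `family`, `genus`, `species`).
#' @param rank which rank column to aggregate to.
#' @param relative return relative abundances (default) or summed counts.
#' @return samples x rank-labels matrix; rows sum to 1 when `relative`.
#' @export
aggregate_rank <- function(counts, taxonomy, rank = "family",
                           relative = TRUE) {
  counts <- as.matrix(counts)
  if (!rank %in% names(taxonomy)) stop("taxonomy has no rank '", rank, "'")
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$asv_id)]
  if (anyNA(lab)) {
    stop("taxonomy map missing ASVs: ",
         paste(colnames(counts)[is.na(lab)], collapse = ", "))
  }
  agg <- t(rowsum(t(counts), group = lab))
  if (relative) agg <- agg / rowSums(agg)
  agg
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over the nonzero proportions of one sample
#' (natural log, i.e. nats).
#'
#' @param sample_counts numeric vector of counts or abundances (>= 0, not
#'   all zero).
#' @return Shannon index in nats.
#' @export
shannon_index <- function(sample_counts) {
  if (any(sample_counts < 0)) stop("counts must be non-negative")
  tot <- sum(sample_counts)
  if (tot == 0) stop("cannot compute diversity of an empty sample")
  p <- sample_counts[sample_counts > 0] / tot
  -sum(p * log(p))
}

#' Core archaeome by prevalence and detection thresholds
#'
#' A taxon is core for a group when its relative abundance reaches the
#' detection threshold in at least the prevalence fraction of that group's
#' samples.
#'
#' @param rel_abund samples x taxa relative-abundance matrix.
#' @param groups group label per sample (optional; one core set overall if
#'   omitted).
#' @param prevalence minimum fraction of samples (default 0.5).
#' @param detection minimum relative abundance (default 0.01).
#' @return Named list (per group) of character vectors of core taxa.
#' @export
core_archaeome <- function(rel_abund, groups = NULL, prevalence = 0.5,
                           detection = 0.01) {
  rel_abund <- as.matrix(rel_abund)
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (detection < 0) stop("detection must be >= 0")
  if (is.null(groups)) groups <- rep("all", nrow(rel_abund))
  stopifnot(length(groups) == nrow(rel_abund))
  lapply(split(seq_len(nrow(rel_abund)), groups), function(idx) {
    prev <- colMeans(rel_abund[idx, , drop = FALSE] >= detection)
    colnames(rel_abund)[prev >= prevalence]
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x - y| / sum(x + y)` between sample rows; the standard
#' abundance-based community dissimilarity.
#'
#' @param x samples x taxa abundance matrix.
#' @return `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  stats::as.dist(d)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from among/within sums of squared distances on any distance
#' matrix, with a permutation p-value
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param d `dist` object or square symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list: `F`, `p`, `df`, `ss_among`, `ss_within`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-12)) {
    stop("d must be a square symmetric distance matrix")
  }
  groups <- as.factor(groups)
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  k <- nlevels(groups)
  if (k < 2) stop("at least 2 groups are required")
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  ssw_for <- function(g) {
    sum(vapply(split(seq_len(n), g), function(idx) {
      sum(d2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
  }
  ssw <- ssw_for(groups)
  f_for <- function(ssw) ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  f_obs <- f_for(ssw)
  f_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      f_for(ssw_for(groups[sample.int(n)]))
    }, numeric(1))
  })
  list(F = f_obs,
       p = (1 + sum(f_perm >= f_obs)) / (n_perm + 1),
       df = c(among = k - 1, within = n - k),
       ss_among = ss_total - ssw, ss_within = ssw, n_perm = n_perm)
}

#' Wilcoxon rank sum (Mann-Whitney) test
#'
#' Exact two-sided p from the null rank-sum distribution when both groups
#' have at most `exact_max` observations and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors for the two groups.
#' @param exact_max largest per-group n for the exact distribution
#'   (default 10).
#' @return list: `W` (rank-sum statistic of `a`, i.e. Mann-Whitney U),
#'   `p`, `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 10) {
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na <= exact_max && nb <= exact_max) {
    # two-sided: double the smaller tail (standard convention), capped at 1
    p_lower <- stats::pwilcox(u, na, nb)
    p_upper <- stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lower, p_upper))
    return(list(W = u, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 *
    ((na + nb + 1) - sum(tie_tab^3 - tie_tab) /
       ((na + nb) * (na + nb - 1)))
  if (sigma2 == 0) return(list(W = u, p = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(W = u, p = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)),
       method = "normal")
}
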