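#' One-way analysis of variance
#'
#' Fixed-effect decomposition `Y_ij = mu + A_i + e_ij` computed from the
#' between/within sums of squares. When the data carry no variance at all
#' the F statistic is undefined and returned as `NA` with QC flag
#' `"zero_variance"`.
#'
#' @param values_by_group named list of numeric vectors, one per group
#'   (>= 2 groups, >= 2 values each).
#' @return list: `F`, `p`, `df` (c(between, within)), `ss_between`,
#'   `ss_within`, `ms_within`, `qc_flags`.
#' @export
anova_oneway <- function(values_by_group) {
  k <- length(values_by_group)
  if (k < 2) stop("at least 2 groups are required")
  n_i <- lengths(values_by_group)
  if (any(n_i < 2)) stop("each group needs at least 2 values")
  all_v <- unlist(values_by_group, use.names = FALSE)
  n <- length(all_v)
  gm <- mean(all_v)
  means <- vapply(values_by_group, mean, numeric(1))
  ssb <- sum(n_i * (means - gm)^2)
  ssw <- sum(vapply(values_by_group, function(v) sum((v - mean(v))^2),
                    numeric(1)))
  df <- c(between = k - 1, within = n - k)
  qc <- character()
  if (ssw == 0 && ssb == 0) {
    return(list(F = NA_real_, p = NA_real_, df = df, ss_between = 0,
                ss_within = 0, ms_within = 0, qc_flags = "zero_variance"))
  }
  Fst <- unname((ssb / df[1]) / (ssw / df[2]))
  list(F = Fst,
       p = unname(stats::pf(Fst, df[[1]], df[[2]], lower.tail = FALSE)),
       df = df, ss_between = ssb, ss_within = ssw,
       ms_within = ssw / df[2], qc_flags = qc)
}

#' Tukey HSD pairwise comparisons with a compact letter display
#'
#' Tukey-Kramer studentized-range tests on all group pairs at level `alpha`,
#' followed by the standard insert-and-absorb letter assignment: groups
#' sharing a letter do not differ significantly; groups with no letter in
#' common do.
#'
#' @param values_by_group named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return list: `pairwise` (data frame: group1, group2, diff, p,
#'   significant), `letters` (named character vector, letters per group in
#'   input order).
#' @export
tukey_letters <- function(values_by_group, alpha = 0.05) {
  an <- anova_oneway(values_by_group)
  g <- names(values_by_group)
  if (is.null(g)) g <- paste0("G", seq_along(values_by_group))
  means <- vapply(values_by_group, mean, numeric(1))
  n_i <- lengths(values_by_group)
  k <- length(g)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(group1 = g[pairs[1, ]], group2 = g[pairs[2, ]],
                   diff = means[pairs[2, ]] - means[pairs[1, ]],
                   p = NA_real_, stringsAsFactors = FALSE)
  if (is.na(an$F) || an$ms_within == 0) {
    # no residual variance: any mean difference is "infinitely" significant
    pw$p <- ifelse(abs(pw$diff) > 0, 0, 1)
  } else {
    se <- sqrt(an$ms_within / 2 *
                 (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
    q <- abs(pw$diff) / se
    pw$p <- stats::ptukey(q, nmeans = k, df = an$df[["within"]],
                          lower.tail = FALSE)
  }
  pw$significant <- pw$p <= alpha
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  for (j in seq_len(ncol(pairs))) {
    sig[pairs[1, j], pairs[2, j]] <- sig[pairs[2, j], pairs[1, j]] <-
      pw$significant[j]
  }
  list(pairwise = pw, letters = letter_display(sig, order(means)))
}

# Insert-and-absorb compact letter display from a logical significance
# matrix. `ord` gives the group order in which letters are assigned
# (conventionally increasing mean).
letter_display <- function(sig, ord = seq_len(nrow(sig))) {
  g <- rownames(sig)
  k <- length(g)
  cols <- list(rep(TRUE, k))  # membership columns; start with one letter
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(cols[[ci]] <= cols[[cj]]) &&
              any(cols[[ci]] < cols[[cj]])) {
            keep[ci] <- FALSE
          }
        }
      }
      # drop duplicated columns as well
      sig_cols <- vapply(cols, paste, character(1), collapse = "")
      keep <- keep & !duplicated(sig_cols)
      cols <- cols[keep]
    }
  }
  # order letters so 'a' goes to the column containing the first group in ord
  first_member <- vapply(cols, function(col) min(match(which(col), ord)),
                         numeric(1))
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(out, g)
}

#' Paired t-test
#'
#' Two-sided paired comparison. A zero-variance difference vector makes the
#' statistic degenerate: with all differences equal to a nonzero constant the
#' p-value is reported as 0 with QC flag `"zero_variance"`; with all
#' differences zero, `t = 0` and `p = 1`.
#'
#' @param pre,post matched numeric vectors.
#' @return list: `t`, `p`, `df`, `mean_diff`, `qc_flags`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2) {
    stop("pre and post must be matched vectors of length >= 2")
  }
  d <- post - pre
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0,
                  qc_flags = "zero_variance"))
    }
    return(list(t = sign(md) * Inf, p = 0, df = n - 1, mean_diff = md,
                qc_flags = "zero_variance"))
  }
  tt <- md / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE),
       df = n - 1, mean_diff = md, qc_flags = character())
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the columns of an
#' attribute table, with two-sided p-values from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x numeric data frame or matrix (observations x attributes).
#' @return list: `r` (correlation matrix, unit diagonal), `p` (p-value
#'   matrix, `NA` diagonal), `n` (pairwise complete sample sizes).
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  r <- stats::cor(x, use = "pairwise.complete.obs", method = "pearson")
  k <- ncol(x)
  nmat <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { nmat[i, j] <- sum(!is.na(x[, i])); next }
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n > 2 && abs(r[i, j]) < 1) {
        tt <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
        p[i, j] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
      } else if (n > 2) {
        p[i, j] <- 0
      }
    }
  }
  list(r = r, p = p, n = nmat)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into
#' `K^2 = Z(g1)^2 + Z(g2)^2`, referred to a chi-square distribution with 2
#' degrees of freedom. The transforms are the standard ones (D'Agostino's
#' skewness Z; Anscombe-Glynn kurtosis Z). The statistic is undefined for
#' very small samples: inputs with `n < 8` return `NA` with QC flag
#' `"n_too_small"` rather than a silently unreliable test.
#'
#' @param x numeric vector.
#' @return list: `K2`, `p`, `n`, `z_skew`, `z_kurt`, `qc_flags`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) {
    return(list(K2 = NA_real_, p = NA_real_, n = n, z_skew = NA_real_,
                z_kurt = NA_real_, qc_flags = "n_too_small"))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(list(K2 = NA_real_, p = NA_real_, n = n, z_skew = NA_real_,
                z_kurt = NA_real_, qc_flags = "zero_variance"))
  }
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(K2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE), n = n,
       z_skew = z1, z_kurt = z2, qc_flags = character())
}

#' Group summary table for one attribute
#'
#' The reporting shape used in feeding-trial tables: group means, a pooled
#' SEM from the residual mean square (`sqrt(MS_within / n)` at equal group
#' size, labeled as such), the one-way F and p, and Tukey letters.
#'
#' @param values_by_group named list of numeric vectors.
#' @param attribute attribute name carried into the output.
#' @param alpha level for the letter display.
#' @return one-row data frame: attribute, `<group>` mean columns, `sem`
#'   (pooled residual), `F`, `p`, and `letters` (collapsed `group:letter`).
#' @export
group_summary <- function(values_by_group, attribute = "value",
                          alpha = 0.05) {
  an <- anova_oneway(values_by_group)
  tk <- tukey_letters(values_by_group, alpha = alpha)
  means <- vapply(values_by_group, mean, numeric(1))
  n_h <- length(values_by_group) / sum(1 / lengths(values_by_group))
  out <- data.frame(attribute = attribute, t(means),
                    sem = sqrt(an$ms_within / n_h),
                    F = an$F, p = an$p,
                    letters = paste(names(tk$letters), tk$letters,
                                    sep = ":", collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
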