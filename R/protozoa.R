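#' Construct a protozoa counting-chamber record
#'
#' Per-field microscope counts of rumen ciliate protozoa by morphotype
#' (Entodiniomorphs and Holotrichs), together with the counting-chamber
#' geometry needed to convert field counts to cells per ml:
#'
#' \deqn{N = \frac{\bar n \cdot A \cdot D}{a \cdot v}}
#'
#' where `n-bar` is the mean count per microscopic field, `A` the area over
#' which the diluted sample spreads (mm^2), `D` the dilution of the rumen
#' fluid, `a` the area of one microscopic field (mm^2) and `v` the fluid
#' volume in the chamber cavity (ml).
#'
#' @param field_counts numeric matrix or data frame, fields x morphotypes
#'   (columns named, e.g. `Entodiniomorph`, `Holotrich`), all counts >= 0.
#' @param slide_area `A`, mm^2.
#' @param field_area `a`, mm^2.
#' @param dilution `D`, >= 1 (default 2: equal-volume formaldehyde fixation;
#'   the staining solution is a stain stock, not a sample dilution).
#' @param chamber_volume `v`, ml.
#' @param n_fields expected number of fields (default 30); enforced.
#' @return Object of class `protozoa_count`.
#' @export
protozoa_count <- function(field_counts, slide_area, field_area,
                           dilution = 2, chamber_volume, n_fields = 30) {
  field_counts <- as.matrix(field_counts)
  if (nrow(field_counts) != n_fields) {
    stop("expected ", n_fields, " microscope fields, got ", nrow(field_counts))
  }
  if (any(field_counts < 0)) stop("field counts must be non-negative")
  if (slide_area <= 0 || field_area <= 0 || chamber_volume <= 0) {
    stop("chamber geometry (areas, volume) must be positive")
  }
  if (dilution < 1) stop("dilution must be >= 1")
  structure(
    list(field_counts = field_counts, slide_area = slide_area,
         field_area = field_area, dilution = dilution,
         chamber_volume = chamber_volume),
    class = "protozoa_count"
  )
}

#' Protozoa concentration from chamber counts
#'
#' Applies the counting-chamber formula (see [protozoa_count()]) to one
#' morphotype or to the total across morphotypes.
#'
#' @param pc a [protozoa_count()].
#' @param morphotype a column name of the field-count matrix, or `"total"`.
#' @return Cells per ml of rumen fluid. Report totals and Entodiniomorphs in
#'   units of 1e7 and Holotrichs in 1e6 by dividing accordingly.
#' @export
enumerate_protozoa <- function(pc, morphotype = "total") {
  stopifnot(inherits(pc, "protozoa_count"))
  fc <- pc$field_counts
  if (nrow(fc) == 0) stop("insufficient data: no microscope fields")
  n_bar <- if (identical(morphotype, "total")) {
    mean(rowSums(fc))
  } else {
    if (!morphotype %in% colnames(fc)) {
      stop("unknown morphotype '", morphotype, "'")
    }
    mean(fc[, morphotype])
  }
  n_bar * pc$slide_area * pc$dilution / (pc$field_area * pc$chamber_volume)
}

#' Compare protozoa counts before and after supplement withdrawal
#'
#' Matches animals between the supplementation-period and withdrawal-period
#' enumerations, computes per-animal and per-group deltas, and routes the
#' matched pairs to a paired t-test per group.
#'
#' @param pre,post data frames with columns `animal`, `group`, `cells_ml`.
#' @return list: `per_animal` (animal, group, pre, post, delta), `per_group`
#'   (group, n, mean_delta, t, p).
#' @export
compare_withdrawal <- function(pre, post) {
  need <- c("animal", "group", "cells_ml")
  stopifnot(all(need %in% names(pre)), all(need %in% names(post)))
  if (!setequal(pre$animal, post$animal) ||
      anyDuplicated(pre$animal) || anyDuplicated(post$animal)) {
    stop("pre and post rosters must match one-to-one")
  }
  i <- match(pre$animal, post$animal)
  if (!identical(as.character(pre$group),
                 as.character(post$group[i]))) {
    stop("group labels disagree between pre and post rosters")
  }
  pa <- data.frame(animal = pre$animal, group = pre$group,
                   pre = pre$cells_ml, post = post$cells_ml[i],
                   delta = post$cells_ml[i] - pre$cells_ml,
                   stringsAsFactors = FALSE)
  pg <- do.call(rbind, lapply(split(pa, pa$group), function(d) {
    tt <- paired_t(d$pre, d$post)
    data.frame(group = d$group[1], n = nrow(d),
               mean_delta = mean(d$delta), t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  rownames(pg) <- NULL
  list(per_animal = pa, per_group = pg)
}
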