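# Plain-TSV persistence for trial datasets. Everything is tab-separated
# text so a dataset survives any tooling; the ASV table is written long
# (sample, asv_id, count) to keep files small and diffable.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a trial dataset as a directory of TSV tables
#'
#' Writes `animals.tsv`, `intake.tsv`, `feces.tsv`, `bodyweights.tsv`,
#' `tubes.tsv`, `canisters.tsv`, `canisters_wd.tsv`, `vfa.tsv`,
#' `ammonia.tsv`, `protozoa.tsv`, `asv_counts.tsv` (long form),
#' `taxonomy.tsv`, `latents.tsv`, plus `config.json` echoing the generator
#' configuration (requires the jsonlite package).
#'
#' @param dataset a `trial_dataset` from [generate_trial()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(animals = dataset$animals, intake = dataset$intake,
               feces = dataset$feces, bodyweights = dataset$body_weights,
               tubes = dataset$tubes, canisters = dataset$canisters,
               canisters_wd = dataset$canisters_wd, vfa = dataset$vfa_gc,
               ammonia = dataset$ammonia, protozoa = dataset$protozoa,
               taxonomy = dataset$taxonomy)
  for (nm in names(tabs)) {
    write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  lat <- data.frame(animal = rownames(dataset$latents), dataset$latents,
                    stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(lat, file.path(dir, "latents.tsv"))
  counts <- dataset$asv_counts
  long <- data.frame(sample = rep(rownames(counts), ncol(counts)),
                     asv_id = rep(colnames(counts), each = nrow(counts)),
                     count = as.vector(counts), stringsAsFactors = FALSE)
  write_tsv(long[long$count > 0, ], file.path(dir, "asv_counts.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfgl <- unclass(dataset$config)
    cfgl$group_means <- dataset$config$group_means
    jsonlite::write_json(cfgl, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a trial dataset written by [write_trial_dataset()]
#'
#' @param dir directory containing the TSV tables.
#' @return list with the same tabular components as a `trial_dataset`
#'   (`config` is not reconstructed; `latents` only if present).
#' @export
read_trial_dataset <- function(dir) {
  rd <- function(nm) read_tsv(file.path(dir, paste0(nm, ".tsv")))
  long <- rd("asv_counts")
  samples <- sort(unique(long$sample))
  asvs <- sort(unique(long$asv_id))
  counts <- matrix(0L, length(samples), length(asvs),
                   dimnames = list(samples, asvs))
  counts[cbind(match(long$sample, samples), match(long$asv_id, asvs))] <-
    as.integer(long$count)
  out <- list(animals = rd("animals"), intake = rd("intake"),
              feces = rd("feces"), body_weights = rd("bodyweights"),
              tubes = rd("tubes"), canisters = rd("canisters"),
              canisters_wd = rd("canisters_wd"), vfa_gc = rd("vfa"),
              ammonia = rd("ammonia"), protozoa = rd("protozoa"),
              asv_counts = counts, taxonomy = rd("taxonomy"))
  lat_path <- file.path(dir, "latents.tsv")
  if (file.exists(lat_path)) {
    lat <- read_tsv(lat_path)
    rownames(lat) <- lat$animal
    out$latents <- lat[, -1, drop = FALSE]
  }
  out
}

#' Export an ASV count matrix as a MatrixMarket triplet file
#'
#' Sparse plain-text interchange format readable by most matrix tooling
#' (requires the Matrix package).
#'
#' @param counts samples x ASVs matrix.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
export_asv_mtx <- function(counts, path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MatrixMarket export")
  }
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE), path)
  invisible(path)
}
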