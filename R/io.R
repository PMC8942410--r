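## Readers and writers for the pipeline's exchange formats: MetaPhlAn2-style
## abundance TSV (taxon rows x sample columns), sample-metadata CSV,
## item-level food-record CSV, category-map CSV and long cytokine CSV. The
## synthetic generator writes exactly the formats the real-data readers
## consume.

#' Read the item-to-category map
#'
#' @param path CSV with columns `item`, `category`, `subcategory`,
#'   `conversion` (servings conversion factor).
#' @return Validated data.frame.
#' @export
read_category_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "category", "subcategory", "conversion")
  assert_that(all(need %in% names(map)),
              paste("category map must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(map$item), "every item must map to exactly one category")
  assert_that(all(map$category %in% diet_categories()),
              "unknown category in map")
  map
}

#' Built-in toy category map
#'
#' A small illustrative item map shipped with the package (the full 240-item
#' instrument is not published in machine-readable form).
#'
#' @return Data.frame as from [read_category_map()].
#' @export
default_category_map <- function() {
  read_category_map(system.file("extdata", "category_map.csv",
                                package = "dietshift", mustWork = TRUE))
}

#' Write / read a MetaPhlAn2-style species abundance table
#'
#' Taxon rows by sample columns, first column `#clade_name`. Values are
#' written as percentages by default (the profiler's convention) or as
#' proportions.
#'
#' @param abundance Samples x species matrix of proportions (rows sum to 1).
#' @param path Output TSV path.
#' @param scale `"percent"` or `"proportion"`.
#' @export
write_abundance_tsv <- function(abundance, path, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  m <- t(abundance)
  if (scale == "percent") m <- m * 100
  df <- data.frame(`#clade_name` = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @param scale_in `"auto"` detects percentages (column sums near 100) and
#'   rescales; `"percent"`/`"proportion"` force an interpretation.
#' @return `read_abundance_tsv`: samples x species matrix of proportions.
#' @export
read_abundance_tsv <- function(path, scale_in = c("auto", "percent", "proportion")) {
  scale_in <- match.arg(scale_in)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- taxa
  m <- t(m)  # samples x species
  if (scale_in == "auto") {
    scale_in <- if (stats::median(rowSums(m)) > 1.5) "percent" else "proportion"
  }
  if (scale_in == "percent") m <- m / 100
  ## renormalize residual rounding so downstream compositional checks hold
  m / rowSums(m)
}

#' Write / read per-sample metadata
#'
#' @param samples Per-sample metadata data.frame (as in a
#'   `"longitudinal_cohort"`'s `samples` element).
#' @param path CSV path.
#' @export
write_metadata_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "diagnosis", "period")
  if (!"period" %in% names(md) && "phase" %in% names(md)) md$period <- md$phase
  if (!"phase" %in% names(md) && "period" %in% names(md)) md$phase <- md$period
  assert_that(all(c("sample_id", "subject_id", "diagnosis") %in% names(md)),
              "metadata needs sample_id, subject_id, diagnosis columns")
  md
}

#' Write / read item-level food-query records
#'
#' One row per (subject, day, item): `subject_id, day, week, phase, item,
#' servings`.
#'
#' @param food_items Item-level record data.frame.
#' @param path CSV path.
#' @export
write_food_records_csv <- function(food_items, path) {
  utils::write.csv(food_items, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_food_records_csv
#' @export
read_food_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a long cytokine panel
#'
#' @param panel Long data.frame: `subject_id, timepoint, analyte,
#'   concentration`.
#' @param path CSV path.
#' @export
write_cytokines_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cytokines_csv
#' @export
read_cytokines_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "timepoint", "analyte", "concentration")
  assert_that(all(need %in% names(panel)),
              paste("cytokine CSV must have columns:", paste(need, collapse = ", ")))
  panel
}

#' Export a simulated cohort to the on-disk exchange formats
#'
#' @param cohort A `"longitudinal_cohort"`.
#' @param dir Output directory (created if needed).
#' @param scale Abundance scale for the TSV.
#' @return Named vector of file paths.
#' @export
write_cohort <- function(cohort, dir, scale = "percent") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    food = file.path(dir, "food_records.csv"),
    cytokines = file.path(dir, "cytokines.csv")
  )
  write_abundance_tsv(cohort$abundance, paths[["abundance"]], scale = scale)
  write_metadata_csv(cohort$samples, paths[["metadata"]])
  write_food_records_csv(cohort$food_items, paths[["food"]])
  if (!is.null(cohort$cytokines)) {
    write_cytokines_csv(cohort$cytokines, paths[["cytokines"]])
  } else {
    paths <- paths[names(paths) != "cytokines"]
  }
  paths
}
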