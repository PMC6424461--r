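MAF_REQUIRED_COLUMNS <- c(
  "Tumor_Sample_Barcode", "Chromosome", "Start_Position",
  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification"
)

#' Read a MAF (Mutation Annotation Format) variant table
#'
#' Reads the GDC tab-separated MAF dialect: a header row, `#`-prefixed
#' comment lines (e.g. `#version`) skipped, one row per somatic variant
#' call. Positions are 1-based inclusive, as in the format, and are never
#' converted. Columns beyond the required set are preserved untouched.
#'
#' @param path Path to a (possibly empty) tab-separated MAF file.
#' @param required_columns Columns that must be present; defaults to the
#'   GDC set used downstream: Tumor_Sample_Barcode, Chromosome,
#'   Start_Position, Reference_Allele, Tumor_Seq_Allele2,
#'   Variant_Classification.
#'
#' @return A tibble with one row per variant call. An empty file yields a
#'   zero-row tibble with a warning.
#' @seealso [count_mutations_per_sample()]
#' @export
read_maf <- function(path, required_columns = MAF_REQUIRED_COLUMNS) {
  if (!file.exists(path)) {
    stop(sprintf("MAF file not found: %s", path), call. = FALSE)
  }
  maf <- readr::read_tsv(
    path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  if (nrow(maf) == 0 && ncol(maf) == 0) {
    warning(sprintf("MAF file is empty: %s", path), call. = FALSE)
    maf <- tibble::as_tibble(
      stats::setNames(rep(list(character()), length(required_columns)),
                      required_columns)
    )
  }
  missing <- setdiff(required_columns, names(maf))
  if (length(missing)) {
    stop(sprintf("MAF file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  maf$Start_Position <- as.numeric(maf$Start_Position)
  if (any(!is.finite(maf$Start_Position)) ||
      (nrow(maf) > 0 && any(maf$Start_Position < 1))) {
    stop("Start_Position must be a 1-based positive integer.", call. = FALSE)
  }
  if (nrow(maf) > 0 && any(maf$Tumor_Sample_Barcode == "")) {
    stop("Tumor_Sample_Barcode must be non-empty for every row.",
         call. = FALSE)
  }
  maf
}

#' Write a variant table back to MAF
#'
#' Plain tab-separated output with a header row; the inverse of
#' [read_maf()] for the required columns.
#'
#' @param maf A tibble of variant calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  readr::write_tsv(maf, path, progress = FALSE)
  invisible(path)
}

#' Count somatic mutations per sample
#'
#' Collapses a MAF variant table to one mutation count per tumor sample —
#' the quantity whose cohort distribution the multi-hit model is fitted to.
#' By default all somatic variant rows are counted (including Silent ones:
#' the default genome target count `G` already accounts for
#' synonymous/non-synonymous fixability), and exact duplicate calls are
#' collapsed.
#'
#' @param maf A tibble of variant calls from [read_maf()].
#' @param exclude_classifications Character vector of
#'   `Variant_Classification` values to drop before counting (e.g.
#'   `"Silent"` for a protein-altering-only count). Default: none.
#' @param deduplicate If `TRUE` (default), rows identical in
#'   (sample, chromosome, position, alternate allele) are counted once;
#'   defensive against concatenated MAFs.
#' @param metadata Optional per-sample metadata tibble from
#'   [read_sample_metadata()]; joined by patient identifier.
#' @param id_prefix_length Number of leading barcode characters forming the
#'   patient identifier used for the metadata join (default 12, the TCGA
#'   patient ID).
#' @param cancer_type Optional cohort label stored in a `cancer_type` column.
#'
#' @return A cohort tibble with columns `sample_id`, `mutation_count`, plus
#'   `cancer_type` and any metadata columns when supplied. One row per
#'   distinct sample barcode seen in `maf`.
#' @examples
#' maf <- tibble::tibble(
#'   Tumor_Sample_Barcode = c("S1", "S1", "S2"),
#'   Chromosome = "1", Start_Position = c(100, 200, 100),
#'   Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
#'   Variant_Classification = c("Missense_Mutation", "Silent", "Missense_Mutation")
#' )
#' count_mutations_per_sample(maf)
#' count_mutations_per_sample(maf, exclude_classifications = "Silent")
#' @export
count_mutations_per_sample <- function(maf,
                                       exclude_classifications = character(),
                                       deduplicate = TRUE,
                                       metadata = NULL,
                                       id_prefix_length = 12L,
                                       cancer_type = NULL) {
  kept <- dplyr::filter(
    maf, !(.data$Variant_Classification %in% exclude_classifications)
  )
  if (deduplicate) {
    kept <- dplyr::distinct(
      kept, .data$Tumor_Sample_Barcode, .data$Chromosome,
      .data$Start_Position, .data$Tumor_Seq_Allele2, .keep_all = TRUE
    )
  }
  cohort <- kept |>
    dplyr::count(sample_id = .data$Tumor_Sample_Barcode,
                 name = "mutation_count") |>
    dplyr::arrange(.data$sample_id)
  if (!is.null(cancer_type)) {
    cohort <- dplyr::mutate(cohort, cancer_type = cancer_type,
                            .before = "sample_id")
  }
  if (!is.null(metadata)) {
    cohort <- cohort |>
      dplyr::mutate(patient_id = substr(.data$sample_id, 1L, id_prefix_length)) |>
      dplyr::left_join(metadata, by = "patient_id")
  }
  cohort
}

#' Read per-sample (per-patient) clinical metadata
#'
#' Reads a delimited table of clinical annotations (age at diagnosis,
#' subtype, stage, ...) keyed by a patient/sample identifier column, for
#' joining onto mutation-count cohorts. TCGA clinical files key by the
#' 12-character patient barcode prefix.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension;
#'   `.tsv`/`.txt` are read as tab-separated).
#' @param id_column Name of the identifier column; renamed to `patient_id`.
#' @return A tibble with a `patient_id` column plus the remaining columns.
#' @export
read_sample_metadata <- function(path, id_column = "patient_id") {
  reader <- if (grepl("\\.(tsv|txt)$", path)) readr::read_tsv else readr::read_csv
  meta <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!id_column %in% names(meta)) {
    stop(sprintf("Metadata file %s has no column '%s'.", path, id_column),
         call. = FALSE)
  }
  dplyr::rename(meta, patient_id = dplyr::all_of(id_column))
}

#' Partition a cohort by a metadata column
#'
#' Splits a cohort tibble into named sub-cohorts by the values of a
#' metadata column (e.g. `subtype` or `stage`). Samples with missing values
#' are collected under `"unknown"`. The groups form a partition: every
#' sample appears in exactly one group.
#'
#' @param cohort A cohort tibble (see [count_mutations_per_sample()]).
#' @param by Name of the grouping column.
#' @return A named list of cohort tibbles.
#' @export
group_cohort <- function(cohort, by) {
  if (!by %in% names(cohort)) {
    stop(sprintf("Unknown grouping key '%s'. Available: %s",
                 by, paste(names(cohort), collapse = ", ")), call. = FALSE)
  }
  key <- as.character(cohort[[by]])
  key[is.na(key) | key == ""] <- "unknown"
  split(cohort, key)
}

#' Read a cohort CSV written by this package
#'
#' @param path CSV with at least `sample_id` and `mutation_count` columns.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample_id", "mutation_count"), names(cohort))
  if (length(missing)) {
    stop(sprintf("Cohort file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  cohort
}

#' Write a cohort to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
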