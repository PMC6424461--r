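test_that("MAF reading follows the GDC tab-separated dialect", {
  path <- write_fixture_maf()
  maf <- read_maf(path)
  expect_equal(nrow(maf), 7)  # comment line skipped, duplicate kept as-is
  expect_true(all(MAF_REQUIRED_COLUMNS %in% names(maf)))
  expect_true("Hugo_Symbol" %in% names(maf))  # extra columns preserved

  no_comment <- write_fixture_maf(with_comment = FALSE)
  expect_equal(nrow(read_maf(no_comment)), 7)

  expect_error(read_maf(tempfile()), "not found")

  # missing required column is a named format error
  broken <- tempfile(fileext = ".maf")
  writeLines(c("Chromosome\tStart_Position", "1\t100"), broken)
  expect_error(read_maf(broken), "Tumor_Sample_Barcode")

  empty <- tempfile(fileext = ".maf")
  writeLines(character(0), empty)
  expect_warning(res <- read_maf(empty), "empty")
  expect_equal(nrow(res), 0)
})

test_that("per-sample counting honors exclusion and deduplication", {
  maf <- read_maf(write_fixture_maf())
  # default: duplicates collapsed, Silent counted
  cohort <- count_mutations_per_sample(maf)
  expect_equal(cohort$mutation_count[cohort$sample_id == "TCGA-AA-0001-01A"], 4)
  expect_equal(cohort$mutation_count[cohort$sample_id == "TCGA-BB-0002-01A"], 2)

  no_silent <- count_mutations_per_sample(maf, exclude_classifications = "Silent")
  expect_equal(no_silent$mutation_count, c(3, 2))

  raw <- count_mutations_per_sample(maf, deduplicate = FALSE)
  expect_equal(raw$mutation_count[raw$sample_id == "TCGA-AA-0001-01A"], 5)
  # conservation: totals equal retained records
  expect_equal(sum(raw$mutation_count), nrow(maf))

  labelled <- count_mutations_per_sample(maf, cancer_type = "FIXTURE")
  expect_equal(unique(labelled$cancer_type), "FIXTURE")
})

test_that("metadata joins by patient barcode prefix", {
  maf <- read_maf(write_fixture_maf())
  meta_path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,age_at_diagnosis,subtype",
               "TCGA-AA-0001,61.5,HR+/HER2-",
               "TCGA-BB-0002,47.0,TNBC"), meta_path)
  meta <- read_sample_metadata(meta_path)
  cohort <- count_mutations_per_sample(maf, metadata = meta)
  expect_equal(cohort$age_at_diagnosis, c(61.5, 47.0))
  expect_equal(cohort$subtype, c("HR+/HER2-", "TNBC"))
  expect_error(read_sample_metadata(meta_path, id_column = "bcr_barcode"),
               "bcr_barcode")
})

test_that("grouping partitions the cohort with an unknown bucket", {
  cohort <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:6),
    mutation_count = c(10, 20, 30, 40, 50, 60),
    subtype = c("HR+/HER2-", "TNBC", "HR+/HER2-", NA, "TNBC", "")
  )
  groups <- group_cohort(cohort, "subtype")
  expect_setequal(names(groups), c("HR+/HER2-", "TNBC", "unknown"))
  expect_equal(vapply(groups, nrow, integer(1))[["unknown"]], 2)
  # partition: no sample lost, none duplicated
  all_ids <- unlist(lapply(groups, `[[`, "sample_id"))
  expect_setequal(all_ids, cohort$sample_id)
  expect_equal(length(all_ids), nrow(cohort))

  all_missing <- dplyr::mutate(cohort, subtype = NA_character_)
  expect_named(group_cohort(all_missing, "subtype"), "unknown")
  expect_error(group_cohort(cohort, "stage"), "Available")
})

test_that("MAF round-trips byte-identically through read and write", {
  path <- write_fixture_maf(with_comment = FALSE)
  maf <- read_maf(path)
  out <- tempfile(fileext = ".maf")
  write_maf(dplyr::mutate(maf, Start_Position = format(Start_Position,
                                                       scientific = FALSE)),
            out)
  reread <- read_maf(out)
  expect_identical(maf[MAF_REQUIRED_COLUMNS], reread[MAF_REQUIRED_COLUMNS])
})

test_that("cohort CSV round-trips and validates its columns", {
  cohort <- sample_cohort(multihit_params(h = 2, k = 2e9), n_samples = 20,
                          seed = 5)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_equal(read_cohort(path)$mutation_count, cohort$mutation_count)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample,n", "a,1"), bad)
  expect_error(read_cohort(bad), "mutation_count")
})
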