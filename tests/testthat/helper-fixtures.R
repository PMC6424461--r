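# Small MAF fixture: two samples, one Silent row, one exact duplicate pair.
write_fixture_maf <- function(path = tempfile(fileext = ".maf"),
                              with_comment = TRUE) {
  header <- paste(c("Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome",
                    "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Variant_Type"),
                  collapse = "\t")
  row <- function(sym, sample, chrom, pos, ref, alt, cls) {
    paste(sym, sample, chrom, pos, ref, alt, cls, "SNP", sep = "\t")
  }
  lines <- c(
    if (with_comment) "#version gdc-1.0.0",
    header,
    row("TP53", "TCGA-AA-0001-01A", "17", 7577120, "C", "T", "Missense_Mutation"),
    row("TP53", "TCGA-AA-0001-01A", "17", 7577120, "C", "T", "Missense_Mutation"),
    row("KRAS", "TCGA-AA-0001-01A", "12", 25398284, "C", "A", "Missense_Mutation"),
    row("GAPDH", "TCGA-AA-0001-01A", "12", 6534517, "G", "A", "Silent"),
    row("BRAF", "TCGA-AA-0001-01A", "7", 140453136, "A", "T", "Missense_Mutation"),
    row("EGFR", "TCGA-BB-0002-01A", "7", 55259515, "T", "G", "Missense_Mutation"),
    row("PTEN", "TCGA-BB-0002-01A", "10", 89692905, "C", "T", "Nonsense_Mutation")
  )
  writeLines(lines, path)
  path
}

# deterministic mid-size cohort from a known model, cached per test run
fixture_cohort_h3 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_cohort(multihit_params(h = 3, k = 9e14),
                              n_samples = 500, seed = 421)
    }
    cache
  }
})

default_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_model_grid(default_genome_target_count())
    }
    cache
  }
})
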