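#' Simulate a cohort of per-sample somatic mutation counts
#'
#' Draws mutation counts from the multi-hit model distribution by
#' inverse-CDF sampling: each count `m` is drawn from
#' `P(m) / P_k(m_max)` on `1..m_max`, i.e. the model truncated to the
#' fitting range and renormalized, so the generative model matches the
#' fitted model exactly on that range. An optional hypermutator fraction is
#' drawn uniformly from `(m_max, 10 * m_max]` to emulate the overflow tail
#' seen in real cohorts. For mixture parameters, each sample's component is
#' drawn first (Bernoulli with the mixture share), then its count — one
#' seeded pseudorandom stream in that fixed order, so a seed reproduces the
#' cohort exactly.
#'
#' @param params A [multihit_params()] or [multihit_mixture_params()] object.
#' @param n_samples Number of samples to draw (>= 1).
#' @param seed Integer seed; the cohort is fully determined by it.
#' @param m_max Upper end of the sampling range (default 5000).
#' @param hypermutator_fraction Expected fraction of samples drawn from the
#'   uniform hypermutator tail, in `[0, 1)` (default 0).
#' @param cancer_type Optional label stored in a `cancer_type` column.
#'
#' @return A cohort tibble with columns `sample_id` (`"SIM-0001"`, ...) and
#'   `mutation_count`, plus `component` (`"i"`/`"j"`) for mixtures and
#'   `cancer_type` when labelled.
#' @examples
#' sample_cohort(multihit_params(h = 3, k = 9e14), n_samples = 5, seed = 1)
#' @export
sample_cohort <- function(params, n_samples, seed = NULL, m_max = 5000L,
                          hypermutator_fraction = 0, cancer_type = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer.", call. = FALSE)
  }
  if (hypermutator_fraction < 0 || hypermutator_fraction >= 1) {
    stop("`hypermutator_fraction` must be in [0, 1).", call. = FALSE)
  }
  is_mixture <- inherits(params, "multihit_mixture_params")
  if (!is_mixture && !inherits(params, "multihit_params")) {
    stop("`params` must be multihit_params or multihit_mixture_params.",
         call. = FALSE)
  }
  components <- if (is_mixture) {
    list(i = params$component_i, j = params$component_j)
  } else {
    list(i = params)
  }
  weights <- lapply(components, function(p) {
    inc <- prob_increment(p, seq_len(m_max))
    pk_total <- prob_any_combination(p, m_max)
    if (pk_total <= 0.5) {
      stop(sprintf(
        paste0("P_k(m_max) = %.3g <= 0.5 for (G = %g, h = %d, k = %g): most of ",
               "the model mass lies beyond m_max = %d. Increase m_max."),
        pk_total, p$G, p$h, p$k, m_max), call. = FALSE)
    }
    inc / sum(inc)
  })
  draw <- function() {
    if (is_mixture) {
      comp <- ifelse(stats::runif(n_samples) < params$share_percent / 100,
                     "i", "j")
    } else {
      comp <- rep("i", n_samples)
    }
    hyper <- if (hypermutator_fraction > 0) {
      stats::runif(n_samples) < hypermutator_fraction
    } else {
      rep(FALSE, n_samples)
    }
    counts <- integer(n_samples)
    for (cc in names(components)) {
      sel <- comp == cc & !hyper
      if (any(sel)) {
        counts[sel] <- sample.int(m_max, sum(sel), replace = TRUE,
                                  prob = weights[[cc]])
      }
    }
    if (any(hyper)) {
      counts[hyper] <- m_max + sample.int(9L * m_max, sum(hyper),
                                          replace = TRUE)
    }
    list(counts = counts, component = comp)
  }
  drawn <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble::tibble(
    sample_id = sprintf("SIM-%04d", seq_len(n_samples)),
    mutation_count = drawn$counts
  )
  if (is_mixture) out$component <- drawn$component
  if (!is.null(cancer_type)) {
    out <- dplyr::mutate(out, cancer_type = cancer_type, .before = 1L)
  }
  out
}

#' Write a synthetic MAF realizing a cohort's mutation counts
#'
#' Emits a minimal valid GDC-dialect MAF with one synthetic variant row per
#' mutation, so a simulated cohort can exercise the full
#' [read_maf()] / [count_mutations_per_sample()] path end-to-end. Variant
#' positions are arbitrary but unique within a sample (so deduplication
#' leaves counts unchanged).
#'
#' @param cohort A cohort tibble with `sample_id` and `mutation_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_maf <- function(cohort, path) {
  n <- cohort$mutation_count
  maf <- tibble::tibble(
    Hugo_Symbol = "SYNTHETIC",
    Tumor_Sample_Barcode = rep(cohort$sample_id, n),
    Chromosome = "1",
    Start_Position = unlist(lapply(n, seq_len), use.names = FALSE),
    Reference_Allele = "A",
    Tumor_Seq_Allele2 = "T",
    Variant_Classification = "Missense_Mutation",
    Variant_Type = "SNP"
  )
  writeLines("#version synthetic", path)
  readr::write_tsv(maf, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Simulate-and-refit parameter recovery experiment
#'
#' End-to-end check of the estimation machinery: simulates `n_replicates`
#' cohorts from known parameters and refits each, reporting the fitted
#' `(h, k)`, the RMSD, and whether the true number of hits was recovered.
#'
#' @param true_params A [multihit_params()] object to simulate from.
#' @param n_samples Cohort size per replicate (default 500).
#' @param n_replicates Number of simulated cohorts (default 20).
#' @param seed Integer seed; replicate r uses `seed + r` for its cohort.
#' @inheritParams fit_single
#'
#' @return A tibble with one row per replicate (`replicate`, `h`, `k`,
#'   `rmsd`, `h_correct`) and the recovery fraction as attribute
#'   `recovery_fraction`.
#' @examples
#' parameter_recovery_experiment(multihit_params(h = 2, k = 2e9),
#'                               n_samples = 250, n_replicates = 2, seed = 1)
#' @export
parameter_recovery_experiment <- function(true_params, n_samples = 500L,
                                          n_replicates = 20L, seed = 1L,
                                          G = default_genome_target_count(),
                                          h_range = 1:9, bin_width = 100L,
                                          n_bins = 50L) {
  grid <- build_model_grid(G, h_range, bin_width, n_bins)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cohort <- sample_cohort(true_params, n_samples, seed = seed + r,
                            m_max = bin_width * n_bins)
    fit <- suppressWarnings(fit_single(cohort, G = G, h_range = h_range,
                                       bin_width = bin_width, n_bins = n_bins,
                                       grid = grid))
    tibble::tibble(replicate = r, h = fit$best$h, k = fit$best$k,
                   rmsd = fit$rmsd_percent,
                   h_correct = fit$best$h == true_params$h)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "recovery_fraction") <- mean(out$h_correct)
  out
}
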