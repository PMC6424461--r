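new_binned_distribution <- function(percent, bin_width, n_bins,
                                    n_included, n_overflow, source) {
  # bin 1 covers [0, w]; bin b >= 2 covers [w(b-1)+1, w*b]
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_start = c(0L, as.integer(bin_width * seq_len(n_bins - 1L) + 1L))[seq_len(n_bins)],
    bin_end = as.integer(bin_width * seq_len(n_bins)),
    percent = percent
  )
  attr(out, "bin_width") <- as.integer(bin_width)
  attr(out, "n_bins") <- as.integer(n_bins)
  attr(out, "n_included") <- n_included
  attr(out, "n_overflow") <- n_overflow
  attr(out, "source") <- source
  class(out) <- c("binned_distribution", class(out))
  out
}

# bin index for integer counts under the [0,w], [w+1, 2w], ... convention
bin_index <- function(counts, bin_width) {
  pmax(ceiling(counts / bin_width), 1)
}

#' Bin observed mutation counts into a percentage distribution
#'
#' Groups per-sample mutation counts into fixed-width bins — by default 50
#' bins of width 100, covering 0 to 5000 — and expresses each bin as the
#' percentage of included samples. The first bin covers counts 0 to
#' `bin_width` inclusive; bin b covers `bin_width*(b-1)+1` to `bin_width*b`.
#' Counts above the last bin edge (hypermutators) are excluded from the
#' percentages with a warning and tallied in the `n_overflow` attribute.
#'
#' @param cohort A cohort tibble with a `mutation_count` column, or a bare
#'   numeric vector of counts.
#' @param bin_width Bin width in mutations (default 100).
#' @param n_bins Number of bins (default 50; widen to include hypermutated
#'   samples instead of excluding them).
#'
#' @return A `binned_distribution` tibble with columns `bin`, `bin_start`,
#'   `bin_end`, `percent`, and attributes `bin_width`, `n_bins`,
#'   `n_included`, `n_overflow`. Percentages sum to 100 of included samples.
#' @examples
#' bin_observed(c(50, 150, 250), n_bins = 5)
#' @export
bin_observed <- function(cohort, bin_width = 100L, n_bins = 50L) {
  counts <- if (is.data.frame(cohort)) cohort$mutation_count else cohort
  if (is.null(counts) || length(counts) == 0) {
    stop("Cohort has no mutation counts to bin.", call. = FALSE)
  }
  stopifnot(bin_width >= 1, n_bins >= 1)
  m_max <- bin_width * n_bins
  overflow <- counts > m_max
  if (any(overflow)) {
    warning(sprintf(
      "%d sample(s) with more than %d mutations excluded from the binned distribution.",
      sum(overflow), m_max), call. = FALSE)
  }
  kept <- counts[!overflow]
  if (length(kept) == 0) {
    pct <- numeric(n_bins)
  } else {
    pct <- 100 * tabulate(bin_index(kept, bin_width), nbins = n_bins) / length(kept)
  }
  new_binned_distribution(pct, bin_width, n_bins,
                          n_included = length(kept),
                          n_overflow = sum(overflow),
                          source = "observed")
}

#' Bin the model probability mass into the same bins
#'
#' Accumulates the per-mutation probability `P(m)` of a multi-hit model
#' into the same fixed-width bins used for observed counts: bin b carries
#' `100 * (P_k(bin_end) - P_k(bin_start - 1))` percentage points. Mass
#' beyond the last edge is absent, not renormalized, mirroring how observed
#' hypermutators are excluded; the bin total is `100 * P_k(m_max)`.
#'
#' @param params A [multihit_params()] or [multihit_mixture_params()] object.
#' @inheritParams bin_observed
#' @return A `binned_distribution` tibble (see [bin_observed()]).
#' @examples
#' bin_model(multihit_params(G = 3, h = 2, k = 1), bin_width = 2, n_bins = 2)
#' @export
bin_model <- function(params, bin_width = 100L, n_bins = 50L) {
  stopifnot(bin_width >= 1, n_bins >= 1)
  edges <- as.integer(bin_width) * (0:n_bins)
  if (inherits(params, "multihit_mixture_params")) {
    w <- params$share_percent / 100
    pk <- w * prob_any_combination(params$component_i, edges) +
      (1 - w) * prob_any_combination(params$component_j, edges)
  } else {
    pk <- prob_any_combination(params, edges)
  }
  pct <- 100 * pmax(diff(pk), 0)
  new_binned_distribution(pct, bin_width, n_bins,
                          n_included = NA_integer_,
                          n_overflow = NA_integer_,
                          source = "model")
}

#' Root mean squared difference between two binned distributions
#'
#' The fit criterion: the square root of the mean, over bins, of squared
#' differences in percentage points. Symmetric; 0 for identical
#' distributions.
#'
#' @param observed,model `binned_distribution` tibbles with identical
#'   `bin_width` and `n_bins`.
#' @return A non-negative scalar, in percentage points.
#' @examples
#' obs <- bin_observed(c(50, 150, 250), n_bins = 5)
#' rmsd(obs, obs) # 0
#' @export
rmsd <- function(observed, model) {
  for (x in list(observed, model)) {
    if (!inherits(x, "binned_distribution")) {
      stop("`rmsd()` expects binned_distribution objects; see bin_observed().",
           call. = FALSE)
    }
  }
  if (attr(observed, "bin_width") != attr(model, "bin_width") ||
      attr(observed, "n_bins") != attr(model, "n_bins")) {
    stop("Binned distributions have mismatched bin_width/n_bins.",
         call. = FALSE)
  }
  sqrt(mean((observed$percent - model$percent)^2))
}
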