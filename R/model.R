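#' Default number of fixable somatic mutations for the human exome
#'
#' The number of possible somatic mutations that can become fixed (i.e. do
#' not cause cell death) in a whole-exome assay of the diploid human genome:
#' a ~3.25e9 bp genome, two copies, ~1.5% exome, and on average 1.1 fixable
#' mutations per locus (one of the possible mutations at a locus is
#' synonymous, plus roughly 10% additional non-synonymous tolerance), giving
#' 3.25e9 x 2 x 1.1 x 1.5 / 100 = 1.0725e8.
#'
#' @return A positive scalar, 1.0725e8.
#' @examples
#' default_genome_target_count()
#' @export
default_genome_target_count <- function() {
  3.25e9 * 2 * 1.1 * 1.5 / 100
}

#' Number of possible carcinogenic h-hit combinations, order-of-magnitude
#'
#' Back-of-envelope count of possible carcinogenic combinations: with
#' `loci_per_gene` mutable loci that alter gene function, `copies` copies of
#' each gene, and `genes` genes whose alteration can contribute to
#' carcinogenesis, there are `(loci_per_gene * copies * genes)^h` possible
#' h-hit combinations.
#'
#' @param loci_per_gene Function-altering loci per gene (default 1000 of the
#'   ~1500 coding positions of an average protein).
#' @param copies Gene copies in the diploid genome (default 2).
#' @param genes Number of genes whose alteration is carcinogenic (default 50).
#' @param h Number of hits per combination.
#'
#' @return `(loci_per_gene * copies * genes)^h` as a double.
#' @examples
#' estimate_combination_count(h = 2) # 1e10
#' estimate_combination_count(h = 8) # 1e40
#' @export
estimate_combination_count <- function(loci_per_gene = 1000, copies = 2,
                                       genes = 50, h) {
  stopifnot(loci_per_gene >= 1, copies >= 1, genes >= 1, h >= 1)
  (as.numeric(loci_per_gene) * copies * genes)^h
}

# P_h(m) for m = 0..m_max by a forward recurrence over the number of
# distinct target loci already hit (states 0..h). Each of the m uniform
# draws hits a new target locus with probability (h - s)/G. All terms are
# non-negative, so the recurrence is free of the catastrophic cancellation
# of the alternating inclusion-exclusion sum (terms ~ 1, result ~ 1e-40),
# while being mathematically identical to it.
ph_curve <- function(G, h, m_max) {
  state <- c(1, numeric(h))        # state[s + 1] = P(s target loci hit)
  q <- (h - 0:h) / G               # per-draw probability of a new target hit
  out <- numeric(m_max + 1L)
  idx <- seq_len(h)
  for (m in seq_len(m_max)) {
    moved <- state[idx] * q[idx]
    state <- state * (1 - q)
    state[idx + 1L] <- state[idx + 1L] + moved
    out[m + 1L] <- state[h + 1L]
  }
  out
}

#' Probability of completing one specific h-hit combination
#'
#' `P_h(m)`: the probability that `m` somatic mutations, each equally likely
#' at any of `G` loci (with replacement), include all `h` loci of one given
#' carcinogenic combination. Equal to the inclusion-exclusion sum
#' `1 - sum_{i=1..h} (-1)^(i+1) C(h,i) ((G-i)/G)^m` for `m >= h`, and 0 for
#' `m < h`; evaluated by a cancellation-free recurrence accurate to
#' ~1e-12 relative error across the supported range (including G ~ 1e8,
#' where the alternating sum is numerically unusable in double precision).
#'
#' @param params A [multihit_params()] object (`k` is ignored here).
#' @param m Vector of non-negative integer mutation counts.
#'
#' @return Numeric vector of probabilities in `[0, 1]`, one per element of `m`.
#' @examples
#' prob_single_combination(multihit_params(G = 3, h = 2, k = 1), m = 2) # 2/9
#' prob_single_combination(multihit_params(G = 10, h = 1, k = 1), m = 3)
#' @export
prob_single_combination <- function(params, m) {
  stopifnot(inherits(params, "multihit_params"))
  if (any(m < 0) || any(m != round(m))) {
    stop("`m` must contain non-negative integers.", call. = FALSE)
  }
  curve <- ph_curve(params$G, params$h, max(m, 1))
  curve[m + 1L]
}

#' Cumulative probability of completing any of k combinations
#'
#' `P_k(m) = 1 - (1 - P_h(m))^k`: the probability that `m` accumulated
#' somatic mutations complete at least one of `k` alternative h-hit
#' combinations. Evaluated as `-expm1(k * log1p(-P_h))` so that it remains
#' accurate when `P_h ~ 1e-40` and `k ~ 1e40`. Non-decreasing in both `m`
#' and `k`. The independence of combinations is an approximation, good when
#' `G >> m` (combinations share loci only rarely).
#'
#' @inheritParams prob_single_combination
#' @return Numeric vector of cumulative probabilities, one per element of `m`.
#' @examples
#' prob_any_combination(multihit_params(h = 2, k = 2e9), m = c(1000, 5000))
#' @export
prob_any_combination <- function(params, m) {
  ph <- prob_single_combination(params, m)
  pk_from_ph(ph, params$k)
}

# Eq-2 evaluation on an already-computed P_h vector.
pk_from_ph <- function(ph, k) {
  -expm1(k * log1p(-pmin(ph, 1)))
}

#' Probability that the m-th somatic mutation completes a combination
#'
#' `P(m) = P_k(m) - P_k(m - 1)`: the probability that carcinogenesis occurs
#' exactly on the m-th accumulated somatic mutation. `P_k(0)` is defined as
#' 0 (no mutations, no hits), so `prob_increment(params, 1) = P_k(1)`.
#'
#' @inheritParams prob_single_combination
#' @param m Vector of positive integer mutation counts (`m >= 1`).
#' @return Numeric vector of per-mutation probabilities, always `>= 0`.
#' @examples
#' prob_increment(multihit_params(G = 3, h = 2, k = 1), m = 2:3) # 2/9, 2/9
#' @export
prob_increment <- function(params, m) {
  if (any(m < 1)) {
    stop("`m` must be >= 1 (P_k(m - 1) is undefined for m = 0).",
         call. = FALSE)
  }
  pk <- prob_any_combination(params, c(m - 1L, m))
  n <- length(m)
  pmax(pk[(n + 1L):(2L * n)] - pk[seq_len(n)], 0)
}

#' Evaluate the full probability curve of a multi-hit model
#'
#' Computes `P_h`, `P_k` and the per-mutation increment `P(m)` for
#' `m = 0..m_max` in one pass. `P_h` is computed once for the `(G, h)` pair
#' and reused, so sweeping many `k` values is cheap (see
#' [fit_single()], which exploits this).
#'
#' @inheritParams prob_single_combination
#' @param m_max Largest mutation count to evaluate (default 5000, the
#'   fitting range).
#'
#' @return A tibble with columns `m`, `p_h`, `p_k`, `p_increment`
#'   (`p_increment[m] = p_k[m] - p_k[m-1]`, with `p_increment[0] = 0`).
#' @examples
#' evaluate_curve(multihit_params(G = 3, h = 2, k = 1), m_max = 3)
#' @export
evaluate_curve <- function(params, m_max = 5000L) {
  stopifnot(inherits(params, "multihit_params"), m_max >= 1)
  ph <- ph_curve(params$G, params$h, m_max)
  pk <- pk_from_ph(ph, params$k)
  tibble::tibble(
    m = 0:m_max,
    p_h = ph,
    p_k = pk,
    p_increment = c(0, pmax(diff(pk), 0))
  )
}

#' Exact enumeration reference for the single-combination probability
#'
#' Enumerates all `G^m` equally likely mutation sequences over loci
#' `1..G` and returns the exact fraction in which every locus in
#' `hit_loci` appears at least once. Serves as an independent exact oracle
#' for [prob_single_combination()] at small `G` and `m`; refuses when
#' `G^m` exceeds the enumeration cap.
#'
#' @param G Number of loci (small integer).
#' @param hit_loci Integer vector of distinct target loci in `1..G`
#'   (may be empty, in which case the probability is 1).
#' @param m Number of mutations drawn (small non-negative integer).
#' @param cap Maximum number of sequences to enumerate (default 2e6).
#'
#' @return A list with integer-valued `numerator`, `denominator` (= `G^m`)
#'   and their ratio `probability`.
#' @examples
#' brute_force_reference(G = 3, hit_loci = c(1, 2), m = 2) # 2/9
#' @export
brute_force_reference <- function(G, hit_loci, m, cap = 2e6) {
  stopifnot(G >= 1, m >= 0, m == round(m))
  hit_loci <- unique(as.integer(hit_loci))
  if (length(hit_loci) && (min(hit_loci) < 1 || max(hit_loci) > G)) {
    stop("`hit_loci` must lie in 1..G.", call. = FALSE)
  }
  total <- G^m
  if (total > cap) {
    stop(sprintf("G^m = %g exceeds the enumeration cap (%g).", total, cap),
         call. = FALSE)
  }
  if (m == 0) {
    hits <- if (length(hit_loci) == 0) 1 else 0
  } else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(G)), m)))
    covered <- rep(TRUE, nrow(seqs))
    for (locus in hit_loci) {
      covered <- covered & (rowSums(seqs == locus) > 0)
    }
    hits <- sum(covered)
  }
  list(numerator = hits, denominator = total, probability = hits / total)
}
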