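# Published per-h search ranges for k (log10 exponents): the RMSD local
# minima for h = 1..9 hits lie in 1e3-1e6, 1e8-1e12, 1e12-1e17, 1e16-1e22,
# 1e20-1e27, 1e27-1e33, 1e30-1e38, 1e34-1e43 and 1e37-1e48 respectively.
K_RANGE_EXPONENTS <- list(
  c(3, 6), c(8, 12), c(12, 17), c(16, 22), c(20, 27),
  c(27, 33), c(30, 38), c(34, 43), c(37, 48)
)

#' Coarse search grid for the number of combinations k
#'
#' Single-digit mantissas 1..9 across every decade of the published search
#' range for a given number of hits, plus the range's upper bound. Fitted k
#' values are reported at mantissa-decade resolution (e.g. 9e14), which this
#' grid reproduces; [fit_single()] adds a log-spaced refinement pass around
#' the coarse minimum.
#'
#' @param h Number of hits, 1..9.
#' @return Sorted numeric vector of k values.
#' @export
k_search_grid <- function(h) {
  if (h < 1 || h > length(K_RANGE_EXPONENTS)) {
    stop("`h` must be in 1..9 (the published search ranges).", call. = FALSE)
  }
  ex <- K_RANGE_EXPONENTS[[h]]
  decades <- ex[1]:(ex[2] - 1L)
  sort(unique(c(as.vector(outer(1:9, 10^decades)), 10^ex[2])))
}

# percentage-per-bin matrix (one row per k) from log(1 - P_h) at bin edges
pct_rows_from_lp <- function(lp_edges, k) {
  pk <- -expm1(outer(k, lp_edges))
  100 * pmax(pk[, -1L, drop = FALSE] - pk[, -ncol(pk), drop = FALSE], 0)
}

row_rmsd <- function(pct, o) {
  sqrt(rowMeans((pct - matrix(o, nrow(pct), length(o), byrow = TRUE))^2))
}

# observed bin percentages without the user-facing overflow warning
obs_pct <- function(counts, bin_width, n_bins) {
  kept <- counts[counts <= bin_width * n_bins]
  if (length(kept) == 0) return(numeric(n_bins))
  100 * tabulate(bin_index(kept, bin_width), nbins = n_bins) / length(kept)
}

#' Precompute model bin percentages over the (h, k) search grid
#'
#' For one value of `G`, computes `P_h` once per `h` (the expensive part),
#' stores `log(1 - P_h)` at the bin edges, and tabulates model bin
#' percentages for every coarse-grid `k`. Fitting, bootstrapping and
#' subsampling against the same `G` then reduce to cheap matrix operations,
#' so pass one grid to repeated calls.
#'
#' @param G Number of possible fixable somatic mutations.
#' @param h_range Integer vector of hit numbers to cover (default 1..9).
#' @param bin_width,n_bins Binning of the comparison (defaults 100 and 50,
#'   covering mutation counts 0-5000).
#' @return A `multihit_model_grid` object.
#' @seealso [fit_single()], [fit_mixture()], [bootstrap_hit_ci()]
#' @export
build_model_grid <- function(G, h_range = 1:9, bin_width = 100L, n_bins = 50L) {
  stopifnot(G >= 1, all(h_range >= 1), bin_width >= 1, n_bins >= 1)
  m_max <- bin_width * n_bins
  edges <- as.integer(bin_width) * (0:n_bins)
  per_h <- lapply(h_range, function(h) {
    ph_edges <- ph_curve(G, h, m_max)[edges + 1L]
    lp <- log1p(-pmin(ph_edges, 1))
    k <- k_search_grid(h)
    list(h = h, k = k, lp = lp, pct = pct_rows_from_lp(lp, k))
  })
  structure(
    list(G = G, h_range = as.integer(h_range), bin_width = as.integer(bin_width),
         n_bins = as.integer(n_bins), per_h = per_h),
    class = "multihit_model_grid"
  )
}

# smallest-rmsd row with ties (within tol) broken toward smaller h, then k
pick_best_row <- function(df, tol = 1e-9) {
  cand <- df[df$rmsd <= min(df$rmsd) + tol, , drop = FALSE]
  cand[order(cand$h, cand$k), , drop = FALSE][1L, , drop = FALSE]
}

refine_k_values <- function(k_center, n_points = 20L, half_decades = 0.5) {
  # the center is kept among the candidates so refinement can never
  # do worse than the coarse minimum
  sort(c(k_center,
         10^seq(log10(k_center) - half_decades, log10(k_center) + half_decades,
                length.out = n_points)))
}

#' Fit the optimal multi-combination multi-hit model to a cohort
#'
#' Estimates the number of hits `h` and the number of combinations `k` for a
#' cohort of per-sample somatic mutation counts by minimizing the RMSD
#' between the observed binned distribution and the model's binned
#' probability mass. For each `h` in `h_range`, `k` is swept over the
#' mantissa-decade grid of the published per-h search range
#' ([k_search_grid()]) followed by one refinement pass of 20 log-spaced
#' points within half a decade of the coarse minimum. Ties within 1e-9
#' RMSD are broken toward smaller `h`, then smaller `k` (parsimony).
#'
#' Cohorts with fewer than 200 samples trigger a warning: estimates are
#' robust above that size, unstable below it.
#'
#' @param cohort A cohort tibble with a `mutation_count` column, or a bare
#'   numeric vector of counts.
#' @param G Number of possible fixable somatic mutations (default
#'   [default_genome_target_count()]).
#' @param h_range Hit numbers to search (default 1..9).
#' @param bin_width,n_bins Binning of the comparison (defaults 100, 50).
#' @param refine If `TRUE` (default), run the refinement pass.
#' @param grid Optional precomputed [build_model_grid()] for the same
#'   `(G, h_range, bin_width, n_bins)`; built on the fly when `NULL`.
#'
#' @return A `multihit_fit` object: `best` ([multihit_params()]),
#'   `rmsd_percent`, `per_h` (tibble of the per-h profile `h`, `k`, `rmsd`),
#'   `evaluations` (every grid point evaluated), `observed` (the binned
#'   distribution), `n_samples`, `settings`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cohort <- sample_cohort(multihit_params(h = 3, k = 9e14), n_samples = 300,
#'                         seed = 1)
#' fit <- fit_single(cohort)
#' glance(fit)
#' @export
fit_single <- function(cohort, G = default_genome_target_count(),
                       h_range = 1:9, bin_width = 100L, n_bins = 50L,
                       refine = TRUE, grid = NULL) {
  counts <- if (is.data.frame(cohort)) cohort$mutation_count else cohort
  if (is.null(counts) || length(counts) == 0) {
    stop("Cohort is empty; nothing to fit.", call. = FALSE)
  }
  if (length(counts) < 200) {
    warning(sprintf(
      "Cohort has %d samples; estimates are robust for sample size greater than 200.",
      length(counts)), call. = FALSE)
  }
  observed <- bin_observed(counts, bin_width = bin_width, n_bins = n_bins)
  if (is.null(grid)) {
    grid <- build_model_grid(G, h_range, bin_width, n_bins)
  } else {
    stopifnot(inherits(grid, "multihit_model_grid"),
              isTRUE(all.equal(grid$G, G)),
              grid$bin_width == bin_width, grid$n_bins == n_bins)
  }
  o <- observed$percent

  evals <- purrr::map(grid$per_h, function(e) {
    coarse <- tibble::tibble(h = e$h, k = e$k, rmsd = row_rmsd(e$pct, o),
                             stage = "coarse")
    out <- coarse
    if (refine) {
      k_best <- pick_best_row(coarse)$k
      k_ref <- refine_k_values(k_best)
      out <- dplyr::bind_rows(out, tibble::tibble(
        h = e$h, k = k_ref,
        rmsd = row_rmsd(pct_rows_from_lp(e$lp, k_ref), o),
        stage = "refine"
      ))
    }
    out
  })
  evaluations <- dplyr::bind_rows(evals)
  per_h <- evaluations |>
    dplyr::group_by(.data$h) |>
    dplyr::group_modify(~ pick_best_row(dplyr::mutate(.x, h = .y$h))[, c("k", "rmsd")]) |>
    dplyr::ungroup()
  best <- pick_best_row(per_h |> dplyr::select("h", "k", "rmsd"))

  structure(
    list(
      best = multihit_params(G = G, h = best$h, k = best$k),
      rmsd_percent = best$rmsd,
      per_h = per_h,
      evaluations = evaluations,
      observed = observed,
      n_samples = length(counts),
      settings = list(G = G, h_range = h_range, bin_width = bin_width,
                      n_bins = n_bins, refine = refine)
    ),
    class = "multihit_fit"
  )
}

#' @export
print.multihit_fit <- function(x, ...) {
  cat(sprintf(
    "<multihit_fit> n = %d samples\n  optimal model: h = %d hits, k = %s combinations, RMSD = %.2f%%\n",
    x$n_samples, x$best$h, format(x$best$k, digits = 3), x$rmsd_percent
  ))
  invisible(x)
}

#' Fit a two-component mixture of hit numbers
#'
#' Some cohorts show multimodal mutation-count distributions better
#' described as `a`% of samples governed by an `hi`-hit model and
#' `(100-a)`% by an `hj`-hit model, with combined probability
#' `P = (a * P_hi + (100 - a) * P_hj) / 100`. This searches every pair
#' `hi < hj` from `h_values`, every share in `a_grid`, and each component's
#' `k` over its coarse mantissa-decade grid jointly, then refines both `k`
#' values (20 log-spaced points, half a decade, one alternating pass).
#'
#' @inheritParams fit_single
#' @param h_values Hit numbers from which component pairs `hi < hj` are
#'   drawn (default 1..9).
#' @param a_grid Candidate shares (percent of `hi`-hit samples), default
#'   10, 20, ..., 90.
#'
#' @return A `multihit_mixture_fit` object: `best`
#'   ([multihit_mixture_params()]), `rmsd_percent`, `pair_profile` (best
#'   RMSD per (hi, hj, a)), `observed`, `n_samples`, `settings`.
#' @examples
#' truth <- multihit_mixture_params(
#'   multihit_params(h = 3, k = 3e14), multihit_params(h = 8, k = 8e39), 40)
#' cohort <- sample_cohort(truth, n_samples = 400, seed = 7)
#' fit_mixture(cohort)
#' @export
fit_mixture <- function(cohort, G = default_genome_target_count(),
                        h_values = 1:9, a_grid = seq(10, 90, by = 10),
                        bin_width = 100L, n_bins = 50L, refine = TRUE,
                        grid = NULL) {
  counts <- if (is.data.frame(cohort)) cohort$mutation_count else cohort
  if (is.null(counts) || length(counts) == 0) {
    stop("Cohort is empty; nothing to fit.", call. = FALSE)
  }
  if (length(h_values) < 2 || length(a_grid) < 1) {
    stop("Need at least two hit numbers and a non-empty share grid.",
         call. = FALSE)
  }
  observed <- bin_observed(counts, bin_width = bin_width, n_bins = n_bins)
  if (is.null(grid)) {
    grid <- build_model_grid(G, h_values, bin_width, n_bins)
  }
  o <- observed$percent
  nb <- length(o)
  o2 <- mean(o^2)
  entries <- grid$per_h
  hs <- vapply(entries, function(e) e$h, integer(1))
  # per-h quadratic pieces reused across pairs and shares
  sq <- lapply(entries, function(e) rowMeans(e$pct^2))
  xo <- lapply(entries, function(e) as.vector(e$pct %*% o) / nb)

  pairs <- expand.grid(i = seq_along(entries), j = seq_along(entries))
  pairs <- pairs[hs[pairs$i] < hs[pairs$j], , drop = FALSE]

  best <- NULL
  profile <- vector("list", nrow(pairs) * length(a_grid))
  idx <- 0L
  for (p in seq_len(nrow(pairs))) {
    ei <- entries[[pairs$i[p]]]; ej <- entries[[pairs$j[p]]]
    cross <- (ei$pct %*% t(ej$pct)) / nb
    for (a in a_grid) {
      w <- a / 100; v <- 1 - w
      # mean squared residual for every (ki, kj) via the quadratic expansion
      q <- outer(w^2 * sq[[pairs$i[p]]] - 2 * w * xo[[pairs$i[p]]],
                 v^2 * sq[[pairs$j[p]]] - 2 * v * xo[[pairs$j[p]]], "+") +
        2 * w * v * cross + o2
      hit <- arrayInd(which.min(q), dim(q))
      rec <- tibble::tibble(
        hi = ei$h, hj = ej$h, a_percent = a,
        ki = ei$k[hit[1]], kj = ej$k[hit[2]],
        rmsd = sqrt(max(q[hit], 0))
      )
      idx <- idx + 1L
      profile[[idx]] <- rec
      if (is.null(best) || rec$rmsd < best$rmsd - 1e-9 ||
          (rec$rmsd < best$rmsd + 1e-9 &&
           (rec$hi < best$hi || (rec$hi == best$hi && rec$hj < best$hj)))) {
        best <- rec
      }
    }
  }
  profile <- dplyr::bind_rows(profile)

  if (refine) {
    ei <- entries[[match(best$hi, hs)]]
    ej <- entries[[match(best$hj, hs)]]
    w <- best$a_percent / 100
    mix_rmsd <- function(ki, kj) {
      pct <- w * pct_rows_from_lp(ei$lp, ki) + (1 - w) * pct_rows_from_lp(ej$lp, kj)
      row_rmsd(pct, o)
    }
    ki_cand <- refine_k_values(best$ki)
    r <- mix_rmsd(ki_cand, rep(best$kj, length(ki_cand)))
    best$ki <- ki_cand[which.min(r)]
    kj_cand <- refine_k_values(best$kj)
    r <- mix_rmsd(rep(best$ki, length(kj_cand)), kj_cand)
    best$kj <- kj_cand[which.min(r)]
    best$rmsd <- min(r)
  }

  structure(
    list(
      best = multihit_mixture_params(
        multihit_params(G = grid$G, h = best$hi, k = best$ki),
        multihit_params(G = grid$G, h = best$hj, k = best$kj),
        share_percent = best$a_percent
      ),
      rmsd_percent = best$rmsd,
      pair_profile = profile,
      observed = observed,
      n_samples = length(counts),
      settings = list(G = grid$G, h_values = h_values, a_grid = a_grid,
                      bin_width = bin_width, n_bins = n_bins, refine = refine)
    ),
    class = "multihit_mixture_fit"
  )
}

#' @export
print.multihit_mixture_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<multihit_mixture_fit> n = %d samples\n  %g%% %d-hit (k = %s) + %g%% %d-hit (k = %s), RMSD = %.2f%%\n",
    x$n_samples, b$share_percent, b$component_i$h,
    format(b$component_i$k, digits = 3), 100 - b$share_percent,
    b$component_j$h, format(b$component_j$k, digits = 3), x$rmsd_percent
  ))
  invisible(x)
}

# best h on the coarse grid only (used by the bootstrap for speed)
coarse_best_h <- function(o, grid) {
  per_h <- dplyr::bind_rows(lapply(grid$per_h, function(e) {
    r <- row_rmsd(e$pct, o)
    i <- which.min(r)
    # within-h tie toward smaller k: which.min already takes the first
    tibble::tibble(h = e$h, k = e$k[i], rmsd = r[i])
  }))
  pick_best_row(per_h)$h
}

#' Percentile-bootstrap confidence interval for the number of hits
#'
#' Resamples the cohort with replacement `n_boot` times, refits the number
#' of hits on the coarse k grid for each resample, and returns the
#' empirical percentile interval of the fitted `h`.
#'
#' @inheritParams fit_single
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param confidence Interval level (default 0.95).
#' @param seed Integer seed; the resampling stream is fully determined by it.
#'
#' @return A list with `h_low`, `h_high`, `confidence`, `n_boot`, the table
#'   `h_table` of refitted hit numbers, and `method` notes.
#' @examples
#' cohort <- sample_cohort(multihit_params(h = 3, k = 9e14), n_samples = 300,
#'                         seed = 1)
#' bootstrap_hit_ci(cohort, n_boot = 50, seed = 2)
#' @export
bootstrap_hit_ci <- function(cohort, G = default_genome_target_count(),
                             n_boot = 1000L, confidence = 0.95, seed = NULL,
                             h_range = 1:9, bin_width = 100L, n_bins = 50L,
                             grid = NULL) {
  counts <- if (is.data.frame(cohort)) cohort$mutation_count else cohort
  if (n_boot < 1) stop("`n_boot` must be >= 1.", call. = FALSE)
  if (length(counts) < 2) stop("Need at least 2 samples.", call. = FALSE)
  if (is.null(grid)) grid <- build_model_grid(G, h_range, bin_width, n_bins)
  n <- length(counts)
  draw <- function() {
    res <- counts[sample.int(n, n, replace = TRUE)]
    coarse_best_h(obs_pct(res, bin_width, n_bins), grid)
  }
  hs <- if (is.null(seed)) {
    vapply(seq_len(n_boot), function(i) draw(), integer(1))
  } else {
    withr::with_seed(seed, vapply(seq_len(n_boot), function(i) draw(), integer(1)))
  }
  alpha <- (1 - confidence) / 2
  ci <- stats::quantile(hs, c(alpha, 1 - alpha), type = 1, names = FALSE)
  list(
    h_low = as.integer(ci[1]), h_high = as.integer(ci[2]),
    confidence = confidence, n_boot = as.integer(n_boot),
    h_table = table(hs),
    method = "percentile bootstrap over samples, coarse k grid refits"
  )
}

#' Stability of the fit under random subsampling
#'
#' Refits the model on seeded random subsets (without replacement) of the
#' cohort and reports whether the fitted `h` and `k` match the full-cohort
#' fit and how much the RMSD moves — the robustness check behind the
#' greater-than-200-samples guidance.
#'
#' @inheritParams fit_single
#' @param fraction Fraction of samples per subset, in (0, 1] (default 0.8).
#' @param n_reps Number of subsets (default 10).
#' @param seed Integer seed for the subset draws.
#'
#' @return A tibble with one row per replicate: `replicate`, `n_subset`,
#'   `h`, `k`, `rmsd`, `h_unchanged`, `k_unchanged`, `delta_rmsd`; the
#'   full-cohort fit is attached as attribute `full_fit`.
#' @export
subsample_stability <- function(cohort, G = default_genome_target_count(),
                                fraction = 0.8, n_reps = 10L, seed = NULL,
                                h_range = 1:9, bin_width = 100L, n_bins = 50L) {
  counts <- if (is.data.frame(cohort)) cohort$mutation_count else cohort
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1].", call. = FALSE)
  }
  n_sub <- floor(fraction * length(counts))
  if (n_sub < 2) stop("Subset would have fewer than 2 samples.", call. = FALSE)
  grid <- build_model_grid(G, h_range, bin_width, n_bins)
  full <- suppressWarnings(fit_single(counts, G = G, h_range = h_range,
                                      bin_width = bin_width, n_bins = n_bins,
                                      grid = grid))
  one_rep <- function(rep) {
    sub <- counts[sample.int(length(counts), n_sub, replace = FALSE)]
    f <- suppressWarnings(fit_single(sub, G = G, h_range = h_range,
                                     bin_width = bin_width, n_bins = n_bins,
                                     grid = grid))
    tibble::tibble(
      replicate = rep, n_subset = n_sub, h = f$best$h, k = f$best$k,
      rmsd = f$rmsd_percent,
      h_unchanged = f$best$h == full$best$h,
      k_unchanged = isTRUE(all.equal(f$best$k, full$best$k)),
      delta_rmsd = f$rmsd_percent - full$rmsd_percent
    )
  }
  run <- function() dplyr::bind_rows(lapply(seq_len(n_reps), one_rep))
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "full_fit") <- full
  out
}

#' Sensitivity of the fit to the genome target count G
#'
#' Refits the model with `G` scaled by each factor — e.g. a factor of 8
#' emulates all somatic mutations falling in one eighth of the assayed
#' region — and reports the fitted parameters per factor. The estimated
#' number of hits is expected to be unchanged across large changes in `G`.
#'
#' @inheritParams fit_single
#' @param G_factors Positive scale factors applied to `G` (default `c(1, 8)`).
#'
#' @return A tibble with one row per factor: `G_factor`, `G`, `h`, `k`,
#'   `rmsd`, `h_unchanged` (vs factor closest to 1); fits attached as
#'   attribute `fits`.
#' @export
sensitivity_G <- function(cohort, G_factors = c(1, 8),
                          G = default_genome_target_count(), h_range = 1:9,
                          bin_width = 100L, n_bins = 50L) {
  stopifnot(all(G_factors > 0))
  fits <- lapply(G_factors, function(f) {
    suppressWarnings(fit_single(cohort, G = G * f, h_range = h_range,
                                bin_width = bin_width, n_bins = n_bins))
  })
  ref <- fits[[which.min(abs(G_factors - 1))]]
  out <- dplyr::bind_rows(lapply(seq_along(G_factors), function(i) {
    tibble::tibble(
      G_factor = G_factors[i], G = G * G_factors[i],
      h = fits[[i]]$best$h, k = fits[[i]]$best$k,
      rmsd = fits[[i]]$rmsd_percent,
      h_unchanged = fits[[i]]$best$h == ref$best$h
    )
  }))
  attr(out, "fits") <- fits
  out
}
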