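#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-h profile of a single-model fit
#'
#' One row per number of hits searched, with the best `k` and RMSD at that
#' `h` — the fit's profile over the hit number.
#'
#' @param x A `multihit_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `h`, `k`, `rmsd`, `best`.
#' @method tidy multihit_fit
#' @export
tidy.multihit_fit <- function(x, ...) {
  dplyr::mutate(x$per_h, best = .data$h == x$best$h)
}

#' One-row summary of a single-model fit
#'
#' @param x A `multihit_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `h`, `k`, `rmsd_percent`, `n_samples`,
#'   `n_overflow`, `G`.
#' @method glance multihit_fit
#' @export
glance.multihit_fit <- function(x, ...) {
  tibble::tibble(
    h = x$best$h, k = x$best$k, rmsd_percent = x$rmsd_percent,
    n_samples = x$n_samples,
    n_overflow = attr(x$observed, "n_overflow"),
    G = x$settings$G
  )
}

#' Tidy the (hi, hj, a) profile of a mixture fit
#'
#' @param x A `multihit_mixture_fit` object.
#' @param ... Unused.
#' @return A tibble with the best RMSD for every component pair and share
#'   evaluated on the coarse grid.
#' @method tidy multihit_mixture_fit
#' @export
tidy.multihit_mixture_fit <- function(x, ...) {
  x$pair_profile
}

#' One-row summary of a mixture fit
#'
#' @param x A `multihit_mixture_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `hi`, `hj`, `a_percent`, `ki`, `kj`,
#'   `rmsd_percent`, `n_samples`.
#' @method glance multihit_mixture_fit
#' @export
glance.multihit_mixture_fit <- function(x, ...) {
  b <- x$best
  tibble::tibble(
    hi = b$component_i$h, hj = b$component_j$h,
    a_percent = b$share_percent,
    ki = b$component_i$k, kj = b$component_j$k,
    rmsd_percent = x$rmsd_percent, n_samples = x$n_samples
  )
}
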