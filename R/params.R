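#' Model parameters for the multi-combination multi-hit model
#'
#' Bundles the triple (G, h, k) that defines one multi-combination multi-hit
#' model of carcinogenesis: `G` possible somatic mutations that can become
#' fixed in the assayed genome region, `h` hits (specific carcinogenic
#' mutations) needed to complete a combination, and `k` alternative
#' combinations, any one of which suffices for carcinogenesis.
#'
#' `k` is treated as a positive real rather than an integer because the
#' fitting grid spans roughly 1e3 to 1e48 and the cumulative probability is
#' smooth in `k`.
#'
#' @param G Number of possible somatic mutations that can become fixed
#'   (positive; defaults to [default_genome_target_count()], the
#'   whole-exome value).
#' @param h Number of hits required for carcinogenesis (integer, `1 <= h <= G`).
#' @param k Number of alternative h-hit combinations (real, `k >= 1`).
#'
#' @return An object of class `multihit_params`.
#' @examples
#' multihit_params(h = 3, k = 9e14)
#' multihit_params(G = 3, h = 2, k = 1)
#' @export
multihit_params <- function(G = default_genome_target_count(), h, k) {
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 1) {
    stop("`G` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 1 ||
      h != round(h)) {
    stop("`h` must be a single positive integer.", call. = FALSE)
  }
  if (h > G) {
    stop("`h` must not exceed `G` (cannot require more hits than loci).",
         call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1) {
    stop("`k` must be a single real number >= 1.", call. = FALSE)
  }
  structure(
    list(G = as.numeric(G), h = as.integer(h), k = as.numeric(k)),
    class = "multihit_params"
  )
}

#' @export
print.multihit_params <- function(x, ...) {
  cat(sprintf(
    "<multihit_params> G = %s, h = %d, k = %s\n",
    format(x$G, big.mark = ","), x$h, format(x$k, digits = 3)
  ))
  invisible(x)
}

#' Two-component mixture of multi-hit models
#'
#' Describes a cohort in which `share_percent`% of samples follow an
#' `hi`-hit model and the remainder an `hj`-hit model. The combined
#' per-mutation probability is the share-weighted mean of the component
#' probabilities.
#'
#' @param component_i,component_j [multihit_params()] objects; conventionally
#'   `component_i$h < component_j$h`.
#' @param share_percent Percentage of samples governed by `component_i`,
#'   strictly between 0 and 100.
#'
#' @return An object of class `multihit_mixture_params`.
#' @examples
#' multihit_mixture_params(
#'   multihit_params(h = 3, k = 3e14),
#'   multihit_params(h = 8, k = 8e39),
#'   share_percent = 40
#' )
#' @export
multihit_mixture_params <- function(component_i, component_j, share_percent) {
  stopifnot(inherits(component_i, "multihit_params"),
            inherits(component_j, "multihit_params"))
  if (!is.numeric(share_percent) || length(share_percent) != 1L ||
      share_percent <= 0 || share_percent >= 100) {
    stop("`share_percent` must be strictly between 0 and 100.", call. = FALSE)
  }
  structure(
    list(component_i = component_i, component_j = component_j,
         share_percent = as.numeric(share_percent)),
    class = "multihit_mixture_params"
  )
}

#' @export
print.multihit_mixture_params <- function(x, ...) {
  cat(sprintf(
    "<multihit_mixture_params> %g%% of (h = %d, k = %s) + %g%% of (h = %d, k = %s)\n",
    x$share_percent, x$component_i$h, format(x$component_i$k, digits = 3),
    100 - x$share_percent, x$component_j$h, format(x$component_j$k, digits = 3)
  ))
  invisible(x)
}
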