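test_that("fit recovers known parameters from a simulated cohort", {
  cohort <- fixture_cohort_h3()
  fit <- fit_single(cohort, grid = default_grid())
  expect_s3_class(fit, "multihit_fit")
  expect_equal(fit$best$h, 3)
  # true k = 9e14 within one mantissa step at the fitted h
  expect_lt(abs(log10(fit$best$k) - log10(9e14)), log10(2) + 0.05)
  expect_equal(nrow(fit$per_h), 9)
  expect_equal(fit$rmsd_percent, min(fit$evaluations$rmsd))

  g <- glance(fit)
  expect_equal(g$h, 3)
  expect_equal(g$n_samples, 500)
  expect_true(sum(tidy(fit)$best) == 1)
})

test_that("fit is invariant to sample order and id relabeling", {
  cohort <- fixture_cohort_h3()
  shuffled <- cohort[rev(seq_len(nrow(cohort))), ]
  shuffled$sample_id <- paste0("X", seq_len(nrow(shuffled)))
  f1 <- fit_single(cohort, grid = default_grid())
  f2 <- fit_single(shuffled, grid = default_grid())
  expect_identical(glance(f1)[c("h", "k", "rmsd_percent")],
                   glance(f2)[c("h", "k", "rmsd_percent")])
})

test_that("fit warns on small cohorts and rejects empty ones", {
  small <- sample_cohort(multihit_params(h = 2, k = 2e9), 50, seed = 2)
  expect_warning(fit_single(small, grid = default_grid()), "200")
  expect_error(fit_single(numeric(0)), "empty")
  expect_error(suppressWarnings(fit_single(tibble::tibble())), "empty")
})

test_that("coarse k grid covers the published per-h decade ranges", {
  expect_equal(range(k_search_grid(1)), c(1e3, 1e6))
  expect_equal(range(k_search_grid(9)), c(1e37, 1e48))
  expect_true(9e14 %in% k_search_grid(3))
  expect_true(all(diff(k_search_grid(5)) > 0))
  expect_error(k_search_grid(10), "1..9")
})

test_that("mixture fit recovers bracketing components on a mixed cohort", {
  truth <- multihit_mixture_params(multihit_params(h = 3, k = 3e14),
                                   multihit_params(h = 8, k = 8e39), 40)
  cohort <- sample_cohort(truth, n_samples = 500, seed = 1)
  mf <- fit_mixture(cohort)
  g <- glance(mf)
  expect_equal(c(g$hi, g$hj), c(3, 8))
  expect_lte(abs(g$a_percent - 40), 10)
  expect_lt(mf$rmsd_percent,
            suppressWarnings(fit_single(cohort, grid = default_grid()))$rmsd_percent)
})

test_that("on a pure cohort the mixture brackets h and fits about as well", {
  cohort <- fixture_cohort_h3()
  single <- fit_single(cohort, grid = default_grid())
  mf <- fit_mixture(cohort)
  g <- glance(mf)
  expect_lte(g$hi, single$best$h)
  expect_gte(g$hj, single$best$h)
  expect_lte(mf$rmsd_percent, single$rmsd_percent + 0.2)
})

test_that("mixture fit validates its grids", {
  expect_error(fit_mixture(fixture_cohort_h3(), h_values = 3), "two hit numbers")
  expect_error(fit_mixture(numeric(0)), "empty")
})

test_that("bootstrap CI is reproducible and covers a strong signal", {
  cohort <- fixture_cohort_h3()
  ci <- bootstrap_hit_ci(cohort, n_boot = 100, seed = 7, grid = default_grid())
  expect_lte(ci$h_low, 3)
  expect_gte(ci$h_high, 3)
  ci2 <- bootstrap_hit_ci(cohort, n_boot = 100, seed = 7, grid = default_grid())
  expect_identical(ci[c("h_low", "h_high")], ci2[c("h_low", "h_high")])
  # degenerate case: every refit lands on the same h
  expect_identical(unname(ci$h_table[names(ci$h_table) == "3"] > 90), TRUE)
  expect_error(bootstrap_hit_ci(cohort, n_boot = 0), "n_boot")
  expect_error(bootstrap_hit_ci(c(5), n_boot = 10), "2 samples")
})

test_that("subsampling 80% of a 500-sample cohort leaves h unchanged", {
  rep_tbl <- subsample_stability(fixture_cohort_h3(), n_reps = 5, seed = 99)
  expect_true(all(rep_tbl$h_unchanged))
  expect_equal(nrow(rep_tbl), 5)
  expect_equal(unique(rep_tbl$n_subset), 400)

  # fraction = 1 refits on a permutation: identical fit, zero RMSD change
  full <- subsample_stability(fixture_cohort_h3(), fraction = 1, n_reps = 2,
                              seed = 1)
  expect_true(all(full$h_unchanged & full$k_unchanged))
  expect_equal(full$delta_rmsd, c(0, 0))

  expect_error(subsample_stability(fixture_cohort_h3(), fraction = 0),
               "fraction")
  expect_error(subsample_stability(c(10, 20), fraction = 0.5), "fewer than 2")
})

test_that("the estimated h is insensitive to an 8-fold change in G", {
  out <- sensitivity_G(fixture_cohort_h3(), G_factors = c(1, 8))
  expect_true(all(out$h_unchanged))
  expect_equal(out$h[1], out$h[2])
  # factor 1 reproduces the plain fit
  plain <- fit_single(fixture_cohort_h3(), grid = default_grid())
  expect_equal(out$h[1], plain$best$h)
  expect_equal(out$k[1], plain$best$k)
  expect_equal(out$rmsd[1], plain$rmsd_percent)
})

test_that("fit objects plot without error", {
  fit <- fit_single(fixture_cohort_h3(), grid = default_grid())
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  curve_plot <- plot_probability_curve(fit$best, m_max = 500)
  expect_s3_class(curve_plot, "ggplot")
})
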