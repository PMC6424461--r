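test_that("single-combination probability matches exhaustive enumeration", {
  for (G in 2:5) {
    for (h in 1:3) {
      if (h > G) next
      p <- multihit_params(G = G, h = h, k = 1)
      for (m in 0:5) {
        expected <- brute_force_reference(G, seq_len(h), m)$probability
        expect_equal(prob_single_combination(p, m), expected,
                     tolerance = 1e-12,
                     label = sprintf("P_h(G=%d,h=%d,m=%d)", G, h, m))
      }
    }
  }
})

test_that("hand-derived P_h values are reproduced", {
  p32 <- multihit_params(G = 3, h = 2, k = 1)
  expect_equal(prob_single_combination(p32, 2), 2 / 9, tolerance = 1e-14)
  expect_equal(prob_single_combination(p32, 3), 4 / 9, tolerance = 1e-14)
  expect_identical(prob_single_combination(p32, 1), 0)
  expect_identical(prob_single_combination(p32, 0), 0)
  # one-hit closed form 1 - ((G-1)/G)^m
  p101 <- multihit_params(G = 10, h = 1, k = 1)
  expect_equal(prob_single_combination(p101, 3), 1 - (9 / 10)^3,
               tolerance = 1e-14)
})

test_that("one-hit closed form holds across a parameter grid", {
  for (G in c(2, 7, 1e3, 1.0725e8)) {
    p <- multihit_params(G = G, h = 1, k = 1)
    m <- c(1, 5, 50, 500, 5000)
    # stable evaluation of the same formula (see acceptance test)
    expect_equal(prob_single_combination(p, m), -expm1(m * log1p(-1 / G)),
                 tolerance = 1e-12)
  }
})

test_that("parameter validation rejects out-of-domain triples", {
  expect_error(multihit_params(G = 3, h = 4, k = 1), "exceed")
  expect_error(multihit_params(G = 3, h = 0, k = 1), "positive integer")
  expect_error(multihit_params(G = 3, h = 2, k = 0.5), ">= 1")
  expect_error(multihit_params(G = -1, h = 1, k = 1), "positive")
  expect_error(prob_single_combination(multihit_params(G = 3, h = 2, k = 1), -1),
               "non-negative")
})

test_that("cumulative probability follows 1 - (1 - P_h)^k", {
  # k = 1 reduces exactly to the single-combination probability
  p1 <- multihit_params(G = 50, h = 2, k = 1)
  m <- 0:20
  expect_equal(prob_any_combination(p1, m), prob_single_combination(p1, m),
               tolerance = 1e-15)
  # G=2, h=1, m=1 gives P_h = 1/2; with k = 2: 1 - 0.25 = 0.75
  expect_equal(prob_any_combination(multihit_params(G = 2, h = 1, k = 2), 1),
               0.75, tolerance = 1e-15)
})

test_that("cumulative probability is monotone in m, k and h", {
  G <- 1.0725e8
  for (h in c(2, 5, 8)) {
    p <- multihit_params(G = G, h = h, k = 1e3 * 10^(2 * h))
    pk <- prob_any_combination(p, 0:2000)
    expect_true(all(diff(pk) >= 0), label = sprintf("monotone in m, h=%d", h))
  }
  m <- c(100, 1000, 5000)
  for (kk in 10^c(10, 12, 14)) {
    lo <- prob_any_combination(multihit_params(G = G, h = 3, k = kk), m)
    hi <- prob_any_combination(multihit_params(G = G, h = 3, k = kk * 10), m)
    expect_true(all(hi >= lo), label = "monotone in k")
  }
  for (h in 1:8) {
    lo <- prob_any_combination(multihit_params(G = G, h = h + 1, k = 1e9), m)
    hi <- prob_any_combination(multihit_params(G = G, h = h, k = 1e9), m)
    expect_true(all(hi >= lo), label = sprintf("non-increasing in h at h=%d", h))
  }
})

test_that("large-k cumulative probabilities match the arbitrary-precision reference", {
  ref <- read.csv(test_path("pk-reference-highprec.csv"))
  calc <- mapply(function(G, h, k, m) {
    prob_any_combination(multihit_params(G = G, h = h, k = k), m)
  }, ref$G, ref$h, ref$k, ref$m)
  expect_equal(calc, ref$p_k, tolerance = 1e-9)
  # strictly increasing with m while in the interior of (0, 1)
  interior <- subset(ref, G == 1.0725e8 & h == 8)
  expect_true(all(diff(interior$p_k) >= 0))
})

test_that("increment telescopes back to the cumulative probability", {
  p <- multihit_params(G = 3, h = 2, k = 1)
  expect_equal(prob_increment(p, 2), 2 / 9, tolerance = 1e-14)
  expect_equal(prob_increment(p, 3), 2 / 9, tolerance = 1e-14)
  expect_identical(prob_increment(p, 1), 0)
  expect_error(prob_increment(p, 0), "m")
  for (pars in list(multihit_params(G = 1e6, h = 2, k = 1e4),
                    multihit_params(G = 1.0725e8, h = 5, k = 2e25))) {
    M <- 3000
    expect_equal(sum(prob_increment(pars, 1:M)),
                 prob_any_combination(pars, M), tolerance = 1e-12)
    expect_true(all(prob_increment(pars, 1:M) >= 0))
  }
})

test_that("evaluate_curve returns consistent sequences", {
  cur <- evaluate_curve(multihit_params(G = 3, h = 2, k = 1), m_max = 3)
  expect_equal(cur$p_k, c(0, 0, 2 / 9, 4 / 9), tolerance = 1e-14)
  expect_equal(cur$m, 0:3)

  cur <- evaluate_curve(multihit_params(G = 1e4, h = 3, k = 50), m_max = 400)
  expect_true(all(cur$p_h >= 0 & cur$p_h <= 1))
  expect_true(all(cur$p_k >= 0 & cur$p_k <= 1))
  expect_true(all(diff(cur$p_k) >= 0))
  expect_true(all(cur$p_h[cur$m < 3] == 0))
  expect_equal(cumsum(cur$p_increment[-1]), cur$p_k[-1], tolerance = 1e-12)
  # at m_max = h the first increment is the whole cumulative probability
  tiny <- evaluate_curve(multihit_params(G = 9, h = 4, k = 2), m_max = 4)
  expect_equal(tiny$p_increment[5], tiny$p_k[5], tolerance = 1e-15)
})

test_that("brute-force reference enumerates exactly and refuses huge jobs", {
  expect_equal(brute_force_reference(3, c(1, 2), 2),
               list(numerator = 2, denominator = 9, probability = 2 / 9))
  expect_equal(brute_force_reference(2, 1, 1)$probability, 0.5)
  expect_equal(brute_force_reference(4, 1:4, 3)$probability, 0)
  expect_equal(brute_force_reference(3, integer(0), 0)$probability, 1)
  expect_error(brute_force_reference(8, 1:2, 8), "cap")
  expect_error(brute_force_reference(3, c(1, 5), 2), "1..G")
})

test_that("combination-count and genome-target constants are reproduced", {
  expect_equal(estimate_combination_count(1000, 2, 50, h = 2), 1e10)
  expect_equal(estimate_combination_count(1000, 2, 50, h = 8), 1e40)
  expect_equal(estimate_combination_count(1000, 2, 50, h = 1), 1e5)
  expect_equal(default_genome_target_count(), 3.25e9 * 2 * 1.1 * 1.5 / 100)
  expect_equal(default_genome_target_count(), 1.0725e8)
  expect_lt(default_genome_target_count(), 6.5e9)
  expect_equal(8 * default_genome_target_count(), 8.58e8)
})
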