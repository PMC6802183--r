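test_that("ATP-oxygen map has the half-max, limit and monotonicity properties", {
  m <- atp_model()
  expect_identical(atp_level(0.033, m), 1500)
  expect_equal(atp_level(1, m), 3000 / 1.033)
  expect_lt(atp_level(1e-9, m), 1e-4)
  f <- 10^seq(-4, 0, length.out = 50)
  a <- atp_level(f, m)
  expect_true(all(diff(a) > 0))
  expect_true(all(a < m$atp_normoxia))
  expect_error(atp_level(0), "o2_fraction")
  expect_error(atp_level(-0.1), "o2_fraction")
})

test_that("K^AB calibration reproduces K' and has the km->0 limit", {
  expect_equal(calibrate_kab(10, 100, 3e6), 10 / (100 / 3e6 + 1))
  expect_equal(calibrate_kab(10, 1e-9, 3e6), 10, tolerance = 1e-9)
  # round-trip: ATP-explicit rate at calibration ATP equals the original law
  for (kp in c(5, 50, 500)) {
    law <- phospho_law(vmax = 2, k_m_atp = 100, k_prime = kp,
                       atp_normoxia = 3e6)
    p <- c(0.1, 1, 10, 100, 1000)
    expect_equal(phospho_rate(3e6, p, law), 2 * p / (kp + p),
                 tolerance = 1e-12)
  }
})

test_that("phosphorylation rate is bounded, monotone and matches direct substitution", {
  law <- phospho_law(vmax = 1, k_m_atp = 0.1, k_ab = 10)
  expect_identical(phospho_rate(3000, 0, law), 0)
  # direct substitution oracle
  expected <- 1 * 3000 * 10 / (0.1 * 10 + 10 * 3000 + 3000 * 10)
  expect_equal(phospho_rate(3000, 10, law), expected)
  expect_equal(expected, 0.499992, tolerance = 1e-6)
  # monotone in atp and protein, bounded by vmax
  atp <- 10^seq(0, 5, length.out = 30)
  r_atp <- phospho_rate(atp, 10, law)
  expect_true(all(diff(r_atp) > 0))
  p <- 10^seq(-2, 4, length.out = 30)
  r_p <- phospho_rate(1000, p, law)
  expect_true(all(diff(r_p) > 0))
  expect_true(all(r_p < law$vmax))
  # atp -> infinity limit reduces to the ATP-implicit form
  expect_equal(phospho_rate(1e12, 25, law), 1 * 25 / (10 + 25),
               tolerance = 1e-6)
  expect_error(phospho_rate(0, 1, law), "atp")
})

test_that("ATP-competitive inhibition reduces to the uninhibited law at zero dose and has the documented floor", {
  law <- phospho_law(vmax = 1, k_m_atp = 0.1, k_ab = 10)
  grid <- expand.grid(atp = c(10, 3000), p = c(0.5, 10, 200))
  for (i in seq_len(nrow(grid))) {
    expect_identical(
      phospho_rate_inhibited(grid$atp[i], grid$p[i], 0, law),
      phospho_rate(grid$atp[i], grid$p[i], law))
  }
  # strictly decreasing in dose
  d <- c(0, 1, 10, 100, 1e4)
  r <- phospho_rate_inhibited(3000, 10, d, law)
  expect_true(all(diff(r) < 0))
  # direct substitution at d = 100
  expect_equal(phospho_rate_inhibited(3000, 10, 100, law),
               1 * 3000 * 10 / (0.1 * 10 * 101 + 10 * 3000 + 3000 * 10))
  # competition floor: with the K_M,ATP term negligible the rate tends to
  # vmax*P/(K^AB+P), not zero
  expect_equal(phospho_rate_inhibited(3e6, 10, 1e3, law), 1 * 10 / (10 + 10),
               tolerance = 1e-3)
  expect_error(phospho_rate_inhibited(3000, 10, -1, law), "d_over_ki")
})

test_that("VEGF synthesis law amplifies the mRNA ratio with exponent k_alpha", {
  law <- vegf_synthesis_law(k_syn_original = 3, k_alpha = 2, mrna0 = 5)
  expect_identical(vegf_synthesis_rate(5, law), 3)
  expect_identical(vegf_synthesis_rate(10, law), 12)
  expect_identical(vegf_synthesis_rate(0, law), 0)
  expect_error(vegf_synthesis_rate(-1, law), "mrna")
})

test_that("VEGF binding inhibition divides only the forward term", {
  law <- vegf_binding_law(k1f = 2e-3, k1r = 0.05)
  base <- vegf_binding_rate(10, 100, 7, 0, law)
  expect_equal(base, 2e-3 * 10 * 100 - 0.05 * 7)
  half <- vegf_binding_rate(10, 100, 7, 1, law)
  expect_equal(half + 0.05 * 7, (base + 0.05 * 7) / 2)
  expect_equal(vegf_binding_rate(10, 100, 7, 1e12, law), -0.05 * 7,
               tolerance = 1e-9)
})

test_that("rate laws are homogeneous under consistent unit rescaling", {
  lambda <- 1000 # e.g. nM -> pM
  law1 <- phospho_law(vmax = 1, k_m_atp = 0.1, k_ab = 10)
  law2 <- phospho_law(vmax = 1, k_m_atp = 0.1 * lambda, k_ab = 10 * lambda)
  expect_equal(phospho_rate_inhibited(3000, 10, 5, law1),
               phospho_rate_inhibited(3000 * lambda, 10 * lambda, 5, law2))
  b1 <- vegf_binding_law(2e-3, 0.05)
  b2 <- vegf_binding_law(2e-3 / lambda, 0.05)
  expect_equal(vegf_binding_rate(10, 100, 7, 2, b1) * lambda,
               vegf_binding_rate(10 * lambda, 100 * lambda, 7 * lambda, 2, b2))
})
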