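test_that("effective pressure follows the Starling balance and ignores conductivities", {
  p <- tissue_parameters(K = 1, Lp = 1, SV = 1, pv = 10, sigma = 1,
                         pi_v = 10, pi_i = 10)
  expect_equal(effective_pressure(p), 10)            # zero osmotic difference
  p2 <- tissue_parameters(K = 1, Lp = 1, SV = 1, pv = 7.3, sigma = 0,
                          pi_v = 33, pi_i = 2)
  expect_equal(effective_pressure(p2), 7.3)          # sigma = 0 removes osmosis
  p3 <- tissue_parameters(K = 1, Lp = 1, SV = 1, pv = 15.6, sigma = 0.8,
                          pi_v = 20, pi_i = 15)
  expect_equal(effective_pressure(p3), 15.6 - 0.8 * 5)
  # independent of K, Lp, SV
  p4 <- tissue_parameters(K = 99, Lp = 0.5, SV = 123, pv = 15.6, sigma = 0.8,
                          pi_v = 20, pi_i = 15)
  expect_equal(effective_pressure(p4), effective_pressure(p3))
})

test_that("steady-state pressure interpolates between p_e and pL", {
  lymph_free <- tissue_parameters(K = 1, Lp = 2, SV = 3, pv = 12, sigma = 0.5,
                                  pi_v = 8, pi_i = 4, lymph_coeff = 0)
  expect_identical(steady_state_pressure(lymph_free),
                   effective_pressure(lymph_free))
  only_lymph <- tissue_parameters(K = 1, Lp = 0, SV = 3, pv = 12, sigma = 0.5,
                                  pi_v = 8, pi_i = 4, lymph_coeff = 2, pL = -1)
  expect_equal(steady_state_pressure(only_lymph), -1)
  balanced <- tissue_parameters(K = 1, Lp = 1, SV = 5, pv = 20, sigma = 0,
                                pi_v = 0, pi_i = 0, lymph_coeff = 5, pL = 0)
  expect_equal(steady_state_pressure(balanced), 10)  # mean of p_e = 20 and pL = 0
  dead <- necrotic_parameters(lymph_free)
  expect_error(steady_state_pressure(dead), "dead tissue")
})

test_that("alpha scales linearly in radius and is scale-invariant in K, Lp", {
  p <- tissue_parameters(K = 1e-6, Lp = 1e-6 / 2, SV = 200, pv = 10,
                         sigma = 0, pi_v = 0, pi_i = 0)
  expect_equal(alpha_parameter(p, 0.1), 0.1 * sqrt(100), tolerance = 1e-12)
  expect_equal(alpha_parameter(p, 0.4), 2 * alpha_parameter(p, 0.2))
  scaled <- tissue_parameters(K = 5e-6, Lp = 5e-6 / 2, SV = 200, pv = 10,
                              sigma = 0, pi_v = 0, pi_i = 0)
  expect_equal(alpha_parameter(scaled, 0.7), alpha_parameter(p, 0.7))
})

test_that("source and sink laws are affine and balance at the steady-state pressure", {
  p <- tissue_parameters(K = 1e-7, Lp = 3e-7, SV = 150, pv = 14, sigma = 0.85,
                         pi_v = 19, pi_i = 11, lymph_coeff = 2e-5, pL = 1)
  pe <- effective_pressure(p)
  expect_equal(starling_source(p, pe), 0)
  expect_gt(starling_source(p, 0), 0)
  expect_equal(starling_source(p, 0), p$Lp * p$SV * pe)
  expect_equal(starling_source(p, 3) - starling_source(p, 7),
               -p$Lp * p$SV * (3 - 7))
  expect_equal(lymph_sink(p, p$pL), 0)
  expect_equal(lymph_sink(p, p$pL + 2.5), p$lymph_coeff * 2.5)
  tumor <- baseline_tissue_parameters("tumor")
  expect_identical(lymph_sink(tumor, 37), 0)         # no tumor lymphatics
  # property: source equals sink exactly at p_ss for random parameter sets
  set.seed(41)
  for (i in 1:25) {
    q <- tissue_parameters(K = runif(1, 1e-9, 1e-6), Lp = runif(1, 1e-8, 1e-6),
                           SV = runif(1, 10, 500), pv = runif(1, 5, 30),
                           sigma = runif(1), pi_v = runif(1, 10, 30),
                           pi_i = runif(1, 0, 20),
                           lymph_coeff = runif(1, 0, 1e-4),
                           pL = runif(1, -3, 3))
    pss <- steady_state_pressure(q)
    expect_equal(starling_source(q, pss), lymph_sink(q, pss), tolerance = 1e-12)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(tissue_parameters(K = 0, Lp = 1, SV = 1, pv = 1, sigma = 0.5,
                                 pi_v = 1, pi_i = 1), "'K'")
  expect_error(tissue_parameters(K = 1, Lp = -1, SV = 1, pv = 1, sigma = 0.5,
                                 pi_v = 1, pi_i = 1), "'Lp'")
  expect_error(tissue_parameters(K = 1, Lp = 1, SV = 1, pv = 1, sigma = 1.5,
                                 pi_v = 1, pi_i = 1), "'sigma'")
  expect_error(tissue_parameters(K = 1, Lp = 1, SV = 1, pv = 1, sigma = 0.5,
                                 pi_v = 1, pi_i = 1, lymph_coeff = -2),
               "'lymph_coeff'")
})

test_that("baseline parameter set reproduces the standard derived scalars", {
  tum <- baseline_tissue_parameters("tumor")
  expect_identical(tum$lymph_coeff, 0)
  expect_equal(effective_pressure(tum), 11.5)
  expect_equal(steady_state_pressure(tum), effective_pressure(tum))
  expect_equal(alpha_parameter(tum, 1), sqrt(2.8e-7 * 200 / 4.13e-8),
               tolerance = 1e-12)
  nor <- baseline_tissue_parameters("normal")
  expect_equal(effective_pressure(nor), 15.6 - 0.91 * 10)
})
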