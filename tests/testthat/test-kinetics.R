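k_ref <- kinetic_constants(zeta0 = 1, mu0 = 1, kappa0 = 1, K0 = 1,
                           p0 = 0.6, KM = 30)

test_that("Michaelis-Menten occupancy has its defining values", {
  expect_equal(michaelis_menten_fraction(0, 30), 0)
  expect_equal(michaelis_menten_fraction(30, 30), 0.5)
  expect_equal(michaelis_menten_fraction(90, 30), 0.75)
  expect_error(michaelis_menten_fraction(-1, 30), ">= 0")
  expect_error(michaelis_menten_fraction(1, 0), "> 0")
})

test_that("activity is saturating in ATP and linear in motors", {
  expect_equal(activity(composition(0, 60, 100), k_ref), 0)
  expect_equal(activity(composition(30, 10, 0), k_ref), 5)   # 1 * 10 * 0.5
  expect_equal(activity(composition(1e9, 60, 0), k_ref), 60,
               tolerance = 1e-6)
  atp <- seq(0, 500, by = 5)
  z <- activity(composition(atp, 60, 100), k_ref)
  expect_true(all(diff(z) > 0))              # increasing
  expect_true(all(diff(diff(z)) < 0))        # concave
  expect_equal(activity(composition(50, 120, 0), k_ref),
               2 * activity(composition(50, 60, 0), k_ref))
})

test_that("crosslinker pool interpolates between no-fuel and saturating ATP", {
  expect_equal(crosslinker_concentration(composition(1e12, 60, 100), k_ref),
               60, tolerance = 1e-6)          # all motors stepping: 0.6*100
  expect_equal(crosslinker_concentration(composition(0, 60, 100), k_ref),
               120)                           # nobody steps, all crosslink
  expect_equal(crosslinker_concentration(composition(77, 0, 100), k_ref),
               60)                            # p0 * prc1
  atp <- seq(0, 2000, by = 20)
  xl <- crosslinker_concentration(composition(atp, 60, 100), k_ref)
  expect_true(all(diff(xl) < 0))
  expect_true(all(xl <= 120 & xl >= 60))
})

test_that("moduli scale quadratically with the crosslinker pool", {
  k <- kinetic_constants(1, mu0 = 1, kappa0 = 0.5, K0 = 1, p0 = 1, KM = 30)
  m <- moduli(composition(0, 0, 2), k)        # [XL] = 2
  expect_equal(m$mu, 4)
  expect_equal(m$kappa, 2)
  m0 <- moduli(composition(0, 0, 0), k)
  expect_equal(m0$mu, 0)
  expect_equal(m0$kappa, 0)
  # kappa/mu is composition independent
  set.seed(5)
  cmp <- composition(runif(20, 0, 1000), runif(20, 0, 200),
                     runif(20, 1, 500))
  m <- moduli(cmp, k)
  expect_equal(m$kappa / m$mu, rep(0.5, 20))
})

test_that("nematic elasticity follows the length power law", {
  expect_equal(nematic_elasticity(composition(1, 1, 1, 1.5), k_ref), 2.25)
  k3 <- kinetic_constants(1, 1, 1, 1, p0 = 0.6, length_exponent = 3)
  expect_equal(nematic_elasticity(composition(1, 1, 1, 2), k3) /
                 nematic_elasticity(composition(1, 1, 1, 1), k3), 8)
})

test_that("composition_to_mechanics assembles a consistent elastomer state", {
  cmp <- composition(100, 60, 100, 1.5)
  p <- composition_to_mechanics(cmp, k_ref, gamma = 2)
  expect_s3_class(p, "elastomer_params")
  expect_equal(p$zeta, activity(cmp, k_ref))
  expect_equal(p$mu, moduli(cmp, k_ref)$mu)
  expect_equal(p$K, nematic_elasticity(cmp, k_ref))
  expect_equal(p$gamma, 2)
})

test_that("direction predictions depend only on prefactor ratios", {
  k1 <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
  k2 <- kinetic_constants(zeta0 = 37 * k1$zeta0, mu0 = 37 * k1$mu0,
                          kappa0 = 37 * k1$kappa0, K0 = 37 * k1$K0,
                          p0 = k1$p0, KM = k1$KM)
  set.seed(8)
  for (i in 1:25) {
    cmp <- composition(runif(1, 1, 1500), runif(1, 5, 200),
                       runif(1, 10, 500), runif(1, 0.5, 10))
    r1 <- classify_regime(composition_to_mechanics(cmp, k1))
    r2 <- classify_regime(composition_to_mechanics(cmp, k2))
    expect_identical(r1$regime, r2$regime)
  }
})

test_that("zeta/mu is unimodal in motors with the predicted maximiser", {
  k <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
  for (atp in c(5, 8, 20, 100)) {
    f <- michaelis_menten_fraction(atp, k$KM)
    ratio <- function(m) {
      p <- composition_to_mechanics(composition(atp, m, 100, 1.5), k)
      p$zeta / p$mu
    }
    m_grid <- seq(1, 2000, by = 1)
    r <- vapply(m_grid, ratio, numeric(1))
    peak <- which.max(r)
    expect_true(all(diff(r[1:peak]) > 0))
    expect_true(all(diff(r[peak:length(r)]) < 0))
    # analytic maximiser p0 prc1 / (1 - f) vs numeric optimisation oracle
    m_star <- stats::optimize(ratio, c(1, 2000), maximum = TRUE)$maximum
    expect_equal(m_star, 0.6 * 100 / (1 - f), tolerance = 1e-3)
  }
})
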