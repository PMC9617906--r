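test_that("dispersion relations match hand-evaluated values", {
  p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1, gamma = 1)
  expect_equal(growth_rate_in_plane(p, 1), 0)        # (2-1)*1 - 1*1
  expect_equal(growth_rate_out_of_plane(p, 1), 0)    # 2 - 2
  expect_equal(growth_rate_out_of_plane(p, 0.5), 0.375)
  expect_equal(growth_rate_in_plane(p, 0), 0)        # uniform translation
  expect_equal(growth_rate_out_of_plane(p, 0), 0)
  # friction rescales rates
  p2 <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1, gamma = 4)
  expect_equal(growth_rate_out_of_plane(p2, 0.5), 0.375 / 4)
})

test_that("a passive sheet is linearly stable on both branches", {
  p <- elastomer_params(zeta = 0, mu = 1, kappa = 1, K = 1)
  q <- seq(0.01, 20, length.out = 500)
  expect_true(all(growth_rate_in_plane(p, q) < 0))
  expect_true(all(growth_rate_out_of_plane(p, q) <= 0))
})

test_that("most unstable mode matches its closed form", {
  p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
  m_in <- most_unstable_mode(p, "in_plane")
  expect_true(m_in$unstable)
  expect_equal(m_in$q_star, sqrt(0.5))
  expect_equal(m_in$sigma_star, 0.25)
  expect_equal(m_in$lambda_star * m_in$q_star, 2 * pi)
  m_out <- most_unstable_mode(p, "out_of_plane")
  expect_equal(m_out$q_star, sqrt(0.5))
  expect_equal(m_out$sigma_star, 0.5)
  # at the critical activity the bend mode is marginal
  expect_false(most_unstable_mode(elastomer_params(1, 1, 1, 1),
                                  "in_plane")$unstable)
  # vanishing quartic stiffness on an unstable branch has no finite cutoff
  expect_error(most_unstable_mode(elastomer_params(2, 1, 1, K = 0),
                                  "in_plane"), "unbounded")
  expect_error(most_unstable_mode(elastomer_params(2, 1, kappa = 0, K = 0),
                                  "out_of_plane"), "unbounded")
})

test_that("closed-form mode selection agrees with grid argmax over random draws", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_params()
    for (br in c("in_plane", "out_of_plane")) {
      m <- most_unstable_mode(p, br)
      o <- grid_argmax_mode(p, br)
      if (m$unstable) {
        expect_equal(m$sigma_star, o$sigma_star, tolerance = 1e-4)
        expect_equal(m$q_star, o$q_star, tolerance = 1e-2)
      } else {
        expect_false(o$unstable)
      }
    }
  }
})

test_that("out-of-plane modes grow at any non-zero activity, in-plane only above mu", {
  set.seed(7)
  q <- 10^seq(-3, 1.3, length.out = 400)
  for (i in 1:40) {
    p <- random_params()
    expect_true(any(growth_rate_out_of_plane(p, q) > 0))
    if (p$zeta <= p$mu)
      expect_true(all(growth_rate_in_plane(p, q) <= 0))
    p_sub <- elastomer_params(zeta = p$mu * runif(1, 0, 1), mu = p$mu,
                              kappa = p$kappa, K = p$K, gamma = p$gamma)
    expect_true(all(growth_rate_in_plane(p_sub, q) <= 0))
  }
})

test_that("critical activity ratio matches hand values and the bisection oracle", {
  expect_equal(critical_activity_ratio(3), 2)
  expect_equal(critical_activity_ratio(1), 1 / (1 - 2^-0.5))
  expect_equal(critical_activity_ratio(1e12), 1, tolerance = 1e-5)
  expect_error(critical_activity_ratio(0), "> 0")
  expect_error(critical_activity_ratio(-1), "> 0")
  for (r in 10^seq(-1, 2, length.out = 13))
    expect_equal(critical_activity_ratio(r), bisect_critical_ratio(r),
                 tolerance = 1e-6)
  # strictly decreasing and always above 1
  rs <- 10^seq(-3, 3, length.out = 200)
  vals <- critical_activity_ratio(rs)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 1))
})

test_that("regime classification follows the printed inequalities", {
  lab <- classify_regime(elastomer_params(0.5, 1, 3, 1))
  expect_equal(lab$regime, "i_out_only")
  expect_equal(lab$direction, "out_of_plane")
  lab <- classify_regime(elastomer_params(1.5, 1, 3, 1))   # boundary = 2
  expect_equal(lab$regime, "ii_out_faster")
  expect_equal(lab$direction, "out_of_plane")
  lab <- classify_regime(elastomer_params(3, 1, 3, 1))
  expect_equal(lab$regime, "iii_in_faster")
  expect_equal(lab$direction, "in_plane")
  # exactly on the boundary ties classify as out-of-plane (regime ii)
  expect_equal(classify_regime(elastomer_params(2, 1, 3, 1))$regime,
               "ii_out_faster")
  expect_error(classify_regime(elastomer_params(1, 0, 1, 1)), "fluid")
})

test_that("regime label agrees with direct growth-rate comparison and ignores friction", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_params()
    lab <- classify_regime(p)
    s_in <- most_unstable_mode(p, "in_plane")$sigma_star
    s_out <- most_unstable_mode(p, "out_of_plane")$sigma_star
    expect_equal(lab$direction,
                 if (s_in > s_out) "in_plane" else "out_of_plane")
    p2 <- elastomer_params(p$zeta, p$mu, p$kappa, p$K, gamma = p$gamma * 17)
    expect_identical(classify_regime(p2)$regime, lab$regime)
  }
})

test_that("free energy is exact on single modes and zero for the flat state", {
  x <- seq(0, 2 * pi, length.out = 129)[-129]
  p <- elastomer_params(zeta = 0, mu = 1, kappa = 1, K = 1, nu = 0.7)
  expect_equal(free_energy(deformation_field(x), p), 0)
  # u_y = sin(x): (A^2/4)(mu q^2 + K q^4) L = (1/4)(1+1)(2 pi) = pi
  expect_equal(free_energy(deformation_field(x, u_y = sin(x)), p), pi)
  # h = sin(x): (A^2/4)(kappa + K) q^4 L = pi
  expect_equal(free_energy(deformation_field(x, h = sin(x)), p), pi)
  # u_x = sin(x): (A^2/4) nu q^2 L = (1/4)(0.7)(2 pi)
  expect_equal(free_energy(deformation_field(x, u_x = sin(x)), p),
               0.7 * pi / 2)
  expect_error(deformation_field(x[1:3]), "at least 4")
})

test_that("free energy is non-negative for arbitrary periodic fields", {
  set.seed(3)
  x <- seq(0, 100, length.out = 65)[-65]
  for (i in 1:20) {
    f <- deformation_field(x, u_y = rnorm(64), h = rnorm(64), u_x = rnorm(64))
    p <- random_params()
    expect_gte(free_energy(f, p), 0)
  }
})
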