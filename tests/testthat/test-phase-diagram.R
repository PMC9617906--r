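k_true <- default_generator_config()$k_true

test_that("a single-cell grid reproduces the scalar pipeline", {
  g <- predict_grid(list(atp = 100, prc1 = 150),
                    fixed = list(motors = 60, mt_length = 1.5), k_true)
  expect_equal(nrow(g), 1)
  p <- composition_to_mechanics(composition(100, 60, 150, 1.5), k_true)
  lab <- classify_regime(p)
  expect_identical(g$regime, lab$regime)
  expect_identical(g$direction, lab$direction)
  br <- if (lab$direction == "in_plane") "in_plane" else "out_of_plane"
  expect_equal(g$lambda_star, most_unstable_mode(p, br)$lambda_star)
})

test_that("grid direction field is invariant to friction and input validation holds", {
  axes <- list(atp = 10^seq(0, 3, length.out = 8),
               prc1 = seq(10, 500, length.out = 8))
  g1 <- predict_grid(axes, list(motors = 60), k_true, gamma = 1)
  g2 <- predict_grid(axes, list(motors = 60), k_true, gamma = 250)
  expect_identical(g1$direction, g2$direction)
  expect_error(predict_grid(list(atp = numeric(0), prc1 = 1),
                            list(motors = 60), k_true), "empty")
  expect_error(predict_grid(list(foo = 1, prc1 = 1), list(motors = 60),
                            k_true), "axis names")
})

test_that("more crosslinking requires more ATP to bend in-plane", {
  g <- predict_grid(list(atp = 10^seq(0, log10(1500), length.out = 24),
                         prc1 = c(50, 150, 400)),
                    fixed = list(motors = 60, mt_length = 1.5), k_true)
  min_atp_in <- vapply(c(50, 150, 400), function(pc) {
    sub <- g[g$prc1 == pc & g$direction == "in_plane", ]
    if (nrow(sub) == 0) Inf else min(sub$atp)
  }, numeric(1))
  expect_true(all(diff(min_atp_in) > 0))
})

test_that("boundary points satisfy the closed-form activity-ratio condition", {
  b <- boundary_trace(list(name = "prc1", values = c(60, 120, 250, 400)),
                      list(name = "atp",
                           values = 10^seq(0, 3.18, length.out = 80)),
                      fixed = list(motors = 60, mt_length = 1.5),
                      k_true, tol = 1e-8)
  expect_gt(nrow(b), 0)
  for (i in seq_len(nrow(b))) {
    p <- composition_to_mechanics(
      composition(b$atp[i], 60, b$prc1[i], 1.5), k_true)
    expect_equal(p$zeta / p$mu, critical_activity_ratio(p$kappa / p$K),
                 tolerance = 1e-4)
  }
})

test_that("the re-entrant boundary yields two crossings along motors at limiting ATP", {
  b <- boundary_trace(list(name = "atp", values = c(8)),
                      list(name = "motors", values = seq(5, 200, by = 2)),
                      fixed = list(prc1 = 100, mt_length = 1.5), k_true)
  expect_equal(nrow(b), 2)
  expect_equal(sort(unique(b$crossing)), c(1, 2))
  # no sign change on a line deep in the buckling regime -> empty polyline
  b0 <- boundary_trace(list(name = "atp", values = c(1)),
                       list(name = "motors", values = seq(5, 200, by = 5)),
                       fixed = list(prc1 = 400, mt_length = 1.5), k_true)
  expect_equal(nrow(b0), 0)
})

test_that("wavelengths follow the closed forms and shrink with activity", {
  g <- predict_grid(list(atp = c(50, 200, 1000), prc1 = c(30, 300)),
                    fixed = list(motors = 60, mt_length = 1.5), k_true)
  wm <- wavelength_map(g)
  out <- g$direction == "out_of_plane"
  expect_equal(wm$lambda_star[out],
               2 * pi * sqrt(2 * (g$K[out] + g$kappa[out]) / g$zeta[out]))
  # at fixed elasticity, lambda* decreases with zeta
  lam <- vapply(c(1, 2, 4, 8), function(z)
    most_unstable_mode(elastomer_params(z, 10, 1, 1),
                       "out_of_plane")$lambda_star, numeric(1))
  expect_true(all(diff(lam) < 0))
})

test_that("cell labels away from the boundary are stable under grid refinement", {
  axes_c <- list(atp = 10^seq(0, 3, length.out = 7),
                 prc1 = seq(20, 480, length.out = 7))
  g_c <- predict_grid(axes_c, list(motors = 60), k_true)
  axes_f <- list(atp = sort(c(axes_c$atp, 10^seq(0.1, 2.9, length.out = 6))),
                 prc1 = sort(c(axes_c$prc1, seq(50, 450, length.out = 6))))
  g_f <- predict_grid(axes_f, list(motors = 60), k_true)
  shared_f <- g_f[g_f$atp %in% axes_c$atp & g_f$prc1 %in% axes_c$prc1, ]
  m <- merge(g_c, shared_f, by = c("atp", "prc1"))
  expect_identical(m$direction.x, m$direction.y)
})
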