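vaso <- vaso_params(m_r = 0.05, tau_r = 600, r_hat_min = 0.2, r_v0 = 1e-5)

flow_params <- function(k_vc = 2e-11, lambda_inl = 1e-3)
  vessel_flow_params(k_vc = k_vc, mu = 1.2e-3, p_inl = 2660, p_p = 1330,
                     lambda_inl = lambda_inl, k_v_min = 2e-6, k_v_max = 2e-5,
                     L_vessel = 1e-3, r_v0 = 1e-5)

test_that("normalized radius has the vasoconstriction/recovery limits", {
  expect_equal(normalized_radius(0, c(0, 100, 1e6), vaso), rep(1, 3))
  expect_equal(normalized_radius(46, 1e9, vaso), 1, tolerance = 1e-12)
  expect_equal(normalized_radius(1e6, 0, vaso), vaso$r_hat_min,
               tolerance = 1e-12)
  # bounded and recovering monotonically for a sampled field sweep
  for (E in c(10, 46, 70, 150)) {
    r <- normalized_radius(E, seq(0, 5000, by = 100), vaso)
    expect_true(all(r >= vaso$r_hat_min & r <= 1))
    expect_true(all(diff(r) > 0))
  }
})

test_that("interface speed matches a finite-difference of the radius", {
  expect_equal(interface_speed(0, 500, vaso), 0)
  expect_equal(interface_speed(46, 1e9, vaso), 0, tolerance = 1e-20)
  h <- 1e-3
  for (E in c(20, 46, 70)) for (tp in c(1, 60, 600, 3000)) {
    fd <- vaso$r_v0 *
      (normalized_radius(E, tp + h, vaso) - normalized_radius(E, tp - h, vaso)) / (2 * h)
    an <- interface_speed(E, tp, vaso)
    expect_equal(an, fd, tolerance = 1e-6)
    expect_gt(an, 0)
  }
})

test_that("tissue radial velocity interpolates linearly wall-to-rim", {
  r_v <- 8e-6; R <- 7.5e-5; drv <- 2e-9
  expect_equal(tissue_radial_velocity(R, r_v, R, drv), 0)
  expect_equal(tissue_radial_velocity(r_v, r_v, R, drv), drv)
  expect_equal(tissue_radial_velocity((r_v + R) / 2, r_v, R, drv), drv / 2)
  expect_error(tissue_radial_velocity(R * 1.1, r_v, R, drv), "outside")
})

test_that("leakage flow matches the porous-tube ODE system", {
  skip_if_not_installed("deSolve")
  vf <- flow_params()
  r_v <- 1e-5
  expect_equal(leakage_flow(0, vf, r_v), 0)
  expect_equal(leakage_flow(c(0, 5e-4, 1e-3), flow_params(k_vc = 0), r_v),
               rep(0, 3))
  # quadrature oracle: integrate the coupled Poiseuille/filtration system
  rhs <- function(z, y, p)
    list(c(-8 * vf$mu * y[2] / (pi * r_v^4), -2 * pi * r_v * vf$k_vc * y[1]))
  zs <- seq(0, 1e-3, length.out = 9)
  sol <- deSolve::ode(y = c(vf$p_inl - vf$p_p, vf$Q_inl), times = zs,
                      func = rhs, parms = NULL, rtol = 1e-12, atol = 1e-20)
  ref <- vf$Q_inl - sol[, 3]
  ours <- leakage_flow(zs, vf, r_v)
  expect_equal(ours[-1], ref[-1], tolerance = 1e-4)
})

test_that("plasma velocity starts at the inlet value and decays with leakage", {
  vf <- flow_params()
  r_v <- 1e-5
  expect_equal(plasma_velocity(0, vf, r_v), vf$lambda_inl)
  expect_equal(plasma_velocity(seq(0, 1e-3, length.out = 5),
                               flow_params(k_vc = 0), r_v),
               rep(1e-3, 5))
  lam <- plasma_velocity(seq(0, 1e-3, length.out = 21), vf, r_v)
  expect_true(all(diff(lam) < 0))
  # a draining parameter set is flagged, not silently accepted
  vf_drain <- flow_params(k_vc = 2e-7, lambda_inl = 1e-6)
  expect_warning(plasma_velocity(1e-3, vf_drain, r_v), "drains")
})

test_that("implicit upwind vessel transport is stable and bounded", {
  # zero exchange, uniform state: exact fixed point
  Cv <- rep(0.5, 8)
  out <- advance_vessel_concentration(Cv, rep(0, 8), rep(1e-3, 8), 0,
                                      dt = 10, dz = 1e-4, inlet_value = 0.5)
  expect_equal(out, Cv)
  # stagnant interior node: closed-form implicit relaxation toward C1
  k <- 0.05; dt <- 7
  out1 <- advance_vessel_concentration(c(0.2, 0.2), c(1, 1), c(0, 0), k,
                                       dt, 1e-4, inlet_value = 0.2)
  expect_equal(out1[2], (0.2 + dt * k * 1.0) / (1 + dt * k))
  # pure advection of a step: no overshoot, front speed bounded by lambda
  n <- 50; dz <- 1e-5; lam <- 1e-3; dt <- 2
  Cv <- c(rep(1, 10), rep(0, 40))
  out2 <- Cv
  for (s in 1:10)
    out2 <- advance_vessel_concentration(out2, rep(0, n), rep(lam, n), 0,
                                         dt, dz, inlet_value = 1)
  expect_true(all(out2 >= -1e-15 & out2 <= 1 + 1e-15))
  expect_true(all(diff(out2) <= 1e-12))           # monotone front
  travelled <- 10 * lam * dt
  expect_true(all(out2[seq_len(n)[-(1:10)] * dz > 10 * dz + 2 * travelled] < 0.5))
  # discrete maximum principle with exchange
  set.seed(4)
  Cv <- runif(20); C1 <- runif(20)
  out3 <- advance_vessel_concentration(Cv, C1, rep(5e-4, 20), 0.01, 3, 5e-5, 0.7)
  expect_true(max(out3) <= max(0.7, max(Cv), max(C1)) + 1e-12)
  expect_true(min(out3) >= 0)
  expect_error(advance_vessel_concentration(-Cv, C1, rep(5e-4, 20), 0.01, 3,
                                            5e-5, 0.7),
               "non-negative")
})
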