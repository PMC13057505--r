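test_that("grid construction is deterministic and tracks the vessel radius", {
  cfg <- small_config()
  g1 <- build_grid(cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  g2 <- build_grid(cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  expect_identical(g1$r, g2$r)
  expect_identical(g1$z, g2$z)
  expect_equal(g1$r[1], cfg$tissue$r_v0)
  expect_equal(g1$r[g1$n_r], cfg$tissue$R_cord)
  expect_equal(g1$z[g1$n_z], cfg$tissue$L_cord)
  g3 <- build_grid(0.4 * cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  expect_equal(g3$r[1], 0.4 * cfg$tissue$r_v0)
  expect_error(build_grid(2 * cfg$tissue$R_cord, cfg$tissue, cfg$solver),
               "degenerate")
})

test_that("geometry properties conserve cellular material", {
  cfg <- small_config()
  tis <- cfg$tissue
  g0 <- geometry_properties(tis$r_v0, tis)
  expect_equal(g0$delta1, tis$delta1_0)
  expect_equal(g0$delta2, tis$delta2)
  expect_equal(g0$alpha_geo, tis$alpha_geo)
  expect_equal(g0$D, tis$D0)
  # shrinking the vessel grows the domain: less crowded, faster diffusion
  gs <- geometry_properties(0.3 * tis$r_v0, tis)
  expect_lt(gs$delta2, tis$delta2)
  expect_gt(gs$delta1, tis$delta1_0)
  expect_gt(gs$D, tis$D0)
  # delta2 * volume invariant along a radius sweep
  vol <- function(rv) tis$R_cord^2 - rv^2
  for (rv in c(0.3, 0.6, 1) * tis$r_v0)
    expect_equal(geometry_properties(rv, tis)$delta2 * vol(rv),
                 tis$delta2 * vol(tis$r_v0))
})

test_that("zero fields with a zero inlet stay zero", {
  cfg <- sealed_config(N_points = 60)
  grid <- build_grid(cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  z <- matrix(0, grid$n_r, grid$n_z)
  st <- concentration_state(0, grid, z, z, z, rep(0, grid$n_z), grid$r_v)
  st <- advance_tissue(st, 0, 0, cfg, inlet_value = 0)
  expect_equal(max(abs(st$C1)), 0)
  expect_equal(max(abs(st$C2)), 0)
  expect_equal(max(abs(st$C3)), 0)
})

test_that("sealed domain conserves discrete drug mass over 100 steps", {
  cfg <- sealed_config(N_points = 80, dt = 10)
  st <- random_state(cfg)
  props <- ectcord:::effective_props(cfg, st$r_v, 0, 0)
  m0 <- ectcord:::tissue_mass(st, props)
  for (i in 1:100) st <- advance_tissue(st, 0, 0, cfg, inlet_value = 0)
  drift <- abs(ectcord:::tissue_mass(st, props) - m0) / m0
  expect_lt(drift, 1e-5)
  expect_true(all(st$C1 >= 0) && all(st$C2 >= 0))
  expect_true(all(st$C3 >= 0 & st$C3 <= cfg$tissue$C0))
})

test_that("bound concentration is capped at the binding capacity", {
  cfg <- sealed_config(N_points = 60, dt = 50)
  cfg$tissue$k2 <- 1        # aggressive association
  grid <- build_grid(cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  n <- grid$n_r * grid$n_z
  big <- matrix(3 * cfg$tissue$C0, grid$n_r, grid$n_z)
  st <- concentration_state(0, grid, big, big,
                            matrix(0.99 * cfg$tissue$C0, grid$n_r, grid$n_z),
                            rep(0, grid$n_z), grid$r_v, cfg$tissue$C0)
  for (i in 1:20) st <- advance_tissue(st, 0, 0, cfg, inlet_value = 0)
  expect_true(all(st$C3 <= cfg$tissue$C0 + 1e-12))
  expect_true(all(st$C3 >= 0))
})

test_that("uniform-inlet no-reaction run reaches partial equilibrium", {
  cfg <- small_config(pk_kind = "UPK", N_points = 80, dt = 120,
                      t_end = 12 * 3600)
  cfg$tissue$k2 <- 0
  cfg$tissue$k_minus2 <- 0
  ser <- run_treatment(cfg)
  target <- 3.85802e-2
  # the ratio approaches 1 from below through the whole series
  for (st in ser$snapshots[-1]) {
    rat <- st$C2 / st$C1
    expect_true(all(rat <= 1 + 1e-9))
  }
  last <- ser$snapshots[[length(ser$snapshots)]]
  expect_equal(as.vector(last$C1), rep(target, length(last$C1)),
               tolerance = 1e-4)
  expect_equal(as.vector(last$C2), rep(target, length(last$C2)),
               tolerance = 1e-4)
  expect_equal(max(abs(last$C2 / last$C1 - 1)), 0, tolerance = 1e-5)
})

test_that("spatial operator is second order on a manufactured solution", {
  err <- function(n) {
    cfg <- small_config(N_points = n * n)
    tis <- cfg$tissue
    grid <- build_grid(tis$r_v0, tis, cfg$solver)
    A <- pi / (grid$R_cord - grid$r_v); B <- pi / grid$L_cord
    u <- outer(cos(A * (grid$r - grid$r_v)), cos(B * grid$z))
    lap <- outer(-(A^2) * cos(A * (grid$r - grid$r_v)) -
                   (A / grid$r) * sin(A * (grid$r - grid$r_v)),
                 cos(B * grid$z)) - B^2 * u
    sol <- ectcord:::solve_steady_diffusion(grid, tis$D0, 1e-6,
                                            cos(B * grid$z), -tis$D0 * lap)
    max(abs(sol - u))
  }
  e1 <- err(12); e2 <- err(24); e3 <- err(48)
  expect_gt(e1 / e2, 3)
  expect_gt(e2 / e3, 3)
})

test_that("stepper matches a method-of-lines oracle on the radial reduction", {
  skip_if_not_installed("deSolve")
  cfg <- small_config(lambda_inl = 0.1, pk_kind = "UPK",
                      N_points = 160, dt = 0.5)
  cfg$solver$tol <- 1e-10
  cfg$vessel_flow$k_vc <- 0
  tis <- cfg$tissue
  grid <- build_grid(tis$r_v0, tis, cfg$solver)
  n_r <- grid$n_r
  inlet <- 3.85802e-2
  st <- concentration_state(0, grid,
                            matrix(0, n_r, grid$n_z), matrix(0, n_r, grid$n_z),
                            matrix(0, n_r, grid$n_z), rep(inlet, grid$n_z),
                            grid$r_v, tis$C0)
  nsteps <- 600
  for (i in seq_len(nsteps)) st <- advance_tissue(st, 0, 0, cfg,
                                                  inlet_value = inlet)
  # the fast-advection vessel keeps the problem close to axially uniform
  expect_lt(max(apply(st$C1, 1, function(v) diff(range(v)))), 1e-3 * inlet)
  props <- ectcord:::effective_props(cfg, grid$r_v, 0, 0)
  rhs <- function(t, y, parms) {
    C1 <- y[1:n_r]; C2 <- y[n_r + 1:n_r]; C3 <- y[2 * n_r + 1:n_r]
    rf <- grid$r_face
    flux <- props$D * rf[2:n_r] * diff(C1) / grid$dr
    wall <- props$k_v * grid$r_v * (inlet - C1[1])
    div <- c(flux[1] + wall, diff(flux), -flux[n_r - 1]) / grid$w_r
    ex <- props$alpha_geo * props$k1 * (C2 - C1)
    as_ <- tis$k2 * C2 * (tis$C0 - C3); dis <- tis$k_minus2 * C3
    list(c((div + ex) / props$delta1,
           props$alpha_geo * props$k1 * (C1 - C2) / props$delta2 - as_ + dis,
           as_ - dis))
  }
  out <- deSolve::ode(y = rep(0, 3 * n_r),
                      times = c(0, nsteps * cfg$solver$dt),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  ref <- out[2, -1]
  ours <- c(st$C1[, 1], st$C2[, 1], st$C3[, 1])
  expect_lt(max(abs(ours - ref)) / max(abs(ref)), 1e-3)
})

test_that("untreated run keeps the vessel radius and snapshots on schedule", {
  cfg <- small_config(N_points = 60, dt = 60, t_end = 1800)
  cfg$solver$output_times <- c(0, 600, 1200, 1800)
  ser <- run_treatment(cfg)
  expect_equal(ser$times, c(0, 600, 1200, 1800))
  expect_true(all(vapply(ser$snapshots, function(s) s$r_v, 0) ==
                    cfg$tissue$r_v0))
})

test_that("vasoconstriction run remeshes and keeps fields physical", {
  cfg <- small_config(E = 46, N_points = 60, dt = 60, t_end = 1800,
                      pk_kind = "UPK",
                      protocol_start_times = 0)
  cfg$solver$output_times <- c(0, 600, 1800)
  ser <- run_treatment(cfg)
  rv <- vapply(ser$snapshots, function(s) s$r_v, 0)
  expect_lt(rv[1], cfg$tissue$r_v0)        # constricted at protocol start
  expect_true(all(diff(rv) >= 0))          # recovering
  for (st in ser$snapshots) {
    expect_true(all(is.finite(st$C1)) && all(st$C1 >= 0))
    expect_true(all(st$C3 >= 0 & st$C3 <= cfg$tissue$C0))
    expect_equal(st$grid$r[1], st$r_v)
  }
})

test_that("config round-trips through JSON", {
  cfg <- reference_config(E = 46, lambda_inl = 1e-3, pk_kind = "TPK")
  raw <- list(
    electrical = list(
      tissue = unclass(cfg$electrical_tissue),
      vessel_wall = unclass(cfg$electrical_wall)),
    vaso = unclass(cfg$vaso),
    vessel_flow = unclass(cfg$vessel_flow),
    tissue = unclass(cfg$tissue),
    pk = list(kind = "TPK"),
    solver = list(N_points = 200, dt = 30),
    schedule = list(E = 46, protocol_start_times = c(0, 3600)))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_treatment_config(f)
  expect_s3_class(cfg2, "TreatmentConfig")
  expect_equal(cfg2$tissue$k2, cfg$tissue$k2)
  expect_equal(cfg2$schedule$n_protocols, 2)
  expect_equal(cfg2$solver$N_points, 200L)
  expect_equal(inlet_concentration(180, cfg2$pk),
               inlet_concentration(180, cfg$pk))
})
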