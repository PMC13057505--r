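# Shared fixtures: printed electrical constants and small synthetic
# parameter sets sized for fast tests.

tissue_electro <- function() electro_params(46, 70, 10, 8, 3.141e-1, 1.998e-2, 100)
wall_electro <- function() electro_params(46, 175, 10, 8, 6.250e-1, 0.630e-2, 100)

small_config <- function(E = 0, lambda_inl = 1e-3, pk_kind = "UPK",
                         N_points = 100, dt = 30, t_end = 3600, ...) {
  cfg <- reference_config(E = E, lambda_inl = lambda_inl, pk_kind = pk_kind,
                          N_points = N_points, dt = dt, t_end = t_end, ...)
  cfg
}

# A sealed small config: no wall exchange, no field, no leakage.
sealed_config <- function(N_points = 100, dt = 10) {
  cfg <- small_config(N_points = N_points, dt = dt)
  cfg$vessel_flow$k_v_min <- 0
  cfg$vessel_flow$k_v_max <- 0
  cfg$vessel_flow$k_vc <- 0
  cfg$solver$tol <- 1e-10
  cfg
}

random_state <- function(cfg, seed = 1) {
  grid <- build_grid(cfg$tissue$r_v0, cfg$tissue, cfg$solver)
  set.seed(seed)
  n <- grid$n_r * grid$n_z
  concentration_state(
    0, grid,
    matrix(runif(n, 0.5, 1.5), grid$n_r, grid$n_z),
    matrix(runif(n, 0.1, 0.9), grid$n_r, grid$n_z),
    matrix(runif(n, 0.1, 0.5), grid$n_r, grid$n_z),
    rep(0, grid$n_z), grid$r_v, cfg$tissue$C0)
}

all_cell_names <- function() {
  tab <- scenario_table()
  sprintf("(%s,%s,%s)+%s+%s", tab$t21, tab$t31, tab$t32, tab$reaction, tab$tmt)
}
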