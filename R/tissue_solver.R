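#' Concentration state of the cord at one time
#'
#' Holds the three tissue fields on the collocation grid and the vessel
#' profile at one time instant: `C1` extracellular, `C2` free intracellular,
#' `C3` bound intracellular (all uM, `n_r x n_z` matrices), `Cv` per z-node.
#'
#' @param t Time (s).
#' @param grid A [build_grid()] object.
#' @param C1,C2,C3 Field matrices (`n_r x n_z`, uM).
#' @param Cv Vessel concentration per z-node (uM).
#' @param r_v Current vessel radius (m).
#' @param C0 Binding-site concentration (uM), used for validation.
#' @return A `ConcentrationState`.
#' @export
concentration_state <- function(t, grid, C1, C2, C3, Cv, r_v, C0 = Inf) {
  dims <- c(grid$n_r, grid$n_z)
  for (f in list(C1, C2, C3))
    stop_if(!all(dim(f) == dims), "field dimensions do not match the grid")
  stop_if(length(Cv) != grid$n_z, "Cv length must equal n_z")
  stop_if(any(C1 < 0) || any(C2 < 0) || any(C3 < 0) || any(Cv < 0),
          "concentrations must be non-negative")
  stop_if(any(C3 > C0 * (1 + 1e-12)), "C3 exceeds the binding capacity C0")
  structure(list(t = t, grid = grid, C1 = C1, C2 = C2, C3 = C3,
                 Cv = Cv, r_v = r_v),
            class = "ConcentrationState")
}

#' @export
print.ConcentrationState <- function(x, ...) {
  cat(sprintf("<ConcentrationState> t = %.4g h, %d x %d nodes\n",
              x$t / 3600, x$grid$n_r, x$grid$n_z))
  cat(sprintf("  C1 [%.3g, %.3g]  C2 [%.3g, %.3g]  C3 [%.3g, %.3g] uM\n",
              min(x$C1), max(x$C1), min(x$C2), max(x$C2),
              min(x$C3), max(x$C3)))
  invisible(x)
}

# Per-step solver operators for the C1 linear system; reused across steps
# while the geometry, permeabilities and velocity field are unchanged.
build_step_ops <- function(grid, props, k1_eff, k_v_eff, u_r, dt) {
  V <- as.vector(grid_volumes(grid))
  A <- assemble_diffusion(grid, props$D)
  U <- assemble_advection(grid, u_r)
  rob <- robin_diagonal(grid, k_v_eff)
  M <- Matrix::Diagonal(x = props$delta1 * V / dt + props$alpha_geo * k1_eff * V + rob) +
    A + U
  # row equilibration by the transient scale (the solver's S_T scaling)
  rs <- dt / (props$delta1 * V)
  Ms <- Matrix::Diagonal(x = rs) %*% M
  list(lu = Matrix::lu(Ms), row_scale = rs, V = V, rob = rob,
       wall_idx = 1L + (seq_len(grid$n_z) - 1L) * grid$n_r,
       k1_eff = k1_eff, k_v_eff = k_v_eff, dt = dt, props = props)
}

# One coupled implicit step of the three tissue fields plus the vessel
# profile, solved by an outer Gauss-Seidel sweep with under-relaxation.
step_fields <- function(state, ops, grid, props, cfg, lambda_z, k_v_rate,
                        inlet_value, source_C1 = NULL) {
  dt <- ops$dt
  V <- ops$V
  S_C <- cfg$S_C %||% max(inlet_value, max(state$Cv), max(state$C1), 1e-12)
  C1o <- as.vector(state$C1); C2o <- as.vector(state$C2); C3o <- as.vector(state$C3)
  C1 <- C1o; C2 <- C2o; C3 <- C3o
  Cv <- state$Cv
  src <- if (is.null(source_C1)) 0 else V * as.vector(source_C1)
  base_rhs <- props$delta1 * V / dt * C1o + src
  omega <- cfg$omega
  it <- 0L; err <- Inf
  res_hist <- numeric(0)
  while (err > cfg$tol) {
    it <- it + 1L
    if (it > cfg$max_iter)
      stop(sprintf("Gauss-Seidel failed to converge (last residuals %s)",
                   paste(signif(utils::tail(res_hist, 5), 3), collapse = " ")),
           call. = FALSE)
    # vessel profile (implicit upwind), using the current wall iterate
    C1_wall <- C1[ops$wall_idx]
    Cv_new <- advance_vessel_concentration(state$Cv, C1_wall, lambda_z,
                                           k_v_rate, dt, grid$dz, inlet_value)
    Cv_it <- omega * Cv_new + (1 - omega) * Cv
    # C1: sparse linear solve with the cached factorization
    rhs <- base_rhs + props$alpha_geo * ops$k1_eff * V * C2
    rhs[ops$wall_idx] <- rhs[ops$wall_idx] +
      ops$k_v_eff * grid$r_v * grid$w_z * Cv_it
    C1_new <- as.numeric(Matrix::solve(ops$lu, ops$row_scale * rhs))
    C1_it <- omega * C1_new + (1 - omega) * C1
    # C2: pointwise implicit balance (membrane exchange + binding)
    a <- props$alpha_geo * ops$k1_eff
    d2 <- props$delta2
    C2_new <- (d2 / dt * C2o + a * C1_it + d2 * props$k_minus2_ * C3) /
      (d2 / dt + a + d2 * props$k2_ * pmax(props$C0_ - C3, 0))
    C2_it <- omega * C2_new + (1 - omega) * C2
    # C3: pointwise implicit reaction pair; keeps 0 <= C3 <= C0
    C3_new <- (C3o / dt + props$k2_ * C2_it * props$C0_) /
      (1 / dt + props$k2_ * C2_it + props$k_minus2_)
    C3_it <- omega * C3_new + (1 - omega) * C3
    err <- max(max(abs(C1_it - C1)), max(abs(C2_it - C2)),
               max(abs(C3_it - C3)), max(abs(Cv_it - Cv))) / S_C
    res_hist <- c(res_hist, err)
    C1 <- C1_it; C2 <- C2_it; C3 <- C3_it; Cv <- Cv_it
  }
  list(C1 = matrix(pmax(C1, 0), grid$n_r, grid$n_z),
       C2 = matrix(pmax(C2, 0), grid$n_r, grid$n_z),
       C3 = matrix(pmin(pmax(C3, 0), props$C0_), grid$n_r, grid$n_z),
       Cv = pmax(Cv, 0), iterations = it)
}

# Effective material/kinetic properties at (E, t_p): geometry-frozen props
# plus the electro-modulated permeabilities.
effective_props <- function(config, r_v_geom, E, t_p) {
  tis <- config$tissue
  g <- geometry_properties(r_v_geom, tis)
  k1 <- modulated_permeability(E, t_p, tis$k1_min, tis$k1_max,
                               config$electrical_tissue)
  k_v <- modulated_permeability(E, t_p, config$vessel_flow$k_v_min,
                                config$vessel_flow$k_v_max,
                                config$electrical_wall)
  c(g, list(k1 = k1, k_v = k_v,
            k2_ = tis$k2, k_minus2_ = tis$k_minus2, C0_ = tis$C0))
}

#' Advance the coupled tissue/vessel system by one implicit step
#'
#' One implicit-Euler step of the coupled species equations: `C1` receives
#' axisymmetric diffusion, radial advection by the wall-recovery velocity and
#' membrane exchange; `C2` membrane exchange and the association/dissociation
#' pair; `C3` the reaction pair; the vessel profile is advanced in the same
#' step.  The three fields and the vessel profile are swept by an outer
#' Gauss-Seidel iteration with under-relaxation until the maximum scaled
#' field change drops below `cfg$tol`.
#'
#' @param state A [concentration_state()].
#' @param E Field magnitude (kV/m).
#' @param t_p Time since the last pulse (s); ignored when `E = 0`.
#' @param config A [treatment_config()].
#' @param inlet_value Inlet concentration (uM); defaults to the configured PK
#'   profile evaluated at the new time.
#' @param source_C1 Optional manufactured source for the `C1` equation
#'   (`n_r x n_z`, uM/s); verification hook.
#' @return The advanced `ConcentrationState`.
#' @export
advance_tissue <- function(state, E, t_p, config, inlet_value = NULL,
                           source_C1 = NULL) {
  cfg <- config$solver
  stop_if(cfg$dt <= 0, "dt must be positive")
  grid <- state$grid
  props <- effective_props(config, state$r_v, E, t_p)
  drv <- if (E > 0) interface_speed(E, t_p, config$vaso) else 0
  u_r <- tissue_radial_velocity(grid$r, grid$r_v, grid$R_cord, drv)
  u_r[1] <- 0   # wall node flux is carried by the Robin closure
  ops <- build_step_ops(grid, props, props$k1, props$k_v, u_r, cfg$dt)
  lambda_z <- plasma_velocity(grid$z, config$vessel_flow, state$r_v)
  k_v_rate <- wall_exchange_rate(props$k_v, state$r_v)
  if (is.null(inlet_value))
    inlet_value <- inlet_concentration(state$t + cfg$dt, config$pk)
  out <- step_fields(state, ops, grid, props, cfg, lambda_z, k_v_rate,
                     inlet_value, source_C1)
  concentration_state(state$t + cfg$dt, grid, out$C1, out$C2, out$C3,
                      out$Cv, state$r_v, config$tissue$C0)
}

# Linear interpolation of the fields onto a new grid after a remesh, with a
# per-species mass correction so the instantaneous mesh change does not
# create or destroy drug.
remesh_state <- function(state, new_grid, old_props, new_props, C0) {
  interp_field <- function(f) {
    out <- matrix(0, new_grid$n_r, new_grid$n_z)
    for (j in seq_len(state$grid$n_z))
      out[, j] <- stats::approx(state$grid$r, f[, j], xout = new_grid$r,
                                rule = 2)$y
    out
  }
  Vo <- grid_volumes(state$grid); Vn <- grid_volumes(new_grid)
  fields <- list(C1 = state$C1, C2 = state$C2, C3 = state$C3)
  deltas_o <- c(old_props$delta1, old_props$delta2, old_props$delta2)
  deltas_n <- c(new_props$delta1, new_props$delta2, new_props$delta2)
  out <- vector("list", 3); names(out) <- names(fields)
  for (k in 1:3) {
    fi <- interp_field(fields[[k]])
    m_old <- sum(deltas_o[k] * Vo * fields[[k]])
    m_new <- sum(deltas_n[k] * Vn * fi)
    if (m_new > 0) fi <- fi * (m_old / m_new)
    out[[k]] <- fi
  }
  out$C3 <- pmin(out$C3, C0)
  concentration_state(state$t, new_grid, out$C1, out$C2, out$C3,
                      state$Cv, new_grid$r_v, C0)
}

#' Run a full treatment simulation
#'
#' Marches the coupled system from `t = 0` to the treatment horizon,
#' applying the pulse schedule, updating the vessel radius through the
#' vasoconstriction model, remeshing (with mass-preserving interpolation and
#' recomputed geometry-dependent properties) when the radius has moved by
#' more than the remesh threshold since the last mesh, and collecting
#' snapshots at the configured output times (nearest time step).
#'
#' @param config A [treatment_config()].
#' @param verbose Print progress lines.
#' @return A `TreatmentSeries`: list of `ConcentrationState` snapshots plus
#'   the configuration and convergence statistics.
#' @export
run_treatment <- function(config, verbose = FALSE) {
  cfg <- config$solver
  tis <- config$tissue
  sched <- config$schedule
  fs0 <- field_state(0, sched)
  r_hat0 <- if (fs0$E > 0) normalized_radius(fs0$E, fs0$t_p, config$vaso) else 1
  r_v <- r_hat0 * config$vaso$r_v0
  grid <- build_grid(r_v, tis, cfg)
  props <- effective_props(config, r_v, fs0$E, fs0$t_p)
  state <- concentration_state(
    0, grid,
    matrix(0, grid$n_r, grid$n_z), matrix(0, grid$n_r, grid$n_z),
    matrix(0, grid$n_r, grid$n_z), rep(0, grid$n_z), r_v, tis$C0)
  state$Cv[1] <- inlet_concentration(0, config$pk)

  n_steps <- ceiling(cfg$t_end / cfg$dt)
  out_times <- cfg$output_times
  # map each output time to its nearest step index
  snap_steps <- unique(pmin(pmax(round(out_times / cfg$dt), 0L), n_steps))
  snapshots <- vector("list", length(snap_steps))
  names(snapshots) <- as.character(snap_steps)
  if (0 %in% snap_steps) snapshots[["0"]] <- state

  r_v_mesh <- r_v          # radius of the current mesh
  frozen <- FALSE
  ops_cache <- NULL
  cache_key <- NULL
  total_iter <- 0L
  max_iter_seen <- 0L

  for (s in seq_len(n_steps)) {
    t_new <- s * cfg$dt
    fs <- field_state(t_new, sched)
    # vessel radius and freeze logic
    if (fs$E > 0) {
      r_hat <- normalized_radius(fs$E, fs$t_p, config$vaso)
      if (r_hat >= cfg$recovery_freeze) frozen <- TRUE
      if (fs$t_p < cfg$dt) frozen <- FALSE   # a new protocol re-constricts
      if (!frozen) r_v <- r_hat * config$vaso$r_v0
    }
    # remesh when the radius moved enough since the current mesh was built
    if (abs(r_v - r_v_mesh) / config$vaso$r_v0 > cfg$remesh_threshold) {
      new_grid <- build_grid(r_v, tis, cfg)
      new_props <- effective_props(config, r_v, fs$E, fs$t_p)
      state <- remesh_state(state, new_grid, props, new_props, tis$C0)
      grid <- new_grid; props <- new_props
      r_v_mesh <- r_v
      ops_cache <- NULL
    }
    props <- effective_props(config, r_v_mesh, fs$E, fs$t_p)
    drv <- if (fs$E > 0 && !frozen) interface_speed(fs$E, fs$t_p, config$vaso) else 0
    key <- c(r_v_mesh, props$k1, props$k_v, drv)
    if (is.null(ops_cache) || !isTRUE(all.equal(key, cache_key))) {
      u_r <- tissue_radial_velocity(grid$r, grid$r_v, grid$R_cord, drv)
      u_r[1] <- 0
      ops_cache <- build_step_ops(grid, props, props$k1, props$k_v, u_r, cfg$dt)
      cache_key <- key
    }
    lambda_z <- plasma_velocity(grid$z, config$vessel_flow, r_v_mesh)
    k_v_rate <- wall_exchange_rate(props$k_v, r_v_mesh)
    inlet <- inlet_concentration(t_new, config$pk)
    res <- tryCatch(
      step_fields(state, ops_cache, grid, props, cfg, lambda_z, k_v_rate, inlet),
      error = function(e) stop(sprintf("solver failure at t = %.1f s: %s",
                                       t_new, conditionMessage(e)), call. = FALSE))
    state <- concentration_state(t_new, grid, res$C1, res$C2, res$C3,
                                 res$Cv, r_v_mesh, tis$C0)
    total_iter <- total_iter + res$iterations
    max_iter_seen <- max(max_iter_seen, res$iterations)
    if (s %in% snap_steps) snapshots[[as.character(s)]] <- state
    if (verbose && s %% max(1L, n_steps %/% 10L) == 0L)
      message(sprintf("t = %5.2f h  (GS iters: mean %.1f)",
                      t_new / 3600, total_iter / s))
  }
  structure(list(snapshots = unname(snapshots),
                 times = vapply(unname(snapshots), function(x) x$t, 0),
                 config = config,
                 stats = list(steps = n_steps, mean_iter = total_iter / n_steps,
                              max_iter = max_iter_seen)),
            class = "TreatmentSeries")
}

#' @export
print.TreatmentSeries <- function(x, ...) {
  cat(sprintf("<TreatmentSeries> %d snapshots, t = %s h\n",
              length(x$snapshots),
              paste(signif(x$times / 3600, 3), collapse = ", ")))
  cat(sprintf("  %d steps, Gauss-Seidel iters: mean %.1f, max %d\n",
              x$stats$steps, x$stats$mean_iter, x$stats$max_iter))
  invisible(x)
}

#' Export a treatment series as CSV snapshots plus a manifest
#'
#' One long-format CSV per snapshot (`r`, `z`, `C1`, `C2`, `C3`), one vessel
#' CSV (`t`, `z`, `Cv`, `lambda`) and a JSON manifest with the run settings
#' and convergence statistics.
#'
#' @param series A `TreatmentSeries`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vrows <- list()
  for (k in seq_along(series$snapshots)) {
    st <- series$snapshots[[k]]
    g <- st$grid
    df <- data.frame(r = rep(g$r, g$n_z), z = rep(g$z, each = g$n_r),
                     C1 = as.vector(st$C1), C2 = as.vector(st$C2),
                     C3 = as.vector(st$C3))
    utils::write.csv(df, file.path(dir, sprintf("snapshot_%03d.csv", k)),
                     row.names = FALSE)
    lam <- plasma_velocity(g$z, series$config$vessel_flow, st$r_v)
    vrows[[k]] <- data.frame(t = st$t, z = g$z, Cv = st$Cv, lambda = lam)
  }
  utils::write.csv(do.call(rbind, vrows), file.path(dir, "vessel.csv"),
                   row.names = FALSE)
  manifest <- list(times_s = series$times, stats = series$stats,
                   E = series$config$schedule$E,
                   pk = series$config$pk$kind,
                   lambda_inl = series$config$vessel_flow$lambda_inl,
                   n_snapshots = length(series$snapshots))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

grid_from_coords <- function(r, z) {
  n_r <- length(r); n_z <- length(z)
  r_face <- c(r[1], (r[-n_r] + r[-1]) / 2, r[n_r])
  dz <- z[2] - z[1]
  structure(list(r = r, z = z, n_r = n_r, n_z = n_z,
                 dr = r[2] - r[1], dz = dz,
                 r_face = r_face,
                 w_r = (r_face[-1]^2 - r_face[-(n_r + 1)]^2) / 2,
                 w_z = c(dz / 2, rep(dz, n_z - 2), dz / 2),
                 r_v = r[1], R_cord = r[n_r], L_cord = z[n_z]),
            class = "cord_grid")
}

#' Re-import a treatment series exported with [write_series()]
#'
#' @param dir Directory holding `snapshot_*.csv`, `vessel.csv` and
#'   `manifest.json`.
#' @return A `TreatmentSeries` (without the configuration object).
#' @export
read_series <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  vessel <- utils::read.csv(file.path(dir, "vessel.csv"))
  snaps <- lapply(seq_len(man$n_snapshots), function(k) {
    df <- utils::read.csv(file.path(dir, sprintf("snapshot_%03d.csv", k)))
    r <- sort(unique(df$r)); z <- sort(unique(df$z))
    grid <- grid_from_coords(r, z)
    o <- order(df$z, df$r)
    t_k <- man$times_s[k]
    concentration_state(
      t_k, grid,
      matrix(df$C1[o], grid$n_r, grid$n_z),
      matrix(df$C2[o], grid$n_r, grid$n_z),
      matrix(df$C3[o], grid$n_r, grid$n_z),
      vessel$Cv[vessel$t == t_k], r[1])
  })
  structure(list(snapshots = snaps, times = man$times_s, config = NULL,
                 stats = man$stats),
            class = "TreatmentSeries")
}

# Discrete drug mass in the tissue: sum over control volumes of
# delta1 C1 + delta2 (C2 + C3).  Used by the conservation checks.
tissue_mass <- function(state, props) {
  V <- grid_volumes(state$grid)
  sum(V * (props$delta1 * state$C1 + props$delta2 * (state$C2 + state$C3)))
}
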