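#' @keywords internal
"_PACKAGE"

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

new_param_set <- function(x, class) structure(x, class = c(class, "ect_params"))

#' @export
print.ect_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-12s %g\n", nm, flat[[nm]]))
  invisible(x)
}

#' Electrical parameters of a medium
#'
#' Constants describing how one medium (tumor tissue or vessel wall) responds
#' to an applied electric field: the reversible and irreversible field
#' thresholds, the sigmoid fitting constants, the conductivity bounds and the
#' permeability decay time after a pulse.
#'
#' @param E_rev Reversible electroporation threshold (kV/m).
#' @param E_irrev Irreversible electroporation threshold (kV/m); must exceed
#'   `E_rev`.
#' @param alpha_star,beta_star Dimensionless sigmoid fitting constants.
#' @param sigma_max,sigma_min Upper and lower bounds of the effective tissue
#'   conductivity (S/m).
#' @param tau_i Permeability decay time after a pulse (s).
#' @return An `ElectroParams` object (named list).
#' @export
electro_params <- function(E_rev, E_irrev, alpha_star, beta_star,
                           sigma_max, sigma_min, tau_i) {
  p <- list(E_rev = E_rev, E_irrev = E_irrev, alpha_star = alpha_star,
            beta_star = beta_star, sigma_max = sigma_max,
            sigma_min = sigma_min, tau_i = tau_i)
  stop_if(!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)),
          "all electrical parameters must be finite scalars")
  stop_if(!(E_irrev > E_rev && E_rev > 0), "need E_irrev > E_rev > 0")
  stop_if(!(sigma_max > sigma_min && sigma_min > 0), "need sigma_max > sigma_min > 0")
  stop_if(tau_i <= 0, "tau_i must be positive")
  stop_if(alpha_star <= 0 || beta_star <= 0, "alpha_star, beta_star must be positive")
  new_param_set(p, "ElectroParams")
}

#' Electroporation pulse protocol schedule
#'
#' The treatment applies `n_protocols` electroporation protocols; within one
#' protocol the pulse train is collapsed to a single clock that resets at the
#' protocol start time.  Before the first start time the tissue is in the
#' unelectroporated ("no-field") state.
#'
#' @param E Field magnitude applied during the treatment (kV/m).
#' @param protocol_start_times Strictly increasing start times (s).
#' @return A `PulseSchedule` object.
#' @export
pulse_schedule <- function(E, protocol_start_times) {
  stop_if(!is.numeric(E) || length(E) != 1 || E < 0, "E must be a scalar >= 0")
  st <- as.numeric(protocol_start_times)
  stop_if(length(st) > 1 && any(diff(st) <= 0),
          "protocol start times must be strictly increasing")
  structure(list(E = E, protocol_start_times = st, n_protocols = length(st)),
            class = c("PulseSchedule", "ect_params"))
}

#' Vasoconstriction parameters
#'
#' @param m_r Vasoconstriction coefficient (per kV/m).
#' @param tau_r Vessel radius recovery decay time (s).
#' @param r_hat_min Minimum normalized vessel radius, in (0, 1].
#' @param r_v0 Initial (pre-pulse) vessel radius (m).
#' @return A `VasoParams` object.
#' @export
vaso_params <- function(m_r, tau_r, r_hat_min, r_v0) {
  stop_if(!(r_hat_min > 0 && r_hat_min <= 1), "need 0 < r_hat_min <= 1")
  stop_if(tau_r <= 0, "tau_r must be positive")
  stop_if(m_r < 0, "m_r must be >= 0")
  stop_if(r_v0 <= 0, "r_v0 must be positive")
  new_param_set(list(m_r = m_r, tau_r = tau_r, r_hat_min = r_hat_min,
                     r_v0 = r_v0), "VasoParams")
}

#' Vessel flow and wall-exchange parameters
#'
#' @param k_vc Wall filtration (hydraulic) coefficient (m/(Pa s)); may be 0
#'   for an impermeable-to-fluid wall.
#' @param mu Plasma viscosity (Pa s).
#' @param p_inl Inlet blood pressure (Pa).
#' @param p_p Permeate (interstitial) pressure (Pa); must satisfy
#'   `p_inl > p_p` for outward filtration.
#' @param lambda_inl Inlet blood velocity (m/s).
#' @param k_v_min,k_v_max Diffusional wall permeability bounds (m/s).
#' @param L_vessel Vessel segment length (m).
#' @param Q_inl Inlet flow rate (m^3/s); defaults to `pi r_v0^2 lambda_inl`
#'   and is recomputed from the current radius inside the solver.
#' @param r_v0 Reference vessel radius used for the default `Q_inl` (m).
#' @return A `VesselFlowParams` object.
#' @export
vessel_flow_params <- function(k_vc, mu, p_inl, p_p, lambda_inl,
                               k_v_min, k_v_max, L_vessel,
                               r_v0 = NULL, Q_inl = NULL) {
  if (is.null(Q_inl)) {
    stop_if(is.null(r_v0), "give either Q_inl or r_v0")
    Q_inl <- pi * r_v0^2 * lambda_inl
  }
  stop_if(any(c(mu, p_inl, lambda_inl, k_v_max, L_vessel, Q_inl) <= 0),
          "mu, p_inl, lambda_inl, k_v_max, L_vessel, Q_inl must be positive")
  stop_if(k_vc < 0 || k_v_min < 0 || p_p < 0, "k_vc, k_v_min, p_p must be >= 0")
  stop_if(k_v_max < k_v_min, "need k_v_max >= k_v_min")
  new_param_set(list(k_vc = k_vc, mu = mu, p_inl = p_inl, p_p = p_p,
                     Q_inl = Q_inl, lambda_inl = lambda_inl,
                     k_v_min = k_v_min, k_v_max = k_v_max,
                     L_vessel = L_vessel), "VesselFlowParams")
}

#' Tissue transport, reaction and geometry parameters
#'
#' @param D0 Interstitial diffusivity of the drug in the initial
#'   (unconstricted) cord (m^2/s).
#' @param delta1_0 Initial extracellular volume fraction.
#' @param delta2 Intracellular volume fraction of the initial cord.
#' @param alpha_geo Cell-membrane area per unit cord volume (1/m), initial.
#' @param k1_min,k1_max Cell-membrane permeability bounds (m/s).
#' @param k2 Association rate constant (1/(uM s)).
#' @param k_minus2 Dissociation rate constant (1/s).
#' @param C0 Intracellular binding-site concentration (uM); upper bound of
#'   the bound concentration C3.
#' @param R_cord Cord (outer) radius (m).
#' @param L_cord Axial cord length (m).
#' @param r_v0 Initial vessel radius (m); must be below `R_cord`.
#' @return A `TissueParams` object.
#' @export
tissue_params <- function(D0, delta1_0, delta2, alpha_geo, k1_min, k1_max,
                          k2, k_minus2, C0, R_cord, L_cord, r_v0) {
  stop_if(!(delta1_0 > 0 && delta1_0 < 1), "need 0 < delta1_0 < 1")
  stop_if(!(delta2 > 0 && delta2 < 1), "need 0 < delta2 < 1")
  stop_if(C0 <= 0, "C0 must be positive")
  stop_if(any(c(k1_min, k2, k_minus2) < 0), "rates must be >= 0")
  stop_if(k1_max < k1_min, "need k1_max >= k1_min")
  stop_if(D0 <= 0 || alpha_geo <= 0, "D0 and alpha_geo must be positive")
  stop_if(!(R_cord > r_v0 && r_v0 > 0), "need R_cord > r_v0 > 0")
  stop_if(L_cord <= 0, "L_cord must be positive")
  new_param_set(list(D0 = D0, delta1_0 = delta1_0, delta2 = delta2,
                     alpha_geo = alpha_geo, k1_min = k1_min, k1_max = k1_max,
                     k2 = k2, k_minus2 = k_minus2, C0 = C0,
                     R_cord = R_cord, L_cord = L_cord, r_v0 = r_v0),
                "TissueParams")
}

#' Numerical solver settings
#'
#' @param N_points Target total number of collocation nodes (split between the
#'   radial and axial directions by [build_grid()]).
#' @param dt Time step (s).
#' @param omega Under-relaxation factor of the outer Gauss-Seidel sweep over
#'   the three concentration fields, in (0, 1].
#' @param tol Relative convergence threshold of the outer sweep.
#' @param S_L,S_T,S_C Space, time and concentration scale factors used to
#'   non-dimensionalize the linear systems (conditioning); `NULL` selects
#'   the defaults `R_cord`, the treatment horizon, and the maximum inlet
#'   concentration.
#' @param output_times Snapshot times (s).
#' @param remesh_threshold Relative vessel-radius change since the last remesh
#'   that triggers a remesh.
#' @param recovery_freeze Normalized radius above which vasoconstriction
#'   geometry updates are frozen (radius considered recovered).
#' @param max_iter Outer-iteration cap per time step.
#' @param t_end Treatment horizon (s).
#' @return A `SolverConfig` object.
#' @export
solver_config <- function(N_points = 1111, dt = 3.5, omega = 0.30,
                          tol = 1e-6,
                          S_L = NULL, S_T = NULL, S_C = NULL,
                          output_times = c(0, 0.5, 1, 2, 3, 6, 9, 12, 15,
                                           18, 21, 24) * 3600,
                          remesh_threshold = 0.02,
                          recovery_freeze = 0.90,
                          max_iter = 500L,
                          t_end = 24 * 3600) {
  stop_if(N_points < 16, "N_points must allow at least 4 nodes per direction")
  stop_if(dt <= 0, "dt must be positive")
  stop_if(!(omega > 0 && omega <= 1), "need 0 < omega <= 1")
  stop_if(tol <= 0, "tol must be positive")
  new_param_set(list(N_points = as.integer(N_points), dt = dt, omega = omega,
                     tol = tol, S_L = S_L, S_T = S_T, S_C = S_C,
                     output_times = sort(unique(output_times)),
                     remesh_threshold = remesh_threshold,
                     recovery_freeze = recovery_freeze,
                     max_iter = as.integer(max_iter), t_end = t_end),
                "SolverConfig")
}

#' Assemble a full treatment configuration
#'
#' Bundles the per-module parameter sets into the single configuration object
#' consumed by [run_treatment()].
#'
#' @param electrical_tissue,electrical_wall [electro_params()] sets for the
#'   tumor tissue and the vessel wall.
#' @param vaso [vaso_params()].
#' @param vessel_flow [vessel_flow_params()].
#' @param tissue [tissue_params()].
#' @param pk [pk_profile()].
#' @param solver [solver_config()].
#' @param schedule [pulse_schedule()].
#' @return A `TreatmentConfig` object.
#' @export
treatment_config <- function(electrical_tissue, electrical_wall, vaso,
                             vessel_flow, tissue, pk, solver, schedule) {
  stop_if(!inherits(electrical_tissue, "ElectroParams"), "bad electrical_tissue")
  stop_if(!inherits(electrical_wall, "ElectroParams"), "bad electrical_wall")
  stop_if(!inherits(vaso, "VasoParams"), "bad vaso")
  stop_if(!inherits(vessel_flow, "VesselFlowParams"), "bad vessel_flow")
  stop_if(!inherits(tissue, "TissueParams"), "bad tissue")
  stop_if(!inherits(pk, "PKProfile"), "bad pk")
  stop_if(!inherits(solver, "SolverConfig"), "bad solver")
  stop_if(!inherits(schedule, "PulseSchedule"), "bad schedule")
  stop_if(abs(vaso$r_v0 - tissue$r_v0) > 1e-12 * tissue$r_v0,
          "vaso$r_v0 and tissue$r_v0 disagree")
  structure(list(electrical_tissue = electrical_tissue,
                 electrical_wall = electrical_wall,
                 vaso = vaso, vessel_flow = vessel_flow, tissue = tissue,
                 pk = pk, solver = solver, schedule = schedule),
            class = "TreatmentConfig")
}

#' @export
print.TreatmentConfig <- function(x, ...) {
  cat("<TreatmentConfig>\n")
  cat("  E =", x$schedule$E, "kV/m,", x$schedule$n_protocols, "protocol(s)\n")
  cat("  PK:", x$pk$kind, " lambda_inl =", x$vessel_flow$lambda_inl, "m/s\n")
  cat("  grid target:", x$solver$N_points, "nodes, dt =", x$solver$dt, "s\n")
  invisible(x)
}

#' Reference treatment configuration
#'
#' The electrical constants and the pharmacokinetic profiles are the printed
#' treatment values; the transport, reaction, geometry, vasoconstriction and
#' flow constants are a documented reference calibration drawn from
#' doxorubicin tumor-cord literature ranges (see the methods vignette for the
#' rationale behind each value).
#'
#' @param E Field magnitude (kV/m); one of the treatment plan values 0, 46, 70
#'   or any non-negative value.
#' @param lambda_inl Inlet blood velocity (m/s).
#' @param pk_kind `"TPK"` (one-short tri-exponential) or `"UPK"` (uniform).
#' @param N_points,dt,t_end Solver overrides (defaults: the published solver
#'   settings).
#' @param protocol_start_times Protocol starts (s) used when `E > 0`;
#'   defaults to 6 protocols every 4 h.
#' @return A `TreatmentConfig`.
#' @export
reference_config <- function(E = 0, lambda_inl = 1e-4, pk_kind = c("TPK", "UPK"),
                             N_points = 1111, dt = 3.5, t_end = 24 * 3600,
                             protocol_start_times = seq(0, 20, by = 4) * 3600) {
  pk_kind <- match.arg(pk_kind)
  r_v0 <- 1e-5
  tis <- tissue_params(
    D0 = 1.6e-10, delta1_0 = 0.4, delta2 = 0.6, alpha_geo = 2e5,
    k1_min = 3e-9, k1_max = 1e-7,
    k2 = 2e-4, k_minus2 = 1e-6, C0 = 10,
    R_cord = 7.5e-5, L_cord = 1e-3, r_v0 = r_v0)
  cfg <- treatment_config(
    electrical_tissue = electro_params(46, 70, 10, 8, 3.141e-1, 1.998e-2, 100),
    electrical_wall   = electro_params(46, 175, 10, 8, 6.250e-1, 0.630e-2, 100),
    vaso = vaso_params(m_r = 0.05, tau_r = 600, r_hat_min = 0.2, r_v0 = r_v0),
    vessel_flow = vessel_flow_params(
      k_vc = 2e-11, mu = 1.2e-3, p_inl = 2660, p_p = 1330,
      lambda_inl = lambda_inl, k_v_min = 2e-6, k_v_max = 2e-5,
      L_vessel = 1e-3, r_v0 = r_v0),
    tissue = tis,
    pk = pk_profile(pk_kind),
    solver = solver_config(N_points = N_points, dt = dt, t_end = t_end),
    schedule = if (E > 0) pulse_schedule(E, protocol_start_times)
               else pulse_schedule(0, numeric(0)))
  cfg
}

#' Read a treatment configuration from JSON or YAML
#'
#' The file mirrors the constructor arguments in blocks
#' `electrical$tissue`, `electrical$vessel_wall`, `vaso`, `vessel_flow`,
#' `tissue`, `pk`, `solver`, `schedule`.  Missing PK constants default to the
#' published profile values.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `TreatmentConfig`.
#' @export
read_treatment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  el <- raw$electrical
  pkb <- raw$pk
  pk_args <- pkb[setdiff(names(pkb), "kind")]
  treatment_config(
    electrical_tissue = do.call(electro_params, el$tissue),
    electrical_wall = do.call(electro_params, el$vessel_wall),
    vaso = do.call(vaso_params, raw$vaso),
    vessel_flow = do.call(vessel_flow_params, raw$vessel_flow),
    tissue = do.call(tissue_params, raw$tissue),
    pk = do.call(pk_profile, c(list(kind = pkb$kind), pk_args)),
    solver = do.call(solver_config, as.list(raw$solver %||% list())),
    schedule = pulse_schedule(raw$schedule$E %||% 0,
                              raw$schedule$protocol_start_times %||% numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
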