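#' Normalized vessel radius under vasoconstriction and recovery
#'
#' The pulse constricts the vessel in proportion to the field magnitude and
#' the radius recovers exponentially with the time since the pulse:
#' `r_hat = (1 - r_hat_min) exp(-m_r E exp(-t_p/tau_r)) + r_hat_min`.
#' At `E = 0` the radius is unperturbed (`r_hat = 1`); as `t_p -> Inf` it
#' recovers fully.
#'
#' @param E Field magnitude (kV/m).
#' @param t_p Time since the last pulse (s), >= 0; vectorized.
#' @param vaso A [vaso_params()] set.
#' @return Normalized radius in `[r_hat_min, 1]`.
#' @export
normalized_radius <- function(E, t_p, vaso) {
  stopifnot(all(t_p >= 0))
  (1 - vaso$r_hat_min) * exp(-vaso$m_r * E * exp(-t_p / vaso$tau_r)) +
    vaso$r_hat_min
}

#' Tissue-vessel interface speed
#'
#' Analytic time derivative of the vessel radius `r_v = r_v0 r_hat(E, t_p)`:
#' zero without a field, positive (radius recovering) for `E > 0, t_p > 0`.
#'
#' @inheritParams normalized_radius
#' @return Interface speed `dr_v/dt` (m/s).
#' @export
interface_speed <- function(E, t_p, vaso) {
  stopifnot(all(t_p >= 0))
  g <- exp(-t_p / vaso$tau_r)
  vaso$r_v0 * (1 - vaso$r_hat_min) * exp(-vaso$m_r * E * g) *
    (vaso$m_r * E * g / vaso$tau_r)
}

#' Radial tissue velocity induced by vessel wall motion
#'
#' The tissue deforms with the moving wall; the outer cord boundary is fixed,
#' so the radial velocity interpolates linearly from the interface speed at
#' the wall to zero at the cord radius:
#' `u_r = (r - R_cord)/(r_v - R_cord) dr_v/dt`.
#'
#' @param r Radial position(s) (m), inside `[r_v, R_cord]`.
#' @param r_v Current vessel radius (m).
#' @param R_cord Cord radius (m), `> r_v`.
#' @param drv_dt Interface speed (m/s).
#' @return Velocity (m/s).
#' @export
tissue_radial_velocity <- function(r, r_v, R_cord, drv_dt) {
  stop_if(r_v >= R_cord, "need r_v < R_cord")
  if (any(r < r_v - 1e-12 * R_cord | r > R_cord + 1e-12 * R_cord))
    stop("r outside [r_v, R_cord]", call. = FALSE)
  (r - R_cord) / (r_v - R_cord) * drv_dt
}

#' Leakage flow rate through the porous vessel wall
#'
#' Cumulative fluid loss through the wall of a circular porous tube up to
#' axial position `z`, from the coupled Poiseuille/filtration system
#' (`dp/dz = -8 mu Q / (pi r_v^4)`, `dQ/dz = -2 pi r_v k_vc (p - p_p)`):
#' \deqn{Q_{leak}(z) = 2\pi r_v k_{vc}\left[(p_{inl}-p_p)
#'   \frac{e^{\vartheta^* z}-e^{-\vartheta^* z}}{2\vartheta^*}
#'   - \frac{A^*}{32\,\vartheta^*}\left(e^{\vartheta^* z}+e^{-\vartheta^* z}-2\right)\right]}
#' with \eqn{\vartheta^* = \sqrt{16 \mu k_{vc} / r_v^3}} and
#' \eqn{A^* = 128 \mu Q_{inl} / (\pi r_v^4 \vartheta^*)}.
#'
#' @param z Axial position(s) (m), >= 0.
#' @param params A [vessel_flow_params()] set.
#' @param r_v Current vessel radius (m).
#' @return Flow rate (m^3/s); 0 at `z = 0` and identically 0 for `k_vc = 0`.
#' @export
leakage_flow <- function(z, params, r_v) {
  stop_if(r_v <= 0, "r_v must be positive")
  stopifnot(all(z >= 0))
  if (params$k_vc == 0) return(rep(0, length(z)))
  th <- sqrt(16 * params$mu * params$k_vc / r_v^3)
  A_star <- 128 * params$mu * params$Q_inl / (pi * r_v^4 * th)
  dp <- params$p_inl - params$p_p
  x <- th * z
  pre <- 2 * pi * r_v * params$k_vc
  out <- numeric(length(z))
  small <- x < 1e-6
  # series for th*z -> 0 avoids catastrophic cancellation
  out[small] <- pre * (dp * z[small] - (A_star * th / 32) * x[small] * z[small])
  out[!small] <- pre * (dp * sinh(x[!small]) / th -
                          (A_star / (32 * th)) *
                            (exp(x[!small]) + exp(-x[!small]) - 2))
  out
}

#' Axial plasma velocity corrected for wall leakage
#'
#' `lambda(z) = lambda_inl - Q_leak(z) / (pi r_v^2)`.  Warns if the parameter
#' set drains the vessel (negative velocity).
#'
#' @inheritParams leakage_flow
#' @return Velocity (m/s), `lambda(0) = lambda_inl`.
#' @export
plasma_velocity <- function(z, params, r_v) {
  lam <- params$lambda_inl - leakage_flow(z, params, r_v) / (pi * r_v^2)
  if (any(lam < 0))
    warning("plasma velocity negative: leakage drains the vessel", call. = FALSE)
  lam
}

#' One implicit step of the intravascular drug transport equation
#'
#' Advances `dCv/dt = -lambda(z) dCv/dz + k_v_rate (C1_wall - Cv)` by one
#' implicit-Euler step with first-order backward (upwind) differences,
#' solved node by node in increasing `z` (the inlet node is pinned to the
#' prescribed inlet value).  Unconditionally stable; preserves the discrete
#' maximum principle.
#'
#' @param C_v Vessel concentration per z-node (uM).
#' @param C1_wall Extracellular concentration at the wall per z-node (uM).
#' @param lambda Plasma velocity per z-node (m/s).
#' @param k_v_rate Wall exchange rate (1/s); the velocity-form permeability
#'   `k_v` converts as `2 k_v / r_v` (cylinder surface-to-volume), see
#'   [wall_exchange_rate()].
#' @param dt Time step (s).
#' @param dz Axial node spacing (m).
#' @param inlet_value Inlet concentration (uM) pinned at node 1.
#' @return Updated `C_v`.
#' @export
advance_vessel_concentration <- function(C_v, C1_wall, lambda, k_v_rate,
                                         dt, dz, inlet_value) {
  stop_if(dt <= 0 || dz <= 0, "dt and dz must be positive")
  n <- length(C_v)
  stop_if(length(C1_wall) != n || length(lambda) != n,
          "C_v, C1_wall and lambda must have equal length")
  if (any(C_v < 0) || any(C1_wall < 0) || any(inlet_value < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  new <- numeric(n)
  new[1] <- inlet_value
  if (n > 1) {
    a <- lambda * dt / dz
    for (i in 2:n) {
      new[i] <- (C_v[i] + a[i] * new[i - 1] + dt * k_v_rate * C1_wall[i]) /
        (1 + a[i] + dt * k_v_rate)
    }
  }
  new
}

#' Wall exchange rate from the velocity-form permeability
#'
#' The wall boundary condition uses a permeability with velocity units while
#' the intravascular transport equation uses a rate; the two are reconciled
#' by the surface-to-volume ratio of the cylindrical vessel segment:
#' `k_v_rate = 2 k_v / r_v`.
#'
#' @param k_v Wall permeability (m/s).
#' @param r_v Vessel radius (m).
#' @return Exchange rate (1/s).
#' @export
wall_exchange_rate <- function(k_v, r_v) 2 * k_v / r_v
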