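#' Sigmoid fitting coefficients of the conductivity curve
#'
#' The effective-conductivity sigmoid is centred midway between the
#' reversible and irreversible thresholds and its width is their separation
#' scaled by `beta_star`:
#' `a* = (E_rev + E_irrev)/2`, `b* = (E_irrev - E_rev)/beta_star`.
#'
#' @param params An [electro_params()] set.
#' @return Named numeric vector `c(a_star, b_star)` in kV/m.
#' @export
sigmoid_coefficients <- function(params) {
  c(a_star = (params$E_rev + params$E_irrev) / 2,
    b_star = (params$E_irrev - params$E_rev) / params$beta_star)
}

#' Effective electrical conductivity at field magnitude E
#'
#' Sigmoidal interpolation between `sigma_min` (intact membranes) and
#' `sigma_max` (fully permeabilized):
#' `sigma(E) = (sigma_max - sigma_min) / (1 + alpha* exp(-(E - a*)/b*)) + sigma_min`.
#' Strictly increasing in `E` and bounded in `(sigma_min, sigma_max)`.
#'
#' @param E Field magnitude (kV/m); vectorized.
#' @inheritParams sigmoid_coefficients
#' @return Conductivity (S/m).
#' @export
effective_conductivity <- function(E, params) {
  stopifnot(all(E >= 0))
  ab <- sigmoid_coefficients(params)
  (params$sigma_max - params$sigma_min) /
    (1 + params$alpha_star * exp(-(E - ab[["a_star"]]) / ab[["b_star"]])) +
    params$sigma_min
}

#' Electroporation degree functions DOE, DIE and DOER
#'
#' `DOE` is the overall degree of electroporation, the conductivity rise
#' normalized to its full range.  `DIE` is the irreversible part, zero below
#' the irreversible threshold and the rise above `sigma(E_irrev)` normalized
#' to the remaining range otherwise.  `DOER` is the transient degree that
#' decays from `DOE` toward `DIE` with the time `t_p` since the last pulse:
#' `DOER = DOE (1 - DIE) exp(-t_p/tau_i) + DIE`.
#'
#' @param E Field magnitude (kV/m).
#' @param t_p Time since the last pulse (s); must be >= 0.
#' @inheritParams sigmoid_coefficients
#' @return Named numeric vector `c(DOE, DIE, DOER)`, each in `[0, 1]`.
#' @export
electroporation_degrees <- function(E, t_p, params) {
  if (any(t_p < 0)) stop("t_p must be >= 0", call. = FALSE)
  s <- effective_conductivity(E, params)
  DOE <- (s - params$sigma_min) / (params$sigma_max - params$sigma_min)
  if (E < params$E_irrev) {
    DIE <- 0
  } else {
    s_irrev <- effective_conductivity(params$E_irrev, params)
    DIE <- (s - s_irrev) / (params$sigma_max - s_irrev)
  }
  DOER <- DOE * (1 - DIE) * exp(-t_p / params$tau_i) + DIE
  c(DOE = DOE, DIE = DIE, DOER = DOER)
}

#' Permeability modulated by the transient electroporation degree
#'
#' Affine interpolation between the intact and the fully permeabilized
#' membrane permeability: `k = DOER (k_max - k_min) + k_min`.
#'
#' @inheritParams electroporation_degrees
#' @param k_min,k_max Permeability bounds (m/s), `k_max >= k_min >= 0`.
#' @return Permeability (m/s) in `[k_min, k_max]`.
#' @export
modulated_permeability <- function(E, t_p, k_min, k_max, params) {
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  if (k_min < 0) stop("k_min must be >= 0", call. = FALSE)
  d <- electroporation_degrees(E, t_p, params)
  unname(d["DOER"] * (k_max - k_min) + k_min)
}

#' Time since the last electroporation protocol
#'
#' Maps absolute treatment time to the pulse clock `t_p`.  Before the first
#' protocol the tissue is in the "no-field" state: the return value is `NA`
#' and callers must treat the field as absent (`DOER = 0`, `r_hat = 1`).
#'
#' @param t Absolute time (s), >= 0.
#' @param schedule A [pulse_schedule()].
#' @return `t_p` in seconds, or `NA_real_` if no protocol has started yet
#'   (including an empty schedule, i.e. an untreated run).
#' @export
pulse_clock <- function(t, schedule) {
  stopifnot(t >= 0)
  st <- schedule$protocol_start_times
  st <- st[st <= t]
  if (length(st) == 0) return(NA_real_)
  t - max(st)
}

# Field magnitude and pulse clock resolved at absolute time t; E = 0 before
# the first protocol.
field_state <- function(t, schedule) {
  tp <- pulse_clock(t, schedule)
  if (is.na(tp) || schedule$E == 0) list(E = 0, t_p = 0)
  else list(E = schedule$E, t_p = tp)
}
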