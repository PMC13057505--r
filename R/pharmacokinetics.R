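# Printed constants of the one-short tri-exponential doxorubicin plasma
# profile: initial dose Do (umol), infusion duration tau' (s), and the three
# exponential amplitude (1/L) / rate (1/s) pairs.
tpk_defaults <- function() {
  list(Do = 1.1983e2, tau_prime = 180,
       A1 = 7.46e-2, A2 = 2.69e-3,
       B1 = 2.49e-3, B2 = 2.83e-4,
       C1 = 5.52e-4, C2 = 1.18e-5)
}

# Amount-per-litre from Eq-form constants is umol/L, which is numerically uM;
# kept as an explicit named constant so an alternative volume-of-distribution
# convention is a one-line change.
UM_PER_UMOL_PER_L <- 1

#' Inlet pharmacokinetic profile
#'
#' Two inlet concentration profiles are supported: `"TPK"`, a one-short
#' tri-exponential infusion (rising during the infusion time `tau_prime`,
#' tri-exponentially decaying afterwards), and `"UPK"`, a uniform profile
#' held constant for the whole treatment.
#'
#' @param kind `"TPK"` or `"UPK"`.
#' @param value Constant inlet concentration for UPK (uM).
#' @param Do Initial dose (umol), TPK.
#' @param tau_prime Infusion duration (s), TPK.
#' @param A1,A2,B1,B2,C1,C2 Amplitude (1/L) and rate (1/s) constants of the
#'   three exponential terms, TPK.
#' @return A `PKProfile` object.
#' @export
pk_profile <- function(kind = c("TPK", "UPK"), value = 3.85802e-2,
                       Do = NULL, tau_prime = NULL,
                       A1 = NULL, A2 = NULL, B1 = NULL, B2 = NULL,
                       C1 = NULL, C2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "UPK") {
    stop_if(value < 0, "UPK value must be >= 0")
    return(structure(list(kind = "UPK", value = value),
                     class = c("PKProfile", "ect_params")))
  }
  d <- tpk_defaults()
  p <- list(kind = "TPK",
            Do = Do %||% d$Do, tau_prime = tau_prime %||% d$tau_prime,
            A1 = A1 %||% d$A1, A2 = A2 %||% d$A2,
            B1 = B1 %||% d$B1, B2 = B2 %||% d$B2,
            C1 = C1 %||% d$C1, C2 = C2 %||% d$C2)
  stop_if(p$tau_prime <= 0, "tau_prime must be positive")
  stop_if(any(unlist(p[c("A2", "B2", "C2")]) <= 0), "rate constants must be positive")
  structure(p, class = c("PKProfile", "ect_params"))
}

#' Inlet drug concentration at time t
#'
#' Evaluates the inlet boundary value of the vessel concentration.  For the
#' tri-exponential profile the infusion branch applies for `t <= tau_prime`
#' and the decay branch afterwards; the two branches agree at `tau_prime`.
#'
#' @param t Time (s); vectorized, must be >= 0.
#' @param profile A [pk_profile()].
#' @return Concentration (uM).
#' @export
inlet_concentration <- function(t, profile) {
  stopifnot(all(t >= 0))
  if (profile$kind == "UPK") return(rep(profile$value, length(t)))
  p <- profile
  pre <- p$Do / p$tau_prime * UM_PER_UMOL_PER_L
  term <- function(amp, rate, t, infusion) {
    if (infusion) amp / rate * (1 - exp(-rate * t))
    else amp / rate * (exp(rate * p$tau_prime) - 1) * exp(-rate * t)
  }
  branch <- function(t, infusion) {
    pre * (term(p$A1, p$A2, t, infusion) +
           term(p$B1, p$B2, t, infusion) +
           term(p$C1, p$C2, t, infusion))
  }
  ifelse(t <= p$tau_prime, branch(t, TRUE), branch(t, FALSE))
}
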