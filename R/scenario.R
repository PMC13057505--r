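# Trend classification of two concentration snapshots into per-node ratio
# scenarios for the inference engine.

# Trend of the ratio a/b between two snapshots, by cross-multiplication
# (avoids 0/0): "I" when a_j b_i >= (1 - tol) a_i b_j, else "D".  Exact ties
# (including the all-zero case) classify as "I", matching the
# "increases or remains equal" reading of the trend propositions.
ratio_trend <- function(a_i, b_i, a_j, b_j, tol) {
  ifelse(a_j * b_i >= (1 - tol) * a_i * b_j, "I", "D")
}

field_trend <- function(f_i, f_j, tol) {
  ifelse(f_j >= (1 - tol) * f_i, "I", "D")
}

# Safe later-snapshot ratio for the transmembrane direction; the 0/0 case is
# reported as exact balance.
safe_ratio <- function(num, den) {
  r <- num / den
  r[den == 0 & num == 0] <- 1
  r[den == 0 & num > 0] <- Inf
  r
}

#' Per-node ratio dynamics between two snapshots
#'
#' Classifies, at every grid node, the trends of `C2/C1`, `C3/C1`, `C3/C2`,
#' `C3` and `C1` between two output times (ties count as increases), the
#' transmembrane direction from the later `C2/C1` level, the net reaction
#' from the `C3` trend, and the binding-saturation flag (`C3` within
#' tolerance of `C0`, which suppresses the association reading).
#'
#' @param state_i,state_j Two [concentration_state()]s on the same grid with
#'   `state_j$t > state_i$t`.
#' @param tol Relative tie tolerance for the trend comparisons.
#' @param C0 Binding-site concentration (uM) for the saturation flag;
#'   `Inf` disables it.
#' @return A `RatioDynamics` data frame: one row per node with columns `r`,
#'   `z`, the five trends, `tmt`, `reaction`, `saturated`.
#' @export
scenario_from_states <- function(state_i, state_j, tol = 1e-9, C0 = Inf) {
  gi <- state_i$grid; gj <- state_j$grid
  stop_if(!isTRUE(all.equal(gi$r, gj$r)) || !isTRUE(all.equal(gi$z, gj$z)),
          "snapshots live on different grids")
  stop_if(state_j$t <= state_i$t, "state_j must be later than state_i")
  C1i <- as.vector(state_i$C1); C2i <- as.vector(state_i$C2)
  C3i <- as.vector(state_i$C3)
  C1j <- as.vector(state_j$C1); C2j <- as.vector(state_j$C2)
  C3j <- as.vector(state_j$C3)
  ratio_j <- safe_ratio(C2j, C1j)
  df <- data.frame(
    r = rep(gi$r, gi$n_z), z = rep(gi$z, each = gi$n_r),
    trend_C2C1 = ratio_trend(C2i, C1i, C2j, C1j, tol),
    trend_C3C1 = ratio_trend(C3i, C1i, C3j, C1j, tol),
    trend_C3C2 = ratio_trend(C3i, C2i, C3j, C2j, tol),
    trend_C3 = field_trend(C3i, C3j, tol),
    trend_C1 = field_trend(C1i, C1j, tol),
    tmt = tmt_direction(ratio_j, tol),
    saturated = C3j >= C0 * (1 - tol))
  df$reaction <- ifelse(df$trend_C3 == "D", "DIS", "AS")
  class(df) <- c("RatioDynamics", "data.frame")
  df
}
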