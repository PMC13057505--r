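#' Structured collocation grid on the annular cord
#'
#' Uniform tensor grid on `[r_v, R_cord] x [0, L_cord]`.  The target node
#' count is split between the two directions as evenly as the total allows;
#' the inner radial line sits exactly at the current vessel radius.
#'
#' @param r_v Current vessel radius (m), `< R_cord`.
#' @param params A [tissue_params()] set.
#' @param cfg A [solver_config()].
#' @return A `cord_grid`: node coordinates `r`, `z`, spacings, face radii and
#'   control-volume weights used by the finite-volume operators.
#' @export
build_grid <- function(r_v, params, cfg) {
  stop_if(r_v >= params$R_cord, "degenerate annulus: r_v >= R_cord")
  stop_if(r_v <= 0, "r_v must be positive")
  n_r <- max(4L, as.integer(floor(sqrt(cfg$N_points))))
  n_z <- max(4L, as.integer(floor(cfg$N_points / n_r)))
  r <- seq(r_v, params$R_cord, length.out = n_r)
  z <- seq(0, params$L_cord, length.out = n_z)
  dr <- r[2] - r[1]
  dz <- z[2] - z[1]
  r_face <- c(r[1], (r[-n_r] + r[-1]) / 2, r[n_r])   # n_r + 1 face radii
  w_r <- (r_face[-1]^2 - r_face[-(n_r + 1)]^2) / 2    # radial volume weights
  w_z <- c(dz / 2, rep(dz, n_z - 2), dz / 2)          # axial widths
  structure(list(r = r, z = z, n_r = n_r, n_z = n_z, dr = dr, dz = dz,
                 r_face = r_face, w_r = w_r, w_z = w_z,
                 r_v = r_v, R_cord = params$R_cord, L_cord = params$L_cord),
            class = "cord_grid")
}

#' @export
print.cord_grid <- function(x, ...) {
  cat(sprintf("<cord_grid> %d x %d nodes, r in [%.3g, %.3g] m, z in [0, %.3g] m\n",
              x$n_r, x$n_z, x$r_v, x$R_cord, x$L_cord))
  invisible(x)
}

# Control volumes (2*pi dropped) as an n_r x n_z matrix.
grid_volumes <- function(grid) outer(grid$w_r, grid$w_z)

#' Geometry-dependent tissue properties at the current vessel radius
#'
#' Vasoconstriction changes the annulus volume while the cellular material is
#' conserved, so the intracellular volume fraction and the membrane area
#' density scale with the inverse domain volume; the extracellular fraction
#' closes the two-phase balance and carries the diffusivity correction
#' `D = D0 delta1 / delta1_0`.
#'
#' @param r_v Current vessel radius (m).
#' @param params A [tissue_params()] set (initial-state values).
#' @return List with `delta1`, `delta2`, `alpha_geo`, `D`.
#' @export
geometry_properties <- function(r_v, params) {
  stop_if(r_v <= 0 || r_v >= params$R_cord, "r_v outside (0, R_cord)")
  V0 <- params$R_cord^2 - params$r_v0^2   # pi*L cancels in the ratio
  V  <- params$R_cord^2 - r_v^2
  scale <- V0 / V
  delta2 <- params$delta2 * scale
  stop_if(delta2 >= 1, "over-compressed domain: delta2 >= 1")
  delta1 <- 1 - delta2
  list(delta1 = delta1, delta2 = delta2,
       alpha_geo = params$alpha_geo * scale,
       D = params$D0 * delta1 / params$delta1_0)
}

# Sparse finite-volume operator for -div(D grad C) on the annulus
# (cylindrical flux form), plus the Robin wall closure.  Returns the matrix
# contributions only; Robin right-hand-side terms are supplied per step.
# Index convention: node (i, j) -> i + (j-1)*n_r (radial index fastest).
assemble_diffusion <- function(grid, D) {
  n_r <- grid$n_r; n_z <- grid$n_z
  idx <- function(i, j) i + (j - 1L) * n_r
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }
  # radial faces between (i, j) and (i+1, j)
  for (i in seq_len(n_r - 1)) {
    g <- D * grid$r_face[i + 1] / grid$dr * grid$w_z       # length n_z
    a <- idx(i, seq_len(n_z)); b <- idx(i + 1, seq_len(n_z))
    add(a, a, g); add(b, b, g); add(a, b, -g); add(b, a, -g)
  }
  # axial faces between (i, j) and (i, j+1)
  for (j in seq_len(n_z - 1)) {
    g <- D * grid$w_r / grid$dz                            # length n_r
    a <- idx(seq_len(n_r), j); b <- idx(seq_len(n_r), j + 1)
    add(a, a, g); add(b, b, g); add(a, b, -g); add(b, a, -g)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n_r * n_z, n_r * n_z))
}

# Upwind operator for V * u_r dC/dr with u_r >= 0 (wall recovery); first
# radial line is excluded (the wall flux is carried by the Robin closure).
assemble_advection <- function(grid, u_r) {
  n_r <- grid$n_r; n_z <- grid$n_z
  if (all(u_r == 0)) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                 dims = c(n_r * n_z, n_r * n_z)))
  idx <- function(i, j) i + (j - 1L) * n_r
  V <- grid_volumes(grid)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in 2:n_r) {
    coef <- V[i, ] * u_r[i] / grid$dr
    a <- idx(i, seq_len(n_z)); b <- idx(i - 1, seq_len(n_z))
    ii <- c(ii, a, a); jj <- c(jj, a, b); xx <- c(xx, coef, -coef)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n_r * n_z, n_r * n_z))
}

# Diagonal Robin contribution k_v * (wall area per z node) at the inner line,
# as a vector over all nodes (zero away from the wall).
robin_diagonal <- function(grid, k_v) {
  d <- numeric(grid$n_r * grid$n_z)
  wall <- 1L + (seq_len(grid$n_z) - 1L) * grid$n_r
  d[wall] <- k_v * grid$r_v * grid$w_z
  d
}

# Steady diffusion solve with Robin wall data and an interior source:
# used for manufactured-solution verification of the spatial operator.
solve_steady_diffusion <- function(grid, D, k_v, Cv, source) {
  A <- assemble_diffusion(grid, D)
  rob <- robin_diagonal(grid, k_v)
  M <- A + Matrix::Diagonal(x = rob)
  V <- as.vector(grid_volumes(grid))
  rhs <- V * as.vector(source)
  wall <- 1L + (seq_len(grid$n_z) - 1L) * grid$n_r
  rhs[wall] <- rhs[wall] + k_v * grid$r_v * grid$w_z * Cv
  matrix(as.numeric(Matrix::solve(M, rhs)), grid$n_r, grid$n_z)
}
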