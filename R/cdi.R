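# Inverse measurement chain: phase map -> B_z -> current density via
# Ampere's law (single measurable component approximation).

#' Convert a CDI phase map to magnetic flux density
#'
#' Inverts the phase encoding: `B_z = phi / (gamma_p * tc)`.
#'
#' @param phase A `phase` [ep_map()] (rad).
#' @param tc Current-encoding time in seconds (must be positive).
#' @return A `bz` [ep_map()] (T).
#' @export
phase_to_bz <- function(phase, tc = 4e-4) {
  if (!is.finite(tc) || tc <= 0) stop("phase_to_bz: tc must be positive")
  grid <- map_grid(phase)
  gam <- physical_constants()$gamma_p
  ep_map(map_data(phase) / (gam * tc), grid, "bz")
}

#' Current density from a single measured B_z component (Ampere's law)
#'
#' The standard single-component CDI inversion for z-invariant in-plane
#' currents: `j_x = (1/mu0) dB_z/dy`, `j_y = -(1/mu0) dB_z/dx`, by central
#' differences (one-sided at the edges). The out-of-slice derivative terms of
#' the full curl are not measurable with one encoding orientation and are
#' neglected, the usual 2D operating assumption.
#'
#' @param bz A `bz` [ep_map()] (T) on a grid of at least 3 x 3 pixels.
#' @param smooth_mm Optional Gaussian pre-smoothing width (mm) applied to
#'   B_z before differentiation to control noise amplification; default 0
#'   (off).
#' @return A [current_density()] (A/m^2).
#' @export
#' @examples
#' g <- grid_spec(16, fov_mm = 16)
#' co <- coord_grids(g)
#' bz <- ep_map(physical_constants()$mu0 * co$y / 1000, g, "bz")
#' J <- bz_to_current(bz)
#' range(J$j_x)  # 1 A/m^2 everywhere
bz_to_current <- function(bz, smooth_mm = 0) {
  grid <- map_grid(bz)
  if (grid$n_x < 3L || grid$n_y < 3L)
    stop("bz_to_current: grid too small (need at least 3x3)")
  b <- map_data(bz)
  if (smooth_mm > 0) b <- gaussian_smooth(b, smooth_mm / grid$pixel_mm)
  mu0 <- physical_constants()$mu0
  h_m <- grid$pixel_mm / 1000
  g <- grad2d(b, h_m)
  current_density(g$dy / mu0, -g$dx / mu0, grid)
}

#' Pointwise magnitude of a current density map
#'
#' @param J A [current_density()].
#' @return A `current_mag` [ep_map()] (A/m^2), nonnegative.
#' @export
current_magnitude <- function(J) {
  if (!inherits(J, "current_density")) stop("current_magnitude: expected a current_density")
  ep_map(sqrt(J$j_x^2 + J$j_y^2), J$grid, "current_mag")
}

#' Drive current through an electrode (per unit slice thickness)
#'
#' Sums the discrete face fluxes of `sigma grad u` leaving the electrode's
#' pixel set, the exact conserved current of the finite-difference scheme.
#' This is the synthetic analogue of the drive current a current probe
#' records during pulse delivery; the slice-normal direction carries the
#' per-meter normalization (A/m).
#'
#' @param u Potential [ep_map()] (V) from [solve_potential()].
#' @param sigma Conductivity [ep_map()] (S/m) the solve used.
#' @param electrodes An [electrode_config()].
#' @param which Electrode to integrate around, `"a"` or `"b"`.
#' @return Signed line current in A/m (positive = current leaves the
#'   electrode).
#' @export
line_current <- function(u, sigma, electrodes, which = c("a", "b")) {
  which <- match.arg(which)
  grid <- map_grid(u)
  check_same_grid(grid, map_grid(sigma), "potential and conductivity maps")
  mask <- electrode_pixel_masks(grid, electrodes)[[which]]
  uu <- map_data(u); s <- map_data(sigma)
  n_y <- grid$n_y; n_x <- grid$n_x
  harm <- function(a, b) 2 * a * b / (a + b)
  I <- 0
  for (pix in which(mask)) {
    iy <- (pix - 1L) %% n_y + 1L; ix <- (pix - 1L) %/% n_y + 1L
    for (q in list(c(iy, ix - 1L), c(iy, ix + 1L), c(iy - 1L, ix), c(iy + 1L, ix))) {
      if (q[1] >= 1L && q[1] <= n_y && q[2] >= 1L && q[2] <= n_x &&
          !mask[q[1], q[2]])
        I <- I + harm(s[iy, ix], s[q[1], q[2]]) * (uu[iy, ix] - uu[q[1], q[2]])
    }
  }
  I
}

#' Full CDI current recovery with model completion
#'
#' A single measured B_z component determines only the curl-bearing
#' (solenoidal) part of the in-plane current; for needle electrodes in
#' near-homogeneous tissue the current is almost entirely curl-free, so the
#' bare Ampere inversion of [bz_to_current()] cannot see it. The missing
#' curl-free component is supplied by a model: the current of a
#' homogeneous-conductivity solve with the known electrode geometry and
#' potentials, scaled so its drive current matches the measured one. The
#' recovered current is
#' `J = J_ref + (1/mu0) curl_z^{-1}(B_z - B_z(J_ref))`,
#' i.e. the reference current plus the Ampere inversion of the measured
#' B_z deviation from the reference prediction. This is why MREIT
#' reconstruction takes the electrode geometry and potentials as inputs
#' alongside the CDI data.
#'
#' @param bz Measured `bz` [ep_map()] (T).
#' @param electrodes An [electrode_config()] with the applied potentials.
#' @param i_line Measured drive current in A/m (see [line_current()]); used
#'   to scale the homogeneous reference. Exactly one of `i_line` and
#'   `sigma_ref` must be given.
#' @param sigma_ref Alternatively, a reference conductivity (scalar or
#'   [ep_map()]) to solve the model on directly.
#' @param smooth_mm Optional Gaussian pre-smoothing of the B_z deviation
#'   before differentiation (mm); default off.
#' @param solver_tol Relative residual tolerance of the reference solve.
#' @return A [current_density()] (A/m^2).
#' @export
cdi_current <- function(bz, electrodes, i_line = NULL, sigma_ref = NULL,
                        smooth_mm = 0, solver_tol = 1e-8) {
  grid <- map_grid(bz)
  if (is.null(i_line) == is.null(sigma_ref))
    stop("cdi_current: supply exactly one of i_line or sigma_ref")
  if (!is.null(i_line)) {
    s_unit <- ep_map(matrix(1, grid$n_y, grid$n_x), grid, "conductivity")
    u1 <- solve_potential(s_unit, electrodes, tol = solver_tol)
    i_unit <- line_current(u1, s_unit, electrodes, "a")
    scale <- i_line / i_unit
    fl <- compute_fields(u1, s_unit)
    j_ref <- current_density(fl$current$j_x * scale, fl$current$j_y * scale, grid)
  } else {
    s_ref <- if (inherits(sigma_ref, "ep_map")) sigma_ref else
      ep_map(matrix(sigma_ref, grid$n_y, grid$n_x), grid, "conductivity")
    u_ref <- solve_potential(s_ref, electrodes, tol = solver_tol)
    j_ref <- compute_fields(u_ref, s_ref)$current
  }
  bz_ref <- biot_savart_bz(j_ref)
  d_bz <- ep_map(map_data(bz) - map_data(bz_ref), grid, "bz")
  dj <- bz_to_current(d_bz, smooth_mm = smooth_mm)
  current_density(j_ref$j_x + dj$j_x, j_ref$j_y + dj$j_y, grid)
}
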