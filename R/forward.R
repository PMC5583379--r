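# Forward physics: potential solve on a conductivity map, field/current
# derivation via Ohm's law, Biot-Savart synthesis of the B_z map a CDI
# acquisition would measure, and CDI phase encoding.

# Logical masks of pixels covered by each electrode disk. The needle radius
# (0.25 mm) is below half a pixel at the default grid, so each disk is
# guaranteed to contain at least the pixel nearest its center.
electrode_pixel_masks <- function(grid, electrodes) {
  co <- coord_grids(grid)
  one <- function(ctr) {
    d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2
    m <- d2 <= (electrodes$diameter_mm / 2)^2
    if (!any(m)) m[which.min(d2)] <- TRUE
    m
  }
  list(a = one(electrodes$center_a), b = one(electrodes$center_b))
}

# Pixels within `dilate_px` pixels of either electrode disk; used to exclude
# the singular electrode-adjacent region from quantitative error metrics.
#' Electrode-adjacent exclusion mask
#'
#' Returns a logical mask of pixels within the electrode disks plus a
#' `dilate_px`-pixel annulus around them. Current density is singular next to
#' the needles, so quantitative reconstruction metrics conventionally exclude
#' this region.
#'
#' @param grid A [grid_spec()].
#' @param electrodes An [electrode_config()].
#' @param dilate_px Annulus width in pixels (default 2).
#' @return Logical matrix, `TRUE` on excluded pixels.
#' @export
electrode_exclusion_mask <- function(grid, electrodes, dilate_px = 2) {
  co <- coord_grids(grid)
  r <- electrodes$diameter_mm / 2 + dilate_px * grid$pixel_mm
  da <- (co$x - electrodes$center_a[1])^2 + (co$y - electrodes$center_a[2])^2
  db <- (co$x - electrodes$center_b[1])^2 + (co$y - electrodes$center_b[2])^2
  da <= r^2 | db <= r^2
}

#' Solve the electrostatic potential with fixed-potential pixels
#'
#' Low-level solver for `div(sigma grad u) = 0` on the grid with arbitrary
#' Dirichlet pixels and zero-flux (insulating) outer boundaries. Conductivity
#' is averaged harmonically at cell faces so flux stays continuous across
#' conductivity jumps. The sparse symmetric system is solved directly; the
#' relative residual is verified against `tol` afterwards and a failure is
#' reported together with the achieved residual.
#'
#' @param sigma Conductivity [ep_map()] (S/m), strictly positive.
#' @param fixed_idx Integer vector of column-major pixel indices held at
#'   fixed potential.
#' @param fixed_val Numeric vector of potentials (V), same length.
#' @param tol Relative residual tolerance (default 1e-8).
#' @return A `potential` [ep_map()] (V) with attribute `residual`.
#' @export
solve_potential_fixed <- function(sigma, fixed_idx, fixed_val, tol = 1e-8) {
  grid <- map_grid(sigma)
  s <- map_data(sigma)
  if (any(s <= 0)) stop("solve_potential: conductivity must be positive everywhere")
  if (length(fixed_idx) == 0L)
    stop("solve_potential: configuration error - no fixed-potential (electrode) pixels")
  if (length(fixed_idx) != length(fixed_val))
    stop("solve_potential: fixed_idx and fixed_val lengths differ")
  n_y <- grid$n_y; n_x <- grid$n_x; N <- n_y * n_x

  idx <- matrix(seq_len(N), n_y, n_x)   # column-major pixel ids
  harm <- function(a, b) 2 * a * b / (a + b)

  # horizontal faces (x neighbors) and vertical faces (y neighbors)
  wh <- harm(s[, 1:(n_x - 1L)], s[, 2:n_x])
  p_h <- as.vector(idx[, 1:(n_x - 1L)]); q_h <- as.vector(idx[, 2:n_x])
  wv <- harm(s[1:(n_y - 1L), ], s[2:n_y, ])
  p_v <- as.vector(idx[1:(n_y - 1L), ]); q_v <- as.vector(idx[2:n_y, ])

  p <- c(p_h, p_v); q <- c(q_h, q_v); w <- c(as.vector(wh), as.vector(wv))
  A <- Matrix::sparseMatrix(
    i = c(p, q, p, q), j = c(q, p, p, q), x = c(-w, -w, w, w),
    dims = c(N, N))

  fixed <- logical(N); fixed[fixed_idx] <- TRUE
  u <- numeric(N); u[fixed_idx] <- fixed_val
  if (all(fixed)) {
    res <- 0
  } else {
    A_ff <- A[!fixed, !fixed, drop = FALSE]
    rhs <- -as.numeric(A[!fixed, fixed, drop = FALSE] %*% u[fixed])
    u_f <- as.numeric(Matrix::solve(A_ff, rhs))
    res_vec <- as.numeric(A_ff %*% u_f) - rhs
    denom <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
    res <- sqrt(sum(res_vec^2)) / denom
    if (!is.finite(res) || res > tol)
      stop(sprintf("solve_potential: solver failed to reach tol %.3g (relative residual %.3g)",
                   tol, res))
    u[!fixed] <- u_f
  }
  out <- ep_map(matrix(u, n_y, n_x), grid, "potential")
  attr(out, "residual") <- res
  out
}

#' Solve the electrostatic potential for an electrode pair
#'
#' Solves `div(sigma grad u) = 0` with the two electrode disks held at their
#' applied potentials (Dirichlet data) and insulating outer boundaries. This
#' is the potential problem at the heart of the iterative conductivity
#' reconstruction.
#'
#' @param sigma Conductivity [ep_map()] (S/m), strictly positive.
#' @param electrodes An [electrode_config()] inside the field of view.
#' @param tol Relative residual tolerance.
#' @param max_iter Retained for interface compatibility with iterative
#'   solvers; the sparse direct solve either meets `tol` or fails.
#' @return A `potential` [ep_map()] (V) with attribute `residual`.
#' @export
#' @examples
#' ph <- make_phantom(seed = 1)
#' u <- solve_potential(ph$sigma_true, ph$electrodes)
#' range(u)  # bracketed by the electrode potentials
solve_potential <- function(sigma, electrodes, tol = 1e-8, max_iter = 1000L) {
  grid <- map_grid(sigma)
  check_electrodes_in_fov(electrodes, grid)
  em <- electrode_pixel_masks(grid, electrodes)
  fixed_idx <- c(which(em$a), which(em$b))
  fixed_val <- c(rep(electrodes$potential_a, sum(em$a)),
                 rep(electrodes$potential_b, sum(em$b)))
  solve_potential_fixed(sigma, fixed_idx, fixed_val, tol = tol)
}

#' Electric field and current density from a potential map
#'
#' Ohm's law in the forward direction: `E = -grad u` by central differences
#' (one-sided at the outer boundary) and `J = sigma E` componentwise. The
#' grid spacing is converted from mm so the field comes out in V/m and the
#' current density in A/m^2.
#'
#' @param u Potential [ep_map()] (V).
#' @param sigma Conductivity [ep_map()] (S/m) on the same grid.
#' @return List with `e_x`, `e_y` (matrices, V/m), `e_mag` (an `efield`
#'   [ep_map()], V/m) and `current` (a [current_density()], A/m^2).
#' @export
compute_fields <- function(u, sigma) {
  grid <- map_grid(u)
  check_same_grid(grid, map_grid(sigma), "potential and conductivity maps")
  h_m <- grid$pixel_mm / 1000
  g <- grad2d(map_data(u), h_m)
  e_x <- -g$dx; e_y <- -g$dy
  s <- map_data(sigma)
  list(
    e_x = e_x, e_y = e_y,
    e_mag = ep_map(sqrt(e_x^2 + e_y^2), grid, "efield"),
    current = current_density(s * e_x, s * e_y, grid)
  )
}

#' Magnetic flux density B_z induced by an in-plane current distribution
#'
#' Forward model for the CDI measurement: each pixel is treated as a line
#' current running perpendicular to the slice (the needles are parallel to
#' the scanner field, and the slice is thick), giving the two-dimensional
#' Biot-Savart kernel
#' `B_z(r) = (mu0 / 2 pi) * sum_r' [j_x (y - y') - j_y (x - x')] / |r - r'|^2 dA'`
#' evaluated by FFT convolution with the singular self term set to zero.
#'
#' @param J A [current_density()] (A/m^2).
#' @return A `bz` [ep_map()] (T).
#' @export
biot_savart_bz <- function(J) {
  grid <- J$grid
  h_m <- grid$pixel_mm / 1000
  dA <- h_m^2
  mu0 <- physical_constants()$mu0
  ky <- function(dx, dy) { r2 <- dx^2 + dy^2; k <- dy / r2; k[r2 == 0] <- 0; k }
  kx <- function(dx, dy) { r2 <- dx^2 + dy^2; k <- dx / r2; k[r2 == 0] <- 0; k }
  bz <- (mu0 / (2 * pi)) * dA *
    (conv_kernel2d(J$j_x, ky, h_m) - conv_kernel2d(J$j_y, kx, h_m))
  ep_map(bz, grid, "bz")
}

#' Synthesize a current-encoded CDI phase map
#'
#' Phase accumulated by proton spins during the current-encoding window:
#' `phi = gamma_p * B_z * tc`, optionally with additive Gaussian noise of
#' standard deviation `max |phi| / snr`. Phase unwrapping is not modeled
#' (it is acquisition-specific), so an error is raised if the noise-free
#' phase leaves `(-pi, pi]`; synthetic phantoms at the default grid stay
#' well inside that range.
#'
#' @param bz A `bz` [ep_map()] (T).
#' @param tc Current-encoding time in seconds; the emulated sequence applies
#'   four 100 us pulses inside the encoding window, so the effective default
#'   is `4e-4` s of current-on time.
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param seed Integer seed for the noise draw.
#' @return A `phase` [ep_map()] (rad).
#' @export
synthesize_cdi_phase <- function(bz, tc = 4e-4, snr = Inf, seed = 1L) {
  if (!is.finite(tc) || tc <= 0) stop("synthesize_cdi_phase: tc must be positive")
  if (is.na(snr) || snr <= 0) stop("synthesize_cdi_phase: snr must be positive (or Inf)")
  grid <- map_grid(bz)
  gam <- physical_constants()$gamma_p
  phi <- gam * map_data(bz) * tc
  if (max(abs(phi)) > pi)
    stop(sprintf(
      "synthesize_cdi_phase: encoding phase exceeds pi (max |phi| = %.3g rad); phase unwrapping is not modeled",
      max(abs(phi))))
  if (is.finite(snr)) {
    set.seed(as.integer(seed))
    phi <- phi + stats::rnorm(length(phi), sd = max(abs(phi)) / snr)
  }
  ep_map(matrix(phi, grid$n_y, grid$n_x), grid, "phase")
}
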