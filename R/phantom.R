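#' Needle electrode pair configuration
#'
#' Two parallel needle electrodes inserted perpendicular to the imaging
#' slice, modeled in 2D as disks of the needle diameter. Physical needles in
#' the emulated protocol are 0.5 mm in diameter and are driven with a fixed
#' potential difference (700 V by default across the pipeline).
#'
#' @param center_a,center_b Length-2 numeric vectors `(x, y)` in mm giving
#'   the in-plane electrode centers.
#' @param diameter_mm Electrode diameter in mm.
#' @param potential_a,potential_b Applied potentials in volts.
#' @return An object of class `electrode_config`.
#' @export
electrode_config <- function(center_a, center_b, diameter_mm = 0.5,
                             potential_a = 350, potential_b = -350) {
  stopifnot(length(center_a) == 2L, length(center_b) == 2L)
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("electrode_config: diameter_mm must be positive")
  gap <- sqrt(sum((center_a - center_b)^2))
  if (gap < diameter_mm)
    stop(sprintf(
      "electrode_config: electrodes overlap (center distance %.3g mm < diameter %.3g mm)",
      gap, diameter_mm))
  structure(
    list(center_a = as.numeric(center_a), center_b = as.numeric(center_b),
         diameter_mm = diameter_mm,
         potential_a = potential_a, potential_b = potential_b),
    class = "electrode_config"
  )
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf(
    "<electrode_config> A (%.2f, %.2f) mm @ %g V | B (%.2f, %.2f) mm @ %g V | d = %g mm\n",
    x$center_a[1], x$center_a[2], x$potential_a,
    x$center_b[1], x$center_b[2], x$potential_b, x$diameter_mm))
  invisible(x)
}

check_electrodes_in_fov <- function(electrodes, grid) {
  r <- electrodes$diameter_mm / 2
  for (ctr in list(electrodes$center_a, electrodes$center_b)) {
    if (any(ctr - r < 0) || any(ctr + r > grid$fov_mm))
      stop("electrode lies outside the field of view")
  }
  invisible(TRUE)
}

#' Generate a synthetic conductivity phantom with an embedded tumor
#'
#' Builds the test-bed object every downstream stage runs on: a circular (or
#' elliptical) tumor of conductivity `sigma_tumor` embedded in a homogeneous
#' background of `sigma_background`, with a needle electrode pair placed
#' symmetrically about the tumor center along x. Optionally the tumor
#' conductivity is made heterogeneous with a smooth multiplicative random
#' field (see [add_heterogeneity()]); tumor conductivity in vivo can vary by
#' up to roughly 20 percent, which is what the default emulation targets.
#'
#' Tumor/background conductivity defaults are assumptions (soft tissue around
#' 0.2 S/m, tumor more conductive at 0.4 S/m); no measured values are
#' available for the emulated system.
#'
#' @param grid A [grid_spec()]; defaults to the 64 x 64 / 30 mm acquisition.
#' @param tumor_radius_mm Tumor cross-section radius along x in mm (a tumor
#'   of roughly 40 mm^3 has a cross-sectional radius near 2.1-2.5 mm).
#' @param sigma_background,sigma_tumor Conductivities in S/m, both positive.
#' @param electrode_gap_mm Center-to-center electrode distance in mm; the
#'   emulated treatments used 1.2-3.3 mm depending on tumor size.
#' @param voltage Applied electrode-to-electrode voltage (V); split
#'   symmetrically as +V/2 and -V/2.
#' @param electrode_diameter_mm Needle diameter in mm.
#' @param heterogeneity_cv Coefficient of variation of the tumor conductivity
#'   heterogeneity (0 for a piecewise-constant phantom).
#' @param correlation_len_mm Correlation length of the heterogeneity field.
#' @param tumor_aspect Ratio of the y to the x tumor semi-axis (1 = circle).
#' @param seed Integer seed; phantoms are bit-reproducible given the seed.
#' @return An object of class `phantom_case`: list with `grid`, `sigma_true`
#'   (an [ep_map()]), `electrodes`, `tumor_mask` (logical matrix) and `seed`.
#' @export
#' @examples
#' ph <- make_phantom(electrode_gap_mm = 2.2, seed = 1)
#' range(ph$sigma_true)
make_phantom <- function(grid = grid_spec(),
                         tumor_radius_mm = 2.2,
                         sigma_background = 0.2,
                         sigma_tumor = 0.4,
                         electrode_gap_mm = 2.2,
                         voltage = 700,
                         electrode_diameter_mm = 0.5,
                         heterogeneity_cv = 0,
                         correlation_len_mm = 1.5,
                         tumor_aspect = 1,
                         seed = 1L) {
  if (sigma_background <= 0 || sigma_tumor <= 0)
    stop("make_phantom: conductivities must be positive")
  if (electrode_gap_mm < electrode_diameter_mm)
    stop("make_phantom: electrode gap smaller than electrode diameter")
  cx <- grid$fov_mm / 2; cy <- grid$fov_mm / 2
  if (cx + tumor_radius_mm > grid$fov_mm || tumor_radius_mm <= 0)
    stop("make_phantom: tumor does not fit in the field of view")

  co <- coord_grids(grid)
  rx <- tumor_radius_mm; ry <- tumor_radius_mm * tumor_aspect
  tumor_mask <- ((co$x - cx) / rx)^2 + ((co$y - cy) / ry)^2 <= 1

  sigma <- matrix(sigma_background, grid$n_y, grid$n_x)
  sigma[tumor_mask] <- sigma_tumor
  sigma <- ep_map(sigma, grid, "conductivity")
  if (heterogeneity_cv > 0)
    sigma <- add_heterogeneity(sigma, cv = heterogeneity_cv,
                               correlation_len_mm = correlation_len_mm,
                               seed = derive_seed(seed, 1L),
                               mask = tumor_mask)

  electrodes <- electrode_config(
    center_a = c(cx - electrode_gap_mm / 2, cy),
    center_b = c(cx + electrode_gap_mm / 2, cy),
    diameter_mm = electrode_diameter_mm,
    potential_a = voltage / 2, potential_b = -voltage / 2)
  check_electrodes_in_fov(electrodes, grid)

  structure(
    list(grid = grid, sigma_true = sigma, electrodes = electrodes,
         tumor_mask = tumor_mask, seed = as.integer(seed)),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case> %d x %d / %g mm; sigma in [%.3g, %.3g] S/m; tumor %d px; seed %d\n",
    x$grid$n_y, x$grid$n_x, x$grid$fov_mm,
    min(x$sigma_true), max(x$sigma_true), sum(x$tumor_mask), x$seed))
  invisible(x)
}

#' Multiply a conductivity map by a smooth positive random field
#'
#' Emulates tissue heterogeneity: Gaussian-filtered white noise is rescaled
#' in the log domain so the multiplier is log-normal with the requested
#' coefficient of variation over the target region, then divided by its
#' realized mean there so the mean conductivity is preserved. The multiplier
#' is strictly positive by construction, so the output conductivity stays
#' positive for any `cv < 1`.
#'
#' @param sigma Conductivity [ep_map()] (or plain matrix with a grid attr).
#' @param cv Target coefficient of variation, `0 <= cv < 1`. `cv = 0`
#'   returns the input unchanged.
#' @param correlation_len_mm Gaussian smoothing length (mm) of the field.
#' @param seed Integer seed.
#' @param mask Logical matrix selecting where heterogeneity applies
#'   (default: everywhere).
#' @return A conductivity [ep_map()] of the same shape.
#' @export
add_heterogeneity <- function(sigma, cv, correlation_len_mm = 1.5, seed = 1L,
                              mask = NULL) {
  if (!is.finite(cv) || cv < 0 || cv >= 1)
    stop("add_heterogeneity: cv must satisfy 0 <= cv < 1")
  grid <- map_grid(sigma)
  if (cv == 0) return(sigma)
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_y, grid$n_x)
  if (sum(mask) < 2L) stop("add_heterogeneity: mask selects fewer than 2 pixels")

  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(grid$n_y * grid$n_x), grid$n_y, grid$n_x)
  z <- gaussian_smooth(z, sd_px = correlation_len_mm / grid$pixel_mm)
  # standardize over the masked region, then exponentiate with the log-sd
  # that gives a log-normal multiplier of the requested cv
  z <- (z - mean(z[mask])) / stats::sd(z[mask])
  a <- sqrt(log1p(cv^2))
  m <- exp(a * z)
  m <- m / mean(m[mask])

  out <- map_data(sigma)
  out[mask] <- out[mask] * m[mask]
  ep_map(out, grid, "conductivity")
}

#' Ground-truth ablation region of a phantom
#'
#' The synthetic stand-in for a histology reference: solves the forward
#' problem on the phantom's true conductivity, applies the Peleg-Fermi death
#' model for the given pulse protocol, and thresholds the death-probability
#' map at level `p`. Downstream agreement statistics compare reconstruction-
#' based predicted areas against these reference areas.
#'
#' @param phantom A [make_phantom()] result.
#' @param protocol A [pulse_protocol()]; its `(N, t_p)` pair must exist in
#'   the bundled Peleg-Fermi parameter table.
#' @param p Death-probability level in `[0, 1)`; `p = 0` returns the entire
#'   domain (death probability is nonnegative everywhere).
#' @param params Optional [peleg_fermi_params()] overriding the table lookup.
#' @param mask Optional logical matrix restricting the counted region.
#' @param tol,max_iter Passed to [solve_potential()].
#' @return List with `region` (logical matrix), `area_mm2`, and the true
#'   `e_mag` field map (V/m).
#' @export
ground_truth_ablation <- function(phantom, protocol = pulse_protocol(), p,
                                  params = NULL, mask = NULL,
                                  tol = 1e-8, max_iter = 1000L) {
  if (!is.finite(p) || p < 0 || p >= 1)
    stop("ground_truth_ablation: p must be in [0, 1)")
  if (is.null(params)) params <- lookup_params(protocol)
  u <- solve_potential(phantom$sigma_true, phantom$electrodes,
                       tol = tol, max_iter = max_iter)
  fl <- compute_fields(u, phantom$sigma_true)
  d <- death_map(fl$e_mag, params)
  grid <- phantom$grid
  region <- map_data(d) >= p
  if (!is.null(mask)) region <- region & mask
  list(region = region,
       area_mm2 = sum(region) * grid$pixel_mm^2,
       e_mag = fl$e_mag,
       death = d)
}
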