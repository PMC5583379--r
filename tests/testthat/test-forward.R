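test_that("plate mode reproduces the analytic uniform field", {
  # left column 0 V, right column 1 V across a 10 mm field of view
  g <- grid_spec(32, fov_mm = 10)
  sigma <- ep_map(matrix(0.25, 32, 32), g, "conductivity")
  left <- seq_len(32)                     # column 1 (column-major ids)
  right <- (31L * 32L) + seq_len(32)      # column 32
  u <- solve_potential_fixed(sigma, c(left, right),
                             c(rep(0, 32), rep(1, 32)))

  # the linear ramp between the plate columns solves the scheme exactly
  span_m <- (32 - 1) * g$pixel_mm / 1000
  x <- (seq_len(32) - 1) * g$pixel_mm / 1000
  expect_equal(unclass(u)[16, ], x / span_m, tolerance = 1e-10)

  fl <- compute_fields(u, sigma)
  e_expect <- 1 / span_m                  # V/m; about 1 V/cm over ~1 cm
  interior <- 2:31
  expect_lt(max(abs(unclass(fl$e_mag)[interior, interior] - e_expect)) / e_expect,
            0.005)
  # J = sigma E; u rises along +x so the current flows along -x
  expect_equal(fl$current$j_x[interior, interior],
               matrix(-0.25 * e_expect, 30, 30), tolerance = 1e-10)
  expect_equal(max(abs(fl$current$j_y[interior, interior])), 0, tolerance = 1e-6)
})

test_that("two needle electrodes match the two-line-source closed form", {
  # large homogeneous domain so the insulating boundary barely perturbs the
  # free-space solution; evaluate well inside, away from the needles
  n <- 128; fov <- 60
  g <- grid_spec(n, fov_mm = fov)
  ph <- make_phantom(grid = g, sigma_background = 0.3, sigma_tumor = 0.3,
                     electrode_gap_mm = 6, voltage = 700,
                     tumor_radius_mm = 2, seed = 1)
  u <- solve_potential(ph$sigma_true, ph$electrodes)

  co <- mreitire:::coord_grids(g)
  ra <- sqrt((co$x - ph$electrodes$center_a[1])^2 +
               (co$y - ph$electrodes$center_a[2])^2)
  rb <- sqrt((co$x - ph$electrodes$center_b[1])^2 +
               (co$y - ph$electrodes$center_b[2])^2)
  rc <- sqrt((co$x - fov / 2)^2 + (co$y - fov / 2)^2)
  m <- !electrode_exclusion_mask(g, ph$electrodes, dilate_px = 4) & rc < fov / 6

  # u = alpha log(rb/ra) + C with alpha = I / (2 pi sigma) fitted from the
  # solution (the drive current is an output of the Dirichlet problem)
  fit <- stats::lm(as.vector(unclass(u))[m] ~ as.vector(log(rb / ra))[m])
  rel <- max(abs(stats::resid(fit))) / diff(range(unclass(u)[m]))
  expect_lt(rel, 0.02)

  # the fitted alpha also pins the drive current; cross-check against the
  # face-flux current of the same solution
  i_fit <- 2 * pi * 0.3 * coef(fit)[2]
  i_flux <- line_current(u, ph$sigma_true, ph$electrodes, "a")
  expect_lt(abs(i_fit - i_flux) / i_flux, 0.10)
})

test_that("potential respects the discrete maximum principle and linearity", {
  cs <- homog_case()
  expect_gte(min(cs$u), cs$ph$electrodes$potential_b - 1e-9)
  expect_lte(max(cs$u), cs$ph$electrodes$potential_a + 1e-9)

  # swapping electrode potentials negates u up to the additive constant
  el_sw <- cs$ph$electrodes
  el_sw$potential_a <- cs$ph$electrodes$potential_b
  el_sw$potential_b <- cs$ph$electrodes$potential_a
  u_sw <- solve_potential(cs$ph$sigma_true, el_sw)
  vsum <- cs$ph$electrodes$potential_a + cs$ph$electrodes$potential_b
  expect_equal(unclass(u_sw), vsum - unclass(cs$u), tolerance = 1e-9)

  # scaling the drive scales u, E, J, B_z linearly
  el_2 <- cs$ph$electrodes
  el_2$potential_a <- 2 * el_2$potential_a
  el_2$potential_b <- 2 * el_2$potential_b
  u2 <- solve_potential(cs$ph$sigma_true, el_2)
  expect_equal(unclass(u2), 2 * unclass(cs$u), tolerance = 1e-9)
  fl2 <- compute_fields(u2, cs$ph$sigma_true)
  expect_equal(unclass(fl2$e_mag), 2 * unclass(cs$fields$e_mag), tolerance = 1e-9)
  bz1 <- biot_savart_bz(cs$fields$current)
  bz2 <- biot_savart_bz(fl2$current)
  expect_equal(unclass(bz2), 2 * unclass(bz1), tolerance = 1e-9)

  # failure modes: no electrode pixels, non-positive conductivity
  g <- cs$grid
  expect_error(solve_potential_fixed(cs$ph$sigma_true, integer(0), numeric(0)),
               "configuration error")
  bad <- ep_map(matrix(-1, g$n_y, g$n_x), g, "conductivity")
  expect_error(solve_potential(bad, cs$ph$electrodes), "positive")
})

test_that("interior closed-form error shrinks under grid refinement", {
  err_at <- function(n) {
    g <- grid_spec(n, fov_mm = 60)
    ph <- make_phantom(grid = g, sigma_background = 0.3, sigma_tumor = 0.3,
                       electrode_gap_mm = 6, voltage = 700,
                       tumor_radius_mm = 2, seed = 1)
    u <- solve_potential(ph$sigma_true, ph$electrodes)
    co <- mreitire:::coord_grids(g)
    ra <- sqrt((co$x - ph$electrodes$center_a[1])^2 +
                 (co$y - ph$electrodes$center_a[2])^2)
    rb <- sqrt((co$x - ph$electrodes$center_b[1])^2 +
                 (co$y - ph$electrodes$center_b[2])^2)
    rc <- sqrt((co$x - 30)^2 + (co$y - 30)^2)
    m <- !electrode_exclusion_mask(g, ph$electrodes, dilate_px = 4) & rc < 10
    fit <- stats::lm(as.vector(unclass(u))[m] ~ as.vector(log(rb / ra))[m])
    max(abs(stats::resid(fit))) / diff(range(unclass(u)[m]))
  }
  expect_lt(err_at(128), err_at(64))
})

test_that("field and current derivation is exact on analytic potentials", {
  g <- grid_spec(16, fov_mm = 16)
  co <- mreitire:::coord_grids(g)
  # u with slope -100 V/m along x
  u <- ep_map(-100 * co$x / 1000, g, "potential")
  sigma <- ep_map(matrix(0.5, 16, 16), g, "conductivity")
  fl <- compute_fields(u, sigma)
  expect_equal(bare(fl$e_mag), matrix(100, 16, 16), tolerance = 1e-12)
  expect_equal(fl$current$j_x, matrix(50, 16, 16), tolerance = 1e-12)
  expect_equal(fl$current$j_y, matrix(0, 16, 16), tolerance = 1e-12)

  # constant potential: zero field, zero current
  u0 <- ep_map(matrix(3, 16, 16), g, "potential")
  fl0 <- compute_fields(u0, sigma)
  expect_equal(max(unclass(fl0$e_mag)), 0)
  expect_equal(max(abs(fl0$current$j_x)), 0)

  # shape mismatch is refused
  sig_small <- ep_map(matrix(0.5, 8, 8), grid_spec(8, fov_mm = 16), "conductivity")
  expect_error(compute_fields(u, sig_small), "different grids")
})

test_that("current density is discretely divergence-free away from electrodes", {
  cs <- homog_case()
  J <- cs$fields$current
  div <- mreitire:::grad2d(J$j_x, 1)$dx + mreitire:::grad2d(J$j_y, 1)$dy
  co <- mreitire:::coord_grids(cs$grid)
  da <- sqrt((co$x - cs$ph$electrodes$center_a[1])^2 +
               (co$y - cs$ph$electrodes$center_a[2])^2)
  db <- sqrt((co$x - cs$ph$electrodes$center_b[1])^2 +
               (co$y - cs$ph$electrodes$center_b[2])^2)
  far <- pmin(da, db) / cs$grid$pixel_mm >= 8
  bnd <- matrix(FALSE, 64, 64)
  bnd[1:2, ] <- TRUE; bnd[63:64, ] <- TRUE; bnd[, 1:2] <- TRUE; bnd[, 63:64] <- TRUE
  max_j <- max(sqrt(J$j_x^2 + J$j_y^2))
  expect_lt(max(abs(div[far & !bnd])), 1e-3 * max_j)
})

test_that("Biot-Savart matches the straight-wire closed form and is odd in J", {
  g <- grid_spec(64, fov_mm = 30)
  h_m <- g$pixel_mm / 1000
  jx <- matrix(0, 64, 64); jy <- matrix(0, 64, 64)
  jx[32, 32] <- 1e3
  J <- current_density(jx, jy, g)
  bz <- biot_savart_bz(J)
  i_line <- 1e3 * h_m^2
  mu0 <- physical_constants()$mu0
  for (d in c(3, 5, 10)) {
    expect_equal(unclass(bz)[32 + d, 32], mu0 * i_line / (2 * pi * d * h_m),
                 tolerance = 0.03)
  }
  # self pixel zeroed, zero input gives zero output
  expect_equal(unclass(bz)[32, 32], 0)
  bz0 <- biot_savart_bz(current_density(matrix(0, 64, 64), matrix(0, 64, 64), g))
  expect_equal(max(abs(bz0)), 0)

  # reversing all currents negates B_z exactly
  Jn <- current_density(-jx, -jy, g)
  expect_equal(unclass(biot_savart_bz(Jn)), -unclass(bz), tolerance = 1e-14)
})

test_that("phase encoding follows gamma * B * tc and guards its domain", {
  g <- grid_spec(8, fov_mm = 8)
  bz <- ep_map(matrix(1e-6, 8, 8), g, "bz")
  phi <- synthesize_cdi_phase(bz, tc = 4e-4, snr = Inf)
  expect_equal(unclass(phi)[1, 1], 0.107, tolerance = 1e-12)

  bz0 <- ep_map(matrix(0, 8, 8), g, "bz")
  expect_equal(max(abs(synthesize_cdi_phase(bz0, tc = 4e-4, snr = Inf))), 0)

  # noise-free round trip is exact
  expect_equal(unclass(phase_to_bz(phi, tc = 4e-4)), unclass(bz),
               tolerance = 1e-14)

  # noisy synthesis is seeded and reproducible
  p1 <- synthesize_cdi_phase(bz, tc = 4e-4, snr = 20, seed = 9)
  p2 <- synthesize_cdi_phase(bz, tc = 4e-4, snr = 20, seed = 9)
  expect_identical(unclass(p1), unclass(p2))

  expect_error(synthesize_cdi_phase(bz, tc = 0), "tc")
  big <- ep_map(matrix(1e-3, 8, 8), g, "bz")
  expect_error(synthesize_cdi_phase(big, tc = 4e-4), "exceeds pi")
})
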