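# Independent oracles, coded separately from the package paths they check.

# Strip map metadata, keeping only the numeric matrix.
bare <- function(m) array(as.numeric(m), dim = dim(m))

# Potential solver with ARITHMETIC face averaging and its own assembly loop;
# deliberately a different discretization than the package (harmonic faces)
# so phantom-level comparisons are a genuine cross-check.
oracle_solve_potential <- function(sigma, grid, fixed_idx, fixed_val) {
  n_y <- grid$n_y; n_x <- grid$n_x; N <- n_y * n_x
  s <- as.matrix(sigma)
  idx <- matrix(seq_len(N), n_y, n_x)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  add <- function(p, q, w) {
    trip_i <<- c(trip_i, p, q, p, q)
    trip_j <<- c(trip_j, q, p, p, q)
    trip_x <<- c(trip_x, -w, -w, w, w)
  }
  wh <- (s[, 1:(n_x - 1)] + s[, 2:n_x]) / 2
  add(as.vector(idx[, 1:(n_x - 1)]), as.vector(idx[, 2:n_x]), as.vector(wh))
  wv <- (s[1:(n_y - 1), ] + s[2:n_y, ]) / 2
  add(as.vector(idx[1:(n_y - 1), ]), as.vector(idx[2:n_y, ]), as.vector(wv))
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(N, N))
  fixed <- logical(N); fixed[fixed_idx] <- TRUE
  u <- numeric(N); u[fixed_idx] <- fixed_val
  rhs <- -as.numeric(A[!fixed, fixed, drop = FALSE] %*% u[fixed])
  u[!fixed] <- as.numeric(Matrix::solve(A[!fixed, !fixed, drop = FALSE], rhs))
  matrix(u, n_y, n_x)
}

# Ordinary least squares by explicit normal-equation formulas.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  se_slope <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  tval <- slope / se_slope
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}

# Bland-Altman quantities by direct formulas.
oracle_bland_altman <- function(a, b) {
  d <- a - b
  m <- (a + b) / 2
  n <- length(d)
  mu <- sum(d) / n
  sdd <- sqrt(sum((d - mu)^2) / (n - 1))
  r <- sum((d - mean(d)) * (m - mean(m))) /
    sqrt(sum((d - mean(d))^2) * sum((m - mean(m))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(mean_diff = mu, sd_diff = sdd,
       loa_low = mu - 1.96 * sdd, loa_high = mu + 1.96 * sdd,
       r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# Shared fixture: homogeneous two-needle phantom and its forward solution.
homog_case <- function(n = 64, fov = 30, gap = 2, sigma = 0.3, voltage = 700) {
  g <- grid_spec(n, fov_mm = fov)
  ph <- make_phantom(grid = g, sigma_background = sigma, sigma_tumor = sigma,
                     electrode_gap_mm = gap, voltage = voltage,
                     tumor_radius_mm = 2.2, seed = 1)
  u <- solve_potential(ph$sigma_true, ph$electrodes)
  fl <- compute_fields(u, ph$sigma_true)
  list(grid = g, ph = ph, u = u, fields = fl)
}
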