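# Internal numerics helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Physical constants used by the forward and inverse CDI chain
#'
#' Single authoritative definition of the vacuum permeability and the proton
#' gyromagnetic ratio; both the magnetic flux synthesis and the Ampere-law
#' inversion draw from here so the two directions of the chain can never
#' disagree on constants.
#'
#' @return A list with `mu0` (vacuum permeability, T m/A) and `gamma_p`
#'   (proton gyromagnetic ratio, rad s^-1 T^-1).
#' @export
#' @examples
#' physical_constants()$mu0  # 4 pi 1e-7
physical_constants <- function() {
  list(mu0 = 4 * pi * 1e-7, gamma_p = 2.675e8)
}

# Central-difference gradient of a scalar map, one-sided at the edges.
# `h` is the (uniform) grid spacing in the unit the caller wants the
# derivative expressed in. Columns index x, rows index y.
grad2d <- function(u, h) {
  u <- unclass(u)
  n_y <- nrow(u); n_x <- ncol(u)
  if (is.null(n_y) || n_x < 3L || n_y < 3L)
    stop("grid too small for finite differences: need at least 3x3")
  dudx <- matrix(0, n_y, n_x)
  dudx[, 2:(n_x - 1L)] <- (u[, 3:n_x] - u[, 1:(n_x - 2L)]) / (2 * h)
  dudx[, 1L]  <- (u[, 2L] - u[, 1L]) / h
  dudx[, n_x] <- (u[, n_x] - u[, n_x - 1L]) / h
  dudy <- matrix(0, n_y, n_x)
  dudy[2:(n_y - 1L), ] <- (u[3:n_y, ] - u[1:(n_y - 2L), ]) / (2 * h)
  dudy[1L, ]  <- (u[2L, ] - u[1L, ]) / h
  dudy[n_y, ] <- (u[n_y, ] - u[n_y - 1L, ]) / h
  list(dx = dudx, dy = dudy)
}

# Linear convolution of `field` with a translation-invariant kernel,
# evaluated by FFT on a zero-padded (2 n_y) x (2 n_x) grid. `kernel_fun`
# receives matrices of displacements (dx, dy) in the same length unit as `h`
# and must return the kernel value (it is responsible for zeroing the
# singular self term at dx = dy = 0).
conv_kernel2d <- function(field, kernel_fun, h) {
  field <- unclass(field)
  n_y <- nrow(field); n_x <- ncol(field)
  m_y <- 2L * n_y; m_x <- 2L * n_x
  disp_y <- c(0:(n_y - 1L), seq.int(-n_y, -1L)) * h
  disp_x <- c(0:(n_x - 1L), seq.int(-n_x, -1L)) * h
  dy <- matrix(disp_y, m_y, m_x)
  dx <- matrix(disp_x, m_y, m_x, byrow = TRUE)
  k <- kernel_fun(dx, dy)
  fpad <- matrix(0, m_y, m_x)
  fpad[1:n_y, 1:n_x] <- field
  out <- Re(stats::fft(stats::fft(fpad) * stats::fft(k), inverse = TRUE)) / (m_y * m_x)
  out[1:n_y, 1:n_x]
}

# Gaussian smoothing by FFT convolution (periodic wrap); sd in pixels.
gaussian_smooth <- function(field, sd_px) {
  if (sd_px <= 0) return(unclass(field))
  field <- unclass(field)
  n_y <- nrow(field); n_x <- ncol(field)
  wy <- c(0:(n_y %/% 2), seq.int(-(n_y - n_y %/% 2 - 1L), -1L))
  wx <- c(0:(n_x %/% 2), seq.int(-(n_x - n_x %/% 2 - 1L), -1L))
  ky <- exp(-wy^2 / (2 * sd_px^2))
  kx <- exp(-wx^2 / (2 * sd_px^2))
  k <- outer(ky, kx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(field) * stats::fft(k), inverse = TRUE)) / (n_y * n_x)
}

# Deterministic derivation of per-stage / per-case seeds from one master
# seed; keeps everything inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1009 + 7) %% 2147483647)
}
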