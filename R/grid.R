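#' Regular square imaging grid
#'
#' All maps in the package live on a square pixel grid covering a square
#' field of view. Pixel centers sit at `(i - 0.5) * pixel_mm` with the origin
#' at the lower-left corner of the domain; maps are stored as matrices with
#' rows indexing y and columns indexing x. The default matches the
#' acquisition geometry used throughout: a 30 mm field of view sampled on a
#' 64 x 64 matrix.
#'
#' @param n_x Number of pixels along x.
#' @param n_y Number of pixels along y; must equal `n_x`.
#' @param fov_mm Field-of-view width in mm.
#' @return An object of class `grid_spec` with fields `n_x`, `n_y`, `fov_mm`
#'   and the derived `pixel_mm = fov_mm / n_x`.
#' @export
#' @examples
#' g <- grid_spec()
#' g$pixel_mm  # 30/64 = 0.46875
grid_spec <- function(n_x = 64L, n_y = n_x, fov_mm = 30) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 3L) stop("grid_spec: n_x must be at least 3")
  if (n_x != n_y) stop("grid_spec: grid must be square (n_x == n_y)")
  if (!is.finite(fov_mm) || fov_mm <= 0) stop("grid_spec: fov_mm must be positive")
  structure(
    list(n_x = n_x, n_y = n_y, fov_mm = fov_mm, pixel_mm = fov_mm / n_x),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, FOV %g mm, pixel %g mm\n",
              x$n_x, x$n_y, x$fov_mm, x$pixel_mm))
  invisible(x)
}

# Pixel-center coordinates (mm). x varies along columns, y along rows.
pixel_centers <- function(grid) {
  list(x = (seq_len(grid$n_x) - 0.5) * grid$pixel_mm,
       y = (seq_len(grid$n_y) - 0.5) * grid$pixel_mm)
}

# Full coordinate matrices (mm), same layout as the maps.
coord_grids <- function(grid) {
  pc <- pixel_centers(grid)
  list(x = matrix(pc$x, grid$n_y, grid$n_x, byrow = TRUE),
       y = matrix(pc$y, grid$n_y, grid$n_x))
}

# Recognised map kinds and their physical units.
map_units <- c(
  conductivity = "S/m",
  potential    = "V",
  bz           = "T",
  phase        = "rad",
  current_x    = "A/m^2",
  current_y    = "A/m^2",
  current_mag  = "A/m^2",
  efield       = "V/m",
  death_prob   = "probability",
  mask         = "boolean"
)

#' Typed scalar map on a grid
#'
#' A numeric matrix tagged with its [grid_spec()] and a `kind` describing the
#' physical quantity it carries (and hence its unit). The kind tag is what
#' lets the I/O layer refuse to hand a conductivity map to code expecting an
#' electric field.
#'
#' @param data Numeric matrix, `n_y` rows by `n_x` columns.
#' @param grid A [grid_spec()].
#' @param kind One of `"conductivity"`, `"potential"`, `"bz"`, `"phase"`,
#'   `"current_x"`, `"current_y"`, `"current_mag"`, `"efield"`,
#'   `"death_prob"`, `"mask"`.
#' @return A matrix of class `ep_map` with attributes `grid` and `kind`.
#' @export
ep_map <- function(data, grid, kind) {
  kind <- match.arg(kind, names(map_units))
  data <- as.matrix(data)
  if (nrow(data) != grid$n_y || ncol(data) != grid$n_x)
    stop(sprintf("ep_map: data is %d x %d but grid expects %d x %d",
                 nrow(data), ncol(data), grid$n_y, grid$n_x))
  structure(data, grid = grid, kind = kind, class = c("ep_map", "matrix", "array"))
}

#' @export
print.ep_map <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<ep_map:%s [%s]> %d x %d, FOV %g mm; range [%.4g, %.4g]\n",
              attr(x, "kind"), map_units[[attr(x, "kind")]],
              g$n_y, g$n_x, g$fov_mm, min(x), max(x)))
  invisible(x)
}

map_grid <- function(map) {
  g <- attr(map, "grid")
  if (is.null(g)) stop("map carries no grid metadata")
  g
}

map_kind <- function(map) attr(map, "kind")

# Strip class/attributes, returning the bare matrix.
map_data <- function(map) {
  m <- unclass(map)
  attr(m, "grid") <- NULL
  attr(m, "kind") <- NULL
  m
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_x", "n_y", "fov_mm")],
                   unclass(b)[c("n_x", "n_y", "fov_mm")]))
}

check_same_grid <- function(a, b, what = "maps") {
  if (!same_grid(a, b)) stop(sprintf("%s are defined on different grids", what))
  invisible(TRUE)
}

#' In-plane current density map
#'
#' Holds both in-plane components of a current density field on a grid.
#'
#' @param j_x,j_y Numeric matrices (A/m^2), x and y components.
#' @param grid A [grid_spec()].
#' @return An object of class `current_density`.
#' @export
current_density <- function(j_x, j_y, grid) {
  j_x <- as.matrix(j_x); j_y <- as.matrix(j_y)
  if (!all(dim(j_x) == c(grid$n_y, grid$n_x)) ||
      !all(dim(j_y) == c(grid$n_y, grid$n_x)))
    stop("current_density: component shape does not match grid")
  if (!all(is.finite(j_x)) || !all(is.finite(j_y)))
    stop("current_density: components must be finite")
  structure(list(j_x = j_x, j_y = j_y, grid = grid), class = "current_density")
}

#' @export
print.current_density <- function(x, ...) {
  cat(sprintf("<current_density> %d x %d, max |J| = %.4g A/m^2\n",
              x$grid$n_y, x$grid$n_x, max(sqrt(x$j_x^2 + x$j_y^2))))
  invisible(x)
}
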