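#' 2D kernel density map of displacement vectors
#'
#' Estimates a Gaussian product-kernel density over Cartesian displacement
#' vectors (dx, dy), jointly encoding event displacement magnitude and
#' direction. Bandwidths default to Silverman's rule per axis
#' (`stats::bw.nrd0`); the grid is normalized so the discrete mass
#' (cell sum times cell area) integrates to 1 when the extents capture the
#' distribution.
#'
#' @param vectors Two-column matrix of displacement vectors in degrees.
#' @param n Grid resolution per axis (default 151).
#' @param bandwidth Optional per-axis kernel SD in degrees, `c(hx, hy)`
#'   (recycled); Silverman's rule when `NULL`.
#' @param extents Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   data range padded by three bandwidths.
#' @return An object of class `fem_density`: list with grid coordinates
#'   `x`, `y`, density matrix `z` (deg^-2), `bandwidth` and `extents`.
#' @export
kde2d_map <- function(vectors, n = 151, bandwidth = NULL, extents = NULL) {
  vectors <- as.matrix(vectors)
  vectors <- vectors[stats::complete.cases(vectors), , drop = FALSE]
  if (nrow(vectors) < 2)
    stop_fem_data("density estimation needs at least 2 vectors")
  if (is.null(bandwidth)) {
    if (stats::sd(vectors[, 1]) == 0 || stats::sd(vectors[, 2]) == 0)
      stop_fem_data("degenerate input: zero spread on an axis and no bandwidth given")
    bandwidth <- c(stats::bw.nrd0(vectors[, 1]), stats::bw.nrd0(vectors[, 2]))
  }
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2)
  if (any(bandwidth <= 0))
    stop_fem_config("bandwidth must be positive")
  if (is.null(extents))
    extents <- c(range(vectors[, 1]) + c(-3, 3) * bandwidth[1],
                 range(vectors[, 2]) + c(-3, 3) * bandwidth[2])
  # MASS::kde2d uses h/4 as the kernel SD, hence the factor 4
  kd <- MASS::kde2d(vectors[, 1], vectors[, 2], h = 4 * bandwidth, n = n,
                    lims = extents)
  structure(list(x = kd$x, y = kd$y, z = kd$z, bandwidth = bandwidth,
                 extents = extents, n_vectors = nrow(vectors)),
            class = "fem_density")
}

#' Equally spaced contour levels for a density map
#'
#' Discretizes a density grid into `n_levels` equally spaced thresholds in
#' `(0, max]`; rendering conventionally omits the lowest level for clarity.
#'
#' @param grid An `fem_density` object (or numeric matrix).
#' @param n_levels Number of levels (default 22).
#' @return Strictly increasing numeric vector of thresholds, the last equal
#'   to the grid maximum.
#' @export
contour_levels <- function(grid, n_levels = 22) {
  z <- if (inherits(grid, "fem_density")) grid$z else as.matrix(grid)
  zmax <- max(z)
  if (!is.finite(zmax) || zmax <= 0)
    stop_fem_data("contour levels undefined for a flat-zero grid")
  seq(zmax / n_levels, zmax, length.out = n_levels)
}

#' Plot a displacement density map
#'
#' Filled contours at equally spaced levels, omitting the lowest level.
#'
#' @param x An `fem_density` object.
#' @param n_levels Number of contour levels (default 22).
#' @param drop_lowest Omit the lowest level (default `TRUE`).
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.fem_density <- function(x, n_levels = 22, drop_lowest = TRUE, ...) {
  lev <- contour_levels(x, n_levels)
  if (drop_lowest) lev <- lev[-1]
  graphics::filled.contour(x$x, x$y, x$z, levels = c(lev, max(lev) * 1.001),
                           color.palette = grDevices::hcl.colors,
                           xlab = "dx (deg)", ylab = "dy (deg)", ...)
  invisible(x)
}

#' Write a density map as delimited matrix plus JSON sidecar
#'
#' @param grid An `fem_density` object.
#' @param path Output path for the matrix (CSV); the sidecar gets the
#'   extension `.json`.
#' @export
write_density <- function(grid, path) {
  stopifnot(inherits(grid, "fem_density"))
  utils::write.table(grid$z, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(extents = grid$extents,
                            bandwidth = grid$bandwidth,
                            n = dim(grid$z), n_vectors = grid$n_vectors),
                       sub("\\.[^.]*$", ".json", path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
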