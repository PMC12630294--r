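#' Bivariate contour ellipse area (BCEA)
#'
#' The standard fixation-stability measure: the area of the ellipse,
#' derived from the bivariate distribution of gaze positions, that contains
#' a stated fraction of those positions. Computed parametrically from the
#' sample moments,
#' \deqn{A = 2\pi k\,\sigma_x \sigma_y \sqrt{1-\rho^2},\qquad
#'       k = -\ln(1-P),}
#' with \eqn{\sigma_x,\sigma_y} the per-axis sample standard deviations and
#' \eqn{\rho} their Pearson correlation. The default coverage
#' \eqn{P = 0.6827} scales the ellipse to contain 68.27% of the gaze
#' positions of a bivariate normal cloud (i.e., 1 standard deviation).
#'
#' @param points Two-column matrix or data frame of gaze positions in
#'   degrees.
#' @param coverage_P Coverage fraction in (0, 1), default 0.6827.
#' @return An object of class `bcea` with `sigma_x`, `sigma_y`, `rho`,
#'   `coverage_P`, `area` (deg^2), `center` and `n`.
#' @export
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(5000), rnorm(5000))
#' bcea(pts)$area  # approaches 2*pi*(-log(1 - 0.6827)) ~ 7.21 deg^2
bcea <- function(points, coverage_P = 0.6827) {
  points <- as.matrix(points)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (ncol(points) != 2)
    stop_fem_data("points must have two columns (x, y)")
  if (nrow(points) < 3)
    stop_fem_data("BCEA needs at least 3 points")
  if (coverage_P <= 0 || coverage_P >= 1)
    stop_fem_config("coverage_P must lie strictly between 0 and 1")
  sx <- stats::sd(points[, 1]); sy <- stats::sd(points[, 2])
  if (sx == 0 || sy == 0)
    stop_fem_data("degenerate geometry: zero variance on an axis")
  rho <- stats::cor(points[, 1], points[, 2])
  if (1 - rho^2 < 1e-12)
    stop_fem_data("degenerate geometry: points are collinear")
  k <- -log(1 - coverage_P)
  structure(list(sigma_x = sx, sigma_y = sy, rho = rho,
                 coverage_P = coverage_P,
                 area = 2 * pi * k * sx * sy * sqrt(1 - rho^2),
                 center = colMeans(points), n = nrow(points)),
            class = "bcea")
}

#' @export
print.bcea <- function(x, ...) {
  cat(sprintf("BCEA (%.2f%% coverage): %.4g deg^2  [sigma_x %.4g, sigma_y %.4g, rho %.3f, n %d]\n",
              100 * x$coverage_P, x$area, x$sigma_x, x$sigma_y, x$rho, x$n))
  invisible(x)
}

#' Test which points fall inside a BCEA ellipse
#'
#' A point lies inside the ellipse when its squared Mahalanobis distance
#' from the cloud center is at most \eqn{2k = -2\ln(1-P)}; for bivariate
#' normal data that region contains exactly the fraction `coverage_P`.
#'
#' @param object A [bcea()] result.
#' @param points Two-column matrix of positions.
#' @return Logical vector.
#' @export
bcea_contains <- function(object, points) {
  stopifnot(inherits(object, "bcea"))
  points <- as.matrix(points)
  dx <- points[, 1] - object$center[1]
  dy <- points[, 2] - object$center[2]
  r2 <- 1 - object$rho^2
  md2 <- (dx^2 / object$sigma_x^2 +
            dy^2 / object$sigma_y^2 -
            2 * object$rho * dx * dy / (object$sigma_x * object$sigma_y)) / r2
  md2 <= 2 * (-log(1 - object$coverage_P))
}
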