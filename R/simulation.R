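# Modified Shepp-Logan ellipse table (Toft parameterization): intensity,
# semi-axes (a along x, b along y), center, rotation (degrees, CCW).
# Defined on the [-1,1]^2 square.
.shepp_logan_ellipses <- matrix(c(
  #  A       a       b       x0      y0     phi
   1.00,  0.6900, 0.9200,  0.00,  0.0000,   0,
  -0.80,  0.6624, 0.8740,  0.00, -0.0184,   0,
  -0.20,  0.1100, 0.3100,  0.22,  0.0000, -18,
  -0.20,  0.1600, 0.4100, -0.22,  0.0000,  18,
   0.10,  0.2100, 0.2500,  0.00,  0.3500,   0,
   0.10,  0.0460, 0.0460,  0.00,  0.1000,   0,
   0.10,  0.0460, 0.0460,  0.00, -0.1000,   0,
   0.10,  0.0460, 0.0230, -0.08, -0.6050,   0,
   0.10,  0.0230, 0.0230,  0.00, -0.6060,   0,
   0.10,  0.0230, 0.0460,  0.06, -0.6050,   0
), ncol = 6, byrow = TRUE)

#' Shepp-Logan head phantom
#'
#' The standard modified (high-contrast) Shepp-Logan phantom sampled on an
#' n x n grid covering \eqn{[-1,1]^2}, with intensities clipped to
#' \eqn{[0,1]}. Row 1 is the top of the image.
#'
#' @param n pixels per side (>= 2).
#' @return n x n numeric matrix with values in `[0, 1]`.
#' @examples
#' mu <- make_shepp_logan(64)
#' range(mu)
#' @export
make_shepp_logan <- function(n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  xs <- (seq_len(n) - 0.5) / n * 2 - 1          # column centers, left -> right
  ys <- 1 - (seq_len(n) - 0.5) / n * 2          # row centers, top -> bottom
  x <- matrix(xs, n, n, byrow = TRUE)
  y <- matrix(ys, n, n)
  img <- matrix(0, n, n)
  for (e in seq_len(nrow(.shepp_logan_ellipses))) {
    p <- .shepp_logan_ellipses[e, ]
    phi <- p[6] * pi / 180
    xr <- (x - p[4]) * cos(phi) + (y - p[5]) * sin(phi)
    yr <- -(x - p[4]) * sin(phi) + (y - p[5]) * cos(phi)
    inside <- (xr / p[2])^2 + (yr / p[3])^2 <= 1
    img <- img + p[1] * inside
  }
  pmin(pmax(img, 0), 1)
}

#' Simulate a fan-beam scan
#'
#' Computes the noiseless line integrals \eqn{l = A\mu}, perturbs them
#' with zero-mean Gaussian noise of per-ray standard deviation
#' `noise_level * l_i` (so `noise_level = 0.001` is "0.1% noise"; rays
#' with \eqn{l_i = 0} stay exact), and derives the photon-count view of
#' the measurement: exit intensity \eqn{y_i = b_0 e^{-\hat l_i}},
#' read-out mean \eqn{r_i = 0}, and statistical weights
#' \eqn{\omega_i = (y_i - r_i)^2 / y_i}. With `poisson = TRUE` the exit
#' intensities are instead drawn as
#' \eqn{y_i \sim \mathrm{Poisson}(b_0 e^{-l_i})} and the measured line
#' integral recomputed as \eqn{\hat l_i = \log(b_0/(y_i - r_i))}; this
#' mode models photon statistics directly and ignores `noise_level`.
#'
#' @param mu attenuation image (N x N matrix, N matching `geom`).
#' @param geom a [build_geometry()] object.
#' @param noise_level relative Gaussian noise fraction (0.001 = 0.1%).
#' @param b0 entrance photon count per ray.
#' @param seed integer seed for reproducibility (`NULL` leaves the RNG
#'   state alone).
#' @param A optional precomputed [system_matrix()] for `geom`.
#' @param poisson simulate Poisson photon counts instead of Gaussian
#'   projection noise.
#' @return An object of class `sinogram`: list with `l_hat`, `y`, `b`,
#'   `r`, `omega`, `l_true` (all length `n_rays`) and the geometry.
#' @export
simulate_scan <- function(mu, geom, noise_level = 0, b0 = 1e6, seed = NULL,
                          A = NULL, poisson = FALSE) {
  stopifnot(inherits(geom, "scan_geometry"))
  stopifnot_image(mu, geom$image_n)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (b0 <= 0) stop("b0 must be positive", call. = FALSE)
  if (is.null(A)) A <- system_matrix(geom)
  l_true <- forward_project(A, mu)
  I <- geom$n_rays
  r <- rep(0, I)
  b <- rep(b0, I)
  sino <- with_seed(seed, {
    if (poisson) {
      y <- rpois(I, b0 * exp(-l_true)) + r
      y <- pmax(y, 1)  # guard log of empty detector bins
      l_hat <- log(b / (y - r + (y == r)))
      list(l_hat = l_hat, y = y)
    } else {
      l_hat <- l_true + rnorm(I, 0, noise_level * l_true)
      list(l_hat = l_hat, y = b0 * exp(-l_hat))
    }
  })
  omega <- (sino$y - r)^2 / sino$y
  structure(list(l_hat = sino$l_hat, y = sino$y, b = b, r = r,
                 omega = omega, l_true = l_true,
                 noise_level = noise_level, geom = geom),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d rays (%d views x %d detectors), noise %.3g%%\n",
              length(x$l_hat), x$geom$n_views, x$geom$n_detectors,
              100 * x$noise_level))
  cat(sprintf("  l_hat in [%.4g, %.4g]\n", min(x$l_hat), max(x$l_hat)))
  invisible(x)
}

#' @rdname simulate_scan
#' @param sino a `sinogram` object.
#' @return `sinogram_matrix()` returns the measured line integrals as an
#'   `n_views` x `n_detectors` matrix (one view per row).
#' @export
sinogram_matrix <- function(sino) {
  matrix(sino$l_hat, sino$geom$n_views, sino$geom$n_detectors, byrow = TRUE)
}
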