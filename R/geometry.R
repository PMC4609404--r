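#' Fan-beam scan geometry
#'
#' Describes a 2-D fan-beam acquisition: a point source rotating on a
#' circle around the image, a flat equispaced detector row opposite the
#' source, and the reconstruction grid. View angles are
#' \eqn{\theta_v = (v-1)\,\Delta\theta}. The source-to-center distance
#' defaults to `source_factor` times the image edge length, and the
#' detector span is sized (with a small margin) so that the fan covers the
#' circumscribed circle of the grid from every view.
#'
#' The default `pixel_size = 2/image_n` places the image on the classical
#' \eqn{[-1,1]^2} square, so that attenuation values of order one yield
#' line integrals of order one and well-scaled photon statistics.
#'
#' @param n_views number of projection views (positive integer).
#' @param angular_step_deg angular increment between views, degrees.
#' @param n_detectors number of detector elements per view.
#' @param image_n pixels per image side (N).
#' @param source_factor source-to-center distance in units of the image
#'   edge length; must be >= 1 (source outside the grid).
#' @param pixel_size pixel edge length in scan length units.
#' @param detector_span total detector width; `NULL` (default) sizes it
#'   automatically to cover the phantom from every view.
#' @return An object of class `scan_geometry`.
#' @examples
#' geom <- build_geometry(120, 3, 512, 256, source_factor = 2)
#' geom$n_rays
#' @export
build_geometry <- function(n_views, angular_step_deg, n_detectors, image_n,
                           source_factor = 2, pixel_size = 2 / image_n,
                           detector_span = NULL) {
  if (n_views < 1 || n_detectors < 1 || image_n < 1) {
    stop("n_views, n_detectors and image_n must be positive", call. = FALSE)
  }
  if (n_views != round(n_views) || n_detectors != round(n_detectors) ||
      image_n != round(image_n)) {
    stop("counts must be whole numbers", call. = FALSE)
  }
  if (angular_step_deg < 0) stop("angular_step_deg must be >= 0", call. = FALSE)
  if (source_factor < 1) stop("source_factor must be >= 1", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)

  edge <- image_n * pixel_size
  rs <- source_factor * edge         # source-to-center
  rd <- rs                           # detector-to-center (symmetric layout)
  rc <- sqrt(2) / 2 * edge           # circumscribed circle of the grid
  half_needed <- (rs + rd) * tan(asin(min(rc / rs, 1)))
  if (is.null(detector_span)) {
    detector_span <- 2 * half_needed * 1.05
  } else if (detector_span / 2 < half_needed) {
    stop("detector span does not cover the image grid from every view",
         call. = FALSE)
  }

  structure(list(
    n_views = as.integer(n_views),
    angular_step_deg = angular_step_deg,
    n_detectors = as.integer(n_detectors),
    image_n = as.integer(image_n),
    pixel_size = pixel_size,
    source_to_center = rs,
    detector_to_center = rd,
    detector_span = detector_span,
    n_rays = as.integer(n_views * n_detectors)
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "Fan-beam geometry: %d views x %.4g deg, %d detectors (span %.4g),\n",
    x$n_views, x$angular_step_deg, x$n_detectors, x$detector_span))
  cat(sprintf("  grid %dx%d (pixel %.4g), source-to-center %.4g\n",
              x$image_n, x$image_n, x$pixel_size, x$source_to_center))
  invisible(x)
}

#' Ray-driven system matrix
#'
#' Builds the sparse system matrix \eqn{A = \{a_{ij}\}} whose entry is the
#' exact intersection length of ray i with pixel j (Siddon traversal).
#' Rays are ordered view-major (`i = (v-1)*n_detectors + k`), pixels
#' row-major with row 1 at the top.
#'
#' @param geom a [build_geometry()] object.
#' @return A `Matrix::dgCMatrix` of dimension `n_rays` x `image_n^2`.
#' @export
system_matrix <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  tr <- cpp_system_triplets(geom$n_views, geom$angular_step_deg,
                            geom$n_detectors, geom$image_n, geom$pixel_size,
                            geom$source_to_center, geom$detector_to_center,
                            geom$detector_span)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(geom$n_rays, geom$image_n^2))
}

#' Trace a single ray
#'
#' Pixel indices (row-major, 1-based) and exact intersection lengths of
#' the source-to-detector line for one (view, detector) pair. Empty
#' vectors are returned when the ray misses the grid.
#'
#' @inheritParams system_matrix
#' @param view view index in `1:n_views`.
#' @param detector detector index in `1:n_detectors`.
#' @return A list with integer `j` and numeric `a` of equal length.
#' @export
trace_ray <- function(geom, view, detector) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (view < 1 || view > geom$n_views) stop("view index out of range", call. = FALSE)
  if (detector < 1 || detector > geom$n_detectors) {
    stop("detector index out of range", call. = FALSE)
  }
  cpp_trace_ray(as.integer(view), as.integer(detector), geom$n_views,
                geom$angular_step_deg, geom$n_detectors, geom$image_n,
                geom$pixel_size, geom$source_to_center,
                geom$detector_to_center, geom$detector_span)
}

#' Forward and back projection
#'
#' `forward_project()` computes the line integrals \eqn{l = A\mu};
#' `back_project()` applies the adjoint \eqn{A^T v}, returning an image.
#'
#' @param A system matrix from [system_matrix()].
#' @param mu image matrix (N x N) or row-major vectorized image.
#' @param v numeric vector of length `nrow(A)`.
#' @return `forward_project()`: numeric vector of length `nrow(A)`;
#'   `back_project()`: an N x N matrix.
#' @export
forward_project <- function(A, mu) {
  n <- as.integer(sqrt(ncol(A)))
  v <- if (is.matrix(mu)) {
    stopifnot_image(mu, n)
    img_to_vec(mu)
  } else {
    if (length(mu) != ncol(A)) stop("dimension mismatch", call. = FALSE)
    mu
  }
  as.vector(A %*% v)
}

#' @rdname forward_project
#' @export
back_project <- function(A, v) {
  if (length(v) != nrow(A)) stop("dimension mismatch", call. = FALSE)
  n <- as.integer(sqrt(ncol(A)))
  vec_to_img(as.vector(Matrix::crossprod(A, v)), n)
}
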