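# Image-quality metrics and display windowing.

#' Normalized mean absolute deviation (percent)
#'
#' \eqn{\mathrm{NMAD} = 100 \sum_{ij} |\mu_{ij} - \mu^{truth}_{ij}| /
#' \sum_{ij} \mu^{truth}_{ij}}. The denominator is the plain (unsigned)
#' sum of the truth image, which is the standard form for nonnegative
#' attenuation maps.
#'
#' @param mu reconstructed image.
#' @param mu_truth reference image of the same dimensions.
#' @return NMAD in percent.
#' @examples
#' nmad(matrix(c(1, 1, 1, 0.5), 2), matrix(1, 2, 2))  # 12.5
#' @export
nmad <- function(mu, mu_truth) {
  if (!all(dim(mu) == dim(mu_truth))) stop("shape mismatch", call. = FALSE)
  den <- sum(mu_truth)
  if (den == 0) stop("truth image sums to zero", call. = FALSE)
  100 * sum(abs(mu - mu_truth)) / den
}

#' Signal-to-noise ratio (dB)
#'
#' \eqn{\mathrm{SNR} = 10 \log_{10}\left(\sum \mu_{truth}^2 / \sum (\mu -
#' \mu_{truth})^2\right)}. Identical images have infinite SNR; `Inf` is
#' returned in that case.
#'
#' @inheritParams nmad
#' @return SNR in decibels (`Inf` for identical images).
#' @export
snr <- function(mu, mu_truth) {
  if (!all(dim(mu) == dim(mu_truth))) stop("shape mismatch", call. = FALSE)
  err <- sum((mu - mu_truth)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(mu_truth^2) / err)
}

#' Linear display windowing
#'
#' Clips the image to `[lo, hi]` and rescales linearly to 8-bit
#' (0..255) for export/display; values at or below `lo` map to 0, at or
#' above `hi` to 255, and the window midpoint rounds to 128 (R's
#' round-half-to-even). For dimensionless phantoms the window is given
#' on the attenuation scale directly (e.g. `[0.15, 0.45]`); for
#' HU-calibrated images, in HU. Difference images use symmetric windows.
#'
#' @param image numeric matrix.
#' @param lo,hi window bounds, `lo < hi`.
#' @return Integer matrix with values in 0..255.
#' @export
hu_window <- function(image, lo, hi) {
  if (lo >= hi) stop("window must have lo < hi", call. = FALSE)
  x <- (pmin(pmax(image, lo), hi) - lo) / (hi - lo) * 255
  out <- round(x)
  storage.mode(out) <- "integer"
  out
}

#' Quality report for a reconstruction
#'
#' Bundles NMAD and SNR against a reference image. The report can be
#' serialized to a plain key=value text file and read back losslessly.
#'
#' @inheritParams nmad
#' @param window optional display window `c(lo, hi)` recorded in the
#'   report.
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(mu, mu_truth, window = NULL) {
  structure(list(nmad_percent = nmad(mu, mu_truth),
                 snr_db = snr(mu, mu_truth),
                 n_pixels = length(mu),
                 window = window),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("NMAD = %.4f%%   SNR = %.4f dB   (%d pixels)\n",
              x$nmad_percent, x$snr_db, x$n_pixels))
  invisible(x)
}

#' @rdname quality_report
#' @param report a `quality_report`.
#' @param path file path for the serialized report.
#' @export
write_quality_report <- function(report, path) {
  vals <- c(nmad_percent = report$nmad_percent, snr_db = report$snr_db,
            n_pixels = report$n_pixels)
  lines <- sprintf("%s=%s", names(vals),
                   vapply(vals, function(v) format(v, digits = 17), ""))
  if (!is.null(report$window)) {
    lines <- c(lines, sprintf("window=%s,%s",
                              format(report$window[1], digits = 17),
                              format(report$window[2], digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname quality_report
#' @export
read_quality_report <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  window <- if (!is.null(vals$window)) {
    as.numeric(strsplit(vals$window, ",")[[1]])
  }
  structure(list(nmad_percent = as.numeric(vals$nmad_percent),
                 snr_db = as.numeric(vals$snr_db),
                 n_pixels = as.integer(as.numeric(vals$n_pixels)),
                 window = window),
            class = "quality_report")
}

#' Export an 8-bit PNG of a windowed image
#'
#' Convenience wrapper used by the command-line interface; requires the
#' `png` package.
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param lo,hi display window.
#' @export
write_png_window <- function(image, path, lo, hi) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(hu_window(image, lo, hi) / 255, path)
  invisible(path)
}
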