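# Image <-> vector conventions.
#
# Images are N x N base-R matrices with row 1 at the top. The vectorized
# image used by the projector is ROW-major: pixel (r, c) maps to
# j = (r-1)*N + c. Base R matrices are column-major, hence the transposes.

img_to_vec <- function(mu) {
  as.vector(t(mu))
}

vec_to_img <- function(v, n) {
  matrix(v, n, n, byrow = TRUE)
}

stopifnot_image <- function(mu, n = NULL) {
  if (!is.matrix(mu) || nrow(mu) != ncol(mu)) {
    stop("image must be a square matrix", call. = FALSE)
  }
  if (!is.null(n) && nrow(mu) != n) {
    stop(sprintf("image is %dx%d but the geometry expects %dx%d",
                 nrow(mu), ncol(mu), n, n), call. = FALSE)
  }
  if (any(!is.finite(mu))) stop("image contains non-finite values", call. = FALSE)
  invisible(mu)
}

#' Read or write a plain-text matrix
#'
#' Whitespace-separated text with one matrix row per line; the format used
#' by the command-line interface for images and sinograms.
#'
#' @param path file path.
#' @param x numeric matrix.
#' @return `read_matrix_txt()` returns a numeric matrix.
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_matrix_txt
#' @export
write_matrix_txt <- function(x, path) {
  utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Run an expression with a locally-seeded RNG, restoring the caller's
# RNG state afterwards so simulation helpers do not disturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
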