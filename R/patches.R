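#' Overlapping-patch extraction scheme
#'
#' Describes the sliding-window patch decomposition used by the
#' dictionary regularizer: `patch_size` x `patch_size` windows placed
#' every `stride` pixels, `floor((N - patch_size)/stride) + 1` positions
#' per axis. The object precomputes the pixel-index table of every patch
#' and the per-pixel coverage counts
#' \eqn{q_j = \sum_s \sum_n e^s_{nj}} (how many patches contain pixel j;
#' each row of an extraction operator has a single unit entry).
#'
#' @param image_n image side length N.
#' @param patch_size patch side length \eqn{N_0}.
#' @param stride window step in pixels, `1 <= stride <= patch_size`.
#' @return An object of class `patch_scheme`.
#' @examples
#' sc <- patch_scheme(256, 8, 1)
#' sc$n_patches  # 249^2
#' @export
patch_scheme <- function(image_n, patch_size = 8, stride = 1) {
  if (stride < 1 || stride > patch_size || patch_size > image_n) {
    stop("need 1 <= stride <= patch_size <= image_n", call. = FALSE)
  }
  n_axis <- floor((image_n - patch_size) / stride) + 1
  starts <- 1 + (seq_len(n_axis) - 1) * stride
  # linear (column-major, base-R) indices of each patch's pixels;
  # patches ordered column-of-positions-major, pixels column-major
  # within the patch -- any fixed convention works, this one is fast.
  off <- as.vector(outer(0:(patch_size - 1),
                         0:(patch_size - 1) * image_n, `+`))
  top_left <- as.vector(outer(starts, (starts - 1) * image_n, `+`))
  idx <- outer(off, top_left, `+`)  # patch_size^2 x n_patches
  storage.mode(idx) <- "integer"
  q <- matrix(tabulate(idx, image_n^2), image_n, image_n)
  structure(list(image_n = as.integer(image_n),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 n_axis = as.integer(n_axis),
                 n_patches = as.integer(n_axis^2),
                 idx = idx, q = q),
            class = "patch_scheme")
}

#' @export
print.patch_scheme <- function(x, ...) {
  cat(sprintf("Patch scheme: %dx%d windows, stride %d, %d patches on a %dx%d grid\n",
              x$patch_size, x$patch_size, x$stride, x$n_patches,
              x$image_n, x$image_n))
  invisible(x)
}

#' Extract overlapping patches
#'
#' Column s of the result is \eqn{E_s \mu}, the s-th patch of the image.
#'
#' @param mu N x N image matrix.
#' @param scheme a [patch_scheme()].
#' @return A `patch_size^2` x `n_patches` matrix.
#' @export
extract_patches <- function(mu, scheme) {
  stopifnot(inherits(scheme, "patch_scheme"))
  stopifnot_image(mu, scheme$image_n)
  matrix(mu[scheme$idx], nrow = scheme$patch_size^2)
}

#' Accumulate patch values back into the image (adjoint of extraction)
#'
#' Computes \eqn{\sum_s E_s^T v_s}: every patch column is added back at
#' its window position. Together with the coverage counts `q` this is the
#' building block of the dictionary-driven update target.
#'
#' @param values `patch_size^2` x `n_patches` matrix of patch values.
#' @param scheme a [patch_scheme()].
#' @return A list with `image` (N x N accumulated values) and `q`
#'   (N x N per-pixel patch coverage counts).
#' @export
patch_adjoint_accumulate <- function(values, scheme) {
  stopifnot(inherits(scheme, "patch_scheme"))
  if (!is.matrix(values) || nrow(values) != scheme$patch_size^2 ||
      ncol(values) != scheme$n_patches) {
    stop("values must be patch_size^2 x n_patches", call. = FALSE)
  }
  n2 <- scheme$image_n^2
  acc <- numeric(n2)
  # within one in-patch offset all target pixels are distinct, so each
  # offset is one vectorized scatter-add
  for (n in seq_len(nrow(values))) {
    ii <- scheme$idx[n, ]
    acc[ii] <- acc[ii] + values[n, ]
  }
  list(image = matrix(acc, scheme$image_n, scheme$image_n), q = scheme$q)
}
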