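#' Patch dictionary
#'
#' An overcomplete dictionary of unit-norm atoms, one column per atom,
#' each the size of a vectorized patch.
#'
#' @param atoms `patch_size^2` x K matrix; columns are normalized to unit
#'   Euclidean norm.
#' @return An object of class `patch_dictionary`.
#' @export
patch_dictionary <- function(atoms) {
  if (!is.matrix(atoms)) stop("atoms must be a matrix", call. = FALSE)
  nrm <- sqrt(colSums(atoms^2))
  if (any(nrm <= 1e-12)) stop("zero-norm atoms are not allowed", call. = FALSE)
  atoms <- sweep(atoms, 2, nrm, `/`)
  n0 <- sqrt(nrow(atoms))
  if (n0 != round(n0)) stop("atom length must be a square", call. = FALSE)
  structure(list(atoms = atoms, patch_size = as.integer(n0),
                 K = ncol(atoms)),
            class = "patch_dictionary")
}

#' @export
print.patch_dictionary <- function(x, ...) {
  cat(sprintf("Patch dictionary: %d atoms of %dx%d pixels\n",
              x$K, x$patch_size, x$patch_size))
  invisible(x)
}

#' Orthogonal matching pursuit sparse coding
#'
#' Greedy OMP: at each step the atom with the largest absolute
#' correlation to the current residual is added to the active set and the
#' coefficients are re-fit by least squares on that set; coding stops at
#' `L` atoms or when the residual norm drops below
#' `rel_tol * ||x||`. An atom is never selected twice.
#'
#' @param dict a [patch_dictionary()] (or a plain atom matrix).
#' @param x one signal (vector) or a matrix of signals in columns.
#' @param L maximum number of nonzero coefficients per signal.
#' @param rel_tol relative residual tolerance.
#' @return A sparse `Matrix::dgCMatrix` of codes, K x n_signals.
#' @examples
#' D <- patch_dictionary(matrix(rnorm(16 * 24), 16))
#' a <- omp_code(D, D$atoms[, 3], L = 2)
#' which(a[, 1] != 0)
#' @export
omp_code <- function(dict, x, L = 5, rel_tol = 1e-6) {
  D <- if (inherits(dict, "patch_dictionary")) dict$atoms else dict
  if (any(sqrt(colSums(D^2)) <= 1e-12)) {
    stop("zero-norm atoms are not allowed", call. = FALSE)
  }
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) != nrow(D)) stop("signal/atom size mismatch", call. = FALSE)
  tr <- cpp_batch_omp(D, X, as.integer(L), rel_tol)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(ncol(D), ncol(X)))
}

#' K-SVD dictionary learning
#'
#' Alternates OMP sparse coding of the training signals with a
#' dictionary-update stage of `n_sweeps` per-atom rank-1 SVD passes on
#' each atom's support (the atom's coefficients are refreshed
#' simultaneously, so each pass cannot increase the training objective
#' \eqn{\sum_s \|x_s - D\alpha_s\|^2}). Between iterations the
#' dictionary is cleared: atoms nearly duplicating another atom
#' (coherence above `purge_coherence`) or left unused by the coding pass
#' are re-seeded from the principal residual direction of the
#' worst-represented signals. Clearing is what lets the training escape
#' local minima in which one atom models a combination of two underlying
#' directions; it can raise the recorded objective transiently by a
#' fraction of a percent. The initial dictionary is drawn (reproducibly,
#' via `seed`) from random training columns unless `init` is supplied.
#'
#' @param patches training signals in columns (at least K of them).
#' @param K number of atoms; larger than the signal length for an
#'   overcomplete dictionary.
#' @param L sparsity level used during training.
#' @param n_iters K-SVD iterations (coding/dictionary-update
#'   alternations).
#' @param seed integer seed controlling the initial atom draw.
#' @param init optional initial dictionary (`patch_dictionary` or matrix)
#'   to warm-start training.
#' @param rel_tol OMP residual tolerance.
#' @param n_sweeps atom-update passes per dictionary-update stage.
#' @param purge_coherence duplicate-atom clearing threshold.
#' @return A [patch_dictionary()] with an `objective` attribute holding
#'   the per-iteration training objective.
#' @export
ksvd_train <- function(patches, K, L = 5, n_iters = 20, seed = NULL,
                       init = NULL, rel_tol = 1e-6, n_sweeps = 3,
                       purge_coherence = 0.9) {
  if (!is.matrix(patches)) stop("patches must be a matrix", call. = FALSE)
  nrms <- sqrt(colSums(patches^2))
  if (all(nrms <= 1e-10)) {
    stop("degenerate training set: all patches are (numerically) zero",
         call. = FALSE)
  }
  if (ncol(patches) < K) stop("need at least K training patches", call. = FALSE)
  D0 <- if (!is.null(init)) {
    if (inherits(init, "patch_dictionary")) init$atoms else init
  } else {
    nz <- which(nrms > 1e-10)
    pick <- with_seed(seed, {
      if (length(nz) >= K) sample(nz, K)
      else c(nz, sample(nz, K - length(nz), replace = TRUE))
    })
    sweep(patches[, pick, drop = FALSE], 2, nrms[pick], `/`)
  }
  if (ncol(D0) != K) stop("init dictionary must have K atoms", call. = FALSE)
  fit <- cpp_ksvd(patches, D0, as.integer(L), as.integer(n_iters), rel_tol,
                  as.integer(n_sweeps), purge_coherence)
  out <- patch_dictionary(fit$D)
  attr(out, "objective") <- fit$objective
  out
}

# Remove per-patch means before coding; the DC component is restored on
# reassembly so no atoms are spent on it.
code_patches <- function(dict, patches, L = 5, rel_tol = 1e-6) {
  mns <- colMeans(patches)
  alpha <- omp_code(dict, patches - rep(mns, each = nrow(patches)),
                    L = L, rel_tol = rel_tol)
  list(alpha = alpha, means = mns)
}

# D alpha with the per-patch mean restored: the regularizer's patch
# approximation Dalpha_s (+ DC) for every patch.
approx_patches <- function(dict, codes) {
  D <- if (inherits(dict, "patch_dictionary")) dict$atoms else dict
  as.matrix(D %*% codes$alpha) + rep(codes$means, each = nrow(D))
}

#' Train a global dictionary from a reference image
#'
#' Extracts the overlapping patches of `reference`, removes their means,
#' and trains a K-SVD dictionary on a random (seeded) subsample. This is
#' the dictionary used by the global-dictionary reconstruction modes.
#'
#' @param reference N x N reference image.
#' @param scheme a [patch_scheme()] matching the image.
#' @param K,L,n_iters,seed,rel_tol passed to [ksvd_train()].
#' @param max_train cap on the number of training patches (subsampled
#'   reproducibly when exceeded).
#' @return A [patch_dictionary()].
#' @export
train_global_dictionary <- function(reference, scheme, K = 256, L = 5,
                                    n_iters = 15, seed = NULL,
                                    max_train = 10000, rel_tol = 1e-6) {
  P <- extract_patches(reference, scheme)
  P <- P - rep(colMeans(P), each = nrow(P))
  keep <- which(sqrt(colSums(P^2)) > 1e-10)
  if (length(keep) < K) {
    stop("reference image has too few non-constant patches to train on",
         call. = FALSE)
  }
  if (length(keep) > max_train) {
    keep <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                      sample(keep, max_train))
  }
  ksvd_train(P[, keep, drop = FALSE], K = K, L = L, n_iters = n_iters,
             seed = seed, rel_tol = rel_tol)
}
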