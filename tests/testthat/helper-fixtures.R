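# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small but non-trivial scan: 32x32 phantom, 40 views, 64 detectors.
toy_scan <- function(noise = 0, seed = 7) {
  key <- sprintf("toy_%g_%d", noise, seed)
  fixture(key, function() {
    mu <- make_shepp_logan(32)
    geom <- build_geometry(40, 9, 64, 32, 2)
    A <- system_matrix(geom)
    sino <- simulate_scan(mu, geom, noise_level = noise, seed = seed, A = A)
    list(mu = mu, geom = geom, A = A, sino = sino)
  })
}

# Dense system matrix of a tiny geometry, for adjoint/oracle checks.
dense_A <- function(A) as.matrix(A)

# Draw a unit-norm dictionary whose mutual coherence stays below mu_max
# (identifiable planted model for recovery oracles).
draw_incoherent_dictionary <- function(n, K, mu_max = 0.5) {
  D <- matrix(0, n, 0)
  while (ncol(D) < K) {
    d <- rnorm(n)
    d <- d / sqrt(sum(d^2))
    if (ncol(D) == 0 || max(abs(crossprod(D, d))) <= mu_max) D <- cbind(D, d)
  }
  D
}

expect_images_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
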