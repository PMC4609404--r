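# A tiny overdetermined scan whose weighted least-squares solution is
# unique: 8x8 grid, 20 views x 16 detectors.
tiny_scan <- function(noise = 0, seed = 13) {
  fixture(sprintf("tiny_%g_%d", noise, seed), function() {
    mu <- matrix(0, 8, 8)
    mu[3:6, 3:6] <- 0.5
    mu[4:5, 4:5] <- 1
    geom <- build_geometry(20, 18, 16, 8, 2, pixel_size = 0.25)
    A <- system_matrix(geom)
    sino <- simulate_scan(mu, geom, noise_level = noise, seed = seed, A = A)
    list(mu = mu, geom = geom, A = A, sino = sino)
  })
}

test_that("SART converges to the consistent solution and clamps at zero", {
  ts <- tiny_scan()
  # noiseless consistent overdetermined system: the unique LS solution is
  # the phantom itself
  dense <- dense_A(ts$A)
  ls <- qr.solve(dense, ts$sino$l_hat)
  expect_equal(max(abs(ls - awrct:::img_to_vec(ts$mu))), 0, tolerance = 1e-8)

  rec <- sart_reconstruct(ts$sino, ts$geom,
                          recon_config(max_outer_iters = 600, stop_tol = 0))
  expect_lt(max(abs(rec$image - ts$mu)), 1e-4)
  expect_gte(min(rec$image), 0)

  # starting at the truth with noiseless data is a fixed point
  rec1 <- sart_reconstruct(ts$sino, ts$geom,
                           recon_config(max_outer_iters = 1, stop_tol = 0),
                           A = ts$A, init = ts$mu)
  expect_lt(max(abs(rec1$image - ts$mu)), 1e-10)

  # noisy data: output still nonnegative
  tsn <- tiny_scan(noise = 0.05)
  recn <- sart_reconstruct(tsn$sino, tsn$geom,
                           recon_config(max_outer_iters = 30, stop_tol = 0),
                           A = tsn$A)
  expect_gte(min(recn$image), 0)

  empty <- ts$sino
  empty$l_hat <- numeric(0)
  expect_error(sart_reconstruct(empty, ts$geom), "empty")
})

test_that("GPBB with zero TV weight solves weighted least squares", {
  ts <- tiny_scan()
  cfg <- recon_config(max_outer_iters = 400, stop_tol = 0, tv_weight = 0)
  rec <- gpbb_reconstruct(ts$sino, ts$geom, cfg, A = ts$A)
  expect_lt(max(abs(rec$image - ts$mu)), 1e-4)
  # objective is monotone under the safeguard
  expect_true(all(diff(rec$trace$objective) <= 1e-8 * rec$trace$objective[1]))
})

test_that("TV regularization lowers the total variation below SART's", {
  # piecewise-constant phantom under genuinely sparse views, where SART
  # leaves streaks that the TV penalty removes
  n <- 32
  xs <- (seq_len(n) - 0.5) / n * 2 - 1
  disk <- outer(rev(xs), xs, function(y, x)
    0.5 * (x^2 + y^2 <= 0.64) + 0.5 * ((x - 0.2)^2 + y^2 <= 0.04))
  geom <- build_geometry(12, 30, 64, n, 2)
  A <- system_matrix(geom)
  sino <- simulate_scan(disk, geom, noise_level = 0.001, seed = 29, A = A)
  tv_of <- function(img) {
    sum(abs(img[, -1] - img[, -n])) + sum(abs(img[-1, ] - img[-n, ]))
  }
  cfg <- recon_config(max_outer_iters = 150)
  s <- sart_reconstruct(sino, geom, cfg, A = A)
  g <- gpbb_reconstruct(sino, geom, cfg, A = A)
  expect_lt(tv_of(g$image), tv_of(s$image))
})

test_that("surrogate coefficients match hand computation and scale in omega", {
  # single horizontal ray through a 4x4 unit-pixel grid
  g <- build_geometry(1, 0, 1, 4, 2, pixel_size = 1)
  A <- system_matrix(g)
  sc <- patch_scheme(4, 2, 1)
  pq <- compute_p_q(A, omega = 1, sc)
  on_ray <- which(pq$p > 0)
  expect_length(on_ray, 4)
  expect_equal(unname(pq$p[on_ray]), rep(4, 4))  # a_ij * omega * row sum

  pq2 <- compute_p_q(A, omega = 2, sc)
  expect_images_equal(pq2$p, 2 * pq$p, 1e-12)

  expect_error(compute_p_q(A, omega = c(1, 2), sc), "mismatch")
})

test_that("update targets c and d are exact fixed points at consistency", {
  ts <- toy_scan()
  sc <- patch_scheme(32, 8, 1)
  D <- fixture("toy_dict", function() {
    train_global_dictionary(ts$mu, sc, K = 96, L = 5, n_iters = 8,
                            seed = 41, max_train = 500)
  })
  codes <- awrct:::code_patches(D, extract_patches(ts$mu, sc), L = 5)
  cd <- compute_c_d(ts$mu, ts$A, ts$sino$omega, ts$sino$l_hat, D, codes, sc)
  # noiseless data and mu = truth: zero residual, c = mu
  expect_images_equal(cd$c, ts$mu, 1e-10)

  # patches perfectly represented => d = mu: feed the patch approximation
  # itself as the dictionary target
  Phat <- extract_patches(ts$mu, sc)
  cd2 <- compute_c_d(ts$mu, ts$A, ts$sino$omega, ts$sino$l_hat, D, codes, sc,
                     patch_approx = Phat)
  expect_images_equal(cd2$d, ts$mu, 1e-10)
})

test_that("update targets match a dense-matrix evaluation", {
  # 4x4 toy instance, dense oracle for c and d
  g <- build_geometry(6, 60, 8, 4, 2, pixel_size = 0.5)
  A <- system_matrix(g)
  set.seed(51)
  mu_t <- matrix(runif(16), 4)
  truth <- matrix(runif(16, 0.2, 1), 4)
  sino <- simulate_scan(truth, g, noise_level = 0, A = A)
  omega <- sino$omega
  sc <- patch_scheme(4, 2, 1)
  D <- patch_dictionary(matrix(rnorm(4 * 8), 4))
  codes <- awrct:::code_patches(D, extract_patches(mu_t, sc), L = 2)
  Phat <- awrct:::approx_patches(D, codes)

  Ad <- dense_A(A)
  muv <- awrct:::img_to_vec(mu_t)
  p <- as.vector(crossprod(Ad, omega * rowSums(Ad)))
  cvec <- muv - as.vector(crossprod(Ad, omega * (Ad %*% muv - sino$l_hat))) /
    ifelse(p > 0, p, Inf)
  cd <- compute_c_d(mu_t, A, omega, sino$l_hat, D, codes, sc,
                    patch_approx = Phat)
  expect_equal(awrct:::img_to_vec(cd$c), cvec, tolerance = 1e-10)

  # dense d: accumulate patch residuals with an explicitly built operator
  q <- sc$q
  pres <- extract_patches(mu_t, sc) - Phat
  acc <- matrix(0, 4, 4)
  for (s in seq_len(sc$n_patches)) {
    e <- matrix(0, 4, 4)
    e[sc$idx[, s]] <- pres[, s]
    acc <- acc + e
  }
  d_oracle <- mu_t - acc / q
  expect_images_equal(cd$d, d_oracle, 1e-10)
})

test_that("awr_step takes the clamped convex combination", {
  cmat <- matrix(2, 3, 3)
  dmat <- matrix(4, 3, 3)
  expect_images_equal(awr_step(cmat, dmat, 1), matrix(3, 3, 3))
  expect_images_equal(awr_step(cmat, dmat, 0), cmat)
  expect_images_equal(awr_step(cmat, dmat, Inf), dmat)
  neg <- matrix(-1, 3, 3)
  expect_images_equal(awr_step(neg, neg, 0.5), matrix(0, 3, 3))
  expect_error(awr_step(cmat, dmat, -1), ">= 0")
})

test_that("sir_dl_step minimizes the separable surrogate pixel by pixel", {
  # 6x6 toy problem: compare against numeric 1-D minimization of the
  # separable paraboloid surrogate plus the patch penalty
  g <- build_geometry(8, 45, 10, 6, 2, pixel_size = 1 / 3)
  A <- system_matrix(g)
  set.seed(61)
  truth <- matrix(runif(36, 0, 1), 6)
  sino <- simulate_scan(truth, g, noise_level = 0.01, seed = 62, A = A)
  sc <- patch_scheme(6, 3, 1)
  D <- patch_dictionary(matrix(rnorm(9 * 16), 9))
  mu_t <- matrix(runif(36, 0, 1), 6)
  codes <- awrct:::code_patches(D, extract_patches(mu_t, sc), L = 3)
  Phat <- awrct:::approx_patches(D, codes)
  lambda <- 0.7

  stepped <- sir_dl_step(mu_t, A, sino$omega, sino$l_hat, D, codes, lambda, sc)

  Ad <- dense_A(A)
  muv <- awrct:::img_to_vec(mu_t)
  rs <- rowSums(Ad)
  resid <- as.vector(Ad %*% muv) - sino$l_hat
  for (jimg in c(8, 15, 22, 29)) {
    # jimg indexes the image matrix (column-major); map to projector order
    rr <- (jimg - 1) %% 6 + 1
    cc <- (jimg - 1) %/% 6 + 1
    j <- (rr - 1) * 6 + cc
    surrogate <- function(x) {
      dx <- x - muv[j]
      qterm <- sum(ifelse(Ad[, j] > 0,
                          (Ad[, j] / rs) * (sino$omega / 2) *
                            (rs * dx + resid)^2, 0))
      hits <- which(sc$idx == jimg, arr.ind = TRUE)
      rterm <- sum((x - Phat[hits]) ^ 2)
      qterm + lambda * rterm
    }
    # the surrogate restricted to one pixel is a parabola: read its
    # vertex off three evaluations (machine-precision 1-D minimizer)
    f0 <- surrogate(0); f1 <- surrogate(1); f2 <- surrogate(2)
    a <- (f2 - 2 * f1 + f0) / 2
    b <- f1 - f0 - a
    opt <- max(0, -b / (2 * a))
    expect_equal(stepped[rr, cc], opt, tolerance = 1e-8)
  }
})

test_that("the surrogate update never increases the full objective", {
  set.seed(71)
  g <- build_geometry(8, 45, 10, 6, 2, pixel_size = 1 / 3)
  A <- system_matrix(g)
  sc <- patch_scheme(6, 3, 1)
  for (trial in 1:20) {
    truth <- matrix(runif(36, 0, 1), 6)
    sino <- simulate_scan(truth, g, noise_level = 0.02,
                          seed = 700 + trial, A = A)
    D <- patch_dictionary(matrix(rnorm(9 * 16), 9))
    mu_t <- matrix(runif(36, 0, 1), 6)
    codes <- awrct:::code_patches(D, extract_patches(mu_t, sc), L = 3)
    Phat <- awrct:::approx_patches(D, codes)
    lambda <- runif(1, 0, 5)
    objective <- function(m) {
      r <- forward_project(A, m) - sino$l_hat
      sum(sino$omega / 2 * r^2) +
        lambda * sum((extract_patches(m, sc) - Phat)^2)
    }
    stepped <- sir_dl_step(mu_t, A, sino$omega, sino$l_hat, D, codes,
                           lambda, sc)
    expect_lte(objective(stepped), objective(mu_t) + 1e-10)
  }
})

test_that("reweighting makes the surrogate update identical to awr_step", {
  ts <- toy_scan()
  sc <- patch_scheme(32, 8, 1)
  D <- patch_dictionary(matrix(rnorm(64 * 96), 64))
  set.seed(81)
  mu_t <- matrix(runif(32^2, 0, 1), 32)
  codes <- awrct:::code_patches(D, extract_patches(mu_t, sc), L = 5)
  for (lambda in c(0.3, 1, 7)) {
    s1 <- sir_dl_step(mu_t, ts$A, ts$sino$omega, ts$sino$l_hat, D, codes,
                      lambda, sc, reweighted = TRUE)
    pq <- compute_p_q(ts$A, ts$sino$omega, sc)
    cd <- compute_c_d(mu_t, ts$A, ts$sino$omega, ts$sino$l_hat, D, codes,
                      sc, p = pq$p)
    s2 <- awr_step(cd$c, cd$d, lambda)
    # identical where the data term informs the pixel; frozen pixels are
    # handled by the full-update path only
    inf_px <- pq$p > 0
    expect_lt(max(abs(s1[inf_px] - s2[inf_px])), 1e-10)
  }
})

test_that("run_reconstruction respects the stopping rule and pass counter", {
  ts <- toy_scan(noise = 0.002, seed = 17)
  reset_recon_pass_count()
  cfg <- recon_config(lambda = 0, max_outer_iters = 40, n_subsets = 5,
                      warmup = 3)
  rec <- suppressWarnings(
    run_reconstruction(ts$sino, ts$geom, "global", cfg, A = ts$A,
                       dictionary = patch_dictionary(matrix(rnorm(64 * 96), 64)))
  )
  expect_equal(recon_pass_count(), 1L)
  expect_gte(min(rec$image), 0)
  expect_true(all(c("iter", "delta", "err_delta") %in% names(rec$trace)))

  # a one-iteration budget cannot converge: warning + flag
  cfgs <- recon_config(lambda = 0, max_outer_iters = 1, warmup = 2)
  expect_warning(
    r1 <- run_reconstruction(ts$sino, ts$geom, "global", cfgs, A = ts$A,
                             dictionary = patch_dictionary(matrix(rnorm(64 * 96), 64))),
    "did not reach")
  expect_false(r1$converged)

  # global mode needs a dictionary once the regularizer is active
  cfg_reg <- recon_config(lambda = 1, max_outer_iters = 2, warmup = 2)
  expect_error(run_reconstruction(ts$sino, ts$geom, "global", cfg_reg,
                                  A = ts$A), "dictionary")
})
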