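test_that("gaussian_psf builds a normalized, point-symmetric kernel with radial decay", {
  h <- gaussian_psf(1)
  v <- h$values
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))
  ctr <- v[h$center[1], h$center[2]]
  expect_true(all(ctr >= v) && sum(v == ctr) == 1)  # strict maximum
  expect_equal(v, v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))])  # h(x,y)=h(-x,-y)
  # closed form: h(1,0)/h(0,0) = exp(-1/(2 sigma^2))
  expect_equal(v[h$center[1] + 1, h$center[2]] / ctr, exp(-0.5), tolerance = 1e-12)
  expect_error(gaussian_psf(2, size = 4), "odd")
  expect_error(gaussian_psf(0), "positive")
})

test_that("turbulence_otf evaluates exp(-k r^(5/3)) on centered frequencies", {
  H <- turbulence_otf(c(16, 16), 0.0025)
  expect_equal(Re(H$values[1, 1]), 1)          # zero frequency
  expect_equal(Re(H$values[1, 2]), exp(-0.0025), tolerance = 1e-12)  # radius^2 = 1
  expect_equal(Re(H$values[2, 1]), exp(-0.0025), tolerance = 1e-12)
  H0 <- turbulence_otf(c(8, 8), 0)
  expect_true(all(H0$values == 1))
  expect_error(turbulence_otf(c(8, 8), -1), "nonnegative")
})

test_that("psf_to_otf places the kernel center at zero frequency", {
  delta <- structure(list(values = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3),
                          center = c(2L, 2L)), class = "psf_kernel")
  H <- psf_to_otf(delta, c(8, 8))
  expect_equal(H$values, matrix(1 + 0i, 8, 8), tolerance = 1e-12)

  g <- gaussian_psf(1.5)
  Hg <- psf_to_otf(g, c(32, 32))
  expect_equal(Re(Hg$values[1, 1]), 1, tolerance = 1e-12)  # unit tap sum
  # point-symmetric real kernel -> real transfer function
  expect_lt(max(abs(Im(Hg$values))), 1e-12)
  expect_error(psf_to_otf(g, c(4, 4)), "shape error")
})

test_that("wiener_restore is the identity for a flat transfer function and inverts noiseless blur", {
  set.seed(20)
  f <- matrix(runif(32 * 32, 0, 255), 32, 32)
  flat <- turbulence_otf(c(32, 32), 0)
  expect_equal(wiener_restore(f, flat, nsr = 0), f, tolerance = 1e-10)

  # |H| bounded away from zero: exact inverse in the noiseless limit
  H <- turbulence_otf(c(32, 32), 0.005)
  g <- ctrestore:::apply_otf(f, H)
  expect_lt(max(abs(wiener_restore(g, H, nsr = 0) - f)), 1e-8)
  expect_error(wiener_restore(matrix(0, 8, 8), H), "shape error")
})

test_that("wiener restoration at a matched nsr beats the degraded input", {
  set.seed(21)
  ph <- make_phantom(phantom_spec(n_frames = 1, background_rank = 1, seed = 21))
  f <- ph$clean$frames[[1]]
  otf <- psf_to_otf(gaussian_psf(2), dim(f))
  g <- degrade(f, otf, noise_std = 5, seed = 3)
  nsr <- 25 / mean((f - mean(f))^2)
  expect_lt(rmse(wiener_restore(g, otf, nsr), f), rmse(g, f))
})

test_that("the wiener filter is linear, vanishes as nsr grows, and obeys the gain bound", {
  set.seed(22)
  H <- psf_to_otf(gaussian_psf(1), c(16, 16))
  g1 <- matrix(rnorm(256), 16, 16); g2 <- matrix(rnorm(256), 16, 16)
  lhs <- wiener_restore(2 * g1 - 3 * g2, H, 0.05)
  rhs <- 2 * wiener_restore(g1, H, 0.05) - 3 * wiener_restore(g2, H, 0.05)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_lt(max(abs(wiener_restore(g1, H, nsr = 1e12))), 1e-9)

  for (nsr in c(1e-4, 0.01, 1)) {
    W <- ctrestore:::wiener_filter(H, nsr)
    expect_lte(max(Mod(W)), 1 / (2 * sqrt(nsr)) + 1e-12)
  }
})

test_that("match_turbulence_k reproduces a Gaussian transfer function closely", {
  k <- match_turbulence_k(2, c(64, 64))
  expect_gt(k, 0)
  G <- Mod(psf_to_otf(gaussian_psf(2), c(64, 64))$values)
  Tk <- Re(turbulence_otf(c(64, 64), k)$values)
  expect_lt(sqrt(mean((G - Tk)^2)), 0.05)
})
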