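test_that("mean_lowrank averages columns and respects stacking linearity", {
  f1 <- matrix(1:6, 2, 3, byrow = TRUE)
  s <- image_sequence(list(f1, f1))
  M <- stack_sequence(s)
  expect_equal(mean_lowrank(M), f1)
  # columns v and -v cancel
  V <- cbind(as.vector(t(f1)), -as.vector(t(f1)))
  expect_equal(mean_lowrank(V, 2, 3), matrix(0, 2, 3))
  # mean of columns == column of means under the stack/unstack round trip
  set.seed(50)
  s2 <- image_sequence(lapply(1:4, function(i) matrix(rnorm(24), 4, 6)))
  M2 <- stack_sequence(s2)
  expect_equal(mean_lowrank(M2), Reduce(`+`, s2$frames) / 4)
})

test_that("a rank-1 sequence restores to the Gaussian-Wiener restoration of the shared frame", {
  set.seed(51)
  base <- matrix(runif(32 * 32, 30, 220), 32, 32)
  s <- image_sequence(lapply(1:5, function(i) base))
  cfg <- restoration_config("rpca", gauss_sigma = 1.2, gauss_nsr = 0.01,
                            solver_opts = solver_options(lam = 10))
  res <- restore_sequence(s, cfg)
  expect_lt(sqrt(sum(res$decomposition$sparse^2)) /
              sqrt(sum(stack_sequence(s)$values^2)), 1e-6)
  expected <- pmin(pmax(baseline_wiener_gaussian(base, 1.2, 0.01), 0), 255)
  for (i in 1:5)
    expect_equal(res$restored$frames[[i]], expected, tolerance = 1e-5)
})

test_that("recombination identity holds exactly before clipping, for every model", {
  ph <- make_phantom(phantom_spec(n_frames = 6, height = 24, width = 24, seed = 52))
  for (model in c("rpca", "ladmap", "godec")) {
    cfg <- restoration_config(model, solver_opts = solver_options(r = 2, k = 60, seed = 1))
    res <- restore_sequence(ph$degraded, cfg)
    expect_equal(res$restored$n_frames, 6)
    expect_identical(dim(res$restored$frames[[1]]), c(24L, 24L))
    for (i in 1:6) {
      recombined <- res$sparse_restored$frames[[i]] + res$lowrank_mean_restored
      expect_identical(res$restored$frames[[i]],
                       pmin(pmax(recombined, 0), 255))
    }
    expect_identical(res$decomposition$model, model)
  }
})

test_that("the godec path carries a noise component satisfying the reconstruction identity", {
  ph <- make_phantom(phantom_spec(n_frames = 6, height = 24, width = 24,
                                  noise_std = 8, seed = 53))
  cfg <- restoration_config("godec", solver_opts = solver_options(r = 2, k = 150, seed = 2))
  res <- restore_sequence(ph$degraded, cfg)
  dec <- res$decomposition
  expect_false(is.null(dec$noise))
  M <- stack_sequence(ph$degraded)$values
  expect_equal(dec$low_rank + dec$sparse + dec$noise, M, tolerance = 1e-12)
  expect_identical(cfg$alpha, 1L)
  expect_identical(restoration_config("rpca")$alpha, 0L)
})

test_that("baseline_wiener_gaussian is near-identity for a narrow kernel and linear", {
  set.seed(54)
  f <- matrix(runif(24 * 24, 0, 255), 24, 24)
  expect_lt(max(abs(baseline_wiener_gaussian(f, 0.15, nsr = 0) - f)), 1e-6)
  g <- matrix(runif(24 * 24, 0, 255), 24, 24)
  lhs <- baseline_wiener_gaussian(1.5 * f - 0.5 * g, 2, 0.02)
  rhs <- 1.5 * baseline_wiener_gaussian(f, 2, 0.02) -
    0.5 * baseline_wiener_gaussian(g, 2, 0.02)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("single-frame sequences are accepted with a warning", {
  set.seed(55)
  s <- image_sequence(list(matrix(runif(16 * 16, 0, 255), 16, 16)))
  expect_warning(res <- restore_sequence(s, restoration_config("rpca")),
                 "single-frame")
  expect_equal(res$restored$n_frames, 1)
})

test_that("noise estimation and model auto-selection respond to the noise level", {
  ph_quiet <- make_phantom(phantom_spec(noise_std = 2, seed = 56))
  ph_noisy <- make_phantom(phantom_spec(noise_std = 20, seed = 56))
  est_q <- mean(vapply(ph_quiet$degraded$frames, estimate_noise_std, numeric(1)))
  est_n <- mean(vapply(ph_noisy$degraded$frames, estimate_noise_std, numeric(1)))
  expect_lt(est_q, est_n)
  expect_identical(auto_select_model(ph_quiet$degraded), "rpca")
  expect_identical(auto_select_model(ph_noisy$degraded), "godec")
})
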