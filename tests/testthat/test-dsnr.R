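test_that("dsnr_core reproduces the hand-evaluated decomposition", {
  # v = [1,0] on both bins; v_hat = [1,1] and [1,-1]:
  # signal magnitudes 1,1; noise magnitudes 1,1 -> dSNR = 1
  v <- rbind(c(1, 0), c(1, 0))
  vh <- rbind(c(1, 1), c(1, -1))
  expect_equal(dsnr_core(vh, v), 1)

  # always orthogonal: zero signal
  vh_orth <- rbind(c(0, 1), c(0, -1))
  expect_equal(dsnr_core(vh_orth, v), 0)

  # noiseless: infinite, flagged as Inf
  expect_true(is.infinite(dsnr_core(3 * v, v)))

  # all rows zero-intent: undefined
  expect_true(is.na(dsnr_core(vh, matrix(0, 2, 2))))
})

test_that("dsnr decomposition satisfies Pythagoras and rotation invariance", {
  set.seed(13)
  for (i in 1:20) {
    n <- 50
    th <- runif(n, 0, 2 * pi)
    v <- cbind(cos(th), sin(th))
    vh <- matrix(rnorm(2 * n), n)
    # independent recomputation of the decomposition
    s <- rowSums(vh * v)
    nrm <- sqrt(rowSums(vh^2))
    noise <- sin(acos(pmin(pmax(s / nrm, -1), 1))) * nrm
    expect_equal(s^2 + noise^2, nrm^2, tolerance = 1e-9)

    # rotating v_hat and v together leaves dSNR unchanged
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    expect_equal(dsnr_core(vh %*% R, v %*% R), dsnr_core(vh, v),
                 tolerance = 1e-9)
  }
})

test_that("cross-validated dSNR separates signal from null populations", {
  # pure-noise population: dSNR indistinguishable from the permutation null
  null_model <- make_population(16, 2, tuning_sd = 0, noise_sd = 1, seed = 3)
  ds_null <- make_dsnr_dataset(null_model, n_bins = 3000, seed = 4)
  expect_lt(dsnr_cv(ds_null), 0.1)

  # noiseless linear population: essentially infinite
  clean <- make_population(16, 2, tuning_sd = 1, noise_sd = 0, seed = 5)
  ds_clean <- make_dsnr_dataset(clean, n_bins = 600, seed = 6)
  v_clean <- dsnr_cv(ds_clean)
  expect_true(is.infinite(v_clean) || v_clean > 1e3)

  # doubling the channel noise halves the dSNR
  m1 <- make_population(24, 2, tuning_sd = 1, noise_sd = 1, seed = 7)
  m2 <- m1; m2$noise_sd <- m1$noise_sd * 2
  d1 <- dsnr_cv(make_dsnr_dataset(m1, n_bins = 4000, seed = 8))
  d2 <- dsnr_cv(make_dsnr_dataset(m2, n_bins = 4000, seed = 8))
  expect_equal(d1 / d2, 2, tolerance = 0.15)

  expect_error(dsnr_cv(list(X = matrix(0, 4, 3), V = matrix(0, 4, 2))),
               "folds")
})

test_that("dsnr_cv is invariant to channel permutation and common scale", {
  m <- make_population(12, 2, tuning_sd = 1, noise_sd = 1, seed = 9)
  ds <- make_dsnr_dataset(m, n_bins = 900, seed = 10)
  base <- dsnr_cv(ds)
  set.seed(1)
  perm <- sample(ncol(ds$X))
  expect_equal(dsnr_cv(list(X = ds$X[, perm], V = ds$V)), base,
               tolerance = 1e-8)
  expect_equal(dsnr_cv(list(X = 3.7 * ds$X, V = ds$V)), base,
               tolerance = 1e-8)
})

test_that("the channel curve grows for ideal populations and saturates
           under a shared-noise ceiling", {
  # near-monotone growth: averaged subsets, at most one inversion
  for (s in 1:3) {
    m <- make_population(40, 2, tuning_sd = 1, noise_sd = 1, seed = 100 + s)
    ds <- make_dsnr_dataset(m, n_bins = 2000, seed = 200 + s)
    cu <- dsnr_vs_channels(ds, n_subsets = 20, seed = 300 + s)
    expect_lte(sum(diff(cu$mean_dsnr) < 0), 1)
  }

  # informative channels with high SNR + motor (shared) noise: the curve
  # saturates; doubling channels adds < 5%
  sat <- make_population(40, 2, tuning_sd = 5, noise_sd = 0.3, seed = 21)
  sat$tuning[11:40, ] <- 0
  ds <- make_dsnr_dataset(sat, n_bins = 2000, motor_noise_sd = 0.5,
                          seed = 22)
  set.seed(23)
  full <- mean(replicate(12, dsnr_cv(list(X = ds$X, V = ds$V))))
  half <- mean(replicate(12,
    dsnr_cv(list(X = ds$X[, sample(40, 20)], V = ds$V))))
  expect_lt((full - half) / half, 0.05)

  expect_error(dsnr_vs_channels(ds, min_channels = 100), "exceeds")
})

test_that("dsnr_vs_channels is deterministic per seed", {
  m <- make_population(10, 2, tuning_sd = 1, noise_sd = 1, seed = 31)
  ds <- make_dsnr_dataset(m, n_bins = 300, seed = 32)
  a <- dsnr_vs_channels(ds, n_subsets = 3, seed = 33)
  b <- dsnr_vs_channels(ds, n_subsets = 3, seed = 33)
  expect_identical(a, b)
})

test_that("power-law fits recover synthetic exponents exactly", {
  N <- c(5, 10, 20, 40, 80, 160)
  fit <- power_law_fit(list(channel_counts = N, mean_dsnr = 2 * N^0.5))
  expect_equal(fit$m, 0.5, tolerance = 1e-9)
  expect_equal(fit$B, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- power_law_fit(list(channel_counts = N, mean_dsnr = rep(7, 6)))
  expect_equal(flat$m, 0, tolerance = 1e-12)
  expect_true(is.nan(flat$r_squared))

  for (m_true in c(-1, -0.3, 0.25, 1)) {
    f <- power_law_fit(list(channel_counts = N,
                            mean_dsnr = 1.7 * N^m_true))
    expect_equal(f$m, m_true, tolerance = 1e-9)
    expect_equal(f$B, 1.7, tolerance = 1e-8)
  }

  # only the highest 75% of counts are used
  f75 <- power_law_fit(list(channel_counts = c(2, N),
                            mean_dsnr = c(1e6, 2 * N^0.5)))
  expect_equal(f75$m, 0.5, tolerance = 1e-9)
  expect_false(2 %in% f75$channel_counts)

  expect_error(power_law_fit(list(channel_counts = N,
                                  mean_dsnr = c(2 * N[-6]^0.5, -1))),
               "positive")
})
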