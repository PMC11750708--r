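test_that("initialization is deterministic and Kaiming-scaled", {
  cfg <- decoder_config(6, 2, hidden_widths = c(256L, 256L, 64L, 2L))
  a <- init_decoder(cfg, seed = 5)
  b <- init_decoder(cfg, seed = 5)
  expect_identical(a, b)

  # fan-in 256 layer: empirical weight SD within 10% of sqrt(2/256)
  expect_lt(abs(sd(a$W2) - sqrt(2 / 256)) / sqrt(2 / 256), 0.1)

  expect_error(decoder_config(6, 2, hidden_widths = c(32L, 32L, 32L, 3L)),
               "last hidden width")
  expect_error(decoder_config(6, 2, dropout = 1), "dropout")
})

test_that("forward pass honors the mean-free output construction", {
  cfg <- quick_decoder_config(5, 2, width = 16L)
  p <- init_decoder(cfg, seed = 1)
  w <- matrix(rnorm(15), 5, 3)

  # zero final layer: exactly zero output (no affine escape hatch)
  p0 <- p
  p0$W4[] <- 0
  expect_equal(decoder_forward(p0, w), c(0, 0))

  # inference is a pure function: identical twice
  expect_identical(decoder_forward(p, w), decoder_forward(p, w))

  expect_error(decoder_forward(p, matrix(0, 4, 3)), "5 x 3")

  # a converged decoder's raw output is near mean-free
  model <- quick_population(16, 2, noise_sd = 0)
  dec <- quick_trained_decoder(model, n = 1200, epochs = 40)
  set.seed(9)
  V <- matrix(rnorm(800 * 2, sd = 0.3), 800)
  raw <- decoder_forward(dec, make_windows(emit_sbp_series(model, V)))
  expect_true(all(abs(colMeans(raw)) < 0.05 * apply(raw, 2, sd)))
})

test_that("output normalization and gain follow the affine contract", {
  cfg <- quick_decoder_config(5, 2, width = 16L)
  p <- init_decoder(cfg, seed = 1)
  expect_error(apply_normalization_and_gain(c(1, 1), p), "unset")

  p$out_mean <- c(0.3, -0.2)
  p$out_sd <- c(2, 4)
  p$gains <- c(0.5, 1.5)
  expect_equal(apply_normalization_and_gain(c(0.3, -0.2), p), c(0, 0))
  # one SD above the mean: gain times the speed constant
  expect_equal(apply_normalization_and_gain(c(2.3, 3.8), p),
               c(0.5, 1.5) * p$config$speed_constant)
  p$gains <- c(0, 0)
  expect_equal(apply_normalization_and_gain(c(7, -3), p), c(0, 0))
})

test_that("supervised training learns and is seed-deterministic", {
  model <- quick_population(12, 2, noise_sd = 0.5)
  set.seed(4)
  V <- matrix(rnorm(500 * 2, sd = 0.3), 500)
  tset <- training_set(make_windows(emit_sbp_series(model, V)), V)
  cfg <- quick_decoder_config(12, 2, width = 32L)

  d1 <- train_supervised(init_decoder(cfg, 1), tset, epochs = 3, seed = 9)
  d2 <- train_supervised(init_decoder(cfg, 1), tset, epochs = 3, seed = 9)
  expect_equal(unclass(d1)[names(d1) != "config"],
               unclass(d2)[names(d2) != "config"], tolerance = 1e-12)
  expect_equal(d1$version, 1L)

  # all-zero targets: trained output magnitude shrinks at least 50%
  z <- matrix(0, 500, 2)
  tz <- training_set(tset$windows, z)
  init <- init_decoder(cfg, 2)
  before <- mean(abs(decoder_forward(init, tset$windows)))
  trained <- train_supervised(init, tz, epochs = 5, seed = 3,
                              standardize_labels = FALSE)
  after <- mean(abs(decoder_forward(trained, tset$windows)))
  expect_lt(after, 0.5 * before)

  # descent sanity: inference loss on a fixed batch does not increase
  # after one epoch, averaged over 5 seeds
  tgt <- scale(V)
  attr(tgt, "scaled:center") <- NULL
  attr(tgt, "scaled:scale") <- NULL
  drops <- vapply(1:5, function(s) {
    init <- init_decoder(cfg, s)
    loss0 <- mean((decoder_forward(init, tset$windows) - tgt)^2)
    tr <- train_supervised(init, tset, epochs = 1, seed = s)
    loss1 <- mean((decoder_forward(tr, tset$windows) - tgt)^2)
    loss1 - loss0
  }, 0)
  expect_lt(mean(drops), 0)

  expect_error(train_supervised(init_decoder(cfg, 1),
                                training_set(tset$windows[, , 0, drop = FALSE],
                                             V[0, , drop = FALSE])),
               "empty")
})

test_that("decoder recovers a noiseless linear code almost perfectly", {
  model <- quick_population(16, 2, noise_sd = 0)
  dec <- quick_trained_decoder(model, n = 1200, epochs = 40)
  set.seed(31)
  V2 <- matrix(rnorm(400 * 2, sd = 0.3), 400)
  X2 <- emit_sbp_series(model, V2)
  pred <- decode_velocity(dec, make_windows(X2))
  expect_true(all(diag(cor(pred, V2)) > 0.95))
})

test_that("ReFIT relabeling flips signs toward the target, never magnitudes", {
  # worked cases: decoded -0.3 with target above -> +0.3; +0.3 -> +0.3
  rec <- schedule_record(inside_bins = 21:30, n_bins = 30)
  rec$decoded[1, 1] <- -0.3     # position 0.2, target 0.7: away
  rec$decoded[2, 1] <- 0.3      # toward
  rec$decoded[3, 1] <- 0
  rl <- refit_relabel(list(rec), zero_inside_target = FALSE)
  expect_equal(rl$targets[1, 1], 0.3)
  expect_equal(rl$targets[2, 1], 0.3)
  expect_equal(rl$targets[3, 1], 0)

  # on randomized logs: magnitudes preserved, signs point at the target,
  # in-target bins zeroed
  model <- quick_population(12, 2, noise_sd = 2)
  task <- task_config("cl2d")
  recs <- run_closed_loop_session(task, oracle_controller(0.5), model,
                                  n_trials = 10, seed = 21)
  rl <- refit_relabel(recs)
  off <- 0L
  for (r in recs) {
    k <- r$n_bins
    lab <- rl$targets[off + seq_len(k), , drop = FALSE]
    off <- off + k
    pos <- r$positions[seq_len(k), , drop = FALSE]
    err <- rep(r$centers, each = k) - pos
    inside <- abs(err) <= r$width / 2
    expect_true(all(lab[inside] == 0))
    expect_equal(abs(lab[!inside]), abs(r$decoded[!inside]))
    nz <- !inside & lab != 0
    expect_true(all(sign(lab[nz]) == sign(err[nz])))
  }

  bad <- recs[[1]]
  bad$decoded <- NULL
  expect_error(refit_relabel(list(bad)), "decoded")
})

test_that("ReFIT update is deterministic and near-stationary at an optimum", {
  model <- quick_population(12, 2, noise_sd = 1)
  task <- task_config("cl2d")
  dec <- quick_trained_decoder(model, n = 600, epochs = 8, width = 32L)
  recs <- run_closed_loop_session(task, dec, model, n_trials = 8, seed = 2)
  rl <- refit_relabel(recs)

  u1 <- refit_update(dec, rl, seed = 7)
  u2 <- refit_update(dec, rl, seed = 7)
  expect_equal(unclass(u1)[names(u1) != "config"],
               unclass(u2)[names(u2) != "config"], tolerance = 1e-12)
  expect_equal(u1$version, dec$version + 1L)

  # a set the decoder already fits essentially perfectly moves parameters
  # very little (weight decay off to isolate the gradient signal)
  model0 <- quick_population(12, 2, noise_sd = 0)
  dec0 <- quick_trained_decoder(model0, n = 800, epochs = 40, width = 32L)
  set.seed(5)
  V <- matrix(rnorm(300 * 2, sd = 0.3), 300)
  fitset <- training_set(make_windows(emit_sbp_series(model0, V)), V)
  upd <- refit_update(dec0, fitset, seed = 8, iterations = 100,
                      weight_decay = 0, learning_rate = 1e-5)
  rel <- sqrt(sum((upd$W2 - dec0$W2)^2)) / sqrt(sum(dec0$W2^2))
  expect_lt(rel, 0.01)
})

test_that("decoder parameters survive a serialization round trip", {
  model <- quick_population(8, 2)
  dec <- quick_trained_decoder(model, n = 300, epochs = 3, width = 16L)
  f <- withr::local_tempfile(fileext = ".json")
  save_decoder(dec, f)
  dec2 <- load_decoder(f)
  w <- make_windows(emit_sbp_series(model, matrix(c(0.3, -0.2), 1)))[, , 1]
  expect_equal(decode_velocity(dec2, w), decode_velocity(dec, w),
               tolerance = 1e-12)
})
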