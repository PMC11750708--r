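test_that("open-loop trajectories follow a minimum-jerk profile", {
  # 2 s of movement and 1 s of hold in 50-ms bins: 40 + 20 bins
  tr <- open_loop_trajectory("thumb_flex", "flex", dof = 4)
  expect_equal(nrow(tr$positions), 61L)          # start + 40 move + 20 hold
  expect_equal(tr$positions[1, 1], 0.5)
  expect_equal(tr$positions[61, 1], 1.0)
  expect_equal(tr$positions[41, 1], 1.0)         # end of the 2-s movement
  expect_equal(tr$positions[21, 1], 0.75)        # midpoint of the movement
  expect_true(all(tr$positions[, 2:4] == 0.5))   # uncued DOF constant

  ext <- open_loop_trajectory("index_middle", "extend", dof = 4)
  expect_equal(ext$positions[61, 3], 0)
  peak <- max(abs(ext$velocities[, 3]))
  expect_lt(abs(ext$velocities[1, 3]), 0.01 * peak)
  expect_lt(abs(ext$velocities[40, 3]), 0.01 * peak)  # last motion bin
})

test_that("target generation obeys each variant's pairing rules", {
  groups4 <- finger_groups(4)
  task <- task_config("cl4d_two_new")
  set.seed(1)
  prev <- NULL
  for (trial in 1:40) {
    ts <- generate_targets(task, prev)
    if (!ts$is_center) {
      at_center <- vapply(groups4, function(ix) all(ts$centers[ix] == 0.5),
                          NA)
      expect_equal(sum(!at_center), 2L)      # exactly two groups moved
      expect_equal(length(ts$cued_groups), 2L)
    } else {
      expect_true(all(ts$centers == 0.5))
    }
    expect_true(all(ts$centers >= ts$width / 2 &
                      ts$centers <= 1 - ts$width / 2))
    prev <- ts
  }

  t2 <- task_config("cl2d")
  set.seed(2)
  out <- generate_targets(t2, NULL)
  expect_false(out$is_center)
  back <- generate_targets(t2, out)
  expect_true(all(back$centers == 0.5))

  tt <- task_config("t_train")
  expect_equal(tt$hold_required, 1.5)
  expect_equal(tt$timeout, 5)
  set.seed(3)
  first <- generate_targets(tt, NULL)            # odd trial: stationary
  expect_true(all(first$centers == 0.5))
  expect_equal(first$frozen_dof, 1:4)
  second <- generate_targets(tt, first)          # even trial: two new
  expect_false(second$is_center)
  expect_equal(length(second$cued_groups), 2L)
  unsel <- setdiff(names(groups4), second$cued_groups)
  expect_equal(sort(second$frozen_dof),
               sort(unlist(groups4[unsel], use.names = FALSE)))

  one <- task_config("cl4d_one_new")
  set.seed(4)
  o1 <- generate_targets(one, NULL)
  expect_equal(length(o1$cued_groups), 1L)

  expect_error(task_config("bogus"), "task kind")
})

test_that("trial stepping enforces hold, reset and timeout semantics", {
  task <- task_config("cl2d")
  set.seed(1)
  target <- generate_targets(task, NULL)
  st <- finger_state(2, target$centers)  # start on target

  hold <- 0L
  status <- "running"
  for (k in 1:10) {
    r <- step_trial(st, c(0, 0), target, k * 0.05, hold)
    st <- r$state; hold <- r$hold_count; status <- r$status
  }
  expect_equal(status, "success")
  expect_equal(hold, 10L)

  # 9 in, 1 out, 10 in: success only after the second streak
  st <- finger_state(2, target$centers)
  hold <- 0L; k <- 0L
  for (i in 1:9) {
    k <- k + 1L
    r <- step_trial(st, c(0, 0), target, k * 0.05, hold)
    st <- r$state; hold <- r$hold_count
  }
  expect_equal(r$status, "running")
  k <- k + 1L
  r <- step_trial(st, c(10, 0), target, k * 0.05, hold)  # bounce out
  st <- r$state; hold <- r$hold_count
  expect_equal(hold, 0L)
  st$positions <- target$centers                         # jump back in
  for (i in 1:10) {
    k <- k + 1L
    r <- step_trial(st, c(0, 0), target, k * 0.05, hold)
    st <- r$state; hold <- r$hold_count
  }
  expect_equal(r$status, "success")
  expect_equal(k, 20L)

  # never inside: timeout at 10 s
  st <- finger_state(2, c(0, 0))
  hold <- 0L
  for (k in 1:200) {
    r <- step_trial(st, c(0, 0), target, k * 0.05, hold)
    hold <- r$hold_count
  }
  expect_equal(r$status, "timeout")

  # positions clamp to [0, 1]
  r <- step_trial(finger_state(2, c(0.99, 0.01)), c(5, -5), target, 0.05, 0L)
  expect_equal(r$state$positions, c(1, 0))
})

test_that("simulated user intent is a unit (or zero) target vector", {
  task <- task_config("cl2d")
  tg <- structure(list(centers = c(0.8, 0.8), width = 0.2,
                       hold_required = 0.5, timeout = 10,
                       cued_groups = c("thumb", "index_middle"),
                       frozen_dof = integer(0), is_center = FALSE),
                  class = "target_set")
  st <- finger_state(2, c(0.5, 0.5))
  v <- simulated_user_intent(st, tg)
  expect_equal(v, c(1, 1) / sqrt(2), tolerance = 1e-12)

  on_target <- finger_state(2, c(0.8, 0.8))
  expect_equal(simulated_user_intent(on_target, tg), c(0, 0))

  one_off <- finger_state(2, c(0.5, 0.8))
  expect_equal(simulated_user_intent(one_off, tg), c(1, 0))

  set.seed(7)
  for (i in 1:50) {
    st <- finger_state(2, runif(2))
    n <- sqrt(sum(simulated_user_intent(st, tg)^2))
    expect_true(abs(n) < 1e-12 || abs(n - 1) < 1e-12)
  }
})

test_that("closed-loop sessions behave at the controller extremes", {
  model <- quick_population(12, 2, noise_sd = 1)
  task <- task_config("cl2d")
  recs <- run_closed_loop_session(task, oracle_controller(0.6), model,
                                  n_trials = 50, seed = 3)
  expect_equal(session_success_rate(recs), 1)

  # null controller: every out trial times out; back trials that happen to
  # start on target are degenerate immediate successes
  null_recs <- run_closed_loop_session(task, null_controller(), model,
                                       n_trials = 10, seed = 4)
  out_trials <- Filter(function(r) !r$is_center, null_recs)
  expect_true(all(!vapply(out_trials, function(r) r$success, NA)))

  # determinism
  a <- run_closed_loop_session(task, oracle_controller(0.6), model,
                               n_trials = 5, seed = 11)
  b <- run_closed_loop_session(task, oracle_controller(0.6), model,
                               n_trials = 5, seed = 11)
  expect_identical(a, b)
})

test_that("trial records satisfy the timing and range invariants", {
  model <- quick_population(12, 2, noise_sd = 2)
  task <- task_config("cl2d")
  recs <- run_closed_loop_session(task, oracle_controller(0.5), model,
                                  n_trials = 30, seed = 8)
  for (r in recs) {
    expect_true(all(r$positions >= 0 & r$positions <= 1))
    if (r$success) {
      expect_lte(r$first_entry_time, r$last_entry_time)
      expect_lt(r$last_entry_time, r$completion_time)
      expect_equal(r$completion_time - r$last_entry_time, r$hold_required)
      expect_equal(r$completion_time * 20, round(r$completion_time * 20),
                   tolerance = 1e-9)
    }
  }
})
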