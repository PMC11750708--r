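#' Virtual finger state
#'
#' Positions are kept in canonical units `u` in `[0, 1]` per degree of
#' freedom, with `u = 0.5` the neutral posture; the display convention
#' `s = 2u - 1` (full extension -1, full flexion +1) is available via
#' [to_display()]. The four canonical DOF are thumb flexion/extension,
#' thumb abduction/adduction, index--middle flexion and ring--little
#' flexion; the 2-DOF variant keeps thumb flexion and index--middle.
#'
#' @param dof 2 or 4.
#' @param positions optional initial positions (default all 0.5).
#' @return object of class `finger_state` with `positions`, `velocities`
#'   and `dof_labels`.
#' @export
finger_state <- function(dof = 4, positions = NULL) {
  labels <- dof_labels(dof)
  if (is.null(positions)) positions <- rep(0.5, dof)
  stopifnot(length(positions) == dof)
  structure(list(
    positions = pmin(pmax(as.numeric(positions), 0), 1),
    velocities = rep(0, dof),
    dof_labels = labels
  ), class = "finger_state")
}

#' @rdname finger_state
#' @export
dof_labels <- function(dof) {
  switch(as.character(dof),
         "2" = c("thumb_flex", "index_middle"),
         "4" = c("thumb_flex", "thumb_abd", "index_middle", "ring_little"),
         stop("`dof` must be 2 or 4", call. = FALSE))
}

#' Finger groups for a DOF count
#'
#' The thumb's two axes form one group in the 4-DOF configuration; each
#' 1D finger pair is its own group.
#' @param dof 2 or 4.
#' @return named list mapping group name to DOF indices.
#' @export
finger_groups <- function(dof) {
  if (dof == 2) {
    list(thumb = 1L, index_middle = 2L)
  } else if (dof == 4) {
    list(thumb = c(1L, 2L), index_middle = 3L, ring_little = 4L)
  } else {
    stop("`dof` must be 2 or 4", call. = FALSE)
  }
}

#' @rdname finger_state
#' @param u positions in `[0, 1]`.
#' @export
to_display <- function(u) 2 * u - 1

#' Task configuration
#'
#' Bundles the target geometry and timing of one task variant. Defaults
#' follow the standard closed-loop finger task: target width 20% of the
#' range of motion, 500-ms hold, 10-s timeout. The `t_train` training
#' variant overrides hold to 1.5 s and timeout to 5 s, snaps fingers back
#' to center at the end of every trial, freezes the unselected finger
#' group at center, and alternates in stationary all-center trials.
#'
#' @param kind one of `"cl2d"`, `"cl4d_two_new"`, `"cl4d_one_new"`,
#'   `"cl4d_random"`, `"t_train"`.
#' @param width target width in ROM units.
#' @param hold_required required in-target hold (s).
#' @param timeout trial timeout (s).
#' @param user_speed simulated-user commanded speed (ROM-units/s).
#' @param motor_noise_sd Gaussian motor noise added to the simulated
#'   user's intended velocity (ROM-units/s).
#' @return object of class `task_config`.
#' @export
task_config <- function(kind = "cl2d", width = 0.2,
                        hold_required = if (kind == "t_train") 1.5 else 0.5,
                        timeout = if (kind == "t_train") 5 else 10,
                        user_speed = 0.6, motor_noise_sd = 0.05) {
  kinds <- c("cl2d", "cl4d_two_new", "cl4d_one_new", "cl4d_random", "t_train")
  if (!kind %in% kinds) {
    stop("unknown task kind: ", kind, call. = FALSE)
  }
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  if (hold_required > timeout) {
    stop("`hold_required` must not exceed `timeout`", call. = FALSE)
  }
  dof <- if (kind == "cl2d") 2L else 4L
  structure(list(kind = kind, dof = dof, width = width,
                 hold_required = hold_required, timeout = timeout,
                 user_speed = user_speed, motor_noise_sd = motor_noise_sd),
            class = "task_config")
}

#' Minimum-jerk open-loop trajectory for one cued DOF
#'
#' Open-loop trials move the cued finger group from the neutral position
#' (`u = 0.5`) to full flexion (`u = 1`) or full extension (`u = 0`) over
#' `move_time`, then hold for `hold_time`. The profile is minimum-jerk, so
#' velocity and acceleration vanish at both endpoints, matching a smooth
#' cued trajectory. Uncued DOF stay at `start`.
#'
#' @param cued_dof index (or label) of the cued DOF.
#' @param direction `"flex"` (to 1) or `"extend"` (to 0).
#' @param move_time,hold_time durations (s).
#' @param dof total number of DOF.
#' @param start starting positions (scalar or vector, default 0.5).
#' @return list with `positions` (`(n_bins + 1) x dof`, first row the
#'   start), `velocities` (`n_bins x dof`, per-bin displacement / 50 ms)
#'   and `times` (bin end times, s).
#' @export
open_loop_trajectory <- function(cued_dof, direction = c("flex", "extend"),
                                 move_time = 2, hold_time = 1, dof = 4,
                                 start = 0.5) {
  direction <- match.arg(direction)
  if (is.character(cued_dof)) cued_dof <- match(cued_dof, dof_labels(dof))
  stopifnot(length(cued_dof) >= 1, all(cued_dof %in% seq_len(dof)))
  start <- rep_len(start, dof)
  target <- if (direction == "flex") 1 else 0
  n_move <- round(move_time / BIN_S)
  n_hold <- round(hold_time / BIN_S)
  tau <- seq_len(n_move) / n_move
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  n_bins <- n_move + n_hold
  pos <- matrix(rep(start, each = n_bins + 1L), n_bins + 1L, dof)
  for (j in cued_dof) {
    prof <- start[j] + (target - start[j]) * c(s, rep(1, n_hold))
    pos[-1L, j] <- prof
  }
  vel <- diff(pos) / BIN_S
  list(positions = pos, velocities = vel,
       times = seq_len(n_bins) * BIN_S)
}

#' Generate a block of paired open-loop trials
#'
#' Center-out-and-back pairs: on the out trial one finger group is chosen
#' at random to flex or extend fully; on the back trial it returns to
#' neutral. Optional rest trials hold all fingers still. Concatenates the
#' per-bin cued positions and velocities of the whole block.
#'
#' @param dof 2 or 4.
#' @param n_pairs number of out/back pairs.
#' @param rest_every insert a 1.5-s rest trial after every this many pairs
#'   (0 disables).
#' @param move_time,hold_time per-trial timing (s).
#' @return list with `positions` (`n_bins x dof`, at bin ends),
#'   `velocities` (`n_bins x dof`) and `trial_index` per bin.
#' @export
open_loop_block <- function(dof = 4, n_pairs = 12, rest_every = 4,
                            move_time = 2, hold_time = 1) {
  groups <- finger_groups(dof)
  pos_list <- list(); vel_list <- list(); tri <- integer(0)
  cur <- rep(0.5, dof)
  trial <- 0L
  for (p in seq_len(n_pairs)) {
    g <- groups[[sample.int(length(groups), 1)]]
    dir <- sample(c("flex", "extend"), 1)
    out <- open_loop_trajectory(g, dir, move_time, hold_time, dof, cur)
    cur_out <- out$positions[nrow(out$positions), ]
    trial <- trial + 1L
    pos_list[[length(pos_list) + 1L]] <- out$positions[-1L, , drop = FALSE]
    vel_list[[length(vel_list) + 1L]] <- out$velocities
    tri <- c(tri, rep(trial, nrow(out$velocities)))
    # back trial: return to neutral along the same profile
    n_move <- round(move_time / BIN_S); n_hold <- round(hold_time / BIN_S)
    tau <- seq_len(n_move) / n_move
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    back <- matrix(rep(cur_out, each = n_move + n_hold), ncol = dof)
    for (j in g) back[, j] <- cur_out[j] + (0.5 - cur_out[j]) * c(s, rep(1, n_hold))
    trial <- trial + 1L
    vel_back <- diff(rbind(cur_out, back)) / BIN_S
    pos_list[[length(pos_list) + 1L]] <- back
    vel_list[[length(vel_list) + 1L]] <- vel_back
    tri <- c(tri, rep(trial, nrow(back)))
    cur <- back[nrow(back), ]
    if (rest_every > 0 && p %% rest_every == 0) {
      n_rest <- round(1.5 / BIN_S)
      trial <- trial + 1L
      pos_list[[length(pos_list) + 1L]] <-
        matrix(rep(cur, each = n_rest), ncol = dof)
      vel_list[[length(vel_list) + 1L]] <- matrix(0, n_rest, dof)
      tri <- c(tri, rep(trial, n_rest))
    }
  }
  list(positions = do.call(rbind, pos_list),
       velocities = do.call(rbind, vel_list),
       trial_index = tri)
}

#' Targets for the next trial of a task variant
#'
#' Implements the pairing rules of each closed-loop variant. Paired
#' variants alternate "out" trials (random targets in the active range)
#' with "back" trials (all targets at center). The 4-DOF two-new variant
#' draws new targets for two of the three finger groups, leaving the third
#' at its center target; the one-new variant moves a single group;
#' `cl4d_random` draws two new targets each trial with no pairing;
#' `t_train` alternates stationary all-center trials with two-new trials
#' in which the unselected group's DOF are frozen in place.
#'
#' Out-targets are drawn uniformly in the active range
#' `[width/2, 1 - width/2]`, redrawn until they lie outside the central
#' target so that an out trial always demands movement. Draws use R's
#' current RNG stream.
#'
#' @param task a [task_config()].
#' @param previous the previous trial's target set, or `NULL` at block
#'   start (treated as a center trial).
#' @return object of class `target_set`: `centers`, `width`,
#'   `hold_required`, `timeout`, `cued_groups` (character), `frozen_dof`
#'   (integer indices pinned in place), `is_center` flag.
#' @export
generate_targets <- function(task, previous = NULL) {
  stopifnot(inherits(task, "task_config"))
  dof <- task$dof
  groups <- finger_groups(dof)
  w <- task$width
  center <- rep(0.5, dof)
  draw_target <- function() {
    repeat {
      c0 <- stats::runif(1, w / 2, 1 - w / 2)
      if (abs(c0 - 0.5) > w / 2) return(c0)
    }
  }
  new_set <- function(centers, cued, frozen, is_center) {
    structure(list(centers = centers, width = w,
                   hold_required = task$hold_required,
                   timeout = task$timeout,
                   cued_groups = cued, frozen_dof = frozen,
                   is_center = is_center),
              class = "target_set")
  }
  prev_center <- is.null(previous) || isTRUE(previous$is_center)
  kind <- task$kind
  if (kind == "cl2d") {
    if (prev_center) {
      centers <- vapply(seq_len(dof), function(i) draw_target(), 0)
      return(new_set(centers, names(groups), integer(0), FALSE))
    }
    return(new_set(center, names(groups), integer(0), TRUE))
  }
  n_new <- switch(kind, cl4d_two_new = 2L, cl4d_one_new = 1L,
                  cl4d_random = 2L, t_train = 2L)
  if (kind == "cl4d_random") {
    sel <- sample(names(groups), n_new)
    centers <- if (is.null(previous)) center else previous$centers
    for (g in sel) for (j in groups[[g]]) centers[j] <- draw_target()
    return(new_set(centers, sel, integer(0), FALSE))
  }
  if (kind == "t_train") {
    # alternation: a stationary all-center trial follows every moving trial
    stationary <- !is.null(previous) && !isTRUE(previous$stationary)
    if (!is.null(previous) && isTRUE(previous$stationary)) stationary <- FALSE
    if (is.null(previous)) stationary <- TRUE
    if (stationary) {
      ts <- new_set(center, character(0), seq_len(dof), TRUE)
      ts$stationary <- TRUE
      return(ts)
    }
    sel <- sample(names(groups), n_new)
    centers <- center
    for (g in sel) for (j in groups[[g]]) centers[j] <- draw_target()
    frozen <- unlist(groups[setdiff(names(groups), sel)], use.names = FALSE)
    ts <- new_set(centers, sel, as.integer(frozen), FALSE)
    ts$stationary <- FALSE
    return(ts)
  }
  # paired 4D variants
  if (prev_center) {
    sel <- sample(names(groups), n_new)
    centers <- center
    for (g in sel) for (j in groups[[g]]) centers[j] <- draw_target()
    new_set(centers, sel, integer(0), FALSE)
  } else {
    new_set(center, previous$cued_groups, integer(0), TRUE)
  }
}

.inside_target <- function(positions, target) {
  abs(positions - target$centers) <= target$width / 2
}

#' Advance one 50-ms bin of a closed-loop trial
#'
#' Integrates the decoded velocity into position (`u <- u + v * 0.05`,
#' clamped to `[0, 1]`; frozen DOF are pinned), and updates the
#' consecutive-hold counter: the trial succeeds once all DOF have been
#' inside their targets for `hold_required` of consecutive bins, and fails
#' when the clock exceeds `timeout`. Any exit from the target resets the
#' hold counter.
#'
#' @param state a [finger_state()].
#' @param decoded_velocity dof-vector (ROM-units/s).
#' @param target a `target_set` from [generate_targets()].
#' @param trial_clock time at the *end* of this bin (s).
#' @param hold_count consecutive inside-bins so far.
#' @return list `state`, `hold_count`, `inside` (all-DOF flag),
#'   `status` (`"running"`, `"success"` or `"timeout"`).
#' @export
step_trial <- function(state, decoded_velocity, target, trial_clock,
                       hold_count = 0L) {
  v <- as.numeric(decoded_velocity)
  if (length(target$frozen_dof)) v[target$frozen_dof] <- 0
  pos <- pmin(pmax(state$positions + v * BIN_S, 0), 1)
  state$positions <- pos
  state$velocities <- v
  inside <- all(.inside_target(pos, target))
  hold_count <- if (inside) hold_count + 1L else 0L
  hold_bins <- round(target$hold_required / BIN_S)
  status <- if (hold_count >= hold_bins) {
    "success"
  } else if (trial_clock >= target$timeout - 1e-9) {
    "timeout"
  } else "running"
  list(state = state, hold_count = hold_count, inside = inside,
       status = status)
}

#' Simulated user's intended direction
#'
#' The simulated user pushes each finger straight toward its target: the
#' intent is the error vector `centers - positions`, with components
#' zeroed for DOF already within `dead_zone` of their target (default:
#' inside the target, i.e. half the target width) and for frozen DOF, then
#' normalized to unit length. All DOF on target gives the zero vector, so
#' the intent norm is always 0 or 1.
#'
#' @param state a [finger_state()].
#' @param target a `target_set`.
#' @param dead_zone per-DOF dead zone (ROM units); default `width / 2`.
#' @return unit (or zero) dof-vector.
#' @export
simulated_user_intent <- function(state, target, dead_zone = NULL) {
  if (is.null(dead_zone)) dead_zone <- target$width / 2
  err <- target$centers - state$positions
  err[abs(err) <= dead_zone] <- 0
  if (length(target$frozen_dof)) err[target$frozen_dof] <- 0
  nrm <- sqrt(sum(err^2))
  if (nrm == 0) rep(0, length(err)) else err / nrm
}

#' Reference controllers for closed-loop simulation
#'
#' `oracle_controller()` returns the simulated user's intent scaled by a
#' constant speed -- a perfect decoder, useful as a sanity upper bound.
#' `null_controller()` always returns zero velocity.
#'
#' @param speed commanded speed (ROM-units/s).
#' @return a controller function of the per-bin context (see
#'   [run_closed_loop_session()]).
#' @export
oracle_controller <- function(speed = 0.6) {
  function(ctx) ctx$intent * speed
}

#' @rdname oracle_controller
#' @export
null_controller <- function() {
  function(ctx) rep(0, length(ctx$intent))
}

#' Run a closed-loop session against the synthetic population
#'
#' Simulates the full closed-loop pipeline, bin by bin at 50 ms: the
#' simulated user forms an intent toward the current targets, the
#' population emits SBP for the intended velocity, the controller (a
#' trained decoder or a plain function) maps the 3-bin SBP window to a
#' decoded velocity, and the virtual fingers integrate that velocity until
#' the trial succeeds or times out. Deterministic for a fixed seed.
#'
#' @param task a [task_config()].
#' @param controller either decoder parameters (class `finger_decoder`,
#'   decoded via [decode_velocity()]) or a function of a context list with
#'   elements `window` (`n_channels x 3`), `intent`, `state`, `target`.
#' @param model an [sbp_population][make_population]; its `dof` must match
#'   the task.
#' @param n_trials number of trials.
#' @param seed integer seed for the session stream.
#' @param gravity apply the quadcopter-style neutral-position bias to the
#'   fingers (off for finger-task blocks).
#' @param mapping a [control_mapping()] used only when `gravity = TRUE`.
#' @return list of `trial_record` objects; see [trial_metrics()].
#' @export
run_closed_loop_session <- function(task, controller, model, n_trials = 20,
                                    seed = 1L, gravity = FALSE,
                                    mapping = control_mapping()) {
  stopifnot(inherits(task, "task_config"), inherits(model, "sbp_population"))
  if (model$dof != task$dof) {
    stop(sprintf("model has %d DOF but task needs %d", model$dof, task$dof),
         call. = FALSE)
  }
  decode_fn <- if (inherits(controller, "finger_decoder")) {
    if (controller$config$n_channels != model$n_channels) {
      stop("decoder/population channel mismatch", call. = FALSE)
    }
    function(ctx) decode_velocity(controller, ctx$window)
  } else if (is.function(controller)) {
    controller
  } else stop("`controller` must be a decoder or a function", call. = FALSE)

  set.seed(as.integer(seed))
  dof <- task$dof
  state <- finger_state(dof)
  # seed the window buffer with resting-state bins
  buffer <- t(emit_sbp_series(model, matrix(0, 3, dof)))
  records <- vector("list", n_trials)
  target <- NULL
  session_clock <- 0
  max_bins <- round(task$timeout / BIN_S)
  hold_bins_fun <- function(tg) round(tg$hold_required / BIN_S)
  for (tr in seq_len(n_trials)) {
    target <- generate_targets(task, target)
    if (length(target$frozen_dof)) {
      state$positions[target$frozen_dof] <- target$centers[target$frozen_dof]
    }
    n_alloc <- max_bins
    pos_log <- matrix(NA_real_, n_alloc + 1L, dof)
    dec_log <- matrix(NA_real_, n_alloc, dof)
    int_log <- matrix(NA_real_, n_alloc, dof)
    sbp_log <- matrix(NA_real_, n_alloc, model$n_channels)
    pos_log[1L, ] <- state$positions
    hold <- 0L
    first_entry <- NA_real_
    status <- "running"
    k <- 0L
    while (status == "running" && k < max_bins) {
      k <- k + 1L
      intent <- simulated_user_intent(state, target)
      vel_int <- intent * task$user_speed
      if (task$motor_noise_sd > 0) {
        vel_int <- vel_int + stats::rnorm(dof, sd = task$motor_noise_sd)
      }
      if (length(target$frozen_dof)) vel_int[target$frozen_dof] <- 0
      sbp <- emit_sbp(model, vel_int)
      buffer <- cbind(buffer[, -1, drop = FALSE], sbp)
      ctx <- list(window = buffer, intent = intent, state = state,
                  target = target)
      v_dec <- as.numeric(decode_fn(ctx))
      if (gravity) {
        v_dec <- apply_neutral_gravity(state$positions, v_dec, mapping)
      }
      st <- step_trial(state, v_dec, target, k * BIN_S, hold)
      state <- st$state
      hold <- st$hold_count
      status <- st$status
      pos_log[k + 1L, ] <- state$positions
      dec_log[k, ] <- v_dec
      int_log[k, ] <- intent
      sbp_log[k, ] <- sbp
      if (is.na(first_entry) && st$inside) first_entry <- (k - 1L) * BIN_S
    }
    success <- status == "success"
    hb <- hold_bins_fun(target)
    completion <- if (success) k * BIN_S else NA_real_
    last_entry <- if (success) (k - hb) * BIN_S else NA_real_
    records[[tr]] <- structure(list(
      task_kind = task$kind,
      centers = target$centers,
      width = target$width,
      hold_required = target$hold_required,
      timeout = target$timeout,
      cued_groups = target$cued_groups,
      frozen_dof = target$frozen_dof,
      is_center = isTRUE(target$is_center),
      cue_time = session_clock,
      n_bins = k,
      positions = pos_log[seq_len(k + 1L), , drop = FALSE],
      decoded = dec_log[seq_len(k), , drop = FALSE],
      intents = int_log[seq_len(k), , drop = FALSE],
      sbp = sbp_log[seq_len(k), , drop = FALSE],
      success = success,
      first_entry_time = first_entry,
      last_entry_time = last_entry,
      completion_time = completion
    ), class = "trial_record")
    session_clock <- session_clock + k * BIN_S
    if (task$kind == "t_train") {
      state$positions <- rep(0.5, dof)  # end-of-trial snap to center
    }
  }
  records
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s %s, %d bins, cued: %s\n",
              x$task_kind, if (x$success) "success" else "timeout",
              x$n_bins, paste(x$cued_groups, collapse = "+")))
  invisible(x)
}
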