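#' Finger-to-quadcopter control mapping
#'
#' Gains and limits for mapping finger displacements to quadcopter
#' velocity commands. Defaults follow the empirically tuned values of the
#' 4-DOF paradigm: gains 0.6 (thumb flexion), 0.8 (thumb abduction), 0.4
#' (index--middle) and 0.6 (ring--little); commands capped at +/-10 m/s
#' linear and +/-90 deg/s yaw. The neutral-position "gravity" is a small
#' constant velocity bias pulling a finger back to neutral whenever it is
#' within `neutral_zone` (10% of the range of motion) of neutral, so the
#' quadcopter holds still when the user relaxes.
#'
#' @param gains named per-DOF gain vector.
#' @param max_linear_speed cap on each linear axis (m/s).
#' @param max_yaw_rate cap on yaw (deg/s).
#' @param neutral_zone half-width of the neutral band (ROM units, in
#'   `(0, 0.5)`).
#' @param gravity_amplitude bias magnitude (ROM-units/s). Must satisfy
#'   `gravity_amplitude * 0.05 < neutral_zone` so a single 50-ms step of
#'   pure gravity can never carry a finger across neutral.
#' @return object of class `control_mapping`.
#' @export
control_mapping <- function(gains = c(thumb_flex = 0.6, thumb_abd = 0.8,
                                      index_middle = 0.4,
                                      ring_little = 0.6),
                            max_linear_speed = 10, max_yaw_rate = 90,
                            neutral_zone = 0.10, gravity_amplitude = 0.05) {
  if (any(gains < 0)) stop("`gains` must be nonnegative", call. = FALSE)
  if (neutral_zone <= 0 || neutral_zone >= 0.5) {
    stop("`neutral_zone` must be in (0, 0.5)", call. = FALSE)
  }
  if (gravity_amplitude * BIN_S >= neutral_zone) {
    stop("`gravity_amplitude` * 50 ms must be smaller than `neutral_zone`",
         call. = FALSE)
  }
  structure(list(gains = gains, max_linear_speed = max_linear_speed,
                 max_yaw_rate = max_yaw_rate, neutral_zone = neutral_zone,
                 gravity_amplitude = gravity_amplitude),
            class = "control_mapping")
}

#' Neutral-position gravity on finger velocities
#'
#' Adds a constant bias of magnitude `gravity_amplitude` toward neutral
#' (`u = 0.5`) to each DOF whose position lies strictly inside the neutral
#' zone; fingers outside the zone, or exactly at neutral, are unchanged.
#' Within one 50-ms step of neutral the bias is capped at the value that
#' reaches neutral exactly, so pure gravity settles on the neutral point
#' rather than oscillating across it.
#'
#' @param position_u finger positions in `[0, 1]` (vector).
#' @param decoded_velocity decoded velocities (ROM-units/s).
#' @param mapping a [control_mapping()].
#' @return adjusted velocities.
#' @export
apply_neutral_gravity <- function(position_u, decoded_velocity, mapping) {
  off <- position_u - 0.5
  in_zone <- abs(off) < mapping$neutral_zone & off != 0
  bias <- pmin(mapping$gravity_amplitude, abs(off) / BIN_S)
  decoded_velocity - in_zone * sign(off) * bias
}

#' Map finger positions to a quadcopter velocity command
#'
#' The displacement `s = 2u - 1` of each DOF drives one command axis:
#' thumb flexion -> forward/backward, thumb abduction -> right/left,
#' index--middle -> up/down, ring--little -> yaw. Each axis is scaled by
#' its gain times the axis maximum and clamped to the maximum.
#'
#' @param state a 4-DOF [finger_state()] (or a length-4 position vector).
#' @param mapping a [control_mapping()].
#' @return named vector `(v_forward, v_right, v_up, yaw_rate)` in m/s and
#'   deg/s.
#' @export
fingers_to_command <- function(state, mapping = control_mapping()) {
  u <- if (inherits(state, "finger_state")) state$positions else state
  if (length(u) != 4) {
    stop("quadcopter control requires a 4-DOF finger state", call. = FALSE)
  }
  s <- to_display(u)
  g <- mapping$gains
  lin <- mapping$max_linear_speed
  cmd <- c(
    v_forward = g[[1]] * s[1] * lin,
    v_right = g[[2]] * s[2] * lin,
    v_up = g[[3]] * s[3] * lin,
    yaw_rate = g[[4]] * s[4] * mapping$max_yaw_rate
  )
  cmd[1:3] <- pmin(pmax(cmd[1:3], -lin), lin)
  cmd[4] <- min(max(cmd[4], -mapping$max_yaw_rate), mapping$max_yaw_rate)
  cmd
}

#' Quadcopter pose
#'
#' @param position 3-vector (m), world frame with `z` up.
#' @param yaw heading (deg), wrapped to `[0, 360)`; yaw 0 faces +x and
#'   positive yaw turns counterclockwise (toward +y).
#' @param clock elapsed time (s).
#' @return object of class `quad_pose`.
#' @export
quad_pose <- function(position = c(0, 0, 5), yaw = 0, clock = 0) {
  structure(list(position = as.numeric(position), yaw = yaw %% 360,
                 clock = clock),
            class = "quad_pose")
}

#' Integrate a velocity command over one time step
#'
#' First-order kinematics: the yaw rate updates the heading, the
#' body-frame forward/right components are rotated into the world frame
#' at the midpoint heading of the step (second-order accurate for
#' turning flight), and the position integrates the world-frame velocity;
#' the vertical component adds directly.
#'
#' @param pose a [quad_pose()].
#' @param command vector `(v_forward, v_right, v_up, yaw_rate)`.
#' @param dt time step (s, default 0.05).
#' @return updated `quad_pose`.
#' @export
step_quadcopter <- function(pose, command, dt = BIN_S) {
  stopifnot(all(is.finite(command)))
  yaw <- (pose$yaw + command[4] * dt) %% 360
  th <- (pose$yaw + command[4] * dt / 2) * pi / 180
  fwd <- c(cos(th), sin(th), 0)
  rgt <- c(sin(th), -cos(th), 0)
  vel <- command[1] * fwd + command[2] * rgt + c(0, 0, command[3])
  quad_pose(pose$position + vel * dt, yaw, pose$clock + dt)
}

#' Define a ring
#'
#' @param center 3-vector (m).
#' @param normal plane normal; normalized internally.
#' @param radius ring radius (m, > 0).
#' @return object of class `ring`.
#' @export
ring <- function(center, normal = c(1, 0, 0), radius = 2.5) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("`normal` must be nonzero", call. = FALSE)
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), normal = normal / nrm,
                 radius = radius),
            class = "ring")
}

#' Did a movement segment cross a ring?
#'
#' `TRUE` iff the segment from the first pose's position to the second's
#' crosses the ring's plane with the intersection point within `radius`
#' of the center. The crossing direction (sign of the motion along the
#' ring normal) is attached as attribute `"direction"`. Zero-length or
#' plane-parallel segments never cross.
#'
#' @param pose_before,pose_after consecutive [quad_pose()]s (or bare
#'   position vectors).
#' @param rg a [ring()].
#' @return logical scalar with attribute `direction`.
#' @export
ring_crossing <- function(pose_before, pose_after, rg) {
  p0 <- if (inherits(pose_before, "quad_pose")) pose_before$position else pose_before
  p1 <- if (inherits(pose_after, "quad_pose")) pose_after$position else pose_after
  d <- p1 - p0
  denom <- sum(rg$normal * d)
  if (abs(denom) < 1e-12) return(structure(FALSE, direction = 0))
  t <- sum(rg$normal * (rg$center - p0)) / denom
  if (t < 0 || t > 1) return(structure(FALSE, direction = 0))
  pt <- p0 + t * d
  hit <- sqrt(sum((pt - rg$center)^2)) <= rg$radius
  structure(hit, direction = if (hit) sign(denom) else 0)
}

#' Course specifications
#'
#' `obstacle_course()` builds the fixed two-ring course on a virtual
#' basketball court: rings of radius `radius` placed along the court's
#' long axis, flown through in order (one pass through both rings is one
#' lap). `random_ring_course()` is a seeded generator of single random
#' rings (uniform position inside a box, random horizontal-ish
#' orientation) with a per-ring timeout.
#'
#' @param radius ring radius (m).
#' @param spacing distance between the two rings (m).
#' @param height ring center height (m).
#' @return a course specification list for [run_course()].
#' @export
obstacle_course <- function(radius = 2.5, spacing = 20, height = 5) {
  list(type = "obstacle",
       rings = list(ring(c(spacing / 2, 0, height), c(1, 0, 0), radius),
                    ring(c(-spacing / 2, 0, height), c(1, 0, 0), radius)))
}

#' @rdname obstacle_course
#' @param box half-widths of the spawn box `(x, y)` (m); heights are drawn
#'   in `[2, 12]` m.
#' @param ring_timeout seconds allowed per ring before it is respawned.
#' @export
random_ring_course <- function(radius = 2.5, box = c(20, 20),
                               ring_timeout = 20) {
  list(type = "random_rings", radius = radius, box = box,
       ring_timeout = ring_timeout)
}

.spawn_random_ring <- function(course) {
  ctr <- c(stats::runif(1, -course$box[1], course$box[1]),
           stats::runif(1, -course$box[2], course$box[2]),
           stats::runif(1, 2, 12))
  az <- stats::runif(1, 0, 2 * pi)
  el <- stats::runif(1, -pi / 6, pi / 6)
  nrm <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  ring(ctr, nrm, course$radius)
}

#' Fly a quadcopter course under finger control
#'
#' Steps the control loop at 50 ms: the controller supplies finger
#' positions given the current pose and active ring, [fingers_to_command()]
#' maps them to a velocity command, and the pose integrates it. Ring
#' crossings advance the course (obstacle: next ring in sequence, wrapping
#' into a new lap; random rings: a new random ring). In random-ring mode a
#' ring that survives `ring_timeout` seconds is respawned and the timeout
#' logged.
#'
#' @param course a course spec from [obstacle_course()] or
#'   [random_ring_course()].
#' @param controller function `(pose, ring, t)` returning 4 finger
#'   positions in `[0, 1]`.
#' @param mapping a [control_mapping()].
#' @param max_time session length (s).
#' @param seed seed for random-ring generation.
#' @param start_pose initial [quad_pose()].
#' @return list of class `flight_log`: `poses` (matrix with columns x, y,
#'   z, yaw, t), `events` (data.frame of ring crossings and timeouts),
#'   `summary` (rings crossed, rings/min, lap times for the obstacle
#'   course).
#' @export
run_course <- function(course, controller, mapping = control_mapping(),
                       max_time = 60, seed = 1L,
                       start_pose = quad_pose()) {
  set.seed(as.integer(seed))
  n_steps <- round(max_time / BIN_S)
  pose <- start_pose
  poses <- matrix(NA_real_, n_steps + 1L, 5,
                  dimnames = list(NULL, c("x", "y", "z", "yaw", "t")))
  poses[1L, ] <- c(pose$position, pose$yaw, pose$clock)
  events <- list()
  ring_idx <- 1L
  current <- if (course$type == "obstacle") {
    course$rings[[1L]]
  } else .spawn_random_ring(course)
  ring_clock <- 0
  crossings <- 0L
  lap_times <- numeric(0)
  lap_start <- 0
  for (k in seq_len(n_steps)) {
    u <- controller(pose, current, pose$clock)
    u <- pmin(pmax(as.numeric(u), 0), 1)
    cmd <- fingers_to_command(u, mapping)
    new_pose <- step_quadcopter(pose, cmd)
    ring_clock <- ring_clock + BIN_S
    cr <- ring_crossing(pose, new_pose, current)
    if (isTRUE(cr[1])) {
      crossings <- crossings + 1L
      events[[length(events) + 1L]] <-
        data.frame(t = new_pose$clock, event = "crossing",
                   ring = ring_idx, direction = attr(cr, "direction"))
      if (course$type == "obstacle") {
        nxt <- ring_idx %% length(course$rings) + 1L
        if (nxt == 1L) {        # completed a pass through all rings
          lap_times <- c(lap_times, new_pose$clock - lap_start)
          lap_start <- new_pose$clock
        }
        ring_idx <- nxt
        current <- course$rings[[ring_idx]]
      } else {
        ring_idx <- ring_idx + 1L
        current <- .spawn_random_ring(course)
      }
      ring_clock <- 0
    } else if (course$type == "random_rings" &&
               ring_clock >= course$ring_timeout - 1e-9) {
      events[[length(events) + 1L]] <-
        data.frame(t = new_pose$clock, event = "timeout",
                   ring = ring_idx, direction = 0)
      ring_idx <- ring_idx + 1L
      current <- .spawn_random_ring(course)
      ring_clock <- 0
    }
    pose <- new_pose
    poses[k + 1L, ] <- c(pose$position, pose$yaw, pose$clock)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(t = numeric(0), event = character(0), ring = integer(0),
               direction = numeric(0))
  structure(list(
    poses = poses,
    events = events,
    summary = list(rings_crossed = crossings,
                   rings_per_min = crossings / (max_time / 60),
                   lap_times = lap_times,
                   timeouts = sum(events$event == "timeout"))
  ), class = "flight_log")
}

#' @export
print.flight_log <- function(x, ...) {
  cat(sprintf("<flight_log> %d rings crossed (%.2f rings/min), %d timeouts\n",
              x$summary$rings_crossed, x$summary$rings_per_min,
              x$summary$timeouts))
  invisible(x)
}
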