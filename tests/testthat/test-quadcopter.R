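test_that("neutral gravity biases toward neutral only inside the zone", {
  m <- control_mapping()
  expect_equal(apply_neutral_gravity(0.56, 0, m), -m$gravity_amplitude)
  expect_equal(apply_neutral_gravity(0.44, 0, m), m$gravity_amplitude)
  expect_equal(apply_neutral_gravity(0.80, 0.3, m), 0.3)
  expect_equal(apply_neutral_gravity(0.5, 0.12, m), 0.12)

  # a pure-gravity 50-ms step never crosses neutral (enforced at config)
  expect_error(control_mapping(gravity_amplitude = 3), "gravity_amplitude")
  u <- seq(0.401, 0.599, by = 0.001)
  v <- apply_neutral_gravity(u, 0, m)
  u2 <- u + v * 0.05
  expect_true(all(sign(u2 - 0.5) == sign(u - 0.5) | u2 == 0.5 | u == 0.5))
})

test_that("finger displacements map to the printed command gains", {
  m <- control_mapping()
  # full thumb flexion: 0.6 x 10 m/s forward
  expect_equal(unname(fingers_to_command(c(1, 0.5, 0.5, 0.5), m)),
               c(6, 0, 0, 0))
  # full ring-little flexion: 0.6 x 90 deg/s yaw, no translation
  expect_equal(unname(fingers_to_command(c(0.5, 0.5, 0.5, 1), m)),
               c(0, 0, 0, 54))
  expect_equal(unname(fingers_to_command(rep(0.5, 4), m)), rep(0, 4))

  # odd symmetry and caps
  set.seed(4)
  for (i in 1:50) {
    u <- runif(4)
    a <- fingers_to_command(u, m)
    b <- fingers_to_command(1 - u, m)
    expect_equal(unname(a), -unname(b), tolerance = 1e-12)
    expect_true(all(abs(a[1:3]) <= 10) && abs(a[4]) <= 90)
  }
  expect_error(fingers_to_command(c(0.5, 0.5), m), "4-DOF")
})

test_that("kinematic integration matches closed-form motions", {
  p <- quad_pose(c(0, 0, 5), yaw = 0)
  for (k in 1:60) p <- step_quadcopter(p, c(2, 0, 0, 0))
  expect_equal(p$position, c(6, 0, 5), tolerance = 1e-9)
  expect_equal(p$yaw, 0)

  p <- quad_pose()
  for (k in 1:40) p <- step_quadcopter(p, c(0, 0, 0, 90))
  expect_equal(p$yaw, 180)
  expect_equal(p$position, quad_pose()$position, tolerance = 1e-9)

  # quarter arc: forward 1 m/s with 90 deg/s for 1 s; compare with a
  # fine-step (1 ms) integration of the same kinematics
  coarse <- quad_pose(c(0, 0, 0))
  for (k in 1:20) coarse <- step_quadcopter(coarse, c(1, 0, 0, 90))
  fine <- quad_pose(c(0, 0, 0))
  for (k in 1:1000) fine <- step_quadcopter(fine, c(1, 0, 0, 90), dt = 1e-3)
  r <- 1 / (pi / 2)  # v / omega
  expect_lt(sqrt(sum((coarse$position - fine$position)^2)), 0.02 * r)
})

test_that("ring crossing agrees with a dense-sampling oracle", {
  rg <- ring(c(5, 0, 5), c(1, 0, 0), 2)
  expect_true(as.logical(ring_crossing(c(0, 0, 5), c(10, 0, 5), rg)))
  expect_false(as.logical(ring_crossing(c(0, 4.5, 5), c(10, 4.5, 5), rg)))
  expect_false(as.logical(ring_crossing(c(0, 0, 5), c(0.1, 0, 5), rg)))
  expect_false(as.logical(ring_crossing(c(1, 0, 5), c(1, 0, 5), rg)))

  # randomized agreement with 1-mm sampling of the segment: a crossing is
  # a sign change of the plane coordinate with the switch point in-disc
  dense_oracle <- function(p0, p1, rg) {
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / 0.001))
    tt <- seq(0, 1, length.out = n)
    pts <- outer(tt, p1 - p0) + rep(p0, each = n)
    side <- (pts - rep(rg$center, each = n)) %*% rg$normal
    flips <- which(diff(sign(side)) != 0 | side[-n] == 0)
    for (j in flips) {
      if (sqrt(sum((pts[j, ] - rg$center)^2)) <= rg$radius + 0.002) {
        return(TRUE)
      }
    }
    FALSE
  }
  set.seed(17)
  mismatches <- 0L
  for (i in 1:1000) {
    p0 <- runif(3, -4, 4) + rg$center
    p1 <- runif(3, -4, 4) + rg$center
    got <- as.logical(ring_crossing(p0, p1, rg))
    want <- dense_oracle(p0, p1, rg)
    # the oracle's 1-mm grid is ambiguous within 2 mm of the rim; skip
    # those boundary cases
    tval <- sum(rg$normal * (rg$center - p0)) / sum(rg$normal * (p1 - p0))
    near_rim <- is.finite(tval) && tval >= 0 && tval <= 1 &&
      abs(sqrt(sum((p0 + tval * (p1 - p0) - rg$center)^2)) - rg$radius) < 0.005
    if (!near_rim && got != want) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("course runs log crossings, timeouts and are reproducible", {
  m <- control_mapping()
  # scripted straight flight through the ring directly ahead: exactly one
  # crossing (the second course ring lies behind the flight path)
  straight <- function(pose, rg, t) c(1, 0.5, 0.5, 0.5)
  fl <- run_course(obstacle_course(), straight, m, max_time = 20, seed = 1)
  expect_equal(fl$summary$rings_crossed, 1L)
  expect_equal(sum(fl$events$event == "crossing"), 1L)

  # null controller in random-ring mode: no rings, a timeout every 20 s
  hover <- function(pose, rg, t) rep(0.5, 4)
  fl0 <- run_course(random_ring_course(), hover, m, max_time = 60, seed = 2)
  expect_equal(fl0$summary$rings_crossed, 0L)
  expect_equal(fl0$summary$timeouts, 3L)
  expect_equal(fl0$events$t, c(20, 40, 60), tolerance = 1e-9)

  a <- run_course(random_ring_course(), hover, m, max_time = 30, seed = 7)
  b <- run_course(random_ring_course(), hover, m, max_time = 30, seed = 7)
  expect_identical(a, b)
})
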