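test_that("forward kinematics matches closed-form poses", {
  arm <- arm_model(L1 = 1, L2 = 1, L3 = 1, L4 = 1)
  fk <- function(...) forward_kinematics(
    tibble::tibble(theta1 = ..1, theta2 = ..2, theta3 = ..3, theta4 = ..4),
    arm)
  p0 <- fk(0, 0, 0, 0)
  expect_equal(as.numeric(p0[1, c("x", "y", "z")]), c(2, 0, 2))
  p1 <- fk(0, pi / 2, 0, 0)
  expect_equal(as.numeric(p1[1, c("x", "y", "z")]), c(3, 0, 1))
  p2 <- fk(pi / 2, 0, 0, 0)
  expect_equal(as.numeric(p2[1, c("x", "y", "z")]), c(0, 2, 2))
  expect_equal(fk(0.3, 0, 0, 0.2)$yaw, 0.5)
  expect_error(fk(Inf, 0, 0, 0), "finite")
})

test_that("inverse kinematics inverts forward kinematics on 1000 poses", {
  arm <- arm_model()
  joints <- random_elbow_up_joints(1000, seed = 42)
  pose <- forward_kinematics(joints, arm)
  back <- suppressWarnings(inverse_kinematics(pose, arm))
  expect_lt(max(abs(as.matrix(back) - as.matrix(joints))), 1e-9)
  pose2 <- forward_kinematics(back, arm)
  expect_lt(max(abs(as.matrix(pose2) - as.matrix(pose))), 1e-9)
})

test_that("inverse kinematics solves the unit-arm zero pose and yaw split", {
  arm <- arm_model(L1 = 1, L2 = 1, L3 = 1, L4 = 1)
  j <- inverse_kinematics(tibble::tibble(x = 2, y = 0, z = 2, yaw = 0), arm)
  expect_equal(as.numeric(j), c(0, 0, 0, 0), tolerance = 1e-12)
  # theta4 carries whatever yaw the base rotation does not
  j2 <- suppressWarnings(
    inverse_kinematics(tibble::tibble(x = 0, y = 2, z = 2, yaw = 0.25), arm))
  expect_equal(j2$theta1, pi / 2)
  expect_equal(j2$theta4, 0.25 - pi / 2)
})

test_that("unreachable targets raise errors naming the violated bound", {
  arm <- arm_model(L1 = 1, L2 = 1, L3 = 1, L4 = 1)
  far <- tibble::tibble(x = 1 + 1 + 1 + 1, y = 0, z = 1)  # rho = 3 > L2 + L3
  expect_error(inverse_kinematics(far, arm), "exceeds L2 \\+ L3")
  inner <- arm_model(L1 = 1, L2 = 2, L3 = 0.5, L4 = 0.1)
  near <- tibble::tibble(x = 0.1 + 0.2, y = 0, z = 1)     # rho < |L2 - L3|
  expect_error(inverse_kinematics(near, inner), "inside \\|L2 - L3\\|")
})

test_that("joint limits warn but do not block the solution", {
  arm <- arm_model()
  # a pose requiring theta2 beyond 85 deg: far and low
  pose <- forward_kinematics(
    tibble::tibble(theta1 = 0, theta2 = 88 * pi / 180, theta3 = 0, theta4 = 0),
    arm)
  expect_warning(inverse_kinematics(pose, arm), "joint limit")
})

test_that("elbow-down branch is the mirror solution", {
  arm <- arm_model()
  pose <- tibble::tibble(x = 250, y = 40, z = 60, yaw = 0)
  up <- suppressWarnings(inverse_kinematics(pose, arm, elbow = "up"))
  dn <- suppressWarnings(inverse_kinematics(pose, arm, elbow = "down"))
  expect_false(isTRUE(all.equal(up$theta2, dn$theta2)))
  for (j in list(up, dn)) {
    p <- forward_kinematics(j, arm)
    expect_equal(as.numeric(p[1, c("x", "y", "z")]),
                 as.numeric(pose[1, c("x", "y", "z")]), tolerance = 1e-9)
  }
})

test_that("cartesian chord execution samples segments evenly", {
  arm <- arm_model()
  wp <- tibble::tibble(x = c(240, 250), y = 0, z = 50)
  ex <- execute_path(wp, arm, mode = "cartesian_chord",
                     samples_per_segment = 5)
  expect_equal(nrow(ex), 6)
  expect_equal(diff(ex$x), rep(2, 5))
  expect_true(all(ex$y == 0 & ex$z == 50))
})

test_that("joint-linear execution shares waypoints with the chord model", {
  arm <- arm_model()
  wp <- circle_waypoints(6, D = 20, center = c(250, 0, 50))
  jl <- execute_path(wp, arm, mode = "joint_linear", samples_per_segment = 10)
  cc <- execute_path(wp, arm, mode = "cartesian_chord",
                     samples_per_segment = 10)
  # segment endpoints coincide across modes (IK/FK round trip at waypoints)
  ends <- c(1, which(diff(jl$segment) != 0) + 0, nrow(jl))
  for (i in seq_len(nrow(wp))) {
    k <- 1 + (i - 1) * 10
    expect_equal(as.numeric(jl[k, c("x", "y", "z")]),
                 as.numeric(cc[k, c("x", "y", "z")]), tolerance = 1e-9)
  }
  # identical consecutive waypoints execute as a stationary segment
  still <- tibble::tibble(x = c(250, 250), y = c(0, 0), z = c(50, 50))
  exs <- execute_path(still, arm, mode = "joint_linear",
                      samples_per_segment = 4)
  expect_true(all(abs(exs$x - 250) < 1e-9))
  expect_true(all(abs(exs$z - 50) < 1e-9))
  # unreachable waypoint errors
  bad <- tibble::tibble(x = c(250, 900), y = 0, z = 50)
  expect_error(execute_path(bad, arm, mode = "joint_linear"),
               "unreachable")
})

test_that("joint-linear deviation from the chord shrinks with waypoint count", {
  arm <- arm_model()
  dev_for <- function(N) {
    wp <- circle_waypoints(N, D = 20, center = c(250, 0, 50))
    wp <- dplyr::bind_rows(wp, wp[1, ])
    jl <- execute_path(wp, arm, mode = "joint_linear",
                       samples_per_segment = 50)
    cc <- execute_path(wp, arm, mode = "cartesian_chord",
                       samples_per_segment = 50)
    max(sqrt((jl$x - cc$x)^2 + (jl$y - cc$y)^2 + (jl$z - cc$z)^2))
  }
  devs <- vapply(c(5, 10, 20, 30), dev_for, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[4], devs[1] / 10)
})
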