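#' 4-DOF articulated-arm model
#'
#' Kinematic model of a four-joint desktop arm of the DOBOT MG400 class: a
#' base yaw joint, a parallelogram-constrained shoulder/elbow pair that keeps
#' the tool axis vertical at all times, and a tool-yaw wrist. Link lengths
#' L1–L4 (mm) are the base column height, upper arm, forearm and the
#' horizontal tool offset. Because of the parallelogram constraint the
#' forward map is
#'
#'   r = L2 sin(t2) + L3 cos(t3) + L4,
#'   x = r cos(t1),  y = r sin(t1),
#'   z = L1 + L2 cos(t2) - L3 sin(t3),  yaw = t1 + t4,
#'
#' with t2 the shoulder angle from vertical and t3 the forearm angle from
#' horizontal. This matches a nozzle held perpendicular to the build plate.
#'
#' @param L1,L2,L3,L4 link lengths (mm), all positive. Defaults follow the
#'   published MG400-class geometry (base 140, arm 175, forearm 175, tool
#'   offset 66 mm); results of the circular benchmark in chord mode are
#'   independent of these values.
#' @param joint_limits 4x2 matrix of per-joint `[min, max]` limits (rad).
#'   Limits are checked and reported with a warning, not enforced as errors:
#'   paths are expected to stay in the verified central workspace.
#' @param repeatability_eps positional repeatability of the device (mm);
#'   0.05 mm for the MG400. The accuracy floor against which discretization
#'   error is judged.
#' @return An object of class `arm_model`.
#' @export
#' @examples
#' arm <- arm_model(L1 = 1, L2 = 1, L3 = 1, L4 = 1)
#' forward_kinematics(tibble::tibble(theta1 = 0, theta2 = 0,
#'                                   theta3 = 0, theta4 = 0), arm)
arm_model <- function(L1 = 140, L2 = 175, L3 = 175, L4 = 66,
                      joint_limits = default_joint_limits(),
                      repeatability_eps = 0.05) {
  L <- c(L1, L2, L3, L4)
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("all link lengths must be positive and finite", call. = FALSE)
  }
  joint_limits <- as.matrix(joint_limits)
  stopifnot(nrow(joint_limits) == 4, ncol(joint_limits) == 2,
            all(joint_limits[, 1] < joint_limits[, 2]))
  structure(list(L1 = L1, L2 = L2, L3 = L3, L4 = L4,
                 joint_limits = joint_limits,
                 repeatability_eps = repeatability_eps),
            class = "arm_model")
}

# MG400-class working ranges (rad): base +-160 deg, shoulder -25..85 deg,
# forearm -25..105 deg, wrist +-360 deg.
default_joint_limits <- function() {
  rbind(c(-160, 160), c(-25, 85), c(-25, 105), c(-360, 360)) * pi / 180
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("<arm_model> L1-L4 = %.1f / %.1f / %.1f / %.1f mm, eps = %.3f mm\n",
              x$L1, x$L2, x$L3, x$L4, x$repeatability_eps))
  invisible(x)
}

#' Forward kinematics: joint angles to end-effector pose
#'
#' Vectorised over rows: each row of `joints` is one joint state.
#'
#' @param joints data frame with columns `theta1`..`theta4` (rad).
#' @param arm an [arm_model()].
#' @return A tibble with columns `x`, `y`, `z` (mm) and `yaw` (rad).
#' @export
forward_kinematics <- function(joints, arm) {
  stopifnot(inherits(arm, "arm_model"),
            all(c("theta1", "theta2", "theta3", "theta4") %in% names(joints)))
  t1 <- joints$theta1; t2 <- joints$theta2
  t3 <- joints$theta3; t4 <- joints$theta4
  if (any(!is.finite(c(t1, t2, t3, t4)))) {
    stop("joint angles must be finite", call. = FALSE)
  }
  r <- arm$L2 * sin(t2) + arm$L3 * cos(t3) + arm$L4
  tibble::tibble(
    x = r * cos(t1),
    y = r * sin(t1),
    z = arm$L1 + arm$L2 * cos(t2) - arm$L3 * sin(t3),
    yaw = t1 + t4
  )
}

#' Inverse kinematics: end-effector pose to joint angles (elbow-up)
#'
#' Analytic inverse of [forward_kinematics()] on the elbow-up branch, the
#' device's working posture (`elbow = "down"` selects the mirror branch).
#' Vectorised over rows. Poses outside the reachable annulus — the planar
#' distance `sqrt(r^2 + h^2)` from the shoulder, with `r = sqrt(x^2 + y^2) -
#' L4` and `h = z - L1`, must lie in `[|L2 - L3|, L2 + L3]` — raise an error
#' naming the violated bound. Solutions outside the joint limits produce a
#' warning, not an error.
#'
#' @param pose data frame with columns `x`, `y`, `z` (mm) and optionally
#'   `yaw` (rad, default 0).
#' @param arm an [arm_model()].
#' @param elbow `"up"` (default) or `"down"` branch.
#' @return A tibble with columns `theta1`..`theta4` (rad).
#' @export
inverse_kinematics <- function(pose, arm, elbow = c("up", "down")) {
  elbow <- match.arg(elbow)
  stopifnot(inherits(arm, "arm_model"),
            all(c("x", "y", "z") %in% names(pose)))
  yaw <- if ("yaw" %in% names(pose)) pose$yaw else rep(0, nrow(pose))
  t1 <- atan2(pose$y, pose$x)
  r <- sqrt(pose$x^2 + pose$y^2) - arm$L4
  h <- pose$z - arm$L1
  rho <- sqrt(r^2 + h^2)
  tol <- 1e-9
  too_far <- rho > arm$L2 + arm$L3 + tol
  too_close <- rho < abs(arm$L2 - arm$L3) - tol
  if (any(too_far)) {
    i <- which(too_far)[1]
    stop(sprintf(
      "pose %d unreachable: planar distance %.4f mm exceeds L2 + L3 = %.4f mm",
      i, rho[i], arm$L2 + arm$L3), call. = FALSE)
  }
  if (any(too_close)) {
    i <- which(too_close)[1]
    stop(sprintf(
      "pose %d unreachable: planar distance %.4f mm is inside |L2 - L3| = %.4f mm",
      i, rho[i], abs(arm$L2 - arm$L3)), call. = FALSE)
  }
  # Two-link problem in the (r, h) plane with angles measured from vertical:
  # u2 = t2, u3 = t3 + pi/2; r = L2 sin u2 + L3 sin u3, h = L2 cos u2 + L3 cos u3.
  cg <- (rho^2 - arm$L2^2 - arm$L3^2) / (2 * arm$L2 * arm$L3)
  cg <- pmin(1, pmax(-1, cg))
  gamma <- acos(cg)                               # inter-link bend in [0, pi]
  if (elbow == "down") gamma <- -gamma
  u2 <- atan2(r, h) - atan2(arm$L3 * sin(gamma), arm$L2 + arm$L3 * cos(gamma))
  t2 <- u2
  t3 <- (u2 + gamma) - pi / 2
  out <- tibble::tibble(theta1 = t1, theta2 = t2, theta3 = t3,
                        yaw = yaw)
  out$theta4 <- out$yaw - out$theta1
  out <- out[, c("theta1", "theta2", "theta3", "theta4")]
  check_joint_limits(out, arm)
  out
}

check_joint_limits <- function(joints, arm) {
  m <- as.matrix(joints[, c("theta1", "theta2", "theta3", "theta4")])
  lim <- arm$joint_limits
  bad <- sweep(m, 2, lim[, 1], "<") | sweep(m, 2, lim[, 2], ">")
  if (any(bad)) {
    j <- which(colSums(bad) > 0)
    warning("joint limit exceeded for joint(s) ",
            paste(j, collapse = ", "),
            " (reported, not enforced)", call. = FALSE)
  }
  invisible(!any(bad))
}

#' Execute a waypoint path with the arm model
#'
#' Turns a sparse waypoint list into the densely sampled trajectory the
#' end-effector actually traces, under ideal actuation (no backlash or
#' compliance). Two interpolation models:
#'
#' * `cartesian_chord` — the end-effector moves on the straight chord
#'   between consecutive waypoints; each chord is sampled at `M + 1` evenly
#'   spaced points. This is pure geometry, independent of the arm.
#' * `joint_linear` — inverse kinematics at each waypoint, linear
#'   interpolation of the four joint angles in `M` steps, forward
#'   kinematics back to Cartesian samples. The executed curve bulges away
#'   from the chord by an amount that vanishes as waypoint spacing shrinks.
#'
#' Waypoints themselves are always included; endpoints shared by
#' consecutive chords are emitted once.
#'
#' @param waypoints data frame with columns `x`, `y`, `z` (mm).
#' @param arm an [arm_model()].
#' @param mode `"cartesian_chord"` or `"joint_linear"`.
#' @param samples_per_segment M, samples per chord (>= 1).
#' @return A tibble of executed points `x`, `y`, `z` with a `segment`
#'   column identifying the source chord.
#' @export
execute_path <- function(waypoints, arm,
                         mode = c("cartesian_chord", "joint_linear"),
                         samples_per_segment = 200L) {
  mode <- match.arg(mode)
  M <- as.integer(samples_per_segment)
  stopifnot(M >= 1L, nrow(waypoints) >= 2L,
            all(c("x", "y", "z") %in% names(waypoints)))
  p <- as.matrix(waypoints[, c("x", "y", "z")])
  n_seg <- nrow(p) - 1L
  if (mode == "joint_linear") {
    joints <- tryCatch(
      inverse_kinematics(waypoints, arm),
      error = function(e) stop("waypoint unreachable: ", conditionMessage(e),
                               call. = FALSE))
    jm <- as.matrix(joints)
  }
  out <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    t <- seq(0, 1, length.out = M + 1L)
    if (s > 1L) t <- t[-1]                        # shared endpoint once
    if (mode == "cartesian_chord") {
      seg <- outer(1 - t, p[s, ]) + outer(t, p[s + 1L, ])
      out[[s]] <- tibble::tibble(segment = s, x = seg[, 1], y = seg[, 2],
                                 z = seg[, 3])
    } else {
      ji <- outer(1 - t, jm[s, ]) + outer(t, jm[s + 1L, ])
      colnames(ji) <- colnames(jm)
      fk <- forward_kinematics(tibble::as_tibble(ji), arm)
      out[[s]] <- tibble::tibble(segment = s, x = fk$x, y = fk$y, z = fk$z)
    }
  }
  dplyr::bind_rows(out)
}
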