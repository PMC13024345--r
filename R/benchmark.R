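#' Spatial step and discretization density of a circular trajectory
#'
#' A circle of diameter `D` traversed with `N` uniformly spaced waypoints
#' has arc length `pi * D / N` between consecutive waypoints: the spatial
#' sampling step S. Its reciprocal per unit arc, `N / (pi * D)`, is the
#' discretization density. S is the quantity tabulated against trajectory
#' accuracy (S = 2.09 mm at N = 30 on the 20 mm reference circle).
#'
#' @param N number of waypoints (>= 1).
#' @param D circle diameter (mm).
#' @return `spatial_step()`: S in mm, with `S * N = pi * D` exactly.
#'   `discretization_density()`: waypoints per mm of arc.
#' @export
#' @examples
#' spatial_step(30, 20)   # 2.094 mm, the benchmark-optimal step
spatial_step <- function(N, D = 20) {
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  stopifnot(D > 0)
  pi * D / N
}

#' @rdname spatial_step
#' @export
discretization_density <- function(N, D = 20) {
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  stopifnot(D > 0)
  N / (pi * D)
}

#' Waypoints of the circular reference trajectory
#'
#' `N` points at angles `2*pi*k/N`, `k = 0..N-1`, radius `D/2` about
#' `center`, in the horizontal plane through `center`. The trajectory is
#' executed as a closed cycle (the chord from the last waypoint back to the
#' first is included).
#'
#' @param N waypoint count (>= 3).
#' @param D circle diameter (mm).
#' @param center length-3 circle centre (mm).
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
circle_waypoints <- function(N, D = 20, center = c(250, 0, 50)) {
  stopifnot(N >= 3, D > 0, length(center) == 3)
  ang <- 2 * pi * (seq_len(N) - 1L) / N
  tibble::tibble(x = center[1] + D / 2 * cos(ang),
                 y = center[2] + D / 2 * sin(ang),
                 z = center[3])
}

#' Run the circular discretization benchmark
#'
#' The accuracy study behind the choice of spatial step: place `N` waypoints
#' on a circle of diameter `D`, execute the closed trajectory with the arm
#' model (chord interpolation by default: the executed path is the inscribed
#' polygon, sampled densely and uniformly), and measure the radial distance
#' of every executed sample from the centre. The sampled radii fall short of
#' the ideal `D/2` between waypoints — the chord sags toward the centre —
#' and their spread shrinks as `N` grows; the benchmark quantifies both as
#' the mean radius and the sample standard deviation of the radii about
#' their mean (the deviation statistic reported per discretization). RMS
#' deviation from the ideal radius is computed alongside.
#'
#' @param arm an [arm_model()]; chord-mode statistics are independent of it.
#' @param N waypoint count.
#' @param D circle diameter (mm, default 20).
#' @param center circle centre; the default sits in the arm's central
#'   workspace.
#' @param mode interpolation model, see [execute_path()].
#' @param M samples per chord (default 200: dense uniform sampling).
#' @return A `circle_benchmark` object: list with `samples` (executed points
#'   with their radii), `stats` (one-row tibble: `N`, `S_mm`, `mean_radius`,
#'   `std_radius`, `rms_dev`, `n_samples`) and the configuration. Use
#'   [glance.circle_benchmark()] / [tidy.circle_benchmark()] to extract
#'   tables.
#' @export
#' @examples
#' bench <- run_circle_benchmark(arm_model(), N = 30)
#' glance(bench)
run_circle_benchmark <- function(arm, N, D = 20, center = c(250, 0, 50),
                                 mode = c("cartesian_chord", "joint_linear"),
                                 M = 200L) {
  mode <- match.arg(mode)
  stopifnot(inherits(arm, "arm_model"))
  wp <- circle_waypoints(N, D, center)
  wp_closed <- dplyr::bind_rows(wp, wp[1, ])      # closed cycle
  ex <- execute_path(wp_closed, arm, mode = mode, samples_per_segment = M)
  # drop the duplicated seam point (waypoint 0 appears as both start and end)
  ex <- ex[-nrow(ex), ]
  radii <- sqrt((ex$x - center[1])^2 + (ex$y - center[2])^2 +
                  (ex$z - center[3])^2)
  ex$radius <- radii
  stats <- tibble::tibble(
    N = as.integer(N),
    S_mm = spatial_step(N, D),
    mean_radius = mean(radii),
    std_radius = stats::sd(radii),
    rms_dev = sqrt(mean((radii - D / 2)^2)),
    n_samples = length(radii)
  )
  structure(list(samples = ex, stats = stats,
                 config = list(N = N, D = D, center = center, mode = mode,
                               M = M, eps = arm$repeatability_eps)),
            class = "circle_benchmark")
}

#' @export
print.circle_benchmark <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<circle_benchmark> N = %d, D = %g mm, %s: S = %.3f mm, mean radius = %.4f mm, sd = %.4f mm\n",
    s$N, x$config$D, x$config$mode, s$S_mm, s$mean_radius, s$std_radius))
  invisible(x)
}

#' Broom-style accessors for benchmark objects
#'
#' `tidy()` returns the per-sample executed points with radii; `glance()`
#' the one-row summary statistics.
#'
#' @param x a `circle_benchmark`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.circle_benchmark <- function(x, ...) tibble::as_tibble(x$samples)

#' @rdname tidy.circle_benchmark
#' @exportS3Method generics::glance
glance.circle_benchmark <- function(x, ...) x$stats

#' Discretization report across waypoint counts
#'
#' Runs [run_circle_benchmark()] for each `N` and tabulates spatial step,
#' mean radius, standard deviation and whether the deviation falls below
#' the arm's repeatability threshold — the decision table for picking the
#' coarsest discretization the hardware cannot distinguish from ideal.
#'
#' @inheritParams run_circle_benchmark
#' @param N_list waypoint counts (default the study grid 5, 10, 20, 30).
#' @return A `discretization_report` tibble: one row per `N` with columns
#'   `N`, `S_mm`, `mean_radius`, `std_radius`, `rms_dev`, `below_threshold`,
#'   sorted by `N`; attribute `eps` records the threshold used.
#' @export
#' @examples
#' rep <- discretization_report(arm_model(), N_list = c(5, 10, 20, 30))
#' rep
discretization_report <- function(arm, N_list = c(5L, 10L, 20L, 30L), D = 20,
                                  center = c(250, 0, 50),
                                  mode = c("cartesian_chord", "joint_linear"),
                                  M = 200L) {
  mode <- match.arg(mode)
  stopifnot(length(N_list) >= 1)
  rows <- purrr::map_dfr(sort(as.integer(N_list)), function(n) {
    glance(run_circle_benchmark(arm, n, D, center, mode, M))
  })
  rows$below_threshold <- rows$std_radius < arm$repeatability_eps
  structure(rows, eps = arm$repeatability_eps,
            class = c("discretization_report", class(rows)))
}

#' Write a discretization report as CSV
#'
#' Columns `N, S_mm, mean_radius_mm, std_radius_mm, below_threshold`, the
#' layout of the printed decision table.
#'
#' @param report a `discretization_report`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_report_csv <- function(report, file) {
  df <- data.frame(N = report$N,
                   S_mm = sprintf("%.6f", report$S_mm),
                   mean_radius_mm = sprintf("%.6f", report$mean_radius),
                   std_radius_mm = sprintf("%.6f", report$std_radius),
                   below_threshold = report$below_threshold)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot a discretization report
#'
#' Deviation versus waypoint count with the repeatability band shaded: the
#' discretization is adequate once the curve enters the band.
#'
#' @param object a `discretization_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.discretization_report <- function(object, ...) {
  eps <- attr(object, "eps")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$N, .data$std_radius)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = eps,
                      alpha = 0.2, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "waypoints N", y = "std of sampled radii [mm]",
                  title = "Trajectory deviation vs spatial discretization",
                  subtitle = sprintf("shaded band: repeatability %.2f mm", eps)) +
    ggplot2::theme_minimal()
}

#' Plot an executed benchmark trajectory
#'
#' @param object a `circle_benchmark`.
#' @param ... unused.
#' @return A ggplot object: executed samples over the ideal circle.
#' @exportS3Method ggplot2::autoplot
autoplot.circle_benchmark <- function(object, ...) {
  cfg <- object$config
  ideal <- circle_waypoints(720, cfg$D, cfg$center)
  ggplot2::ggplot(object$samples, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = ideal, colour = "steelblue") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]",
                  title = sprintf("Executed vs ideal circle (N = %d)", cfg$N)) +
    ggplot2::theme_minimal()
}
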