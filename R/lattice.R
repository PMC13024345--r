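#' Generate a conformal lattice deposition path
#'
#' The core toolpath builder: slices the surface with two orthogonal families
#' of parallel planes (spacing `d`, the pore pitch), orders each family's
#' contour lines in serpentine fashion (scanning direction alternating
#' left-to-right, then right-to-left) so consecutive line endpoints are near
#' each other, resamples every line to the spatial step `max_step`, and joins
#' lines with straight travel moves — the shortest 3D vector between the
#' previous end point and the next start point. The result is a single
#' connected point sequence: the X-family lines first, then the Y-family,
#' forming a reticulated grid conforming to the surface.
#'
#' With `layers > 1` the path is replayed per layer with the family order
#' swapped on alternate layers (the interlayer pattern alternates direction
#' for a consistent pore structure) and each layer lifted by `layer_height`,
#' which must then be supplied.
#'
#' @param mesh a [triangle_mesh()] height-field patch.
#' @param d interplanar distance (mm); default 1 mm, giving 1 mm pores.
#' @param max_step maximum spacing S between consecutive path points (mm);
#'   default 2.09 mm, the benchmark-validated spatial step.
#' @param layers number of stacked lattice layers (default 1: a single
#'   surface pass laying both families).
#' @param layer_height z-offset between consecutive layers (mm); required
#'   when `layers > 1`.
#' @return A `lattice_path` tibble with columns `index`, `x`, `y`, `z` (mm),
#'   `move` (`"deposit"` or `"travel"`: how the arm reaches that point),
#'   `family` (`"x"`/`"y"` slicing family), `line` (global line counter) and
#'   `layer`. Attributes `d` and `max_step` record the construction
#'   parameters.
#' @export
#' @examples
#' plate <- make_flat_plate(extent = 10, resolution = 1)
#' path <- generate_lattice_path(plate, d = 1, max_step = 2.09)
#' path_metrics(path)
generate_lattice_path <- function(mesh, d = 1, max_step = 2.09,
                                  layers = 1L, layer_height = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), d > 0, max_step > 0, layers >= 1)
  if (layers > 1 && is.null(layer_height)) {
    stop("`layer_height` must be given when layers > 1 (no default exists)",
         call. = FALSE)
  }
  fams <- lapply(c("x", "y"), function(ax) {
    fam <- build_plane_family(mesh, ax, spacing = d)
    lines <- slice_mesh_family(mesh, fam)
    if (nrow(lines) == 0L) {
      stop("mesh too small along ", ax, ": slicing produced no lines",
           call. = FALSE)
    }
    serpentine_order(resample_polyline(lines, max_step))
  })
  names(fams) <- c("x", "y")

  one_layer <- function(order, layer, z_off) {
    df <- dplyr::bind_rows(fams[order])
    df$z <- df$z + z_off
    # global line counter in traversal order
    lid <- paste(df$axis, df$offset, df$line)
    df$line <- match(lid, unique(lid))
    df <- dplyr::group_by(df, .data$line)
    df <- dplyr::mutate(df, move = dplyr::if_else(dplyr::row_number() == 1L,
                                                  "travel", "deposit"))
    df <- dplyr::ungroup(df)
    tibble::tibble(x = df$x, y = df$y, z = df$z, move = df$move,
                   family = df$axis, line = df$line, layer = layer)
  }

  out <- purrr::map_dfr(seq_len(layers), function(l) {
    order <- if (l %% 2 == 1) c("x", "y") else c("y", "x")
    z_off <- if (layers > 1) (l - 1) * layer_height else 0
    one_layer(order, l, z_off)
  })
  out <- dplyr::mutate(out, index = dplyr::row_number(), .before = 1)
  n_lines <- purrr::map_int(fams, ~ dplyr::n_distinct(.x$offset, .x$line))
  structure(out,
            d = d, max_step = max_step,
            n_x_lines = n_lines[["x"]], n_y_lines = n_lines[["y"]],
            class = c("lattice_path", class(out)))
}

#' Serpentine ordering of a polyline family
#'
#' Orders the lines of one slicing family by plane offset and reverses every
#' second line, so the end of each line lies next to the start of the next
#' and inter-line travel is short — the classic zigzag raster used in grid
#' infill.
#'
#' @param polylines tibble of polyline points (`axis`, `offset`, `line`,
#'   `x`, `y`, `z`), one slicing family.
#' @return The same tibble with rows of odd lines (0-based line order)
#'   reversed, rows sorted in traversal order.
#' @export
serpentine_order <- function(polylines) {
  if (nrow(polylines) == 0L) return(polylines)
  polylines <- dplyr::arrange(polylines, .data$offset, .data$line)
  key <- paste(polylines$offset, polylines$line)
  rank0 <- match(key, unique(key)) - 1L          # 0-based traversal rank
  parts <- split(seq_len(nrow(polylines)), rank0)
  idx <- unlist(lapply(seq_along(parts), function(i) {
    rows <- parts[[i]]
    if ((i - 1L) %% 2L == 1L) rev(rows) else rows
  }), use.names = FALSE)
  polylines[idx, , drop = FALSE]
}

#' Summary metrics of a lattice path
#'
#' @param path a `lattice_path` from [generate_lattice_path()].
#' @return A one-row tibble: total deposited filament length, total travel
#'   length, point count, the largest consecutive deposit spacing (must not
#'   exceed the configured S), line counts per family, and — for planar
#'   (height-field) input — the pore pitch, the mean spacing between
#'   consecutive parallel deposit lines measured at mid-span.
#' @export
path_metrics <- function(path) {
  if (!inherits(path, "lattice_path") || nrow(path) == 0L) {
    stop("`path` must be a non-empty lattice_path", call. = FALSE)
  }
  p <- as.matrix(path[, c("x", "y", "z")])
  step <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  kind <- path$move[-1]                          # move type of the arriving point
  deposit_len <- sum(step[kind == "deposit"])
  travel_len <- sum(step[kind == "travel"])
  pitch <- pore_pitch(path)
  tibble::tibble(
    total_deposit_mm = deposit_len,
    total_travel_mm = travel_len,
    n_points = nrow(path),
    max_deposit_spacing_mm = if (any(kind == "deposit"))
      max(step[kind == "deposit"]) else NA_real_,
    n_x_lines = attr(path, "n_x_lines"),
    n_y_lines = attr(path, "n_y_lines"),
    pore_pitch_mm = pitch
  )
}

# Mean spacing between consecutive parallel deposit lines, measured at the
# mid-span of each line (the line's mean position along the plane-normal
# axis). Averaged over both families.
pore_pitch <- function(path) {
  one_family <- function(fam) {
    df <- path[path$family == fam & path$layer == min(path$layer), ]
    if (nrow(df) == 0L) return(NA_real_)
    coord <- if (fam == "x") df$x else df$y
    centers <- tapply(coord, df$line, mean)
    if (length(centers) < 2) return(NA_real_)
    mean(diff(sort(centers)))
  }
  mean(c(one_family("x"), one_family("y")), na.rm = TRUE)
}

#' Export a lattice path or executed trajectory to CSV
#'
#' Waypoint CSV (`index, x_mm, y_mm, z_mm, move`, 6 decimal places,
#' deterministic row order) — the file a robot driver would consume.
#'
#' @param path a `lattice_path` tibble (or any tibble with `x`, `y`, `z` and
#'   optionally `move` columns).
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_path_csv <- function(path, file) {
  df <- tibble::tibble(
    index = seq_len(nrow(path)),
    x_mm = sprintf("%.6f", path$x),
    y_mm = sprintf("%.6f", path$y),
    z_mm = sprintf("%.6f", path$z),
    move = if ("move" %in% names(path)) path$move else "deposit"
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_path_csv
#' @export
write_path_json <- function(path, file) {
  payload <- list(
    d_mm = attr(path, "d"),
    max_step_mm = attr(path, "max_step"),
    points = lapply(seq_len(nrow(path)), function(i) {
      list(x = round(path$x[i], 6), y = round(path$y[i], 6),
           z = round(path$z[i], 6),
           move = if ("move" %in% names(path)) path$move[i] else "deposit")
    })
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Plot a lattice path
#'
#' Top view of the deposition lattice: deposit moves drawn as solid
#' segments coloured by height, travel moves dashed.
#'
#' @param object a `lattice_path`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lattice_path <- function(object, ...) {
  df <- tibble::tibble(
    x = object$x[-nrow(object)], y = object$y[-nrow(object)],
    xend = object$x[-1], yend = object$y[-1],
    z = object$z[-1], move = object$move[-1]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                   yend = .data$yend)) +
    ggplot2::geom_segment(data = df[df$move == "travel", ],
                          linetype = "dashed", colour = "grey60") +
    ggplot2::geom_segment(data = df[df$move == "deposit", ],
                          ggplot2::aes(colour = .data$z)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", colour = "z [mm]",
                  title = "Conformal lattice deposition path") +
    ggplot2::theme_minimal()
}
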