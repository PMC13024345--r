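#' Plane families for orthogonal slicing
#'
#' Builds the family of parallel axis-normal planes used to cut the surface
#' into deposit lines. Planes are placed at `min + k * spacing` for
#' `k = 1, 2, ...`, strictly inside the mesh extent along the slicing axis:
#' boundary-touching planes would generate tangential, zero-width contours,
#' so they are excluded by convention and plane counts are deterministic.
#'
#' @param mesh a [triangle_mesh()] (or a `mesh_summary()` tibble).
#' @param axis `"x"` or `"y"`: the plane normal direction.
#' @param spacing interplanar distance d (mm); the lattice pore pitch.
#' @return A tibble with columns `axis` and `offset` (one row per plane),
#'   offsets strictly increasing with uniform spacing.
#' @export
#' @examples
#' plate <- make_flat_plate(extent = 10, resolution = 1)
#' build_plane_family(plate, "x", spacing = 1)   # 9 planes at 1..9 mm
build_plane_family <- function(mesh, axis = c("x", "y"), spacing = 1) {
  axis <- match.arg(axis)
  stopifnot(spacing > 0)
  b <- if (inherits(mesh, "triangle_mesh")) mesh_bounds(mesh) else
    stop("`mesh` must be a triangle_mesh", call. = FALSE)
  lo <- b["min", axis]
  hi <- b["max", axis]
  span <- hi - lo
  if (span <= spacing) {
    stop(sprintf(
      "mesh span along %s (%.3f mm) does not exceed the plane spacing (%.3f mm): empty plane family",
      axis, span, spacing), call. = FALSE)
  }
  k <- seq_len(floor(span / spacing - 1e-9))
  tibble::tibble(axis = axis, offset = lo + k * spacing)
}

#' Intersect one plane with one triangle
#'
#' Computes the intersection segment of a plane with a single triangle, if
#' any. Robustness follows the standard slicer convention of symbolic
#' perturbation: a vertex lying on the plane (within `tol`) is assigned to
#' the positive side. Consequences: a fully coplanar triangle contributes
#' nothing; a triangle merely touching the plane at a vertex contributes
#' nothing; an edge lying in the plane is emitted exactly once — by the
#' triangle whose third vertex is on the negative side — so interior mesh
#' edges coinciding with a slicing plane produce a single, non-duplicated
#' contour, and boundary edges with the surface on the positive side are
#' suppressed.
#'
#' @param tri 3x3 numeric matrix, one vertex per row.
#' @param normal unit plane normal.
#' @param offset plane offset: the plane is `{p : normal . p = offset}`.
#' @param tol geometric predicate tolerance (mm).
#' @return A 2x3 matrix (segment endpoints, each satisfying the plane
#'   equation to `tol` and lying inside the triangle) or `NULL` when there
#'   is no proper crossing or the segment is shorter than `tol`.
#' @export
intersect_plane_triangle <- function(tri, normal, offset, tol = 1e-9) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3, ncol(tri) == 3)
  if (face_areas(tri, matrix(1:3, nrow = 1)) <= 1e-12) {
    stop("degenerate triangle: area below 1e-12 mm^2", call. = FALSE)
  }
  s <- as.vector(tri %*% normal) - offset
  on_plane <- abs(s) <= tol
  side <- ifelse(s < -tol, -1L, 1L)          # on-plane vertices -> positive
  if (all(side == 1L) || all(side == -1L)) return(NULL)
  pts <- matrix(numeric(0), ncol = 3)
  for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
    i <- e[1]; j <- e[2]
    if (side[i] != side[j]) {
      if (on_plane[i]) {
        pts <- rbind(pts, tri[i, ] - s[i] * normal)
      } else if (on_plane[j]) {
        pts <- rbind(pts, tri[j, ] - s[j] * normal)
      } else {
        t <- s[i] / (s[i] - s[j])
        pts <- rbind(pts, tri[i, ] + t * (tri[j, ] - tri[i, ]))
      }
    }
  }
  if (nrow(pts) < 2) return(NULL)
  # Keep the two extreme points (duplicates arise from on-plane vertices).
  d <- as.matrix(stats::dist(pts))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  seg <- pts[ij, , drop = FALSE]
  if (sqrt(sum((seg[1, ] - seg[2, ])^2)) < tol) return(NULL)
  seg
}

axis_normal <- function(axis) {
  switch(axis, x = c(1, 0, 0), y = c(0, 1, 0),
         stop("axis must be 'x' or 'y'", call. = FALSE))
}

# Sweep coordinate: for an x-normal plane the contour runs along y, and
# vice versa.
sweep_axis <- function(axis) switch(axis, x = "y", y = "x")

#' Slice a mesh with one plane into ordered surface polylines
#'
#' Intersects every upward-facing triangle (`normal . z > 0`; deposition is
#' from above with a vertically held nozzle, so only upward geometry is
#' printable) with the plane, then chains the per-triangle segments into
#' maximal polylines by endpoint matching at 1e-6 mm. Each polyline is
#' ordered monotonically along the in-plane sweep coordinate; contours that
#' reverse direction (non-height-field meshes) are split at the reversal
#' points so the monotone ordering always holds.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis plane normal axis, `"x"` or `"y"`.
#' @param offset plane offset (mm).
#' @return A tibble with columns `axis`, `offset`, `line` (polyline id within
#'   this plane), and `x`, `y`, `z`; zero rows when the plane misses the mesh.
#' @export
slice_mesh <- function(mesh, axis = c("x", "y"), offset) {
  axis <- match.arg(axis)
  stopifnot(inherits(mesh, "triangle_mesh"))
  normal <- axis_normal(axis)
  up <- mesh$normals[, "z"] > 0
  faces <- mesh$faces[up, , drop = FALSE]
  segs <- vector("list", nrow(faces))
  n_seg <- 0L
  for (i in seq_len(nrow(faces))) {
    tri <- mesh$vertices[faces[i, ], , drop = FALSE]
    seg <- intersect_plane_triangle(tri, normal, offset)
    if (!is.null(seg)) {
      n_seg <- n_seg + 1L
      segs[[n_seg]] <- seg
    }
  }
  empty <- tibble::tibble(axis = character(), offset = numeric(),
                          line = integer(), x = numeric(), y = numeric(),
                          z = numeric())
  if (n_seg == 0L) return(empty)
  segs <- segs[seq_len(n_seg)]
  polys <- chain_segments(segs, tol = 1e-6)
  polys <- unlist(lapply(polys, split_at_reversals,
                         sweep = sweep_axis(axis)), recursive = FALSE)
  purrr::imap_dfr(polys, function(p, i) {
    # orient along increasing sweep coordinate
    sw <- p[, sweep_axis(axis)]
    if (sw[length(sw)] < sw[1]) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    tibble::tibble(axis = axis, offset = offset, line = as.integer(i),
                   x = p[, "x"], y = p[, "y"], z = p[, "z"])
  })
}

# Chain 2-point segments into maximal polylines by matching endpoints
# quantized at tol. Returns a list of n x 3 matrices.
chain_segments <- function(segs, tol = 1e-6) {
  pts <- do.call(rbind, segs)                     # 2 rows per segment
  key <- apply(round(pts / tol), 1, paste, collapse = ",")
  node <- match(key, unique(key))                 # node id per endpoint
  n_seg <- length(segs)
  ends <- matrix(node, ncol = 2, byrow = TRUE)    # per-segment node pair
  n_nodes <- max(node)
  # adjacency: node id -> incident segment indices (positional)
  inc <- split(rep(seq_len(n_seg), 2),
               factor(c(ends[, 1], ends[, 2]), levels = seq_len(n_nodes)))
  degree <- lengths(inc)
  used <- logical(n_seg)
  coords <- pts[!duplicated(key), , drop = FALSE] # representative coordinates
  out <- list()

  walk <- function(seg0, from_node) {
    path_nodes <- from_node
    seg <- seg0
    node_cur <- from_node
    repeat {
      used[seg] <<- TRUE
      node_nxt <- if (ends[seg, 1] == node_cur) ends[seg, 2] else ends[seg, 1]
      path_nodes <- c(path_nodes, node_nxt)
      nxt <- inc[[node_nxt]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      seg <- nxt[1]
      node_cur <- node_nxt
    }
    path_nodes
  }

  # open chains first (start at degree-1 nodes), then remaining loops
  for (start in which(degree == 1)) {
    cand <- inc[[start]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) next
    out[[length(out) + 1L]] <- walk(cand[1], start)
  }
  for (s in which(!used)) {
    if (used[s]) next
    out[[length(out) + 1L]] <- walk(s, ends[s, 1])
  }
  lapply(out, function(nodes) {
    m <- coords[nodes, , drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
}

# Split a polyline matrix wherever the sweep coordinate reverses direction.
split_at_reversals <- function(p, sweep) {
  if (nrow(p) < 3) return(list(p))
  sw <- p[, sweep]
  dir <- sign(diff(sw))
  dir[dir == 0] <- NA                      # plateaus don't flip direction
  dir <- zoo_locf(dir)
  flips <- which(diff(dir) != 0 & !is.na(diff(dir))) + 1L
  if (length(flips) == 0L) return(list(p))
  bounds <- c(1L, flips, nrow(p))
  lapply(seq_len(length(bounds) - 1L), function(i) {
    p[bounds[i]:bounds[i + 1L], , drop = FALSE]
  })
}

# last-observation-carried-forward for the direction vector (tiny helper;
# avoids a zoo dependency for one line)
zoo_locf <- function(x) {
  if (all(is.na(x))) return(x)
  idx <- cumsum(!is.na(x))
  idx[idx == 0] <- NA
  filled <- x[!is.na(x)][idx]
  filled
}

#' Slice a mesh with a whole plane family
#'
#' @param mesh a [triangle_mesh()].
#' @param family a plane-family tibble from [build_plane_family()].
#' @return A tibble of polyline points (`axis`, `offset`, `line`, `x`, `y`,
#'   `z`), rows ordered by plane offset then line then sweep coordinate.
#' @export
slice_mesh_family <- function(mesh, family) {
  purrr::pmap_dfr(family, function(axis, offset) {
    slice_mesh(mesh, axis, offset)
  })
}

#' Resample polylines to a maximum point spacing
#'
#' Subdivides every chord of every polyline into `ceiling(length /
#' max_step)` equal parts, so consecutive points are at most `max_step`
#' apart while the first and last point of each polyline — and every
#' original point — are preserved exactly. New points are linear
#' interpolations on the existing chords: resampling never moves the path.
#' The bound is the benchmark-derived spatial step S, chosen so the executed
#' trajectory deviates from the ideal path by less than the arm's
#' repeatability.
#'
#' @param polylines tibble as returned by [slice_mesh_family()] (columns
#'   `axis`, `offset`, `line`, `x`, `y`, `z`).
#' @param max_step maximum consecutive point spacing S (mm).
#' @return A tibble with the same columns, resampled.
#' @export
resample_polyline <- function(polylines, max_step) {
  stopifnot(max_step > 0)
  dplyr::group_modify(
    dplyr::group_by(polylines, .data$axis, .data$offset, .data$line),
    function(df, key) {
      if (nrow(df) < 2) {
        stop("cannot resample a single-point polyline", call. = FALSE)
      }
      p <- as.matrix(df[, c("x", "y", "z")])
      out <- p[1, , drop = FALSE]
      for (i in seq_len(nrow(p) - 1L)) {
        a <- p[i, ]; b <- p[i + 1L, ]
        len <- sqrt(sum((b - a)^2))
        k <- max(1L, ceiling(len / max_step - 1e-9))
        t <- seq_len(k) / k
        out <- rbind(out, outer(t, b - a) + rep(a, each = k))
      }
      tibble::tibble(x = out[, 1], y = out[, 2], z = out[, 3])
    }
  ) |> dplyr::ungroup()
}
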