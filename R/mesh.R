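#' Triangulated surface meshes
#'
#' A `triangle_mesh` is the package's internal surface representation: a
#' numeric vertex matrix (millimetres) plus an integer face matrix of 1-based
#' vertex indices. Face normals are always recomputed from the vertex winding;
#' normals stored in STL files are ignored because they are frequently wrong
#' in files found in the wild.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param n_degenerate_removed count of degenerate faces dropped during
#'   cleaning, carried for reporting.
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `normals` (unit face normals, recomputed) and the attribute
#'   `n_degenerate_removed`.
#' @export
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1L, 2L, 3L), nrow = 1))
#' mesh_summary(m)
triangle_mesh <- function(vertices, faces, n_degenerate_removed = 0L) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  if (any(!is.finite(vertices))) {
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  }
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face index out of range: every face index must address a vertex",
         call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         normals = face_normals(vertices, faces)),
    n_degenerate_removed = as.integer(n_degenerate_removed),
    class = "triangle_mesh"
  )
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  b <- mesh_bounds(x)
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounds [mm]: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              b[1, "x"], b[2, "x"], b[1, "y"], b[2, "y"], b[1, "z"], b[2, "z"]))
  invisible(x)
}

# Unit face normals from vertex winding (right-hand rule).
face_normals <- function(vertices, faces) {
  if (nrow(faces) == 0L) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1   # degenerate faces are removed upstream; keep finite here
  n <- n / len
  dimnames(n) <- list(NULL, c("x", "y", "z"))
  n
}

# Twice-area per face; used by the degeneracy filter.
face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

mesh_bounds <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("empty mesh has no bounds", call. = FALSE)
  rbind(min = apply(v, 2, min), max = apply(v, 2, max))
}

#' Clean a raw triangle soup into a valid mesh
#'
#' Merges vertices closer than `merge_tol` (1e-9 mm by default, far below the
#' 0.05 mm arm repeatability, so topology is preserved) and drops faces whose
#' area falls below `area_tol`. This is the load-time cleaning applied by
#' [read_stl()].
#'
#' @param vertices raw vertex matrix (one row per corner, possibly duplicated).
#' @param faces face index matrix into `vertices`.
#' @param merge_tol absolute vertex-merge tolerance in mm.
#' @param area_tol minimum face area in mm^2; smaller faces are dropped and
#'   counted.
#' @return A cleaned [triangle_mesh()].
#' @export
clean_mesh <- function(vertices, faces, merge_tol = 1e-9, area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  # Quantize to the merge tolerance to key duplicates.
  key <- apply(round(vertices / merge_tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  new_vertices <- vertices[first, , drop = FALSE]
  new_faces <- matrix(remap[faces], ncol = 3)
  # Collapsed faces (repeated indices) and tiny-area faces are degenerate.
  collapsed <- new_faces[, 1] == new_faces[, 2] |
    new_faces[, 2] == new_faces[, 3] | new_faces[, 1] == new_faces[, 3]
  areas <- face_areas(new_vertices, new_faces)
  keep <- !collapsed & areas > area_tol
  n_dropped <- sum(!keep)
  new_faces <- new_faces[keep, , drop = FALSE]
  # Drop unreferenced vertices.
  used <- sort(unique(as.vector(new_faces)))
  if (length(used) > 0L) {
    new_vertices <- new_vertices[used, , drop = FALSE]
    new_faces <- matrix(match(new_faces, used), ncol = 3)
  } else {
    new_vertices <- new_vertices[0, , drop = FALSE]
  }
  triangle_mesh(new_vertices, new_faces, n_degenerate_removed = n_dropped)
}

#' Summarise a mesh as a one-row tibble
#'
#' @param mesh a [triangle_mesh()].
#' @return A one-row tibble: vertex/face counts, the number of degenerate
#'   faces removed at load time, and the axis-aligned bounds (mm).
#' @export
mesh_summary <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  b <- mesh_bounds(mesh)
  tibble::tibble(
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    n_degenerate_removed = attr(mesh, "n_degenerate_removed") %||% 0L,
    min_x = b["min", "x"], max_x = b["max", "x"],
    min_y = b["min", "y"], max_y = b["max", "y"],
    min_z = b["min", "z"], max_z = b["max", "z"]
  )
}

#' Rigidly translate a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param offset length-3 numeric displacement (mm).
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot(inherits(mesh, "triangle_mesh"), length(offset) == 3)
  triangle_mesh(sweep(mesh$vertices, 2, as.numeric(offset), "+"), mesh$faces,
                attr(mesh, "n_degenerate_removed"))
}
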