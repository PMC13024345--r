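#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (autodetected) into a cleaned [triangle_mesh()].
#' Coordinates are interpreted as millimetres: STL carries no unit metadata
#' and the whole toolchain works in mm. Duplicate vertices within 1e-9 mm are
#' merged and degenerate (zero-area) facets dropped; stored facet normals are
#' discarded and recomputed from the winding.
#'
#' Autodetection: a file is ASCII if it starts with "solid" *and* its size is
#' inconsistent with the binary layout (80-byte header + 4-byte count +
#' 50-byte records); binary files that happen to begin with "solid" are still
#' parsed as binary.
#'
#' @param path path to an `.stl` file.
#' @return A cleaned [triangle_mesh()]; the number of degenerate faces removed
#'   is available through [mesh_summary()].
#' @export
#' @seealso [write_stl()]
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  head_raw <- readBin(path, "raw", n = min(size, 84))
  starts_solid <- length(head_raw) >= 5 &&
    identical(rawToChar(head_raw[1:5]), "solid")
  is_binary <- TRUE
  if (starts_solid) {
    if (size >= 84) {
      n_tri <- readBin(head_raw[81:84], "integer", size = 4, endian = "little")
      is_binary <- (size == 84 + 50 * as.numeric(n_tri))
    } else {
      is_binary <- FALSE
    }
  }
  raw_tris <- if (is_binary) read_stl_binary(path, size) else read_stl_ascii(path)
  mesh <- clean_mesh(raw_tris$vertices, raw_tris$faces)
  if (nrow(mesh$faces) == 0L) {
    stop("empty mesh: no valid faces remain after cleaning ", path,
         call. = FALSE)
  }
  mesh
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(n_tri) || n_tri < 0) {
    stop("truncated binary STL: unreadable facet count at byte offset 80",
         call. = FALSE)
  }
  expected <- 84 + 50 * as.numeric(n_tri)
  if (size < expected) {
    stop(sprintf(
      "truncated binary STL: %d facets declared need %.0f bytes, file ends at byte offset %.0f",
      n_tri, expected, size), call. = FALSE)
  }
  body <- readBin(con, "raw", n = 50 * n_tri)
  # Each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute.
  idx <- rep(seq_len(n_tri) - 1L, each = 48) * 50L +
    rep(seq_len(48), times = n_tri)
  floats <- readBin(body[idx], "double", size = 4, n = 12 * n_tri,
                    endian = "little")
  m <- matrix(floats, ncol = 12, byrow = TRUE)   # n1 n2 n3 v1 v2 v3 (xyz each)
  vertices <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                    m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * n_tri), ncol = 3)))  # interleave corners
  vertices <- vertices[ord, , drop = FALSE]
  faces <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vertex_lines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vertex_lines) == 0L) {
    stop("ASCII STL parse error: no vertex lines found (byte offset 0)",
         call. = FALSE)
  }
  coords <- lapply(strsplit(trimws(vertex_lines), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (length(tok) < 4 || any(is.na(v))) {
      stop("ASCII STL parse error near: ", paste(tok, collapse = " "),
           call. = FALSE)
    }
    v
  })
  vertices <- do.call(rbind, coords)
  if (nrow(vertices) %% 3 != 0) {
    stop("ASCII STL parse error: vertex count not a multiple of 3",
         call. = FALSE)
  }
  faces <- matrix(seq_len(nrow(vertices)), ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

#' Write a mesh to STL
#'
#' @param mesh a [triangle_mesh()] with at least one face.
#' @param path output path.
#' @param dialect `"binary"` (80-byte header, little-endian 50-byte facet
#'   records) or `"ascii"`.
#' @return Invisibly, `path`. Round-tripping through [read_stl()] reproduces
#'   vertices and faces to within 1e-6 mm (binary STL stores float32).
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) {
    stop("refusing to write an empty mesh (no faces)", call. = FALSE)
  }
  ok <- tryCatch({
    if (dialect == "binary") write_stl_binary(mesh, path)
    else write_stl_ascii(mesh, path)
    TRUE
  }, error = function(e) {
    stop("cannot write STL to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "patchpath binary STL"))[1:80]
  writeBin(header, con)
  n_tri <- nrow(mesh$faces)
  writeBin(as.integer(n_tri), con, size = 4, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  n <- mesh$normals
  rec <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  for (i in seq_len(n_tri)) {
    writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- mesh$normals
  out <- character(2 + 7 * nrow(f))
  out[1] <- "solid patchpath"
  k <- 2L
  for (i in seq_len(nrow(f))) {
    out[k] <- sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3])
    out[k + 1L] <- "    outer loop"
    for (j in 1:3) {
      p <- v[f[i, j], ]
      out[k + 1L + j] <- sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3])
    }
    out[k + 5L] <- "    endloop"
    out[k + 6L] <- "  endfacet"
    k <- k + 7L
  }
  out[k] <- "endsolid patchpath"
  writeLines(out, path)
}
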