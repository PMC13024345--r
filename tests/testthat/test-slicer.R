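test_that("plane family follows the interior placement convention", {
  plate <- make_flat_plate(extent = 10, resolution = 1)
  fam <- build_plane_family(plate, "x", spacing = 1)
  expect_equal(fam$offset, 1:9)                  # 9 interior planes
  fam4 <- build_plane_family(plate, "x", spacing = 4)
  expect_equal(fam4$offset, c(4, 8))
  expect_true(all(diff(fam$offset) - 1 < 1e-9))
  small <- make_flat_plate(extent = 1, resolution = 1)
  expect_error(build_plane_family(small, "y", spacing = 2), "span")
})

test_that("plane-triangle intersection matches analytic cases", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  seg <- intersect_plane_triangle(tri, c(1, 0, 0), 1)
  expect_false(is.null(seg))
  key <- apply(seg[order(seg[, 2]), ], 1, paste, collapse = ",")
  expect_equal(seg[order(seg[, 2]), ], rbind(c(1, 0, 0), c(1, 1, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # plane beyond the triangle: no segment
  expect_null(intersect_plane_triangle(tri, c(1, 0, 0), 3))
  # boundary edge lying in the plane with the surface on the positive side:
  # suppressed (tangential contact)
  expect_null(intersect_plane_triangle(tri, c(1, 0, 0), 0))
  # same edge seen from a triangle on the negative side: emitted once
  tri_neg <- rbind(c(0, 0, 0), c(0, 2, 0), c(-2, 0, 0))
  seg2 <- intersect_plane_triangle(tri_neg, c(1, 0, 0), 0)
  expect_false(is.null(seg2))
  expect_equal(sort(seg2[, 2]), c(0, 2))
  # vertex-touch only: suppressed
  expect_null(intersect_plane_triangle(tri, c(1, 0, 0), 2))
  # degenerate triangle is an error
  expect_error(
    intersect_plane_triangle(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0)),
                             c(1, 0, 0), 0.5),
    "degenerate")
  # endpoints satisfy the plane equation to 1e-9
  cap <- make_spherical_cap(20, 25, 1)
  f <- cap$faces[10, ]
  tri3 <- cap$vertices[f, ]
  mid <- mean(tri3[, 1])
  seg3 <- intersect_plane_triangle(tri3, c(1, 0, 0), mid)
  if (!is.null(seg3)) expect_lt(max(abs(seg3[, 1] - mid)), 1e-9)
})

test_that("slicing a flat plate yields one full-span polyline at z = 0", {
  plate <- make_flat_plate(extent = 10, resolution = 1)
  lines <- slice_mesh(plate, "x", 5)
  expect_equal(dplyr::n_distinct(lines$line), 1)
  expect_equal(range(lines$y), c(0, 10))
  expect_true(all(abs(lines$z) < 1e-12))
  expect_true(all(abs(lines$x - 5) < 1e-9))
  expect_true(all(diff(lines$y) > 0))            # monotone sweep ordering
})

test_that("slicing the spherical cap gives a circular arc on the sphere", {
  R <- 25; D <- 20
  cap <- make_spherical_cap(D, R, resolution = 0.5)
  arc <- slice_mesh(cap, "x", 0)                 # plane through the apex
  expect_gt(nrow(arc), 10)
  zc <- -sqrt(R^2 - (D / 2)^2)
  resid <- sqrt(arc$x^2 + arc$y^2 + (arc$z - zc)^2) - R
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("disconnected intersections become separate polylines", {
  # two coplanar plates side by side, 5 mm gap
  a <- soup_square(extent = 4)
  b <- soup_square(extent = 4)
  b$vertices[, 2] <- b$vertices[, 2] + 9
  mesh <- clean_mesh(rbind(a$vertices, b$vertices),
                     rbind(a$faces, b$faces + 6))
  lines <- slice_mesh(mesh, "x", 2)
  expect_equal(dplyr::n_distinct(lines$line), 2)
})

test_that("every polyline point lies on the mesh surface (brute-force oracle)", {
  set.seed(11)
  meshes <- list(
    make_wavy_patch(8, 1.5, 5, resolution = 1),
    make_spherical_cap(12, 10, resolution = 1)
  )
  for (mesh in meshes) {
    fam <- build_plane_family(mesh, "y", spacing = 2.5)
    lines <- slice_mesh_family(mesh, fam)
    expect_gt(nrow(lines), 0)
    idx <- sample(nrow(lines), min(40, nrow(lines)))
    d <- point_to_mesh_distance(lines[idx, c("x", "y", "z")], mesh)
    expect_lt(max(d), 1e-6)
  }
})

test_that("total intersection length is invariant under rigid translation", {
  mesh <- make_wavy_patch(8, 1, 6, resolution = 1)
  fam <- build_plane_family(mesh, "x", spacing = 2)
  l0 <- slice_mesh_family(mesh, fam)
  len0 <- sum(vapply(split(l0, paste(l0$offset, l0$line)), path_length,
                     numeric(1)))
  off <- c(3.25, -1.5, 7.75)
  mesh2 <- translate_mesh(mesh, off)
  fam2 <- fam
  fam2$offset <- fam2$offset + off[1]
  l1 <- slice_mesh_family(mesh2, fam2)
  len1 <- sum(vapply(split(l1, paste(l1$offset, l1$line)), path_length,
                     numeric(1)))
  expect_equal(len0, len1, tolerance = 1e-9)
})

test_that("chaining conserves per-triangle segments", {
  mesh <- make_wavy_patch(8, 1, 6, resolution = 1)
  offset <- 3.3
  n_seg <- 0L
  for (i in seq_len(nrow(mesh$faces))) {
    if (mesh$normals[i, "z"] <= 0) next
    tri <- mesh$vertices[mesh$faces[i, ], ]
    if (!is.null(intersect_plane_triangle(tri, c(1, 0, 0), offset))) {
      n_seg <- n_seg + 1L
    }
  }
  lines <- slice_mesh(mesh, "x", offset)
  n_chained <- sum(vapply(split(seq_len(nrow(lines)), lines$line),
                          function(i) length(i) - 1L, integer(1)))
  expect_equal(n_chained, n_seg)
})

test_that("resampling subdivides chords equally and preserves the path", {
  line <- tibble::tibble(axis = "x", offset = 0, line = 1L,
                         x = 0, y = c(0, 10), z = 0)
  out <- resample_polyline(line, max_step = 2.09)
  expect_equal(nrow(out), 6)                     # ceiling(10/2.09) = 5 parts
  expect_equal(diff(out$y), rep(2, 5))
  expect_equal(out$y[c(1, 6)], c(0, 10))         # endpoints preserved
  # already-compliant polyline is returned unchanged
  fine <- resample_polyline(out, max_step = 2.09)
  expect_equal(fine$y, out$y)
  # resampled points lie exactly on the original polyline (here: x = z = 0)
  expect_true(all(fine$x == 0 & fine$z == 0))
  # max_step larger than every chord: identity
  wide <- resample_polyline(line, max_step = 100)
  expect_equal(wide$y, c(0, 10))
  expect_error(
    resample_polyline(tibble::tibble(axis = "x", offset = 0, line = 1L,
                                     x = 0, y = 0, z = 0), 1),
    "single-point")
})

test_that("resampling enforces the spacing bound on curved contours", {
  cap <- make_spherical_cap(20, 25, resolution = 3)   # coarse: long chords
  lines <- slice_mesh(cap, "x", 0.5)
  out <- resample_polyline(lines, max_step = 0.7)
  steps <- sqrt(diff(out$x)^2 + diff(out$y)^2 + diff(out$z)^2)
  expect_true(all(steps <= 0.7 + 1e-9))
  # resampling adds no chord-length error
  expect_equal(path_length(out), path_length(lines), tolerance = 1e-12)
})
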