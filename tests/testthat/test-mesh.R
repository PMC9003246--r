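test_that("beam lattice has hand-countable topology and rest lengths", {
  m <- gen_beam_mesh(2, 1, 1, spacing = 0.01)
  expect_identical(nrow(m$positions), 12L)
  # axis edges: 8 + 6 + 6; both diagonals on 4+4+3 faces
  expect_identical(nrow(m$elements), 20L + 22L)
  expect_true(all(abs(m$rest_lengths - 0.01) < 1e-12 |
                    abs(m$rest_lengths - 0.01 * sqrt(2)) < 1e-12))
  expect_identical(length(m$fixed_nodes), 4L)   # x = 0 face
  expect_identical(length(m$driven_nodes), 4L)  # x = max face
  # no duplicate elements, endpoints distinct
  expect_false(any(duplicated(m$elements)))
  expect_true(all(m$elements[, 1] != m$elements[, 2]))
  # axis-aligned variant drops the diagonals
  m0 <- gen_beam_mesh(2, 1, 1, spacing = 0.01, diagonals = FALSE)
  expect_identical(nrow(m0$elements), 20L)
})

test_that("mass lumping conserves the reference mass", {
  m <- gen_beam_mesh(3, 2, 2, spacing = 0.01, diagonals = TRUE)
  expect_equal(sum(m$masses), 1060 * (0.03 * 0.02 * 0.02))
  expect_true(all(m$masses > 0))
})

test_that("icosphere mesh has the known polyhedral counts", {
  ico <- gen_ellipsoid_mesh(0, radii = c(1, 1, 1))
  expect_identical(nrow(ico$positions), 12L)
  expect_identical(nrow(ico$elements), 30L)
  expect_identical(nrow(attr(ico, "faces")), 20L)
  s1 <- gen_ellipsoid_mesh(1)
  s2 <- gen_ellipsoid_mesh(2)
  expect_identical(nrow(attr(s1, "faces")), 80L)
  expect_identical(nrow(attr(s2, "faces")), 320L)
  expect_identical(nrow(s2$elements), 30L * 16L)
  expect_true(all(s2$rest_lengths > 0))
})

test_that("OBJ files load, deduplicate shared edges, and round-trip", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 1 1 0",
               "f 1 2 3", "f 2/1 4/2 3/3"), path)
  m <- load_mesh(path)
  expect_identical(nrow(m$positions), 4L)
  expect_identical(nrow(m$elements), 5L)  # edge 2-3 shared, stored once
  out <- withr::local_tempfile(fileext = ".obj")
  save_mesh(m, out)
  m2 <- load_mesh(out)
  expect_equal(m2$positions, m$positions)
  expect_identical(m2$elements, m$elements)
  # degenerate file reports context
  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0"), bad)
  expect_error(load_mesh(bad), "no vertices or no faces")
})

test_that("duplicate triangles in a soup are flagged and deduplicated", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
               "f 1 2 3", "f 1 2 3"), path)
  expect_message(m <- load_mesh(path), "duplicate")
  expect_identical(nrow(m$elements), 3L)
})

test_that("VTK tetrahedral fixture loads with the expected unique edges", {
  fix <- system.file("extdata", "cube_tet.vtk", package = "eesm")
  m <- load_mesh(fix)
  expect_identical(nrow(m$positions), 8L)
  expect_identical(length(attr(m, "cells")), 5L)
  # 12 cube edges + 6 face diagonals from the five-tet split
  expect_identical(nrow(m$elements), 18L)
  out <- withr::local_tempfile(fileext = ".vtk")
  save_mesh(m, out)
  m2 <- load_mesh(out)
  expect_equal(m2$positions, m$positions)
  expect_identical(m2$elements, m$elements)
})

test_that("mesh construction validates its inputs", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(spring_mesh(pos, rbind(c(1, 1))), "distinct")
  expect_error(spring_mesh(pos, rbind(c(1, 3))), "out of range")
  expect_error(spring_mesh(rbind(c(0, 0, 0), c(0, 0, 0)), rbind(c(1, 2))),
               "zero-length")
  expect_message(spring_mesh(pos, rbind(c(1, 2), c(2, 1))), "duplicate")
})

test_that("frame series writes one VTK file per frame", {
  m <- single_element_mesh()
  dir <- withr::local_tempdir()
  frames <- list(m$positions, m$positions + 0.001)
  write_vtk_series(frames, m, file.path(dir, "frame"))
  files <- list.files(dir, pattern = "^frame_\\d+\\.vtk$")
  expect_identical(length(files), 2L)
  back <- load_mesh(file.path(dir, "frame_0002.vtk"))
  expect_equal(back$positions, frames[[2]])
})
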