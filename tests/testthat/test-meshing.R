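test_that("minimal triangulation of the unit square", {
  m <- triangulate_region(unit_square(), target_edge = 2)
  expect_equal(nrow(m$nodes), 4)
  expect_equal(nrow(m$elements), 2)
  expect_true(all(lvtrack:::tri_signed_areas(m$nodes, m$elements) > 0))
})

test_that("element areas sum to the boundary polygon area", {
  for (cc in list(circle_contour(50, 64), blob_contour(21, r = 30))) {
    m <- triangulate_region(cc, target_edge = perimeter(cc) / 48)
    ring <- contour(m$nodes[seq_len(m$n_boundary), ], validate = FALSE)
    expect_lt(abs(sum(lvtrack:::tri_signed_areas(m$nodes, m$elements)) -
                    polygon_area(ring)) / polygon_area(ring), 1e-6)
  }
})

test_that("boundary nodes lie on the input polyline and quality holds", {
  circ <- circle_contour(50, 128)
  m <- triangulate_region(circ, target_edge = 5)
  bd <- lvtrack:::dist_to_polyline(m$nodes[seq_len(m$n_boundary), ],
                                   circ$points)
  expect_lt(max(bd), 1e-9)
  expect_gte(mesh_min_angle(m), 20)
})

test_that("find_boundary identifies faces per the anticlockwise convention", {
  # single triangle: all faces boundary
  tri <- structure(list(nodes = rbind(c(0, 0), c(1, 0), c(0, 1)),
                        elements = matrix(1:3, 1), n_boundary = 3L),
                   class = "lv_mesh")
  fb <- find_boundary(tri)
  expect_equal(sort(fb$boundary_faces$face), 1:3)
  expect_equal(fb$boundary_nodes, 1:3)
  # two-triangle square: 4 boundary edges, diagonal excluded
  sq <- triangulate_region(unit_square(), target_edge = 2)
  fb2 <- find_boundary(sq)
  expect_equal(nrow(fb2$boundary_faces), 4)
  # every node appears exactly twice along the closed chain of 4 edges
  expect_equal(sort(c(fb2$boundary_faces$from, fb2$boundary_faces$to)),
               rep(1:4, each = 2))
})

test_that("boundary edges match a brute-force incidence oracle", {
  m <- triangulate_region(circle_contour(40, 96), target_edge = 5)
  tri <- m$elements
  # oracle: hash every undirected edge, boundary iff it appears once
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_edges <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
                 key(tri[, 3], tri[, 1]))
  counts <- table(all_edges)
  oracle <- sort(names(counts)[counts == 1])
  fb <- find_boundary(m)
  got <- sort(key(fb$boundary_faces$from, fb$boundary_faces$to))
  expect_identical(got, oracle)
  # boundary-edge theorem: chain length equals boundary edge count
  ms <- assemble_surface(m, 0.1)
  expect_equal(length(ms$chain), length(oracle))
})

test_that("assemble_surface partitions the boundary into SURFACE and basal set", {
  m <- triangulate_region(circle_contour(40, 96), target_edge = 5)
  # basal fraction 0: everything is SURFACE
  m0 <- assemble_surface(m, 0)
  expect_equal(length(m0$basal_nodes), 0)
  expect_equal(nrow(m0$surface_faces), nrow(m0$boundary_faces))
  # partition: surface + basal edges = boundary edges, disjoint
  m1 <- assemble_surface(m, 0.15)
  basal_edges <- nrow(m1$boundary_faces) - nrow(m1$surface_faces)
  expect_gt(basal_edges, 0)
  expect_true(all(m1$surface_faces$element %in% m1$boundary_faces$element))
  surf_keys <- paste(m1$surface_faces$element, m1$surface_faces$face)
  all_keys <- paste(m1$boundary_faces$element, m1$boundary_faces$face)
  expect_equal(length(intersect(surf_keys, all_keys)), nrow(m1$surface_faces))
})

test_that("basal nodes sit at the top of the LV phantom", {
  cfg <- phantom_config()
  base <- lvtrack:::phantom_base_contour(cfg)
  m <- assemble_surface(triangulate_region(base, perimeter(base) / 48), 0.1)
  yr <- range(m$nodes[, 2])
  basal_y <- m$nodes[m$basal_nodes, 2]
  expect_true(all(basal_y <= yr[1] + 0.15 * diff(yr)))
})

test_that("mesh text round-trip and inp export", {
  m <- triangulate_region(circle_contour(20, 32), target_edge = 4)
  f <- tempfile()
  write_mesh(m, f)
  back <- read_mesh(f)
  expect_equal(back$nodes, unname(m$nodes), tolerance = 1e-9)
  expect_equal(back$elements, m$elements)
  inp <- tempfile(fileext = ".inp")
  write_abaqus_inp(assemble_surface(m, 0.1), inp)
  lines <- readLines(inp)
  expect_true("*NODE" %in% lines)
  expect_true(any(grepl("^\\*ELEMENT, TYPE=CPS3", lines)))
  expect_true(any(grepl("^\\*SURFACE", lines)))
  unlink(c(f, inp))
})

test_that("re-triangulating a deformed boundary reproduces its area", {
  cc <- circle_contour(30, 64)
  # squash it (a deformed frame-to-frame boundary)
  def <- contour(cbind(cc$points[, 1] * 0.85, cc$points[, 2] * 0.95))
  m <- triangulate_region(def, target_edge = perimeter(def) / 48)
  ring <- contour(m$nodes[seq_len(m$n_boundary), ], validate = FALSE)
  expect_lt(abs(sum(lvtrack:::tri_signed_areas(m$nodes, m$elements)) -
                  polygon_area(ring)) / polygon_area(ring), 1e-6)
})
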