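# Mesh generators, quality metrics and file I/O.

test_that("interval meshes have the expected layout", {
  m <- build_interval_mesh(2, 0.01)
  expect_equal(m$n_vertices, 201L)
  expect_equal(m$n_elements, 200L)
  expect_equal(build_interval_mesh(6, 0.001)$n_vertices, 6001L)
  expect_equal(mesh_quality(m)$Q, 1)
  expect_error(build_interval_mesh(-1, 0.1))
})

test_that("generated square meshes are conforming, CCW and near target_h", {
  sq <- build_square_mesh(1, 0.0444, seed = 7)
  hm <- mean_element_diameter(sq)
  expect_gt(hm, 0.0444 * 0.85)
  expect_lt(hm, 0.0444 * 1.15)
  # positive areas (CCW) and conformity via edge counts
  expect_true(all(monodomainhp:::signed_areas(sq$vertices, sq$elements) > 0))
  expect_true(all(sq$edge_elem_count %in% 1:2))
  # Euler characteristic of a disc
  expect_equal(sq$n_vertices - sq$n_edges + sq$n_elements, 1L)
  # determinism
  sq2 <- build_square_mesh(1, 0.0444, seed = 7)
  expect_identical(sq$elements, sq2$elements)
  expect_identical(sq$vertices, sq2$vertices)
  # quasiuniformity stays bounded as target_h decreases
  hs <- c(0.12, 0.08, 0.0444)
  hm_seq <- Q_seq <- numeric(0)
  for (th in hs) {
    m <- build_square_mesh(1, th, seed = 3)
    hm_seq <- c(hm_seq, mean_element_diameter(m))
    Q_seq <- c(Q_seq, mesh_quality(m)$Q)
  }
  expect_true(all(diff(hm_seq) < 0))
  expect_true(all(Q_seq <= 5))
})

test_that("mesh quality metrics match closed forms", {
  # single equilateral triangle of side 1: R = sqrt(3)
  s <- 1
  eq <- monodomainhp:::new_mesh_2d(rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2)),
                                   rbind(c(1L, 2L, 3L)))
  expect_equal(mesh_quality(eq)$R, sqrt(3), tolerance = 1e-12)
  # right isoceles with legs 1: h = sqrt(2), rho = 2 - sqrt(2)
  ri <- monodomainhp:::new_mesh_2d(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                   rbind(c(1L, 2L, 3L)))
  q <- mesh_quality(ri)
  expect_equal(q$h, sqrt(2), tolerance = 1e-12)
  expect_equal(q$R, sqrt(2) / (2 - sqrt(2)), tolerance = 1e-12)
})

test_that("hole meshes have the right topology and boundary geometry", {
  hm <- build_square_with_holes_mesh(1, target_h = 0.06, seed = 3)
  # chi = 1 - #holes
  expect_equal(hm$n_vertices - hm$n_edges + hm$n_elements, -1L)
  # hole-boundary vertices lie on their circles
  for (k in seq_along(hm$holes)) {
    hedges <- which(hm$edge_tags == 4L + k)
    expect_gt(length(hedges), 8L)
    vs <- unique(as.vector(hm$edges[hedges, ]))
    d <- sqrt((hm$vertices[vs, 1] - hm$holes[[k]]$center[1])^2 +
                (hm$vertices[vs, 2] - hm$holes[[k]]$center[2])^2)
    expect_lt(max(abs(d - hm$holes[[k]]$radius)), 1e-8)
  }
  # zero holes: disc topology
  sq <- build_square_mesh(1, 0.1, seed = 1)
  expect_equal(sq$n_vertices - sq$n_edges + sq$n_elements, 1L)
  expect_error(build_square_with_holes_mesh(
    1, holes = list(list(center = c(0.95, 0.5), radius = 0.2)),
    target_h = 0.06), "inside")
})

test_that("triangle and gmsh round trips preserve the mesh", {
  sq <- build_square_mesh(1, 0.15, seed = 5)
  tn <- file.path(tempdir(), "rt.node")
  write_mesh(sq, tn, "triangle_node_ele")
  m2 <- read_mesh(tn, "triangle_node_ele")
  expect_identical(m2$elements, sq$elements)
  expect_equal(m2$vertices, sq$vertices)
  tm <- file.path(tempdir(), "rt.msh")
  write_mesh(sq, tm, "gmsh_msh2")
  m3 <- read_mesh(tm, "gmsh_msh2")
  expect_identical(m3$elements, sq$elements)
  expect_equal(m3$vertices, sq$vertices)
})

test_that("unsupported gmsh elements are rejected with a location", {
  tm <- file.path(tempdir(), "quad.msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4", "1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0",
               "$EndNodes",
               "$Elements", "1", "1 3 2 0 1 1 2 3 4", "$EndElements"), tm)
  expect_error(read_mesh(tm, "gmsh_msh2"), "unsupported element type 3")
})

test_that("VTK output writes constant point data faithfully", {
  sq <- build_square_mesh(1, 0.2, seed = 1)
  tv <- file.path(tempdir(), "f.vtk")
  write_vtk(sq, list(Vm = rep(-84.5, sq$n_vertices)), tv)
  ln <- readLines(tv)
  i <- which(ln == "LOOKUP_TABLE default")
  vals <- as.numeric(ln[(i + 1):(i + sq$n_vertices)])
  expect_true(all(vals == -84.5))
  expect_true(any(grepl("SCALARS Vm", ln)))
})
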