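# Operator assembly: exact small-case values, structural invariants, the
# nodal/hierarchical change of basis, and the matrix-based right-hand side
# against the direct-quadrature oracle.

test_that("1D mass and stiffness match closed-form entries", {
  m <- monodomainhp:::new_mesh_1d(c(0, 0.3), cbind(1L, 2L))
  M <- assemble_mass(m, dof_map(m, 1))$M
  expect_equal(as.matrix(M), 0.3 / 6 * matrix(c(2, 1, 1, 2), 2),
               ignore_attr = TRUE, tolerance = 1e-14)
  u <- monodomainhp:::new_mesh_1d(c(0, 1), cbind(1L, 2L))
  dm2 <- dof_map(u, 2)
  M2 <- as.matrix(assemble_mass(u, dm2)$M)
  expect_equal(M2[1, 3], 1 / 12, tolerance = 1e-14)    # (1-x, x(1-x))
  A1 <- as.matrix(assemble_stiffness(u, dof_map(u, 1), 1))
  expect_equal(A1, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE,
               tolerance = 1e-14)
  A2 <- as.matrix(assemble_stiffness(u, dm2, 1))
  expect_equal(A2[3, 3], 1 / 3, tolerance = 1e-14)     # int (1-2x)^2
  # linearity in the conductivity
  expect_equal(as.matrix(assemble_stiffness(u, dm2, 2.5)), 2.5 * A2,
               tolerance = 1e-13)
})

test_that("mass is SPD and stiffness has exactly the constants as kernel", {
  sq <- build_square_mesh(1, 0.12, seed = 2)
  for (p in c(1, 3, 4)) {
    dm <- dof_map(sq, p)
    M <- assemble_mass(sq, dm)$M
    expect_silent(Matrix::Cholesky(M))
    A <- assemble_stiffness(sq, dm, 1)
    cvec <- numeric(dm$n_dof); cvec[seq_len(sq$n_vertices)] <- 1
    nrmA <- max(abs(A))
    expect_lt(max(abs(A %*% cvec)), 1e-10 * nrmA)
    # the linear block of M sums to the domain measure
    expect_equal(sum(M[seq_len(sq$n_vertices), seq_len(sq$n_vertices)]), 1,
                 tolerance = 1e-10)
    # kernel dimension is 1: second smallest eigenvalue of A is positive
    ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
    expect_lt(ev[length(ev)], 1e-10 * nrmA)
    expect_gt(ev[length(ev) - 1], 1e-8 * nrmA)
  }
})

test_that("Mtilde rows coincide with the degree-p-tilde square mass rows", {
  sq <- build_square_mesh(1, 0.2, seed = 3)
  dm2 <- dof_map(sq, 2); dm4 <- dof_map(sq, 4)
  mm <- assemble_mass(sq, dm2, dm4)
  shared <- shared_mode_indices(dm2, dm4)
  expect_equal(as.matrix(mm$Mtilde), as.matrix(mm$M_pt[shared, ]),
               tolerance = 1e-15)
  # shared rows of the p-tilde mass restricted to shared columns equal M
  expect_lt(max(abs(mm$Mtilde[, shared] - mm$M)), 1e-13)
})

test_that("nodal -> hierarchical interpolation is exact on polynomials", {
  sq <- build_square_mesh(1, 0.2, seed = 4)
  pt <- 4
  dmt <- dof_map(sq, pt)
  nmp <- nodal_map(sq, pt)
  Tg <- nodal_to_hierarchical_matrix(sq, dmt, nmp)
  E <- nodal_evaluation_matrix(sq, dmt, nmp)
  # linear functions have zero higher-mode coefficients (nesting)
  vl <- 1 + 2 * nmp$points[, 1] - 0.5 * nmp$points[, 2]
  cfl <- nodal_to_hierarchical(Tg, vl)
  expect_lt(max(abs(cfl[-seq_len(sq$n_vertices)])), 1e-12)
  expect_equal(cfl[seq_len(sq$n_vertices)],
               1 + 2 * sq$vertices[, 1] - 0.5 * sq$vertices[, 2],
               tolerance = 1e-12)
  # random degree-4 polynomials: evaluate-at-nodes round trip
  set.seed(7)
  for (k in 1:5) {
    cf <- rnorm(15)
    f <- function(q) {
      x <- q[, 1]; y <- q[, 2]
      cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3,
            x^4, x^3 * y, x^2 * y^2, x * y^3, y^4) %*% cf
    }
    v <- as.numeric(f(nmp$points))
    cc <- nodal_to_hierarchical(Tg, v)
    expect_lt(max(abs(as.numeric(E %*% cc) - v)), 1e-10 * max(1, max(abs(v))))
  }
  # the single-element bubble: f = x(1-x) on one interval, p-tilde = 2
  m1 <- monodomainhp:::new_mesh_1d(c(0, 1), cbind(1L, 2L))
  dm1 <- dof_map(m1, 2); nm1 <- nodal_map(m1, 2)
  T1 <- nodal_to_hierarchical_matrix(m1, dm1, nm1)
  v1 <- nm1$points[, 1] * (1 - nm1$points[, 1])
  cf1 <- nodal_to_hierarchical(T1, v1)
  expect_equal(cf1, c(0, 0, 1), tolerance = 1e-13)
})

test_that("matrix-based RHS equals the direct quadrature oracle", {
  sq <- build_square_mesh(1, 0.2, seed = 5)
  p <- 3; pt <- 4
  dm <- dof_map(sq, p); dmt <- dof_map(sq, pt); nmp <- nodal_map(sq, pt)
  mm <- assemble_mass(sq, dm, dmt)
  Tg <- nodal_to_hierarchical_matrix(sq, dmt, nmp)
  set.seed(11)
  worst <- 0
  for (k in 1:10) {
    cf <- rnorm(15)
    f <- function(q) {
      x <- q[, 1]; y <- q[, 2]
      as.numeric(cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3,
                       x^4, x^3 * y, x^2 * y^2, x * y^3, y^4) %*% cf)
    }
    nv <- f(nmp$points)
    r_mb <- rhs_matrix_based(mm$Mtilde, nodal_to_hierarchical(Tg, nv))
    r_q <- rhs_quadrature(sq, dm, nmp, nv)
    worst <- max(worst, max(abs(r_mb - r_q)) / max(abs(r_mb)))
  }
  expect_lt(worst, 1e-11)
  # zero current gives the zero vector
  expect_equal(rhs_matrix_based(mm$Mtilde,
                                nodal_to_hierarchical(Tg, numeric(nmp$n_nodes))),
               numeric(dm$n_dof))
  expect_error(rhs_matrix_based(mm$Mtilde, numeric(3)), "mismatch")
})

test_that("L2 projection recovers polynomials of degree at most p", {
  sq <- build_square_mesh(1, 0.25, seed = 6)
  dm <- dof_map(sq, 3)
  f <- function(q) 1 - q[, 1] + 2 * q[, 2]^3 - q[, 1] * q[, 2]
  cf <- project_l2(sq, dm, f)
  nmp <- nodal_map(sq, 3)
  E <- nodal_evaluation_matrix(sq, dm, nmp)
  expect_lt(max(abs(as.numeric(E %*% cf) - f(nmp$points))), 1e-10)
})
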