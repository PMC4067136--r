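# Hierarchical/nodal bases and quadrature on the reference elements.

test_that("interval hierarchical basis reproduces the classical mode set", {
  b <- hierarchical_basis_interval(3)
  x <- c(0, 0.17, 0.5, 0.83, 1)
  ev <- hbasis_eval(b, x)
  expect_equal(ev$val[, 1], 1 - x)
  expect_equal(ev$val[, 2], x)
  expect_equal(ev$val[, 3], x * (1 - x))
  expect_equal(ev$val[, 4], x * (1 - x) * (1 / 2 - x))
  # analytic gradients
  expect_equal(ev$dx[, 3], 1 - 2 * x)
  # partition of unity of the vertex modes
  set.seed(1)
  xr <- runif(100)
  evr <- hbasis_eval(hierarchical_basis_interval(4), xr)
  expect_lt(max(abs(rowSums(evr$val[, 1:2]) - 1)), 1e-13)
  expect_error(hierarchical_basis_interval(9), "degree")
})

test_that("quartic interval bubble vanishes at the ends and is independent", {
  b <- hierarchical_basis_interval(4)
  ev <- hbasis_eval(b, c(0, 1))
  expect_equal(ev$val[, 5], c(0, 0))
  # Vandermonde of all 5 modes at 5 interior points has full rank
  V <- hbasis_eval(b, c(0.1, 0.3, 0.5, 0.7, 0.9))$val
  expect_equal(qr(V)$rank, 5L)
})

test_that("triangle hierarchical basis has the right structure", {
  expect_equal(vapply(1:4, function(p) hierarchical_basis_triangle(p)$n_modes,
                      1L), c(3L, 6L, 10L, 15L))
  set.seed(2)
  lam <- matrix(runif(300), 100, 3); lam <- lam / rowSums(lam)
  b4 <- hierarchical_basis_triangle(4)
  ev <- hbasis_eval(b4, lam)
  # vertex modes are a partition of unity
  expect_lt(max(abs(rowSums(ev$val[, 1:3]) - 1)), 1e-13)
  # edge and interior modes vanish at the reference vertices
  verts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  evv <- hbasis_eval(b4, verts)
  expect_lt(max(abs(evv$val[, 4:15])), 1e-14)
  # interior modes vanish on the whole boundary
  edge_pts <- rbind(cbind(0, seq(0, 1, 0.1), 1 - seq(0, 1, 0.1)),
                    cbind(seq(0, 1, 0.1), 0, 1 - seq(0, 1, 0.1)),
                    cbind(seq(0, 1, 0.1), 1 - seq(0, 1, 0.1), 0))
  eve <- hbasis_eval(b4, edge_pts)
  int_modes <- which(b4$modes$kind == "interior")
  expect_lt(max(abs(eve$val[, int_modes])), 1e-14)
})

test_that("hierarchical mode lists nest (degree p is a prefix of p+1)", {
  for (p in 1:3) {
    a <- hierarchical_basis_triangle(p)$modes
    b <- hierarchical_basis_triangle(p + 1)$modes
    expect_identical(a, b[seq_len(nrow(a)), ])
    a1 <- hierarchical_basis_interval(p)$modes
    b1 <- hierarchical_basis_interval(p + 1)$modes
    expect_identical(a1, b1[seq_len(nrow(a1)), ])
  }
})

test_that("degree-4 triangle basis spans the full quartic space", {
  b <- hierarchical_basis_triangle(4)
  q <- gauss_rule(2, 8)
  B <- hbasis_eval(b, q$bary)$val
  G <- t(B) %*% (q$weights * B)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(ev) / min(ev), 1e8)  # nonsingular, reasonable conditioning
})

test_that("edge-mode traces reduce to the 1D modes up to a fixed scale", {
  b <- hierarchical_basis_triangle(4)
  b1 <- hierarchical_basis_interval(4)
  t <- seq(0.05, 0.95, by = 0.1)
  # edge 1 runs from vertex 1 to vertex 2: lambda = (1-t, t, 0)
  ev <- hbasis_eval(b, cbind(1 - t, t, 0))
  ev1 <- hbasis_eval(b1, t)
  for (d in 2:4) {
    k2 <- which(b$modes$kind == "edge" & b$modes$entity == 1 & b$modes$degree == d)
    ratio <- ev$val[, k2] / ev1$val[, d + 1]
    expect_lt(diff(range(ratio)), 1e-10)
  }
})

test_that("Gauss-Lobatto nodal points match their closed forms", {
  expect_equal(sort(nodal_points(1, 1)$points[, 1]), c(0, 1))
  p4 <- sort(nodal_points(1, 4)$points[, 1])
  expect_equal(p4, c(0, (1 - sqrt(3 / 7)) / 2, 0.5, (1 + sqrt(3 / 7)) / 2, 1),
               tolerance = 1e-12)
  # 2D degree 2: vertices plus edge midpoints
  nb <- nodal_points(2, 2)
  pts <- nb$points[order(nb$points[, 1], nb$points[, 2]), ]
  expect_equal(pts, rbind(c(0, 0), c(0, 0.5), c(0, 1), c(0.5, 0),
                          c(0.5, 0.5), c(1, 0)), ignore_attr = TRUE)
  expect_error(nodal_points(2, 9), "unsupported")
})

test_that("nodal bases are cardinal and edge traces are Gauss-Lobatto", {
  for (p in c(2, 4, 6)) {
    nb <- nodal_points(2, p)
    C <- nodal_eval(nb, nb$points)
    expect_lt(max(abs(C - diag(nrow(C)))), 1e-10)
    expect_equal(nrow(nb$points), (p + 1) * (p + 2) / 2)
    # points on edge lambda1 = 0 sit at the 1D Gauss-Lobatto positions
    on_e2 <- which(nb$classify$kind == "edge" & nb$classify$entity == 2)
    gl <- gauss_lobatto_points(p + 1)[2:p]
    expect_equal(unname(sort(nb$bary[on_e2, 3])), sort(gl), tolerance = 1e-12)
  }
  nb1 <- nodal_points(1, 5)
  C1 <- nodal_eval(nb1, nb1$points[, 1])
  expect_lt(max(abs(C1 - diag(6))), 1e-12)
})

test_that("quadrature rules are exact for their stated degree", {
  r1 <- gauss_rule(1, 3)
  expect_equal(sum(r1$weights * r1$points[, 1]^3), 0.25, tolerance = 1e-14)
  r2 <- gauss_rule(2, 2)
  expect_equal(sum(r2$weights), 0.5, tolerance = 1e-14)
  expect_true(all(r2$weights > 0))
  # all barycentric monomials up to degree 8 against the closed form
  r8 <- gauss_rule(2, 8)
  for (a in 0:4) for (b in 0:(4 - a)) {
    v <- sum(r8$weights * r8$bary[, 1]^a * r8$bary[, 2]^b)
    expect_equal(v, bary_monomial_integral(a, b, 0), tolerance = 1e-12,
                 label = sprintf("monomial a=%d b=%d", a, b))
  }
  expect_equal(sum(r8$weights * r8$bary[, 1]^4 * r8$bary[, 2]^4),
               bary_monomial_integral(4, 4, 0), tolerance = 1e-14)
  expect_error(gauss_rule(3, 2), "dimension")
})
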