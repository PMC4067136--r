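# Post-processing: activation detection, conduction velocities, error
# norms and convergence-order estimation.

test_that("activation_time interpolates the first upcrossing", {
  expect_equal(activation_time(c(10, 10.01), c(-1, 1)), 10.005)
  expect_true(is.na(activation_time(c(0, 1, 2), c(-80, -70, -60))))
  # downcrossing only: not an activation
  expect_true(is.na(activation_time(c(0, 1, 2), c(5, 1, -3))))
  expect_error(activation_time(c(1, 1, 2), c(-1, 0, 1)), "increasing")
})

test_that("cv_1d implements 2 cm over the transit time", {
  expect_equal(cv_1d(30, 61), 2 / 31 * 1000, tolerance = 1e-12)
  expect_equal(cv_1d(30, 61) / cv_1d(30, 92), 2, tolerance = 1e-12)
  expect_error(cv_1d(30, 30), "transit")
})

test_that("cv_2d recovers an exact planar wave and is seed-stable", {
  sq <- build_square_mesh(1, 0.05, seed = 1)
  v <- 65          # cm/s
  act <- sq$vertices[, 2] / v * 1000
  for (seed in c(1, 7)) {
    expect_equal(cv_2d(act, sq, n_pairs = 500, seed = seed), v,
                 tolerance = 1e-3)
  }
  # a noisy converged map: two seeds agree to 0.5%
  set.seed(9)
  actn <- act + rnorm(length(act), sd = 0.02)
  c1 <- cv_2d(actn, sq, n_pairs = 800, seed = 1)
  c2 <- cv_2d(actn, sq, n_pairs = 800, seed = 2)
  expect_lt(abs(c1 - c2) / c1, 0.005)
  # constant map: no admissible pairs
  expect_error(cv_2d(rep(5, sq$n_vertices), sq, n_pairs = 100, seed = 1),
               "admissible")
})

test_that("error norms are exact on manufactured differences", {
  mk_sim <- function(mesh, dm, coeff_fun, times) {
    snaps <- sapply(times, coeff_fun)
    structure(list(mesh = mesh, dofmap = dm, p = dm$p, times = times,
                   snapshots = snaps), class = "hp_sim")
  }
  mesh_c <- build_interval_mesh(1, 0.05)
  mesh_r <- build_interval_mesh(1, 0.01)
  dm_c <- dof_map(mesh_c, 2)
  dm_r <- dof_map(mesh_r, 4)
  times <- seq(0, 1, by = 0.25)
  # identical constant fields: zero error
  cf_c <- function(t) {u <- numeric(dm_c$n_dof); u[1:mesh_c$n_vertices] <- 3; u}
  cf_r <- function(t) {u <- numeric(dm_r$n_dof); u[1:mesh_r$n_vertices] <- 3; u}
  en0 <- error_norms(mk_sim(mesh_c, dm_c, cf_c, times),
                     mk_sim(mesh_r, dm_r, cf_r, times))
  expect_lt(en0$Linf_L2, 1e-13)
  expect_lt(en0$L2_H1, 1e-13)
  # constant offset c on a unit-length domain: Linf_L2 = c
  cf_c2 <- function(t) {u <- numeric(dm_c$n_dof); u[1:mesh_c$n_vertices] <- 3.7; u}
  en1 <- error_norms(mk_sim(mesh_c, dm_c, cf_c2, times),
                     mk_sim(mesh_r, dm_r, cf_r, times))
  expect_equal(en1$Linf_L2, 0.7, tolerance = 1e-12)
  expect_equal(en1$L2_H1, 0.7, tolerance = 1e-12)  # H1 of a constant
  # difference sin(pi x) * phi(t): hand-integrated norms
  # ||sin(pi x)||_L2^2 = 1/2, ||pi cos(pi x)||_L2^2 = pi^2/2
  phi <- function(t) 1 + t
  cf_c3 <- function(t) project_l2(mesh_c, dm_c,
                                  function(q) 3 + phi(t) * sin(pi * q[, 1]),
                                  exactness = 20)
  en2 <- error_norms(mk_sim(mesh_c, dm_c, cf_c3, times),
                     mk_sim(mesh_r, dm_r, cf_r, times))
  expect_equal(en2$Linf_L2, 2 * sqrt(1 / 2), tolerance = 1e-4)
  h1_sq <- function(t) phi(t)^2 * (1 / 2 + pi^2 / 2)
  expect_equal(en2$L2_H1, sqrt(pracma::trapz(times, h1_sq(times))),
               tolerance = 1e-3)
})

test_that("convergence_slope recovers synthetic orders", {
  h <- c(0.04, 0.02, 0.01, 0.005)
  expect_equal(convergence_slope(h, h^2), 2, tolerance = 1e-10)
  set.seed(4)
  noisy <- 3 * h^3 * (1 + 0.01 * rnorm(4))
  expect_equal(convergence_slope(h, noisy), 3, tolerance = 0.05)
  expect_error(convergence_slope(c(0.1, 0.1, 0.1), c(1, 1, 1)), "distinct")
  expect_error(convergence_slope(h[1], 0.1), "distinct")
})

test_that("the DOF driver satisfies the counting formula on fixtures", {
  meshes <- list(coarse = build_square_mesh(1, 0.2, seed = 1),
                 holes = build_square_with_holes_mesh(1, target_h = 0.08, seed = 2))
  df <- driver_table5_dofs(meshes)
  ip <- c(0, 0, 1, 3)
  expect_equal(df$n_dofs, df$V + (df$p - 1) * df$E + ip[df$p] * df$T)
  # Euler consistency: chi = 1 for the plain square, -1 with two holes
  sub <- df[df$p == 1, ]
  expect_equal(sub$V[1] - sub$E[1] + sub$T[1], 1)
  expect_equal(sub$V[2] - sub$E[2] + sub$T[2], -1)
})

test_that("the 1D CV driver shows the coarse-mesh overestimate and p-convergence", {
  df <- driver_table1_1d_cv(h_values = c(0.1, 0.02), p_values = c(1, 4),
                            sigmas = 1, budget = "desk")
  cv_coarse_p1 <- df$cv[df$h == 0.1 & df$p == 1]
  cv_fine_p4 <- df$cv[df$h == 0.02 & df$p == 4]
  # linear elements on the coarse mesh overestimate the velocity
  expect_gt(cv_coarse_p1, 1.2 * cv_fine_p4)
  # on a fixed mesh, raising p moves the CV toward the converged value
  cv_coarse_p4 <- df$cv[df$h == 0.1 & df$p == 4]
  expect_lt(abs(cv_coarse_p4 - cv_fine_p4), abs(cv_coarse_p1 - cv_fine_p4))
})
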