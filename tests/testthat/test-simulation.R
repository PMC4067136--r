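# The semi-implicit time loop: system matrix, solver, structural and
# physical invariants, and equivalence with a textbook linear-FEM stepper.

zero_reaction_model <- function() {
  structure(list(name = "null", m = 1L, states = "w", gates = integer(0),
                 u0 = 0, w0 = c(w = 0),
                 rates = function(u) list(alpha = matrix(0, length(u), 0),
                                          beta = matrix(0, length(u), 0)),
                 I_ionic = function(u, W) rep(0, length(u)),
                 g = function(u, W) matrix(0, length(u), 1)),
            class = "cell_model")
}

test_that("the system matrix is SPD and limits to M as dt -> 0", {
  mesh <- build_interval_mesh(1, 0.05)
  dm <- dof_map(mesh, 3)
  M <- assemble_mass(mesh, dm)$M
  A <- assemble_stiffness(mesh, dm, 1)
  cst <- physical_constants()
  K <- system_matrix(M, A, 0.01, cst)
  expect_silent(Matrix::Cholesky(K))
  expect_lt(max(abs(system_matrix(M, A, 1e-12, cst) - M)), 1e-9)
  # constants are in A's kernel: K c = M c
  cvec <- numeric(dm$n_dof); cvec[seq_len(mesh$n_vertices)] <- 1
  expect_equal(as.numeric(K %*% cvec), as.numeric(M %*% cvec),
               tolerance = 1e-12)
})

test_that("linear-block ILU-PCG converges fast and solves accurately", {
  mesh <- build_interval_mesh(2, 0.01)
  dm <- dof_map(mesh, 1)
  K <- system_matrix(assemble_mass(mesh, dm)$M,
                     assemble_stiffness(mesh, dm, 1), 0.01,
                     physical_constants())
  set.seed(1)
  rhs <- rnorm(dm$n_dof)
  x <- ilu_linear_block_pcg(K, rhs, dm, tol = 1e-8)
  expect_lte(attr(x, "iterations"), 30)
  expect_lt(max(abs(K %*% x - rhs)) / max(abs(rhs)), 1e-7)
  # identity sanity: K solve(K, y) = y
  y <- sin(seq_len(dm$n_dof))
  x2 <- ilu_linear_block_pcg(K, y, dm, tol = 1e-12)
  expect_equal(as.numeric(K %*% x2), y, tolerance = 1e-9)
})

test_that("CG iteration counts stay bounded as p grows on a fixed mesh", {
  sq <- build_square_mesh(1, 0.12, seed = 2)
  cst <- physical_constants()
  iters <- sapply(1:4, function(p) {
    dm <- dof_map(sq, p)
    K <- system_matrix(assemble_mass(sq, dm)$M,
                       assemble_stiffness(sq, dm, 1), 0.01, cst)
    set.seed(2)
    x <- ilu_linear_block_pcg(K, rnorm(dm$n_dof), dm, tol = 1e-8)
    attr(x, "iterations")
  })
  # with the linear-block ILU + diagonal completion the cold-started count
  # grows with p but stays within a bounded envelope
  expect_true(all(is.finite(iters)))
  expect_true(all(diff(iters) >= 0) || iters[4] < 100)
  expect_lte(iters[4], 50 * iters[1])
})

test_that("a spatially uniform state with zero current is a fixed point", {
  mesh <- build_interval_mesh(1, 0.1)
  cfg <- solver_config(p = 3, dt = 0.05, t_end = 1, p_tilde = 4,
                       solver = "cholesky")
  st <- make_stepper(mesh, zero_reaction_model(), 1, NULL,
                     physical_constants(), cfg)
  u <- numeric(st$ops$dofmap$n_dof)
  u[seq_len(mesh$n_vertices)] <- 7.5
  W <- matrix(0, st$ops$ndmap$n_nodes, 1)
  out <- semi_implicit_step(st, u, W, 0)
  expect_equal(out$u, u, tolerance = 1e-13)
})

test_that("pure diffusion decays like the backward-Euler amplification factor", {
  # u0 = cos(pi x / L) is a Neumann eigenmode; per step the discrete
  # solution contracts by 1 / (1 + dt D (pi/L)^2) as h -> 0
  L <- 1
  mesh <- build_interval_mesh(L, 0.005)
  cfg <- solver_config(p = 2, dt = 0.05, t_end = 1, p_tilde = 2,
                       solver = "cholesky")
  cst <- physical_constants(C_m = 1, beta = 1400)
  sigma <- 1
  D <- 10 * sigma / (cst$beta * cst$C_m)
  st <- make_stepper(mesh, zero_reaction_model(), sigma, NULL, cst, cfg)
  u <- project_l2(mesh, st$ops$dofmap, function(q) cos(pi * q[, 1] / L))
  W <- matrix(0, st$ops$ndmap$n_nodes, 1)
  amp_pred <- 1 / (1 + cfg$dt * D * (pi / L)^2)
  for (s in 1:3) {
    out <- semi_implicit_step(st, u, W, (s - 1) * cfg$dt)
    # track the mode amplitude at x = 0, where cos(pi x/L) = 1
    expect_equal(out$u[1] / u[1], amp_pred, tolerance = 1e-6)
    u <- out$u; W <- out$W
  }
  # conservation: the M-weighted mean is invariant (1^T A = 0)
  u0 <- project_l2(mesh, st$ops$dofmap, function(q) q[, 1]^2)
  ones <- numeric(st$ops$dofmap$n_dof); ones[seq_len(mesh$n_vertices)] <- 1
  m0 <- sum(ones * as.numeric(st$ops$M %*% u0))
  uu <- u0
  for (s in 1:5) uu <- semi_implicit_step(st, uu, W, 0)$u
  m1 <- sum(ones * as.numeric(st$ops$M %*% uu))
  expect_equal(m1, m0, tolerance = 1e-10)
})

test_that("the p = 1 scheme matches a textbook linear-FEM stepper", {
  mesh <- build_interval_mesh(1, 0.1)   # 10 elements
  model <- lr91_noble_form()
  cst <- physical_constants(beta = 2000)
  sigma <- 0.5
  stim <- stimulus_ramp(list(type = "interval_end", width = 0.25),
                        onset = 0, ramp_duration = 2, amplitude = 60)
  cfg <- solver_config(p = 1, dt = 0.01, t_end = 1, p_tilde = 1,
                       solver = "cholesky")
  st <- make_stepper(mesh, model, sigma, stim, cst, cfg)
  # textbook oracle: dense tridiagonal matrices, nodal reaction
  oracle <- textbook_stepper_1d(mesh$vertices[, 1], sigma, cst$C_m, cst$beta)
  stim_fun <- function(x, t) {
    monodomainhp:::stimulus_value(stim, t) *
      monodomainhp:::stimulus_mask(stim, matrix(x, ncol = 1))
  }
  u1 <- numeric(mesh$n_vertices) + model$u0
  W1 <- matrix(rep(model$w0, each = mesh$n_vertices), mesh$n_vertices)
  u2 <- u1; W2 <- W1
  for (s in 1:50) {
    t <- (s - 1) * cfg$dt
    r1 <- semi_implicit_step(st, u1, W1, t)
    r2 <- oracle(u2, W2, t, cfg$dt, model, stim_fun)
    u1 <- r1$u; W1 <- r1$W; u2 <- r2$u; W2 <- r2$W
    expect_lt(max(abs(u1 - u2)), 1e-10)
  }
})

test_that("subthreshold stimuli do not propagate", {
  mesh <- build_interval_mesh(1, 0.02)
  cfg <- solver_config(p = 2, dt = 0.01, t_end = 10, p_tilde = 4)
  expect_warning(
    sim <- run_simulation(mesh, lr91_noble_form(), 1,
                          stimulus_ramp(list(type = "interval_end", width = 0.05),
                                        amplitude = 3),
                          physical_constants(), cfg),
    "no activation")
  outside <- mesh$vertices[, 1] > 0.1
  expect_true(all(is.na(sim$activation[outside])))
})

test_that("activation is causal and CV scales as sqrt(sigma)", {
  mesh <- build_interval_mesh(2, 0.01)
  run1 <- function(sigma) {
    cfg <- solver_config(p = 2, dt = 0.01, t_end = 60, p_tilde = 4)
    probe <- which.min(abs(mesh$vertices[, 1] - 1.6))
    suppressWarnings(run_simulation(
      mesh, lr91_noble_form(), sigma,
      stimulus_ramp(list(type = "interval_end", width = 0.05)),
      physical_constants(), cfg, stop_after = probe))
  }
  s1 <- run1(0.5)
  act <- s1$activation
  ok <- which(!is.na(act) & mesh$vertices[, 1] >= 0.1)
  expect_true(all(diff(act[ok]) > -1e-9))  # monotone with distance
  cv1 <- (1.5 - 0.5) / (activation_at(s1, 1.5) - activation_at(s1, 0.5)) * 1000
  s2 <- run1(1.0)
  cv2 <- (1.5 - 0.5) / (activation_at(s2, 1.5) - activation_at(s2, 0.5)) * 1000
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.03)
})

test_that("halving dt changes the solution at first order (self-convergence)", {
  mesh <- build_interval_mesh(1, 0.02)
  run_dt <- function(dt) {
    cfg <- solver_config(p = 2, dt = dt, t_end = 8, p_tilde = 4,
                         solver = "cholesky", snapshot_dt = 8)
    suppressWarnings(run_simulation(
      mesh, lr91_noble_form(), 0.5,
      stimulus_ramp(list(type = "interval_end", width = 0.1)),
      physical_constants(), cfg))
  }
  u1 <- run_dt(0.01)
  u2 <- run_dt(0.005)
  u3 <- run_dt(0.0025)
  V <- mesh$n_vertices
  d12 <- max(abs(u1$snapshots[1:V, ncol(u1$snapshots)] -
                   u2$snapshots[1:V, ncol(u2$snapshots)]))
  d23 <- max(abs(u2$snapshots[1:V, ncol(u2$snapshots)] -
                   u3$snapshots[1:V, ncol(u3$snapshots)]))
  expect_equal(d12 / d23, 2, tolerance = 0.35)  # order-1 Richardson ratio
})
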