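# The coupled monodomain time loop: semi-implicit backward Euler for the
# transmembrane potential (diffusion implicit, reaction explicit), nodal
# cell-state update, nodal-to-hierarchical change of basis and matrix-based
# right-hand-side assembly, solved by ILU-preconditioned CG.

# Unit conversion: with u in mV, x in cm, t in ms, C_m in uF/cm^2, beta in
# 1/cm and currents in uA/cm^2, a conductivity given in S/m contributes
# (1/beta) * 10 * sigma[S/m] * Laplacian(u) in uA/cm^2.
sigma_unit_factor <- function() 10

#' Physical constants of the monodomain model
#'
#' @param C_m membrane capacitance (uF/cm^2).
#' @param beta surface-to-volume ratio (1/cm). The absolute conduction
#'   velocity scales as `sqrt(sigma / (beta * C_m))`; `beta` is the single
#'   scalar calibrated against a reference conduction velocity when
#'   absolute speeds matter.
#' @export
physical_constants <- function(C_m = 1, beta = 1400) {
  if (C_m <= 0 || beta <= 0) stop("C_m and beta must be positive")
  list(C_m = C_m, beta = beta)
}

#' Ramp stimulus
#'
#' Current density applied in a spatial region with a linear ramp in time:
#' zero before `onset`, rising linearly to `amplitude` over
#' `ramp_duration`, then off.
#'
#' @param region one of `list(type = "interval_end", width = )` (1D),
#'   `list(type = "strip", depth = )` (2D bottom strip),
#'   `list(type = "disc", center = , radius = )`, or a function
#'   `function(pts)` returning a spatial weight in `[0, 1]`. Region lists
#'   accept an optional `taper`: the spatial profile then falls linearly
#'   from 1 to 0 over the last `taper` cm of the region, making the
#'   current continuous in space (with the kinks placeable on element
#'   boundaries, which convergence studies need: a jump-edged region is
#'   represented differently by every mesh's nodal interpolation).
#' @param onset stimulus onset (ms).
#' @param ramp_duration ramp length (ms).
#' @param amplitude peak current density (uA/cm^2), depolarising-positive.
#' @export
stimulus_ramp <- function(region, onset = 0, ramp_duration = 2, amplitude = 80) {
  structure(list(region = region, onset = onset, ramp_duration = ramp_duration,
                 amplitude = amplitude),
            class = "hp_stimulus")
}

# linear shoulder: 1 inside, falling to 0 over [edge - taper, edge]
taper_profile <- function(d, edge, taper) {
  if (is.null(taper) || taper <= 0) return(as.numeric(d <= edge))
  pmin(1, pmax(0, (edge - d) / taper))
}

stimulus_mask <- function(stimulus, pts) {
  region <- stimulus$region
  if (is.function(region)) return(as.numeric(region(pts)))
  switch(region$type,
         interval_end = taper_profile(pts[, 1L], region$width, region$taper),
         strip = taper_profile(pts[, 2L], region$depth, region$taper),
         disc = taper_profile(sqrt((pts[, 1L] - region$center[1L])^2 +
                                     (pts[, 2L] - region$center[2L])^2),
                              region$radius, region$taper),
         stop("unknown stimulus region type"))
}

stimulus_value <- function(stimulus, t) {
  dt0 <- t - stimulus$onset
  if (dt0 >= 0 && dt0 < stimulus$ramp_duration) {
    stimulus$amplitude * dt0 / stimulus$ramp_duration
  } else 0
}

#' Solver configuration
#'
#' @param p hierarchical degree for the transmembrane potential (1..4).
#' @param dt time step (ms).
#' @param t_end end time (ms).
#' @param p_tilde nodal degree for the cell state and interpolated current
#'   (default 4). The full convergence order requires `p_tilde >= p`;
#'   smaller values are allowed (with a warning) for diagnostic runs that
#'   demonstrate the resulting quadratic convergence ceiling.
#' @param tol CG relative residual tolerance.
#' @param solver `"pcg-ilu"` (linear-block ILU preconditioned CG, default)
#'   or `"cholesky"` (sparse direct factorisation, refactored once).
#' @param cell_method state integrator, see [step_states()].
#' @param snapshot_dt interval between stored field snapshots (ms; `NA`
#'   stores only the final field).
#' @param ionic_state `"updated"` evaluates the ionic current at
#'   (u_n, w_{n+1}) (default); `"previous"` uses w_n.
#' @param max_cg_iter CG iteration cap.
#' @param seed RNG seed recorded with the run.
#' @export
solver_config <- function(p, dt, t_end, p_tilde = 4L, tol = 1e-8,
                          solver = c("pcg-ilu", "cholesky"),
                          cell_method = "fe", snapshot_dt = NA,
                          ionic_state = c("updated", "previous"),
                          max_cg_iter = 2000L, seed = 1L) {
  if (p < 1L || p > 4L) stop("p must be in 1..4")
  if (dt <= 0) stop("dt must be positive")
  if (p_tilde < p) warning("p_tilde < p limits convergence to second order")
  list(p = as.integer(p), dt = dt, t_end = t_end, p_tilde = as.integer(p_tilde),
       tol = tol, solver = match.arg(solver), cell_method = cell_method,
       snapshot_dt = snapshot_dt, ionic_state = match.arg(ionic_state),
       max_cg_iter = as.integer(max_cg_iter), seed = as.integer(seed))
}

#' System matrix of the semi-implicit scheme
#'
#' Backward-Euler system matrix `K = M + dt/(beta C_m) A` (with the S/m ->
#' uA-units conversion folded into the stiffness scaling); symmetric
#' positive definite.
#'
#' @param M,A assembled mass and stiffness.
#' @param dt time step (ms).
#' @param constants from [physical_constants()].
#' @export
system_matrix <- function(M, A, dt, constants) {
  M + (dt * sigma_unit_factor() / (constants$beta * constants$C_m)) * A
}

#' Assemble all operators for a monodomain run
#'
#' @param mesh an `hp_mesh`.
#' @param p,p_tilde hierarchical and nodal degrees.
#' @param conductivity a `conductivity_field` or scalar (S/m).
#' @return object of class `hp_operators` bundling dof maps, nodal map,
#'   mass/stiffness/rectangular mass, the nodal evaluation matrix and the
#'   nodal-to-hierarchical transform.
#' @export
assemble_operators <- function(mesh, p, p_tilde, conductivity) {
  dofmap <- dof_map(mesh, p)
  dofmap_pt <- if (p_tilde == p) dofmap else dof_map(mesh, p_tilde)
  ndmap <- nodal_map(mesh, p_tilde)
  mm <- assemble_mass(mesh, dofmap, dofmap_pt)
  A <- assemble_stiffness(mesh, dofmap, conductivity)
  Tg <- nodal_to_hierarchical_matrix(mesh, dofmap_pt, ndmap)
  E <- nodal_evaluation_matrix(mesh, dofmap, ndmap)
  structure(list(mesh = mesh, dofmap = dofmap, dofmap_pt = dofmap_pt,
                 ndmap = ndmap, M = mm$M, Mtilde = mm$Mtilde, A = A,
                 Tg = Tg, E = E, conductivity = conductivity),
            class = "hp_operators")
}

#' @export
print.hp_operators <- function(x, ...) {
  cat(sprintf("Assembled operators: p = %d, p-tilde = %d, N = %d, %d nodal points\n",
              x$dofmap$p, x$dofmap_pt$p, x$dofmap$n_dof, x$ndmap$n_nodes))
  invisible(x)
}

# Internal: everything the inner loop needs, built once.
prepare_stepper <- function(ops, model, stimulus, constants, config) {
  K <- system_matrix(ops$M, ops$A, config$dt, constants)
  solver <- config$solver
  if (solver == "pcg-ilu") {
    setup <- ilu_pcg_setup(K, ops$dofmap$n_vertices)
    solve_K <- function(rhs, x0) {
      ilu_pcg_solve(setup, rhs, x0 = x0, tol = config$tol,
                    maxit = config$max_cg_iter)
    }
  } else {
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(K), "CsparseMatrix"),
                           LDL = FALSE)
    solve_K <- function(rhs, x0) {
      structure(as.numeric(Matrix::solve(ch, rhs)), iterations = 0L)
    }
  }
  mask <- if (is.null(stimulus)) numeric(ops$ndmap$n_nodes) else
    stimulus_mask(stimulus, ops$ndmap$points)
  list(ops = ops, model = model, stimulus = stimulus, constants = constants,
       config = config, K = K, solve_K = solve_K, mask = mask)
}

#' One semi-implicit backward-Euler step
#'
#' Per step: (1) evaluate u_n at the nodal points; (2) advance the cell
#' state at each point; (3) evaluate the total current at the nodal
#' points; (4) change basis nodal -> hierarchical; (5) assemble the right-
#' hand side `M u_n + dt/C_m * Mtilde coeffs`; (6) solve `K u = rhs`.
#'
#' @param stepper state from `prepare_stepper` (built by
#'   [run_simulation()]; exposed for scheme-equivalence testing via
#'   [make_stepper()]).
#' @param u hierarchical coefficients at time t.
#' @param W nodal cell-state matrix at time t.
#' @param t current time (ms); the step advances to `t + dt`.
#' @return list with updated `u`, `W` and the CG iteration count.
#' @export
semi_implicit_step <- function(stepper, u, W, t) {
  cfg <- stepper$config
  ops <- stepper$ops
  dt <- cfg$dt
  u_nodal <- as.numeric(ops$E %*% u)
  if (!is.null(stepper$model$fused_step) && cfg$ionic_state == "updated" &&
      cfg$cell_method %in% c("fe", "rl")) {
    fs <- stepper$model$fused_step(u_nodal, W, dt, cfg$cell_method)
    W_new <- fs$W
    I_tot <- fs$I
  } else {
    W_new <- step_states(stepper$model, u_nodal, W, dt, method = cfg$cell_method)
    W_eval <- if (cfg$ionic_state == "updated") W_new else W
    I_tot <- stepper$model$I_ionic(u_nodal, W_eval)
  }
  if (!is.null(stepper$stimulus)) {
    sv <- stimulus_value(stepper$stimulus, t + dt)
    if (sv != 0) I_tot <- I_tot + sv * stepper$mask
  }
  coeffs <- as.numeric(ops$Tg %*% I_tot)
  rhs <- as.numeric(ops$M %*% u) +
    (dt / stepper$constants$C_m) * as.numeric(ops$Mtilde %*% coeffs)
  sol <- stepper$solve_K(rhs, u)
  if (any(!is.finite(sol))) stop("non-finite potential after linear solve")
  list(u = as.numeric(sol), W = W_new,
       iterations = attr(sol, "iterations"))
}

#' Build a stepper for manual time stepping
#'
#' Assembles operators and the linear solver for repeated calls to
#' [semi_implicit_step()]; [run_simulation()] is the loop most callers
#' want.
#'
#' @inheritParams run_simulation
#' @export
make_stepper <- function(mesh, model, conductivity, stimulus, constants, config) {
  ops <- assemble_operators(mesh, config$p, config$p_tilde, conductivity)
  prepare_stepper(ops, model, stimulus, constants, config)
}

#' Run a monodomain simulation
#'
#' Loops the semi-implicit scheme from 0 to `t_end`, recording per-vertex
#' activation times (first linearly interpolated upcrossing of 0 mV) and
#' field snapshots.
#'
#' @param mesh an `hp_mesh`.
#' @param model a `cell_model`.
#' @param conductivity a `conductivity_field` or scalar (S/m).
#' @param stimulus an `hp_stimulus`, or `NULL`.
#' @param constants from [physical_constants()].
#' @param config from [solver_config()].
#' @param stop_after optional vertex ids: the run stops once all of them
#'   have activated.
#' @param verbose print progress every 1000 steps.
#' @return object of class `hp_sim`: snapshot `times` and coefficient
#'   matrix `snapshots` (one column per time), per-vertex `activation`
#'   times (ms, `NA` if never), CG iteration diagnostics, and the
#'   ingredients needed for post-processing.
#' @export
run_simulation <- function(mesh, model, conductivity, stimulus, constants,
                           config, stop_after = NULL, verbose = FALSE) {
  set.seed(config$seed)
  stepper <- make_stepper(mesh, model, conductivity, stimulus, constants, config)
  ops <- stepper$ops
  V <- mesh$n_vertices
  nstep <- round(config$t_end / config$dt)
  dt <- config$dt
  u <- numeric(ops$dofmap$n_dof)
  u[seq_len(V)] <- model$u0
  W <- matrix(rep(model$w0, each = ops$ndmap$n_nodes), ops$ndmap$n_nodes,
              model$m)
  snap_stride <- if (is.na(config$snapshot_dt)) nstep + 1L else
    max(1L, round(config$snapshot_dt / dt))
  snaps <- matrix(0, ops$dofmap$n_dof, nstep %/% snap_stride + 2L)
  snap_times <- numeric(ncol(snaps))
  snaps[, 1L] <- u
  ks <- 1L
  activation <- rep(NA_real_, V)
  iters <- integer(nstep)
  uv_old <- u[seq_len(V)]
  t <- 0
  last_step <- nstep
  for (s in seq_len(nstep)) {
    st <- semi_implicit_step(stepper, u, W, t)
    u <- st$u; W <- st$W
    iters[s] <- st$iterations
    t <- s * dt
    uv <- u[seq_len(V)]
    idx <- which(is.na(activation) & uv_old < 0 & uv >= 0)
    if (length(idx)) {
      activation[idx] <- (t - dt) + dt * (0 - uv_old[idx]) / (uv[idx] - uv_old[idx])
    }
    uv_old <- uv
    if (s %% snap_stride == 0L || s == nstep) {
      ks <- ks + 1L
      if (ks <= ncol(snaps)) {
        snaps[, ks] <- u
        snap_times[ks] <- t
      }
    }
    if (verbose && s %% 1000L == 0L) {
      message(sprintf("t = %.2f ms, CG iterations %d, max u = %.1f mV",
                      t, st$iterations, max(uv)))
    }
    if (!is.null(stop_after) && all(!is.na(activation[stop_after]))) {
      last_step <- s
      break
    }
  }
  keep <- seq_len(ks)
  if (!is.null(stimulus)) {
    outside <- stimulus_mask_vertices(stepper) == 0
    if (any(outside) && all(is.na(activation[outside]))) {
      warning("no activation outside the stimulated region (propagation failure?)")
    }
  }
  structure(list(mesh = mesh, dofmap = ops$dofmap, ndmap = ops$ndmap,
                 p = config$p, p_tilde = config$p_tilde, dt = dt,
                 times = snap_times[keep], snapshots = snaps[, keep, drop = FALSE],
                 activation = activation, cg_iterations = iters[seq_len(last_step)],
                 config = config, constants = constants,
                 model_name = model$name, t_final = t),
            class = "hp_sim")
}

stimulus_mask_vertices <- function(stepper) {
  if (is.null(stepper$stimulus)) return(numeric(stepper$ops$mesh$n_vertices))
  pts <- stepper$ops$mesh$vertices
  stimulus_mask(stepper$stimulus, pts)
}

#' @export
print.hp_sim <- function(x, ...) {
  cat(sprintf("Monodomain simulation: %s, p = %d, p-tilde = %d, dt = %g ms\n",
              x$model_name, x$p, x$p_tilde, x$dt))
  cat(sprintf("  %dD mesh, %d DOFs, ran to t = %g ms\n",
              x$mesh$dimension, x$dofmap$n_dof, x$t_final))
  na <- sum(!is.na(x$activation))
  cat(sprintf("  %d/%d vertices activated", na, length(x$activation)))
  if (na) cat(sprintf(" (first %.3f ms, last %.3f ms)",
                      min(x$activation, na.rm = TRUE),
                      max(x$activation, na.rm = TRUE)))
  cat("\n")
  if (length(x$cg_iterations) && any(x$cg_iterations > 0)) {
    cat(sprintf("  CG iterations per step: mean %.1f, max %d\n",
                mean(x$cg_iterations), max(x$cg_iterations)))
  }
  invisible(x)
}

#' @export
plot.hp_sim <- function(x, ...) {
  if (x$mesh$dimension == 1L) {
    V <- x$mesh$n_vertices
    graphics::matplot(x$mesh$vertices[, 1L],
                      x$snapshots[seq_len(V), , drop = FALSE],
                      type = "l", lty = 1, xlab = "x (cm)", ylab = "u (mV)",
                      main = "Transmembrane potential snapshots", ...)
  } else {
    act <- x$activation
    cols <- grDevices::hcl.colors(64, "viridis")
    ci <- cols[cut(act, 64, labels = FALSE)]
    plot(x$mesh$vertices, col = ci, pch = 16, cex = 0.5, asp = 1,
         xlab = "x (cm)", ylab = "y (cm)", main = "Activation time (ms)", ...)
  }
  invisible(x)
}
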