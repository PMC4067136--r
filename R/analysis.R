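# Post-processing: activation times, conduction velocities (1D node-pair
# and 2D random-pair), error norms against reference solutions, observed
# convergence orders, and the surface-to-volume calibration.

#' Activation time of a potential trace
#'
#' First upcrossing of 0 mV, linearly interpolated between the straddling
#' samples; `NA` if the trace never crosses upwards.
#'
#' @param t strictly increasing sample times (ms).
#' @param u potential samples (mV).
#' @export
activation_time <- function(t, u) {
  if (is.unsorted(t, strictly = TRUE)) stop("sample times must be strictly increasing")
  i <- which(u[-length(u)] < 0 & u[-1L] >= 0)
  if (!length(i)) return(NA_real_)
  i <- i[1L]
  t[i] + (t[i + 1L] - t[i]) * (0 - u[i]) / (u[i + 1L] - u[i])
}

#' 1D conduction velocity between the 2 cm and 4 cm nodes
#'
#' @param t_at_2cm,t_at_4cm activation times (ms).
#' @return conduction velocity in cm/s.
#' @export
cv_1d <- function(t_at_2cm, t_at_4cm) {
  if (!is.finite(t_at_2cm) || !is.finite(t_at_4cm) || t_at_4cm <= t_at_2cm)
    stop("non-positive transit time")
  2 / (t_at_4cm - t_at_2cm) * 1000
}

# Activation time at the mesh vertex nearest a coordinate.
activation_at <- function(sim, x, y = NULL) {
  v <- sim$mesh$vertices
  d <- if (is.null(y)) abs(v[, 1L] - x) else (v[, 1L] - x)^2 + (v[, 2L] - y)^2
  sim$activation[which.min(d)]
}

#' 1D conduction velocity of a simulation
#'
#' @param sim an `hp_sim` on an interval mesh.
#' @param x1,x2 probe coordinates (cm), defaults 2 and 4.
#' @export
cv_from_sim_1d <- function(sim, x1 = 2, x2 = 4) {
  t1 <- activation_at(sim, x1)
  t2 <- activation_at(sim, x2)
  abs(x2 - x1) / (t2 - t1) * 1000
}

#' Random-pair conduction velocity of a 2D planar wave
#'
#' Averages `|delta coordinate| / delta t` over randomly selected vertex
#' pairs, where the propagation coordinate is the axis perpendicular to
#' the stimulated edge. Pairs need a coordinate separation of at least
#' `min_sep` and an activation-time difference of at least `min_dt`.
#'
#' @param activation per-vertex activation times (ms), or an `hp_sim`.
#' @param mesh the mesh (ignored when `activation` is an `hp_sim`).
#' @param n_pairs number of admissible pairs to average.
#' @param seed RNG seed (sampling is deterministic per seed).
#' @param axis propagation coordinate (2 = y, for a wave from the bottom
#'   edge).
#' @param min_sep,min_dt admissibility thresholds (cm, ms).
#' @return mean pair velocity in cm/s.
#' @export
cv_2d <- function(activation, mesh = NULL, n_pairs = 1000L, seed = 1L,
                  axis = 2L, min_sep = 0.2, min_dt = 0.5) {
  if (inherits(activation, "hp_sim")) {
    mesh <- activation$mesh
    activation <- activation$activation
  }
  ok <- which(!is.na(activation))
  coord <- mesh$vertices[, axis]
  set.seed(seed)
  got <- 0L; total <- 0
  tries <- 0L
  cvs <- numeric(n_pairs)
  while (got < n_pairs && tries < 200L) {
    tries <- tries + 1L
    a <- sample(ok, n_pairs, replace = TRUE)
    b <- sample(ok, n_pairs, replace = TRUE)
    dx <- abs(coord[a] - coord[b])
    dt <- abs(activation[a] - activation[b])
    adm <- which(dx >= min_sep & dt >= min_dt)
    if (length(adm)) {
      take <- adm[seq_len(min(length(adm), n_pairs - got))]
      cvs[got + seq_along(take)] <- dx[take] / dt[take] * 1000
      got <- got + length(take)
    }
  }
  if (got < 10L) stop("fewer than 10 admissible vertex pairs")
  mean(cvs[seq_len(got)])
}

# ---------------------------------------------------------------------------
# Error norms and convergence orders

#' Error norms between a coarse and a reference 1D simulation
#'
#' Evaluates both solutions at the quadrature points of the reference mesh
#' at all common snapshot times and reduces: `Linf_L2` is the maximum over
#' time of the spatial L2 error; `L2_H1` is the L2-in-time norm (trapezoid
#' rule) of the spatial H1 (Sobolev) error.
#'
#' @param sim,sim_ref `hp_sim` objects on the same 1D domain with nested
#'   snapshot times.
#' @return list with `Linf_L2`, `L2_H1` and the per-time norms.
#' @export
error_norms <- function(sim, sim_ref) {
  if (sim$mesh$dimension != 1L) stop("error norms are implemented for 1D studies")
  if (abs(diff(range(sim$mesh$vertices)) - diff(range(sim_ref$mesh$vertices))) > 1e-12)
    stop("incompatible domains")
  tc <- round(sim$times, 9); tr <- round(sim_ref$times, 9)
  common <- intersect(tc, tr)
  if (length(common) < 2L) stop("need at least two common snapshot times")
  ic <- match(common, tc); ir <- match(common, tr)
  quad <- gauss_rule(1L, 2L * max(sim$p, sim_ref$p) + 2L)
  geo <- element_geometry(sim_ref$mesh)
  pts <- map_points_to_elements(sim_ref$mesh, quad$points)[, 1L]
  w <- rep(quad$weights, times = sim_ref$mesh$n_elements) *
    rep(geo$h, each = length(quad$weights))
  Ec <- point_evaluation_matrix_1d(sim$mesh, sim$dofmap, pts)
  Er <- point_evaluation_matrix_1d(sim_ref$mesh, sim_ref$dofmap, pts)
  Dc <- point_evaluation_matrix_1d(sim$mesh, sim$dofmap, pts, derivative = TRUE)
  Dr <- point_evaluation_matrix_1d(sim_ref$mesh, sim_ref$dofmap, pts, derivative = TRUE)
  nT <- length(common)
  l2 <- numeric(nT); h1 <- numeric(nT)
  for (k in seq_len(nT)) {
    d <- as.numeric(Ec %*% sim$snapshots[, ic[k]]) -
      as.numeric(Er %*% sim_ref$snapshots[, ir[k]])
    dd <- as.numeric(Dc %*% sim$snapshots[, ic[k]]) -
      as.numeric(Dr %*% sim_ref$snapshots[, ir[k]])
    l2[k] <- sqrt(sum(w * d^2))
    h1[k] <- sqrt(sum(w * d^2) + sum(w * dd^2))
  }
  l2h1 <- sqrt(pracma::trapz(common, h1^2))
  list(Linf_L2 = max(l2), L2_H1 = l2h1, times = common, l2_t = l2, h1_t = h1)
}

#' Observed convergence order
#'
#' Least-squares slope of log(error) against log(h).
#'
#' @param h element sizes (at least 3 distinct values).
#' @param error matching positive error values.
#' @export
convergence_slope <- function(h, error) {
  if (length(unique(h)) < 3L) stop("need at least 3 distinct h values")
  if (any(error <= 0)) stop("errors must be positive")
  unname(stats::coef(stats::lm(log(error) ~ log(h)))[2L])
}

# ---------------------------------------------------------------------------
# Conduction-velocity protocols

#' Run the 6 cm 1D conduction-velocity protocol
#'
#' Ramp stimulus at one end; stops shortly after the 4 cm node activates.
#'
#' @param sigma conductivity (S/m).
#' @param h element size (cm).
#' @param p basis degree.
#' @param beta surface-to-volume ratio (1/cm).
#' @param dt time step (ms).
#' @param model cell model (default Noble-form LR91).
#' @param t_max latest time to simulate to (ms).
#' @param length domain length (cm).
#' @param ... passed to [solver_config()].
#' @return the `hp_sim`.
#' @export
run_cv_protocol_1d <- function(sigma, h, p, beta, dt = 0.01,
                               model = lr91_noble_form(), t_max = 500,
                               length = 6, ...) {
  mesh <- build_interval_mesh(length, h)
  probe <- which.min(abs(mesh$vertices[, 1L] - 4))
  cfg <- solver_config(p = p, dt = dt, t_end = t_max, ...)
  run_simulation(mesh, model, sigma,
                 stimulus_ramp(list(type = "interval_end", width = 0.05)),
                 physical_constants(beta = beta), cfg,
                 stop_after = probe)
}

#' Calibrate the surface-to-volume ratio against a reference velocity
#'
#' The conduction velocity scales exactly as `sqrt(1/beta)` at fixed
#' conductivity and time step (rescaling space maps the monodomain
#' equation onto itself), so a single converged run determines the scalar
#' `beta` that reproduces a target velocity; one confirmation run refines
#' it.
#'
#' @param target_cv target conduction velocity (cm/s).
#' @param sigma conductivity of the calibration run (S/m).
#' @param h,p,dt discretisation of the calibration run.
#' @param beta0 starting value (1/cm).
#' @param model cell model.
#' @param max_iter at most this many runs.
#' @return list with `beta`, the achieved `cv` and the number of runs.
#' @export
calibrate_beta <- function(target_cv = 64.52, sigma = 1, h = 0.01, p = 4,
                           dt = 0.01, beta0 = 1400, model = lr91_noble_form(),
                           max_iter = 3L) {
  beta <- beta0
  cv <- NA_real_
  for (k in seq_len(max_iter)) {
    sim <- run_cv_protocol_1d(sigma, h, p, beta, dt, model = model)
    cv <- cv_from_sim_1d(sim)
    if (abs(cv - target_cv) / target_cv < 5e-4) break
    beta <- beta * (cv / target_cv)^2
  }
  list(beta = beta, cv = cv, runs = k)
}
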