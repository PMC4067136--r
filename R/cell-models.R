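# Ionic cell models: the Luo-Rudy phase-I (1991) ventricular model in its
# standard form and in a continuity-repaired (Noble-form) variant, and the
# two-variable FitzHugh-Nagumo caricature.
#
# Units: potential mV, time ms, currents uA/cm^2, concentrations mM.
# Sign convention: I_ionic(u, w) is returned depolarising-positive, i.e.
# C_m du/dt = I_ionic + I_stim for an isolated membrane patch.

lr91_constants <- function() {
  RTF <- 8314.0 * 310.0 / 96484.6   # RT/F in mV
  Ko <- 5.4; Ki <- 145; Nao <- 140; Nai <- 18
  PR_NaK <- 0.01833
  list(
    RTF = RTF, Ko = Ko, Ki = Ki,
    g_Na = 23, E_Na = RTF * log(Nao / Nai),
    g_K = 0.282 * sqrt(Ko / 5.4),
    E_K = RTF * log((Ko + PR_NaK * Nao) / (Ki + PR_NaK * Nai)),
    g_K1 = 0.6047 * sqrt(Ko / 5.4),
    E_K1 = RTF * log(Ko / Ki),
    g_Kp = 0.0183, g_b = 0.03921, E_b = -59.87
  )
}

# Resting state of the quiescent LR91 cell.
lr91_initial_state <- function() {
  list(u0 = -84.3801107371,
       w0 = c(m = 0.00171338077730188, h = 0.982660523699656,
              j = 0.989108212766685, d = 0.00302126301779861,
              f = 0.999967936476325, X = 0.0417603108167287,
              Cai = 0.00017948816388306))
}

# exp-ratio x / (1 - exp(-a x)) with its removable singularity at x = 0
expm1_ratio <- function(x, a) {
  out <- x / (1 - exp(-a * x))
  small <- abs(x) < 1e-7
  if (any(small)) out[small] <- 1 / a + x[small] / 2
  out
}

# All twelve LR91 gate transition rates (per ms) at potentials V (mV).
# form = "standard" keeps the published piecewise h/j rates switching at
# -40 mV; form = "noble" blends the two analytic branches with a logistic
# switch s(V) = 1/(1 + exp(-(V + 40)/k)), k = blend_width/4.
lr91_rates <- function(V, form = c("standard", "noble"), blend_width = 1) {
  form <- match.arg(form)
  n <- length(V)
  a_m <- 0.32 * expm1_ratio(V + 47.13, 0.1)
  b_m <- 0.08 * exp(-V / 11)
  # h and j: the two fitted branches
  a_h_lo <- 0.135 * exp(-(80 + V) / 6.8)
  a_h_hi <- rep(0, n)
  b_h_lo <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
  b_h_hi <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
  a_j_lo <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
    (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
  a_j_hi <- rep(0, n)
  b_j_lo <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  b_j_hi <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  if (form == "standard") {
    lo <- V < -40
    a_h <- ifelse(lo, a_h_lo, a_h_hi)
    b_h <- ifelse(lo, b_h_lo, b_h_hi)
    a_j <- ifelse(lo, a_j_lo, a_j_hi)
    b_j <- ifelse(lo, b_j_lo, b_j_hi)
  } else {
    s <- stats::plogis((V + 40) / (blend_width / 4))
    sm <- 1 - s
    a_h <- sm * a_h_lo + s * a_h_hi
    b_h <- sm * b_h_lo + s * b_h_hi
    a_j <- sm * a_j_lo + s * a_j_hi
    b_j <- sm * b_j_lo + s * b_j_hi
  }
  a_d <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  b_d <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  a_f <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  b_f <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  a_X <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  b_X <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))
  list(alpha = cbind(m = a_m, h = a_h, j = a_j, d = a_d, f = a_f, X = a_X),
       beta = cbind(m = b_m, h = b_h, j = b_j, d = b_d, f = b_f, X = b_X))
}

# Time-dependent potassium inactivation Xi (algebraic, not a gate).
lr91_Xi <- function(V) {
  x <- V + 77
  num <- exp(0.04 * x) - 1
  out <- 2.837 * num / (x * exp(0.04 * (V + 35)))
  small <- abs(x) < 1e-7
  if (any(small)) out[small] <- 2.837 * 0.04 / exp(0.04 * (V[small] + 35))
  out[V <= -100] <- 1
  out
}

lr91_currents <- function(V, W, cst) {
  Cai <- W[, 7L]
  if (any(Cai <= 0)) stop("non-positive intracellular calcium in slow-inward reversal")
  E_si <- 7.7 - 13.0287 * log(Cai)
  i_Na <- cst$g_Na * W[, 1L]^3 * W[, 2L] * W[, 3L] * (V - cst$E_Na)
  i_si <- 0.09 * W[, 4L] * W[, 5L] * (V - E_si)
  i_K <- cst$g_K * W[, 6L] * lr91_Xi(V) * (V - cst$E_K)
  aK1 <- 1.02 / (1 + exp(0.2385 * (V - cst$E_K1 - 59.215)))
  bK1 <- (0.49124 * exp(0.08032 * (V - cst$E_K1 + 5.476)) +
            exp(0.06175 * (V - cst$E_K1 - 594.31))) /
    (1 + exp(-0.5143 * (V - cst$E_K1 + 4.753)))
  i_K1 <- cst$g_K1 * aK1 / (aK1 + bK1) * (V - cst$E_K1)
  Kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  i_Kp <- cst$g_Kp * Kp * (V - cst$E_K1)
  i_b <- cst$g_b * (V - cst$E_b)
  list(total = i_Na + i_si + i_K + i_K1 + i_Kp + i_b, i_si = i_si)
}

lr91_model <- function(form, blend_width = 1) {
  cst <- lr91_constants()
  init <- lr91_initial_state()
  rates_fun <- function(u) lr91_rates(u, form = form, blend_width = blend_width)
  structure(list(
    # compiled one-pass state update + current evaluation (hot path of the
    # tissue loop); mirrors g/I_ionic below exactly
    fused_step = function(u, W, dt, method = "fe") {
      lr91_fused_step(u, W, dt, form == "noble", blend_width / 4,
                      match(method, c("fe", "rl")) - 1L)
    },
    name = if (form == "standard") "LR91 (standard)" else
      sprintf("LR91 (Noble form, blend width %g mV)", blend_width),
    m = 7L,
    states = c("m", "h", "j", "d", "f", "X", "Cai"),
    gates = 1:6,
    u0 = init$u0, w0 = init$w0,
    rates = rates_fun,
    I_ionic = function(u, W) {
      W <- as_state_matrix(W, 7L)
      -lr91_currents(u, W, cst)$total
    },
    g = function(u, W) {
      W <- as_state_matrix(W, 7L)
      r <- rates_fun(u)
      G <- r$alpha * (1 - W[, 1:6, drop = FALSE]) - r$beta * W[, 1:6, drop = FALSE]
      i_si <- lr91_currents(u, W, cst)$i_si
      cbind(G, Cai = -1e-4 * i_si + 0.07 * (1e-4 - W[, 7L]))
    }),
    class = "cell_model")
}

as_state_matrix <- function(W, m) {
  if (is.null(dim(W))) matrix(W, ncol = m, byrow = FALSE) else W
}

#' Standard Luo-Rudy 1991 cell model
#'
#' The published LR91 ventricular action-potential model: fast sodium,
#' slow inward (with calcium-dependent reversal), time-dependent and
#' time-independent potassium, plateau and background currents, with the
#' original piecewise h- and j-gate rate definitions that switch analytic
#' branch at -40 mV (and are therefore discontinuous there).
#'
#' @return object of class `cell_model` with fields `u0`, `w0`,
#'   `I_ionic(u, W)` (depolarising-positive, uA/cm^2), `g(u, W)` (state
#'   derivatives per ms) and `rates(u)`.
#' @export
lr91_standard <- function() lr91_model("standard")

#' Continuity-repaired (Noble-form) Luo-Rudy 1991 model
#'
#' Identical to [lr91_standard()] except that each piecewise h/j rate is
#' replaced by a continuous function blending the two analytic branches
#' with a logistic switch centred at -40 mV. Away from the switch
#' (|V + 40| > 10 blend widths) the rates agree with the standard form to
#' relative 1e-6. This restores the smoothness that high-order spatial
#' discretisations need to reach their theoretical convergence rates. The
#' blend is a documented stand-in for the published continuous
#' modification and can be swapped for any other continuous rate set.
#'
#' @param blend_width logistic switch width in mV (default 1).
#' @export
lr91_noble_form <- function(blend_width = 1) {
  if (blend_width <= 0) stop("blend_width must be positive")
  lr91_model("noble", blend_width)
}

#' FitzHugh-Nagumo caricature model
#'
#' The classic two-variable excitable system scaled to a millivolt-like
#' range: `v = (u - V0)/Vs`, `dv/dt = c (v - v^3/3 - w)`,
#' `dw/dt = c eps (v + a - b w)`. Useful as an infinitely smooth reaction
#' term when diagnosing convergence-limiting features of physiological
#' models.
#'
#' @param a,b,eps FitzHugh-Nagumo parameters.
#' @param V0,Vs,c_rate affine voltage scaling (mV) and rate constant (1/ms).
#' @export
fitzhugh_nagumo <- function(a = 0.7, b = 0.8, eps = 0.08,
                            V0 = -85, Vs = 37.5, c_rate = 0.3) {
  # rest state: intersection of the cubic and linear nullclines
  vr <- stats::uniroot(function(v) v - v^3 / 3 - (v + a) / b,
                       c(-3, 0), tol = 1e-14)$root
  wr <- (vr + a) / b
  structure(list(
    name = "FitzHugh-Nagumo", m = 1L, states = "w", gates = integer(0),
    u0 = V0 + Vs * (vr - vr),  # u measured relative to rest: u0 = V0
    w0 = c(w = wr),
    v_rest = vr,
    rates = function(u) list(alpha = matrix(0, length(u), 0),
                             beta = matrix(0, length(u), 0)),
    I_ionic = function(u, W) {
      W <- as_state_matrix(W, 1L)
      v <- (u - V0) / Vs + vr
      Vs * c_rate * (v - v^3 / 3 - W[, 1L])
    },
    g = function(u, W) {
      W <- as_state_matrix(W, 1L)
      v <- (u - V0) / Vs + vr
      cbind(w = c_rate * eps * (v + a - b * W[, 1L]))
    }),
    class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("Cell model: %s (%d state variable%s: %s)\n", x$name, x$m,
              if (x$m > 1) "s" else "", paste(x$states, collapse = ", ")))
  cat(sprintf("  resting potential u0 = %.4g mV\n", x$u0))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Discontinuity scan

#' Scan a cell model's rate functions for discontinuities
#'
#' Evaluates every gate transition rate on a voltage grid and flags
#' adjacent-pair jumps that exceed 100 times the local grid-Lipschitz
#' estimate (the larger of the two neighbouring differences). Flagged
#' jumps are located to 1e-9 mV by bisection.
#'
#' @param model a `cell_model`.
#' @param v_range scan range in mV.
#' @param step grid step in mV.
#' @return data frame (possibly empty) with columns `variable`, `rate`,
#'   `voltage`, `left`, `right`, `jump`.
#' @export
scan_rate_discontinuities <- function(model, v_range = c(-90, 40), step = 0.01) {
  if (step <= 0) stop("step must be positive")
  V <- seq(v_range[1L], v_range[2L], by = step)
  r <- model$rates(V)
  out <- list()
  for (side in c("alpha", "beta")) {
    M <- r[[side]]
    if (!ncol(M)) next
    for (g in colnames(M)) {
      f <- M[, g]
      d <- abs(diff(f))
      n <- length(d)
      if (n < 3L) next
      neigh <- pmax(c(d[-1L], 0), c(0, d[-n]))
      tiny <- 1e-12 * max(abs(f))
      flag <- which(d > 100 * pmax(neigh, tiny) & d > tiny)
      flag <- flag[flag > 1L & flag < n]
      for (i in flag) {
        rate_i <- function(v) model$rates(v)[[side]][, g]
        lo <- V[i]; hi <- V[i + 1L]
        while (hi - lo > 1e-9) {
          mid <- (lo + hi) / 2
          fl <- rate_i(c(lo, mid, hi))
          if (abs(fl[2L] - fl[1L]) >= abs(fl[3L] - fl[2L])) hi <- mid else lo <- mid
        }
        v0 <- (lo + hi) / 2
        lim <- rate_i(c(v0 - 1e-7, v0 + 1e-7))
        out[[length(out) + 1L]] <- data.frame(
          variable = g, rate = paste0(side, "_", g), voltage = v0,
          left = lim[1L], right = lim[2L], jump = abs(lim[2L] - lim[1L]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(variable = character(0), rate = character(0),
                      voltage = numeric(0), left = numeric(0),
                      right = numeric(0), jump = numeric(0)))
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Pointwise state stepping

#' Advance cell states at a set of points
#'
#' Advances the state variables at every point independently by one step
#' of the configured integrator; there is no cross-point coupling (the
#' state PDEs have no spatial derivatives, so the nodal system is a large
#' collection of local ODE systems).
#'
#' @param model a `cell_model`.
#' @param u membrane potential at each point (mV).
#' @param W state matrix, one row per point.
#' @param dt time step (ms).
#' @param method `"fe"` (forward Euler, default) or `"rl"` (Rush-Larsen
#'   exponential update for the gates, forward Euler for the rest; keeps
#'   gates in [0, 1] for any dt).
#' @return updated state matrix.
#' @export
step_states <- function(model, u, W, dt, method = c("fe", "rl")) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  W <- as_state_matrix(W, model$m)
  if (length(u) != nrow(W)) stop("u and W are not congruent")
  if (method == "fe" || !length(model$gates)) {
    Wn <- W + dt * model$g(u, W)
  } else {
    r <- model$rates(u)
    ab <- r$alpha + r$beta
    winf <- r$alpha / pmax(ab, 1e-300)
    Wn <- W
    Wg <- W[, model$gates, drop = FALSE]
    Wn[, model$gates] <- winf + (Wg - winf) * exp(-dt * ab)
    rest <- setdiff(seq_len(model$m), model$gates)
    if (length(rest)) {
      Wn[, rest] <- W[, rest, drop = FALSE] +
        dt * model$g(u, W)[, rest, drop = FALSE]
    }
  }
  bad <- which(!is.finite(Wn), arr.ind = TRUE)
  if (nrow(bad)) stop(sprintf("non-finite cell state at point %d", bad[1L, 1L]))
  Wn
}

#' Run an isolated single-cell simulation
#'
#' Integrates `C_m du/dt = I_ionic(u, w) + I_stim(t)`, `dw/dt = g(u, w)`
#' for one membrane patch. The stimulus is excluded from the ionic
#' bookkeeping (it does not enter the calcium balance).
#'
#' @param model a `cell_model`.
#' @param dt time step (ms).
#' @param t_end end time (ms).
#' @param stim list with `onset`, `duration`, `amplitude` (uA/cm^2;
#'   rectangular pulse) or `NULL` for a quiescent run.
#' @param C_m membrane capacitance (uF/cm^2).
#' @param method state integrator, see [step_states()].
#' @param stride sampling stride in steps.
#' @return data frame with `t`, `u` and one column per state variable.
#' @export
cell_run <- function(model, dt = 0.01, t_end = 500, stim = NULL, C_m = 1,
                     method = "fe", stride = max(1L, round(0.1 / dt))) {
  nstep <- round(t_end / dt)
  u <- model$u0
  W <- matrix(model$w0, nrow = 1L)
  keep <- seq(0L, nstep, by = stride)
  out <- matrix(0, length(keep), model$m + 2L)
  out[1L, ] <- c(0, u, W)
  ki <- 1L
  for (s in seq_len(nstep)) {
    t_new <- s * dt
    W <- step_states(model, u, W, dt, method = method)
    ist <- if (!is.null(stim) && t_new >= stim$onset &&
               t_new < stim$onset + stim$duration) stim$amplitude else 0
    u <- u + dt / C_m * (model$I_ionic(u, W) + ist)
    if (s %% stride == 0L) {
      ki <- ki + 1L
      out[ki, ] <- c(t_new, u, W)
    }
  }
  colnames(out) <- c("t", "u", model$states)
  as.data.frame(out)
}
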