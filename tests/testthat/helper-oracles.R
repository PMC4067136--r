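# Independent oracles used across the suite. These are deliberately
# written from scratch (scalar branches, dense matrices, textbook
# formulas) so they share no code path with the package internals they
# check.

# --- Independent LR91 right-hand side for deSolve -------------------------
# Scalar transcription of the published model; branch selection with
# if/else rather than vectorised masks.
lr91_oracle_deriv <- function(t, y, parms) {
  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]
  d <- y[5]; f <- y[6]; X <- y[7]; Cai <- y[8]
  RTF <- 8314 * 310 / 96484.6
  ENa <- RTF * log(140 / 18)
  EK <- RTF * log((5.4 + 0.01833 * 140) / (145 + 0.01833 * 18))
  EK1 <- RTF * log(5.4 / 145)

  am <- if (abs(V + 47.13) < 1e-9) 3.2 else
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  bm <- 0.08 * exp(-V / 11)
  if (V < -40) {
    ah <- 0.135 * exp((80 + V) / -6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  ad <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  bd <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  af <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  bf <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  aX <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  bX <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))

  Esi <- 7.7 - 13.0287 * log(Cai)
  INa <- 23 * m^3 * h * j * (V - ENa)
  Isi <- 0.09 * d * f * (V - Esi)
  Xi <- if (V > -100) {
    if (abs(V + 77) < 1e-9) 2.837 * 0.04 / exp(0.04 * (V + 35)) else
      2.837 * (exp(0.04 * (V + 77)) - 1) / ((V + 77) * exp(0.04 * (V + 35)))
  } else 1
  IK <- 0.282 * sqrt(5.4 / 5.4) * X * Xi * (V - EK)
  aK1 <- 1.02 / (1 + exp(0.2385 * (V - EK1 - 59.215)))
  bK1 <- (0.49124 * exp(0.08032 * (V - EK1 + 5.476)) +
            exp(0.06175 * (V - EK1 - 594.31))) /
    (1 + exp(-0.5143 * (V - EK1 + 4.753)))
  IK1 <- 0.6047 * aK1 / (aK1 + bK1) * (V - EK1)
  Kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  IKp <- 0.0183 * Kp * (V - EK1)
  Ib <- 0.03921 * (V + 59.87)
  Istim <- if (!is.null(parms$stim) && t >= parms$stim$onset &&
               t < parms$stim$onset + parms$stim$duration)
    parms$stim$amplitude else 0

  list(c(-(INa + Isi + IK + IK1 + IKp + Ib) + Istim,
         am * (1 - m) - bm * m,
         ah * (1 - h) - bh * h,
         aj * (1 - j) - bj * j,
         ad * (1 - d) - bd * d,
         af * (1 - f) - bf * f,
         aX * (1 - X) - bX * X,
         -1e-4 * Isi + 0.07 * (1e-4 - Cai)))
}

run_lr91_oracle <- function(t_end = 500, stim = NULL, times = NULL) {
  m <- lr91_standard()
  y0 <- c(m$u0, m$w0)
  names(y0) <- c("V", names(m$w0))
  if (is.null(times)) times <- seq(0, t_end, by = 1)
  deSolve::ode(y0, times, lr91_oracle_deriv, parms = list(stim = stim),
               method = "lsoda", rtol = 1e-8, atol = 1e-10)
}

# --- Textbook linear-FEM monodomain stepper (dense) -----------------------
# Consistent-mass piecewise-linear FEM on a uniform interval mesh with
# nodal reaction evaluation; semi-implicit backward Euler. Dense tridiagonal
# matrices assembled from the classical hat-function formulas.
textbook_stepper_1d <- function(xv, sigma_Sm, C_m, beta) {
  n <- length(xv)
  h <- diff(xv)
  M <- matrix(0, n, n); A <- matrix(0, n, n)
  for (e in seq_len(n - 1L)) {
    idx <- c(e, e + 1L)
    M[idx, idx] <- M[idx, idx] + h[e] / 6 * matrix(c(2, 1, 1, 2), 2)
    A[idx, idx] <- A[idx, idx] + 1 / h[e] * matrix(c(1, -1, -1, 1), 2)
  }
  # S/m -> uA/(mV cm) units: factor 10
  function(u, W, t, dt, model, stim_fun) {
    Wn <- W + dt * model$g(u, W)
    I <- model$I_ionic(u, Wn) + stim_fun(xv, t + dt)
    K <- M + dt * 10 * sigma_Sm / (beta * C_m) * A
    rhs <- M %*% u + dt / C_m * (M %*% I)
    list(u = as.numeric(solve(K, rhs)), W = Wn)
  }
}

# quadrature-free exact integral of a barycentric monomial over the
# reference triangle (area 1/2)
bary_monomial_integral <- function(a, b, c) {
  factorial(a) * factorial(b) * factorial(c) / factorial(a + b + c + 2)
}
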