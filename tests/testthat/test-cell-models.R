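# Ionic models: resting behaviour against an adaptive-ODE oracle, the
# -40 mV rate discontinuity and its continuous repair, and the pointwise
# state integrators.

test_that("the quiescent LR91 cell stays at rest (ODE oracle agreement)", {
  skip_if_not_installed("deSolve")
  m <- lr91_standard()
  # oracle: independent scalar transcription, adaptive lsoda
  orc <- run_lr91_oracle(t_end = 500)
  expect_lt(max(abs(orc[, "V"] - m$u0)), 1)
  # package integrator agrees
  tr <- cell_run(m, dt = 0.01, t_end = 500)
  expect_lt(max(abs(tr$u - m$u0)), 1)
  expect_lt(max(abs(tail(tr$u, 1) - tail(orc[, "V"], 1))), 0.5)
})

test_that("stimulated action potentials match the ODE oracle", {
  skip_if_not_installed("deSolve")
  stim <- list(onset = 10, duration = 1, amplitude = 80)
  orc <- run_lr91_oracle(t_end = 400, stim = stim,
                         times = seq(0, 400, by = 0.5))
  tr <- cell_run(lr91_standard(), dt = 0.005, t_end = 400, stim = stim,
                 stride = 100)
  expect_equal(max(tr$u), max(orc[, "V"]), tolerance = 0.02)
  # APD90 agreement within 2%
  apd90 <- function(t, u) {
    pk <- max(u); rest <- u[1]; thr <- pk - 0.9 * (pk - rest)
    up <- which(u > thr)
    t[max(up)] - t[min(up)]
  }
  expect_equal(apd90(tr$t, tr$u), apd90(orc[, "time"], orc[, "V"]),
               tolerance = 0.02)
})

test_that("standard LR91 rates jump at -40 mV; Noble form does not", {
  rs <- lr91_rates(c(-40 - 1e-7, -40 + 1e-7), "standard")
  expect_gt(abs(diff(rs$alpha[, "h"])), 1e-5)
  expect_gt(abs(diff(rs$beta[, "h"])), 1e-3)
  rep_std <- scan_rate_discontinuities(lr91_standard())
  expect_gt(nrow(rep_std), 0)
  expect_true(all(abs(rep_std$voltage - (-40)) < 1e-6))
  expect_true(all(c("alpha_h", "beta_h") %in% rep_std$rate))
  # continuous repair: empty report, and genuinely continuous rates at the
  # switch: the straddle difference shrinks in proportion to the straddle
  # width (a jump would leave it constant)
  mn <- lr91_noble_form()
  expect_equal(nrow(scan_rate_discontinuities(mn)), 0)
  for (side in c("alpha", "beta")) {
    d1 <- abs(diff(mn$rates(c(-40 - 5e-7, -40 + 5e-7))[[side]]))
    d2 <- abs(diff(mn$rates(c(-40 - 5e-9, -40 + 5e-9))[[side]]))
    expect_true(all(d2 <= 0.02 * d1 + 1e-14))
    expect_true(all(d1 < 1e-5))    # no O(0.1) branch jump survives
  }
  expect_equal(nrow(scan_rate_discontinuities(fitzhugh_nagumo())), 0)
})

test_that("Noble-form rates match the standard form away from the switch", {
  V <- c(-80, -55, -25, 0, 30)
  rs <- lr91_rates(V, "standard")
  rn <- lr91_rates(V, "noble", blend_width = 1)
  for (side in c("alpha", "beta")) {
    rel <- abs(rs[[side]] - rn[[side]]) / pmax(abs(rs[[side]]), 1e-12)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("Noble-form AP differs little from standard LR91", {
  stim <- list(onset = 5, duration = 1, amplitude = 80)
  tr_s <- cell_run(lr91_standard(), dt = 0.01, t_end = 350, stim = stim,
                   stride = 50)
  tr_n <- cell_run(lr91_noble_form(), dt = 0.01, t_end = 350, stim = stim,
                   stride = 50)
  amp <- diff(range(tr_s$u))
  expect_lt(max(abs(tr_s$u - tr_n$u)), 0.05 * amp)
})

test_that("state stepping is consistent, pure and gate-safe", {
  m <- lr91_noble_form()
  u <- c(-84.38, -20, 15)
  W <- matrix(rep(m$w0, each = 3), 3)
  # first-order consistency: Richardson between dt and dt/2
  g0 <- m$g(u, W)
  w1 <- step_states(m, u, W, 2e-4)
  w2 <- step_states(m, u, step_states(m, u, W, 1e-4), 1e-4)
  expect_lt(max(abs(w1 - W - 2e-4 * g0)), 1e-12)
  expect_lt(max(abs(w1 - w2)), 1e-5)
  # purity: identical points give identical updates
  W2 <- W[c(1, 1, 2), ]; u2 <- u[c(1, 1, 2)]
  out <- step_states(m, u2, W2, 0.01)
  expect_identical(out[1, ], out[2, ])
  # Rush-Larsen keeps gates in [0, 1] for any dt
  wr <- step_states(m, u, W, 50, method = "rl")
  expect_true(all(wr[, 1:6] >= 0 & wr[, 1:6] <= 1))
})

test_that("gates clamped at steady state have zero derivative", {
  m <- lr91_standard()
  u <- rep(-30, 2)
  r <- m$rates(u)
  winf <- r$alpha / (r$alpha + r$beta)
  W <- cbind(winf, Cai = rep(2e-4, 2))
  g <- m$g(u, W)
  expect_lt(max(abs(g[, 1:6])), 1e-14)
})

test_that("FitzHugh-Nagumo rests, fires and recovers", {
  fm <- fitzhugh_nagumo()
  W0 <- matrix(fm$w0, 1)
  expect_equal(as.numeric(fm$g(fm$u0, W0)), 0, tolerance = 1e-12)
  expect_equal(fm$I_ionic(fm$u0, W0), 0, tolerance = 1e-12)
  tr <- cell_run(fm, dt = 0.05, t_end = 400,
                 stim = list(onset = 5, duration = 2, amplitude = 30))
  expect_gt(max(tr$u), fm$u0 + 80)           # suprathreshold excursion
  expect_lt(abs(tail(tr$u, 1) - fm$u0), 2)   # return to rest
  # eps -> 0: recovery variable frozen over short horizons
  fe <- fitzhugh_nagumo(eps = 1e-9)
  tre <- cell_run(fe, dt = 0.05, t_end = 20,
                  stim = list(onset = 1, duration = 2, amplitude = 30))
  expect_lt(max(abs(tre$w - fe$w0)), 1e-6)
})

test_that("non-positive calcium raises a domain error", {
  m <- lr91_standard()
  W <- matrix(c(m$w0), 1)
  W[7] <- -1e-5
  expect_error(m$I_ionic(-80, W), "calcium")
})

test_that("the compiled fused LR91 step matches the reference R path", {
  for (form in list(lr91_standard(), lr91_noble_form())) {
    set.seed(5)
    u <- runif(40, -90, 40)
    W <- matrix(rep(form$w0, each = 40), 40)
    W[, 1:6] <- pmin(pmax(W[, 1:6] + matrix(rnorm(240, 0, 0.05), 40), 0), 1)
    for (method in c("fe", "rl")) {
      fs <- form$fused_step(u, W, 0.01, method)
      Wr <- step_states(form, u, W, 0.01, method = method)
      Ir <- form$I_ionic(u, Wr)
      expect_lt(max(abs(fs$W - Wr)), 1e-12)
      expect_lt(max(abs(fs$I - Ir)) / max(abs(Ir)), 1e-12)
    }
  }
})
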