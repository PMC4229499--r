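test_that("firing-rate sigmoid is zero-centered, monotone, bounded, with correct slope", {
  p <- nm_params()
  expect_equal(nm_sigmoid(0, p), 0)
  v <- seq(-15, 15, by = 0.25)
  s <- nm_sigmoid(v, p)
  expect_true(all(diff(s) > 0))           # strict away from saturation
  vw <- seq(-60, 60, by = 0.5)
  sw <- nm_sigmoid(vw, p)
  expect_true(all(diff(sw) >= 0))
  expect_true(all(sw > -1 & sw < 1))
  # derivative at 0 against central differences
  h <- 1e-5
  fd <- (nm_sigmoid(h, p) - nm_sigmoid(-h, p)) / (2 * h)
  an <- p$rho_1 * exp(p$rho_1 * p$rho_2) / (1 + exp(p$rho_1 * p$rho_2))^2
  expect_lt(abs(fd - an), 1e-6)
})

test_that("synaptic kernel has the closed-form peak and integral", {
  H <- 3.25; tau <- 10
  expect_equal(synaptic_kernel(H, tau, 0), 0)
  tt <- seq(0, 200, by = 0.01)
  h <- synaptic_kernel(H, tau, tt)
  expect_equal(tt[which.max(h)], tau, tolerance = 1e-3)
  expect_equal(max(h), H / exp(1), tolerance = 1e-6)
  int <- integrate(function(t) synaptic_kernel(H, tau, t), 0, Inf)$value
  expect_equal(int, H * tau, tolerance = 1e-6)
})

test_that("stimulus drive is causal and peaks at the onset latency", {
  p <- stimulus_params(onset_latency = 64, width = 16)
  expect_equal(stimulus_input(-50, p), 0)
  expect_equal(stimulus_input(c(-10, -0.01), p), c(0, 0))
  tt <- seq(0, 200, by = 0.1)
  expect_equal(tt[which.max(stimulus_input(tt, p))], 64, tolerance = 0.1)
  expect_error(stimulus_params(width = 0))
})

test_that("rest is an exact fixed point and drive reaches only input nodes", {
  spec <- dcm_spec("dual_route", "none")
  tr0 <- integrate_network(spec, stim = stimulus_params(amplitude = 0),
                           duration = 150)
  expect_true(all(tr0$data == 0))
  # with all extrinsic couplings and intrinsic relay cut at V1 there is no
  # drive into non-input nodes: V1 stays silent when its only afferent is
  # the (absent) input
  cp <- coupling_params(spec)
  g2 <- spec
  g2$graph$forward[] <- FALSE
  g2$graph$backward[] <- FALSE
  tr <- integrate_network(g2, cp = coupling_params(g2), duration = 200)
  expect_true(all(tr$data[, "V1.L", ] == 0))
  expect_true(all(tr$data[, "AMY.L", ] == 0))
  expect_gt(max(abs(tr$data[, "LGN.L", ])), 0)
  expect_gt(max(abs(tr$data[, "PUL.R", ])), 0)
})

test_that("with zero extrinsic coupling each source matches a single-node oracle", {
  # independent R-only RK4 integration of one isolated input node
  spec <- dcm_spec("dual_route", "none")
  g2 <- spec
  g2$graph$forward[] <- FALSE
  g2$graph$backward[] <- FALSE
  stim <- stimulus_params()
  tr <- integrate_network(g2, cp = coupling_params(g2), stim = stim,
                          duration = 200, dt = 0.5, keep_dt = 0.5)
  p <- nm_params()
  sig <- function(v) nm_sigmoid(v, p)
  te <- p$tau_e / 1000; ti <- p$tau_i / 1000
  f <- function(t, x) {
    u <- if (t < 0) 0 else
      stim$amplitude * exp(-0.5 * ((t - stim$onset_latency / 1000) /
                                     (stim$width / 1000))^2)
    vP <- x[3] - x[5]
    c(x[2],
      (p$H_e / te) * (p$gamma_1 * sig(vP) + u) - 2 * x[2] / te - x[1] / te^2,
      x[4],
      (p$H_e / te) * (p$gamma_2 * sig(x[1])) - 2 * x[4] / te - x[3] / te^2,
      x[6],
      (p$H_i / ti) * (p$gamma_4 * sig(x[7])) - 2 * x[6] / ti - x[5] / ti^2,
      x[8],
      (p$H_e / te) * (p$gamma_3 * sig(vP)) - 2 * x[8] / te - x[7] / te^2)
  }
  dt <- 0.5e-3
  x <- rep(0, 8)
  vP_hist <- numeric(401)
  for (k in 0:400) {
    vP_hist[k + 1] <- x[3] - x[5]
    t <- k * dt
    k1 <- f(t, x); k2 <- f(t + dt / 2, x + dt / 2 * k1)
    k3 <- f(t + dt / 2, x + dt / 2 * k2); k4 <- f(t + dt, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(tr$data[, "LGN.L", "principal"], vP_hist, tolerance = 1e-10)
})

test_that("trajectories converge under step halving", {
  spec <- dcm_spec("dual_route", "none")
  a <- integrate_network(spec, duration = 300, dt = 0.5, keep_dt = 1)
  b <- integrate_network(spec, duration = 300, dt = 0.25, keep_dt = 1)
  expect_lt(max(abs(a$data - b$data)), 1e-3 * max(abs(b$data)))
})

test_that("condition modulation scales masked couplings only", {
  spec <- dcm_spec("dual_route", "forward")
  cp0 <- coupling_params(spec, log_b = 0)
  h <- integrate_network(spec, cp = cp0, condition = "happy", duration = 250)
  f <- integrate_network(spec, cp = cp0, condition = "fearful", duration = 250)
  expect_identical(h$data, f$data)         # log_b = 0: conditions identical
  # pattern none: conditions identical regardless of modulation storage
  spec_n <- dcm_spec("dual_route", "none")
  cp_n <- coupling_params(spec_n)
  hn <- integrate_network(spec_n, cp = cp_n, condition = "happy", duration = 250)
  fn <- integrate_network(spec_n, cp = cp_n, condition = "fearful", duration = 250)
  expect_identical(hn$data, fn$data)
  # positive forward modulation raises the fearful amygdala response
  cp1 <- coupling_params(spec, log_b = 0.4)
  h1 <- integrate_network(spec, cp = cp1, condition = "happy", duration = 250)
  f1 <- integrate_network(spec, cp = cp1, condition = "fearful", duration = 250)
  expect_gt(max(abs(f1$data[, "AMY.L", "principal"])),
            max(abs(h1$data[, "AMY.L", "principal"])))
  # log_b outside the mask is rejected
  bad <- spec$modulation$b_mask * 0
  bad["LGN.L", "V1.L"] <- 0.3
  cp_bad <- cp0; cp_bad$log_b <- bad
  expect_error(apply_modulation(cp_bad, spec$modulation, "fearful"),
               "outside the modulation mask")
})

test_that("trajectories vary smoothly with the couplings", {
  spec <- dcm_spec("dual_route", "none")
  base <- coupling_params(spec)
  t0 <- integrate_network(spec, cp = base, duration = 200)
  eps <- 1e-4
  pert <- base
  pert$log_forward["PUL.L", "AMY.L"] <- eps
  t1 <- integrate_network(spec, cp = pert, duration = 200)
  d <- max(abs(t1$data - t0$data))
  expect_gt(d, 0)
  expect_lt(d, 100 * eps * max(abs(t0$data)))   # O(eps) response
})

test_that("dual-route amygdala responds earlier than cortical-only", {
  st <- stimulus_params(onset_latency = 32)
  d <- dcm_spec("dual_route", "none")
  c <- dcm_spec("cortical_only", "none")
  trd <- integrate_network(d, cp = coupling_params(d), stim = st, duration = 300)
  trc <- integrate_network(c, cp = coupling_params(c), stim = st, duration = 300)
  th <- 0.1 * max(abs(trd$data[, "AMY.L", "principal"]))
  onset_d <- trd$time[which(abs(trd$data[, "AMY.L", "principal"]) > th)[1]]
  onset_c <- trc$time[which(abs(trc$data[, "AMY.L", "principal"]) > th)[1]]
  expect_lt(onset_d, onset_c)
})

test_that("integration is deterministic and reports divergence", {
  spec <- dcm_spec("dual_route", "none")
  a <- integrate_network(spec, duration = 150)
  b <- integrate_network(spec, duration = 150)
  expect_identical(a$data, b$data)
  # non-finite drive is caught with an informative error (the saturating
  # sigmoid keeps any finite-parameter trajectory bounded)
  expect_error(integrate_network(spec, stim = stimulus_params(amplitude = Inf),
                                 duration = 50), "diverged")
})
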