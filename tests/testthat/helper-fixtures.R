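# shared fixtures built in code at test time

# one "subject" of noiseless-model ERFs generated directly from known
# parameters (no trial structure): fast input for inversion tests
make_direct_subject <- function(seed = 1, family = "dual_route",
                                latency = 32, pul_gain = 0.25,
                                noise_frac = 0.05, n_sensors = 32,
                                duration = 300) {
  set.seed(seed)
  spec <- dcm_spec(family, "none")
  sens <- sensor_array(n_sensors)
  lf <- build_leadfield(spec$sources, sens)
  par <- subdcm:::dcm_parameters(spec, 1)
  theta <- par$mean
  theta[par$idx_f] <- rnorm(length(par$idx_f), 0, 0.1)
  if (family == "dual_route") {
    ip <- grep("^F\\.PUL", names(theta))
    theta[ip] <- theta[ip] + pul_gain
  }
  theta[par$idx_b] <- rnorm(length(par$idx_b), 0, 0.1)
  theta["latency"] <- latency
  theta[par$idx_mom] <- rnorm(length(par$idx_mom), 0, 1)
  cp <- subdcm:::theta_to_coupling(theta, par, spec)
  tr <- integrate_network(spec, cp = cp,
                          stim = stimulus_params(onset_latency = latency),
                          duration = duration, keep_dt = 5)
  n_src <- nrow(spec$sources)
  mom <- matrix(theta[par$idx_mom], 3, n_src)
  G <- sapply(seq_len(n_src), function(s)
    lf$gain[, 3 * (s - 1) + 1:3] %*% mom[, s])
  erf <- matrix(G, n_sensors, n_src) %*% t(tr$data[, , "principal"])
  noise_sd <- noise_frac * sqrt(mean(erf^2))
  time <- seq(-200, 600, by = 5)
  pad <- function(x) {
    out <- matrix(0, nrow(x), length(time))
    out[, time >= 0 & time <= duration] <- x
    out
  }
  erfs <- list(happy = pad(erf + rnorm(length(erf), 0, noise_sd)),
               fearful = pad(erf + rnorm(length(erf), 0, noise_sd)))
  list(spec = spec, theta = theta, par = par, erfs = erfs, time = time,
       leadfield = lf, sensors = sens)
}

# a minimal fit-like object carrying a parameter vector as its posterior
# mean (for perturbation/simulation property checks that do not need a
# genuine inversion)
make_posterior_stub <- function(theta = NULL, family = "dual_route",
                                seed = 1) {
  set.seed(seed)
  spec <- dcm_spec(family, "none")
  par <- subdcm:::dcm_parameters(spec, 1)
  if (is.null(theta)) {
    theta <- par$mean
    theta[par$idx_f] <- rnorm(length(par$idx_f), 0, 0.1)
    theta["latency"] <- 48
  }
  fit <- list(spec = spec, mean = theta, par = par,
              conditions = c("happy", "fearful"),
              window = c(0, 300))
  class(fit) <- c("subdcm_fit", "vl_fit")
  fit
}
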