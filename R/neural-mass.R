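#' Neural-mass parameters
#'
#' Constants of the three-population convolution model used for every source:
#' synaptic gains and time constants of the excitatory and inhibitory
#' kernels, the four intrinsic coupling gains and the firing-rate sigmoid.
#' Defaults are the conventional values for this model class.
#'
#' @param H_e,H_i synaptic gains (mV).
#' @param tau_e,tau_i synaptic time constants (ms).
#' @param gamma_1,gamma_2,gamma_3,gamma_4 intrinsic coupling gains.
#' @param rho_1 sigmoid slope (1/mV); \code{rho_2} sigmoid offset (mV).
#' @return List of class \code{"nm_params"}.
#' @export
nm_params <- function(H_e = 3.25, H_i = 29.3, tau_e = 10, tau_i = 16,
                      gamma_1 = 128, gamma_2 = 102, gamma_3 = 32,
                      gamma_4 = 32, rho_1 = 2, rho_2 = 1) {
  stopifnot(tau_e > 0, tau_i > 0, H_e >= 0, H_i >= 0,
            gamma_1 >= 0, gamma_2 >= 0, gamma_3 >= 0, gamma_4 >= 0)
  p <- list(H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i,
            gamma_1 = gamma_1, gamma_2 = gamma_2, gamma_3 = gamma_3,
            gamma_4 = gamma_4, rho_1 = rho_1, rho_2 = rho_2)
  class(p) <- "nm_params"
  p
}

#' Zero-centered firing-rate sigmoid
#'
#' \code{S(v) = 1/(1+exp(-rho_1 (v - rho_2))) - 1/(1+exp(rho_1 rho_2))}, so
#' that \code{S(0) = 0}: the resting state is an exact fixed point of the
#' network dynamics.
#'
#' @param v membrane potential (mV), vectorized.
#' @param params an \code{\link{nm_params}} object.
#' @return Firing rate (a.u.).
#' @export
nm_sigmoid <- function(v, params = nm_params()) {
  1 / (1 + exp(-params$rho_1 * (v - params$rho_2))) -
    1 / (1 + exp(params$rho_1 * params$rho_2))
}

#' Synaptic impulse response (alpha kernel)
#'
#' \code{h(t) = (H/tau) t exp(-t/tau)} for \code{t >= 0}; peaks at
#' \code{t = tau} with value \code{H/e} and integrates to \code{H tau}.
#'
#' @param H synaptic gain (mV); \code{tau} time constant (ms); \code{t} time
#'   (ms, vectorized, non-negative).
#' @export
synaptic_kernel <- function(H, tau, t) {
  stopifnot(tau > 0, all(t >= 0))
  (H / tau) * t * exp(-t / tau)
}

#' Stimulus parameters
#' @param onset_latency Gaussian bump centre (ms after stimulus onset).
#' @param width bump standard deviation (ms).
#' @param amplitude drive amplitude (a.u.).
#' @return List of class \code{"stimulus_params"}.
#' @export
stimulus_params <- function(onset_latency = 64, width = 16, amplitude = 32) {
  stopifnot(width > 0)
  p <- list(onset_latency = onset_latency, width = width,
            amplitude = amplitude)
  class(p) <- "stimulus_params"
  p
}

#' Driving input waveform
#'
#' Gaussian bump, identically zero before stimulus onset (t < 0). The drive
#' is injected only at input nodes (LGN, PUL), scaled by their input gains.
#'
#' @param t time (ms, vectorized).
#' @param params a \code{\link{stimulus_params}} object.
#' @export
stimulus_input <- function(t, params = stimulus_params()) {
  u <- params$amplitude *
    exp(-0.5 * ((t - params$onset_latency) / params$width)^2)
  u[t < 0] <- 0
  u
}

#' Coupling parameters for one model
#'
#' Log-scaling parameters over the extrinsic connections of a
#' \code{\link{dcm_spec}}: effective forward gain is
#' \code{scale_forward * exp(log_forward)} (default prior scale 32), backward
#' \code{scale_backward * exp(log_backward)} (16). \code{log_b} is the
#' condition modulation (fearful vs happy) on the edges of the modulation
#' mask. Entries outside the respective masks must stay zero.
#'
#' @param spec a \code{\link{dcm_spec}}.
#' @param log_forward,log_backward,log_b either scalars (applied to every
#'   masked edge) or full matrices aligned with the graph masks.
#' @param log_input scalar or per-node vector of input log-gains.
#' @param delay_extrinsic extrinsic conduction delay (ms).
#' @return List of class \code{"coupling_params"}.
#' @export
coupling_params <- function(spec, log_forward = 0, log_backward = 0,
                            log_b = 0, log_input = 0, delay_extrinsic = 16) {
  g <- spec$graph
  expand <- function(v, mask) {
    if (is.matrix(v)) {
      stopifnot(all(dim(v) == dim(mask)))
      if (any(v[!mask] != 0))
        stop("nonzero log-coupling outside the graph mask")
      return(v * mask)
    }
    mask * v
  }
  n <- nrow(spec$sources)
  li <- if (length(log_input) == 1) rep(log_input, n) else log_input
  stopifnot(length(li) == n)
  names(li) <- spec$sources$name
  cp <- list(
    log_forward = expand(log_forward, g$forward),
    log_backward = expand(log_backward, g$backward),
    log_b = expand(log_b, spec$modulation$b_mask),
    log_input = li,
    delay_extrinsic = delay_extrinsic
  )
  class(cp) <- "coupling_params"
  cp
}

#' Apply condition-specific modulation
#'
#' The happy condition is the baseline; for fearful faces the couplings on
#' the modulation mask are scaled by \code{exp(log_b)} (added on the log
#' scale). With pattern "none" (empty mask) the conditions are identical.
#'
#' @param cp a \code{\link{coupling_params}} object.
#' @param mod a \code{\link{modulation_spec}} (consistent with \code{cp}).
#' @param condition "happy", "neutral" or "fearful".
#' @return Modified \code{coupling_params}.
#' @export
apply_modulation <- function(cp, mod, condition = c("happy", "fearful", "neutral")) {
  condition <- match.arg(condition)
  if (any(cp$log_b[!mod$b_mask] != 0))
    stop("log_b entries outside the modulation mask")
  if (condition != "fearful") return(cp)
  # add log_b on masked forward and backward edges
  cp$log_forward <- cp$log_forward + cp$log_b * (mod$b_mask * 1)
  cp$log_backward <- cp$log_backward + cp$log_b * (mod$b_mask * 1)
  cp
}

#' Integrate the coupled neural-mass network
#'
#' Fixed-step RK4 integration (default dt = 0.5 ms) of the three-population
#' model over the extrinsic graph of \code{spec}, with ring-buffered
#' extrinsic conduction delays. Deterministic given its inputs.
#'
#' @param spec a \code{\link{dcm_spec}}.
#' @param nm \code{\link{nm_params}}; \code{cp} \code{\link{coupling_params}};
#'   \code{stim} \code{\link{stimulus_params}}.
#' @param condition condition label; "fearful" applies the modulation.
#' @param duration total integration time (ms, from 0).
#' @param dt integration step (ms, must be <= 1).
#' @param keep_dt output sampling step (ms, multiple of \code{dt}).
#' @param scale_forward,scale_backward prior coupling scales.
#' @return List of class \code{"source_trajectory"}: \code{time} (ms),
#'   \code{data} (time x sources x populations, mV; populations are
#'   principal, excitatory-interneuron, inhibitory-interneuron), \code{dt}.
#' @export
integrate_network <- function(spec, nm = nm_params(), cp = coupling_params(spec),
                              stim = stimulus_params(),
                              condition = "happy",
                              duration = 300, dt = 0.5, keep_dt = dt,
                              scale_forward = 32, scale_backward = 16) {
  stopifnot(dt <= 1, duration > 0)
  keep_every <- round(keep_dt / dt)
  stopifnot(abs(keep_every * dt - keep_dt) < 1e-9, keep_every >= 1)
  cpc <- apply_modulation(cp, spec$modulation, condition)
  AF <- scale_forward * exp(cpc$log_forward) * spec$graph$forward
  AB <- scale_backward * exp(cpc$log_backward) * spec$graph$backward
  gin <- exp(cpc$log_input) * spec$graph$input
  n_steps <- round(duration / dt)
  # integrate in SI seconds: the conventional gains assume H * tau with tau
  # in seconds (H_e * tau_e = 3.25 mV * 0.010 s), so ms time constants are
  # converted here; the API stays in ms throughout.
  pv <- unlist(nm[c("H_e", "H_i", "tau_e", "tau_i", "gamma_1", "gamma_2",
                    "gamma_3", "gamma_4", "rho_1", "rho_2")])
  pv[c("tau_e", "tau_i")] <- pv[c("tau_e", "tau_i")] / 1000
  arr <- integrate_nm_cpp(AF, AB, as.numeric(gin), as.numeric(spec$self_inhib),
                          as.numeric(pv), stim$onset_latency / 1000,
                          stim$width / 1000,
                          stim$amplitude, cpc$delay_extrinsic / 1000,
                          dt / 1000, n_steps, keep_every)
  dimnames(arr) <- list(NULL, spec$sources$name,
                        c("principal", "excitatory", "inhibitory"))
  tr <- list(time = seq(0, by = keep_dt, length.out = dim(arr)[1]),
             data = arr, dt = keep_dt)
  class(tr) <- "source_trajectory"
  tr
}
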