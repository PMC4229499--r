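#' Synthetic cohort configuration
#'
#' Defaults state the emulated study design: 12 subjects, 3 conditions
#' (neutral, happy, fearful) with 99 trials each, 274 axial gradiometers
#' sampled at 600 Hz, epochs -200..600 ms. The ground-truth network is a
#' dual-route (or cortical-only) model; the driving input arrives early
#' (32 ms geniculate latency) and the pulvinar-to-amygdala forward gain is
#' elevated by +0.25 on the log scale so the amygdala responds at ~140 ms,
#' well before the cortically relayed response — the regime the analysis is
#' designed to detect.
#'
#' @param n_subjects,trials_per_condition,n_sensors,fs_raw design constants.
#' @param epoch_window epoch limits, ms.
#' @param snr_db single-trial signal-to-noise ratio, dB (signal power of the
#'   condition-mean over 0-300 ms vs per-trial white-noise power).
#' @param truth generating family ("dual_route" or "cortical_only").
#' @param modulation_truth fearful-vs-happy log-modulation of the forward
#'   connections to the amygdala (0 = no valence effect, the default; the
#'   generating model then uses the "none" pattern).
#' @param stim_latency group-mean input latency, ms.
#' @param pul_gain group-mean elevation of the PUL->AMY forward log-gain
#'   (dual-route truth only).
#' @param subject_jitter_sd between-subject log-normal coupling jitter (SD
#'   of the log-scaling).
#' @param latency_jitter_sd between-subject input-latency jitter, ms.
#' @param trial_amplitude_jitter per-trial multiplicative amplitude jitter
#'   (uniform in 1 +/- value).
#' @param trial_latency_jitter per-trial latency jitter, ms (uniform +/-).
#' @param outlier_rate probability that a trial is an artifact trial;
#'   \code{outlier_scale} multiplies its noise SD.
#' @param seed seed fixing all randomness.
#' @return List of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_subjects = 12, trials_per_condition = 99,
                          n_sensors = 274, fs_raw = 600,
                          epoch_window = c(-200, 600), snr_db = 5,
                          truth = c("dual_route", "cortical_only"),
                          modulation_truth = 0, stim_latency = 32,
                          pul_gain = 0.25, subject_jitter_sd = 0.1,
                          latency_jitter_sd = 5,
                          trial_amplitude_jitter = 0.1,
                          trial_latency_jitter = 10,
                          outlier_rate = 0.02, outlier_scale = 30,
                          seed = 1) {
  truth <- match.arg(truth)
  stopifnot(n_subjects > 0, trials_per_condition > 0, n_sensors > 0,
            fs_raw > 0, is.finite(snr_db))
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Desk-scale cohort configuration
#'
#' A reduced design that preserves the statistical structure of the full
#' cohort at a runtime compatible with a single CPU: 10 subjects, 40 trials
#' per condition, 64 sensors. (Ten subjects keep a 90%-of-subjects
#' criterion representable: 9/10.)
#'
#' @param ... overrides passed to \code{\link{cohort_config}}.
#' @export
scaled_down_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 10, trials_per_condition = 40, n_sensors = 64)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

#' Generate a synthetic multi-subject MEG cohort
#'
#' For each subject, couplings and input latency are drawn around the group
#' truth, the ground-truth network is integrated per condition, projected to
#' the sensors through subject dipole moments and the spherical-head lead
#' field, and single trials are produced by per-trial amplitude and latency
#' jitter plus white sensor noise at the configured SNR, with occasional
#' high-noise outlier trials. Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return List of class \code{"cohort"}: \code{subjects} (list of
#'   \code{\link{epoch_set}} at \code{fs_raw}), \code{truth} (per-subject
#'   parameter vectors and the generating \code{dcm_spec}), \code{sensors},
#'   \code{leadfield}, \code{config}.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  pattern <- if (cfg$modulation_truth != 0) "forward" else "none"
  spec <- dcm_spec(cfg$truth, pattern)
  sens <- sensor_array(cfg$n_sensors)
  lf <- build_leadfield(spec$sources, sens)
  par <- dcm_parameters(spec, n_modes = 1)
  n_src <- nrow(spec$sources)
  fs <- cfg$fs_raw
  t_ep <- seq(cfg$epoch_window[1], cfg$epoch_window[2], by = 1000 / fs)
  n_samp <- length(t_ep)
  keep_dt <- 1000 / fs
  dt <- keep_dt / 4
  conditions <- c("neutral", "happy", "fearful")
  sensors_meta <- data.frame(name = paste0("MEG", seq_len(cfg$n_sensors)),
                             hemisphere = sens$hemisphere)
  # group-level dipole moments: subjects share a functional topography up
  # to individual jitter, as real cohorts do (this is what makes a
  # group-level sensor-of-interest analysis meaningful)
  group_mom <- stats::rnorm(3 * n_src, 0, 1)
  subjects <- list(); truth <- list()
  for (s in seq_len(cfg$n_subjects)) {
    theta <- par$mean
    theta[par$idx_f] <- stats::rnorm(length(par$idx_f), 0,
                                     cfg$subject_jitter_sd)
    if (cfg$truth == "dual_route") {
      ip <- grep("^F\\.PUL", names(theta))
      theta[ip] <- theta[ip] + cfg$pul_gain
    }
    theta[par$idx_b] <- stats::rnorm(length(par$idx_b), 0,
                                     cfg$subject_jitter_sd)
    if (length(par$idx_bb))
      theta[par$idx_bb] <- cfg$modulation_truth
    theta["latency"] <- cfg$stim_latency +
      stats::rnorm(1, 0, cfg$latency_jitter_sd)
    theta[par$idx_mom] <- group_mom + stats::rnorm(3 * n_src, 0, 0.3)
    cp <- theta_to_coupling(theta, par, spec)
    stim <- stimulus_params(onset_latency = theta["latency"])
    mom <- matrix(theta[par$idx_mom], 3, n_src)
    G <- sapply(seq_len(n_src), function(k)
      lf$gain[, 3 * (k - 1) + 1:3] %*% mom[, k])
    G <- matrix(G, cfg$n_sensors, n_src)
    # condition-mean sensor signals on the post-stimulus grid
    cond_sig <- lapply(conditions, function(cond) {
      cc <- if (cond == "fearful") "fearful" else "happy"
      tr <- integrate_network(spec, cp = cp, stim = stim, condition = cc,
                              duration = cfg$epoch_window[2], dt = dt,
                              keep_dt = keep_dt)
      G %*% t(tr$data[, , "principal"])      # sensors x post samples
    })
    names(cond_sig) <- conditions
    post_t <- seq(0, cfg$epoch_window[2], by = keep_dt)
    sig_sel <- post_t <= 300
    p_sig <- mean(sapply(cond_sig, function(x) mean(x[, sig_sel]^2)))
    if (!is.finite(p_sig) || p_sig <= 0)
      stop("degenerate signal power; cannot scale noise")
    noise_sd <- sqrt(p_sig / 10^(cfg$snr_db / 10))
    n_tr <- cfg$trials_per_condition
    data <- array(0, c(n_tr * 3, cfg$n_sensors, n_samp))
    labels <- rep(conditions, each = n_tr)
    row <- 1
    for (cond in conditions) {
      sig <- cond_sig[[cond]]
      for (tr_i in seq_len(n_tr)) {
        amp <- 1 + stats::runif(1, -cfg$trial_amplitude_jitter,
                                cfg$trial_amplitude_jitter)
        lag <- stats::runif(1, -cfg$trial_latency_jitter,
                            cfg$trial_latency_jitter)
        # shift the post-stimulus signal by lag (ms) via linear interpolation
        tq <- post_t - lag
        wlo <- floor(tq / keep_dt)
        frac <- tq / keep_dt - wlo
        i0 <- pmin(pmax(wlo + 1L, 1L), ncol(sig))
        i1 <- pmin(pmax(wlo + 2L, 1L), ncol(sig))
        zero <- tq < 0
        shifted <- sig[, i0, drop = FALSE] * rep(1 - frac, each = nrow(sig)) +
          sig[, i1, drop = FALSE] * rep(frac, each = nrow(sig))
        shifted[, zero] <- 0
        sd_tr <- noise_sd *
          if (stats::runif(1) < cfg$outlier_rate) cfg$outlier_scale else 1
        trial <- matrix(stats::rnorm(cfg$n_sensors * n_samp, 0, sd_tr),
                        cfg$n_sensors, n_samp)
        trial[, t_ep >= 0] <- trial[, t_ep >= 0] + amp * shifted
        data[row, , ] <- trial
        row <- row + 1
      }
    }
    subjects[[s]] <- epoch_set(data, fs, t0 = cfg$epoch_window[1],
                               labels = labels, sensors = sensors_meta)
    truth[[s]] <- list(theta = theta, noise_sd = noise_sd)
  }
  out <- list(subjects = subjects,
              truth = list(spec = spec, subjects = truth,
                           parameters = par),
              sensors = sens, leadfield = lf, config = cfg)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic MEG cohort: %d subjects, %d trials x 3 conditions, %d sensors @ %g Hz\n",
              cfg$n_subjects, cfg$trials_per_condition, cfg$n_sensors,
              cfg$fs_raw))
  cat(sprintf("  truth: %s, snr %g dB, seed %d\n", cfg$truth, cfg$snr_db,
              cfg$seed))
  invisible(x)
}
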