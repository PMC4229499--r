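#' Prior specification for variational Laplace
#'
#' @param mean named numeric vector of prior means.
#' @param variance prior variances (same length/names as \code{mean}) or a
#'   full covariance matrix.
#' @param noise either \code{list(log_precision, variance)} — a Gaussian
#'   hyperprior on the sensor-noise log-precision — or
#'   \code{list(log_precision, fixed = TRUE)} for known noise.
#' @return List of class \code{"prior_spec"}.
#' @export
prior_spec <- function(mean, variance,
                       noise = list(log_precision = 4, variance = 1 / 16)) {
  if (is.matrix(variance)) {
    cov <- variance
  } else {
    stopifnot(length(variance) == length(mean), all(variance > 0))
    cov <- diag(variance, length(mean))
  }
  p <- list(mean = mean, cov = cov, noise = noise)
  class(p) <- "prior_spec"
  p
}

fd_jacobian <- function(g, theta, step = 1e-3) {
  y0 <- g(theta)
  J <- matrix(0, length(y0), length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + step
    tm <- theta; tm[k] <- tm[k] - step
    J[, k] <- (g(tp) - g(tm)) / (2 * step)
  }
  J
}

logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)

#' Variational Laplace model inversion
#'
#' Gauss-Newton/Levenberg ascent on the Laplace free energy for a nonlinear
#' Gaussian observation model \code{y = g(theta) + e}, with a Gaussian
#' posterior over parameters and an EM update of the sensor-noise
#' log-precision. The returned free energy is a lower bound on the log model
#' evidence and is exact for linear-Gaussian models.
#'
#' @param generative function(theta) -> predicted data vector.
#' @param priors a \code{\link{prior_spec}}.
#' @param data numeric vector of observations.
#' @param jacobian optional function(theta) -> Jacobian matrix; default
#'   central finite differences with step \code{fd_step}.
#' @param max_iter iteration cap (default 64); convergence is declared after
#'   \code{tol_runs} consecutive accepted steps with \code{dF < tol}.
#' @param tol,tol_runs convergence controls (0.01 nats, 4 runs).
#' @param fd_step finite-difference step.
#' @param lambda_rate maximal change of the noise log-precision per
#'   iteration (default unlimited).
#' @return List of class \code{"vl_fit"}: posterior \code{mean} and
#'   \code{cov}, \code{free_energy} (nats), noise \code{log_precision},
#'   \code{trace} of accepted free energies, \code{converged}.
#' @export
variational_laplace <- function(generative, priors, data, jacobian = NULL,
                                max_iter = 64, tol = 0.01, tol_runs = 4,
                                fd_step = 1e-3, lambda_rate = Inf) {
  stopifnot(inherits(priors, "prior_spec"), all(is.finite(data)))
  y <- as.numeric(data)
  N <- length(y)
  mu0 <- priors$mean
  p <- length(mu0)
  P0 <- solve(priors$cov)
  ld0 <- logdet(priors$cov)
  fixed_noise <- isTRUE(priors$noise$fixed)
  lam0 <- priors$noise$log_precision
  vlam <- if (fixed_noise) 0 else priors$noise$variance
  if (is.null(jacobian))
    jacobian <- function(theta) fd_jacobian(generative, theta, fd_step)

  g0 <- generative(mu0)
  if (any(!is.finite(g0)))
    stop("generative model returns non-finite prediction at the prior mean")

  free_energy_at <- function(e, J, Sg, mu, lam, vlam_post) {
    Pi <- exp(lam)
    G <- sum(e^2) + sum(diag(crossprod(J) %*% Sg))
    dmu <- mu - mu0
    Fv <- -Pi / 2 * G - N / 2 * log(2 * pi) + N / 2 * lam -
      0.5 * (t(dmu) %*% P0 %*% dmu)[1] - 0.5 * sum(diag(P0 %*% Sg)) +
      0.5 * (logdet(Sg) - ld0) + p / 2
    if (!fixed_noise)
      Fv <- Fv - (lam - lam0)^2 / (2 * vlam) - vlam_post / (2 * vlam) +
        0.5 * log(vlam_post / vlam) + 0.5
    Fv
  }

  mu <- mu0
  lam <- lam0
  vlam_post <- vlam
  nu <- 1e-6
  Fprev <- -Inf
  trace <- numeric(0)
  runs <- 0
  Sg <- priors$cov
  for (it in seq_len(max_iter)) {
    J <- jacobian(mu)
    if (any(!is.finite(J))) stop("non-finite model Jacobian")
    e <- y - generative(mu)
    JtJ <- crossprod(J)
    # E-step covariance and M-step noise precision at the current mean
    Sg <- solve(exp(lam) * JtJ + P0)
    if (!fixed_noise) {
      G <- sum(e^2) + sum(diag(JtJ %*% Sg))
      lam_old <- lam
      for (q in 1:8) {
        d1 <- N / 2 - exp(lam) / 2 * G - (lam - lam0) / vlam
        d2 <- -exp(lam) / 2 * G - 1 / vlam
        lam <- lam - d1 / d2
      }
      lam <- lam_old + max(min(lam - lam_old, lambda_rate), -lambda_rate)
      vlam_post <- 1 / (exp(lam) / 2 * G + 1 / vlam)
      Sg <- solve(exp(lam) * JtJ + P0)
    }
    Fcur <- free_energy_at(e, J, Sg, mu, lam, vlam_post)
    dF <- Fcur - Fprev
    Fprev <- Fcur
    trace <- c(trace, Fcur)
    if (it > 1 && abs(dF) < tol) runs <- runs + 1 else runs <- 0
    if (runs >= tol_runs) break
    # Levenberg-regularized Gauss-Newton step on the posterior mean
    Pi <- exp(lam)
    H <- Pi * JtJ + P0
    if (rcond(H) < 1e-12) {
      warning("singular curvature; regularizing")
      H <- H + diag(1e-8 * max(diag(H)), p)
    }
    grad <- Pi * crossprod(J, e) - P0 %*% (mu - mu0)
    for (try in 1:8) {
      Hl <- H + diag(nu * diag(H) + 1e-12, p)
      mu_new <- mu + as.numeric(solve(Hl, grad))
      e_new <- y - generative(mu_new)
      if (any(!is.finite(e_new))) { nu <- nu * 16; next }
      F_new <- free_energy_at(e_new, J, Sg, mu_new, lam, vlam_post)
      if (F_new > Fcur) {
        mu <- mu_new
        nu <- max(nu / 4, 1e-8)
        break
      }
      nu <- nu * 16
    }
  }
  out <- list(mean = stats::setNames(as.numeric(mu), names(mu0)), cov = Sg,
              free_energy = Fprev, log_precision = lam,
              trace = trace, converged = runs >= tol_runs, n_data = N)
  class(out) <- "vl_fit"
  out
}

#' Post-stimulus analysis window grid
#'
#' Windows \code{[0, T]} for T from \code{start} to \code{stop} in
#' \code{step} ms increments: the default grid is 0-60 up to 0-300 ms in
#' 10 ms steps (25 windows).
#'
#' @param start,stop,step grid limits and increment, ms.
#' @return List of length-2 vectors \code{c(0, T)}.
#' @export
window_grid <- function(start = 60, stop = 300, step = 10) {
  stopifnot(step > 0)
  lapply(seq(start, stop, by = step), function(T) c(0, T))
}

# linear observation operators applied to model predictions so they live in
# the same space as the preprocessed data: the trial-averaging latency smear
# (uniform per-trial jitter acts as a box blur on the average) followed by
# the preprocessing band-pass; identity when both are absent
make_prediction_filter <- function(band, fs, n_samples, smear = NULL) {
  smear_op <- identity
  if (!is.null(smear) && smear > 0) {
    lags <- round(seq(-smear, smear, by = 1000 / fs) * fs / 1000)
    # bin masses of the uniform density at the sample spacing
    halfbin <- 0.5 * 1000 / fs
    lo <- pmax(lags * 1000 / fs - halfbin, -smear)
    hi <- pmin(lags * 1000 / fs + halfbin, smear)
    wts <- (hi - lo) / (2 * smear)
    S <- matrix(0, n_samples, n_samples)
    for (k in seq_along(lags)) {
      idx <- pmin(pmax(seq_len(n_samples) - lags[k], 1), n_samples)
      S[cbind(seq_len(n_samples), idx)] <-
        S[cbind(seq_len(n_samples), idx)] + wts[k]
    }
    smear_op <- function(M) S %*% M
  }
  if (is.null(band)) return(smear_op)
  hp <- butter_design(4, band[1], fs, "high")
  lp <- butter_design(4, band[2], fs, "low")
  npad <- 3 * (length(lp$a) - 1)
  if (n_samples <= npad)
    stop("analysis window too short for prediction filtering")
  # the whole chain is linear: collapse it into one operator matrix so that
  # every prediction costs a single matrix product
  OP <- filtfilt(lp$b, lp$a, filtfilt(hp$b, hp$a, smear_op(diag(n_samples))))
  function(M) OP %*% M
}

# parameter bookkeeping for one model: named prior vector + index sets
dcm_parameters <- function(spec, n_modes, moment_var = 16) {
  g <- spec$graph
  fe <- which(g$forward, arr.ind = TRUE)
  be <- which(g$backward, arr.ind = TRUE)
  bm <- which(spec$modulation$b_mask, arr.ind = TRUE)
  nm_src <- spec$sources$name
  nms <- c(paste0("F.", nm_src[fe[, 1]], ">", nm_src[fe[, 2]]),
           paste0("B.", nm_src[be[, 1]], ">", nm_src[be[, 2]]),
           if (nrow(bm)) paste0("b.", nm_src[bm[, 1]], ">", nm_src[bm[, 2]]),
           paste0("I.", nm_src[which(g$input)]),
           "latency")
  n_dyn <- length(nms)
  mom <- paste0("M.", rep(nm_src, each = 3), ".", c("x", "y", "z"))
  nms <- c(nms, mom)
  mean <- stats::setNames(rep(0, length(nms)), nms)
  mean["latency"] <- 64
  var <- stats::setNames(rep(1 / 16, length(nms)), nms)
  var["latency"] <- 256
  var[mom] <- moment_var
  list(names = nms, mean = mean, variance = var,
       idx_f = seq_len(nrow(fe)), fe = fe,
       idx_b = nrow(fe) + seq_len(nrow(be)), be = be,
       idx_bb = if (nrow(bm)) nrow(fe) + nrow(be) + seq_len(nrow(bm)), bm = bm,
       idx_in = nrow(fe) + nrow(be) + nrow(bm) + seq_len(sum(g$input)),
       input_nodes = which(g$input),
       idx_lat = n_dyn, n_dyn = n_dyn,
       idx_mom = n_dyn + seq_along(mom))
}

theta_to_coupling <- function(theta, par, spec) {
  g <- spec$graph
  lf <- g$forward * 0; lb <- g$backward * 0
  lf[par$fe] <- theta[par$idx_f]
  lb[par$be] <- theta[par$idx_b]
  lbb <- spec$modulation$b_mask * 0
  if (length(par$idx_bb)) lbb[par$bm] <- theta[par$idx_bb]
  li <- rep(0, nrow(spec$sources))
  li[par$input_nodes] <- theta[par$idx_in]
  cp <- list(log_forward = lf, log_backward = lb, log_b = lbb,
             log_input = stats::setNames(li, spec$sources$name),
             delay_extrinsic = 16)
  class(cp) <- "coupling_params"
  cp
}

#' Fit a DCM to evoked fields over a post-stimulus window
#'
#' Inverts one model for one subject by variational Laplace: the coupled
#' neural-mass network is integrated per condition, projected to sensors
#' through the dipole lead field, reduced to the leading spatial principal
#' modes of the data, and compared with the observed evoked fields on the
#' samples inside the analysis window. Happy and fearful conditions are
#' predicted jointly with shared parameters; condition differences enter
#' only through the modulation gains \code{log_b}. The free energy of the
#' fit is the per-subject model evidence used for group-level comparison.
#'
#' @param spec a \code{\link{dcm_spec}}.
#' @param erfs named list of condition ERFs (sensors x samples matrices),
#'   with names covering \code{conditions}.
#' @param time sample times of the ERF columns, ms.
#' @param leadfield a \code{\link{build_leadfield}} result for the model's
#'   sources.
#' @param window analysis window \code{c(0, T)} ms (T >= 60).
#' @param conditions conditions entering the likelihood.
#' @param n_modes number of spatial principal modes retained.
#' @param dt integration step, ms.
#' @param nm neural-mass constants.
#' @param max_iter passed to \code{\link{variational_laplace}}.
#' @param band optional band-pass corners (Hz): when the data went through
#'   the preprocessing band-pass, the same zero-phase filter is applied to
#'   the model prediction, so the generative model describes the data as
#'   analysed rather than the raw fields.
#' @param latency_smear optional half-width (ms) of uniform per-trial
#'   latency jitter: trial averaging then blurs the evoked response by the
#'   jitter kernel, and the prediction is blurred identically.
#' @param likelihood_dt spacing (ms) of the samples entering the likelihood
#'   (default: the data spacing). With band-limited data the noise is
#'   autocorrelated; since the noise model is white, sampling the likelihood
#'   near the noise bandwidth avoids overcounting information. Predictions
#'   are still computed and filtered at the data rate before subsampling.
#' @param filter_fs acquisition sampling rate (Hz) at which the data were
#'   band-pass filtered before decimation; when given, predictions are
#'   generated and filtered on that grid so the observation operator matches
#'   the data path exactly.
#' @return Object of class \code{"subdcm_fit"} (extends \code{"vl_fit"}).
#' @export
dcm_fit <- function(spec, erfs, time, leadfield, window = c(0, 300),
                    conditions = c("happy", "fearful"), n_modes = 8,
                    dt = 0.5, nm = nm_params(), max_iter = 64, band = NULL,
                    latency_smear = NULL, likelihood_dt = NULL,
                    filter_fs = NULL) {
  stopifnot(window[1] == 0, window[2] >= 60)
  if (window[2] > max(time)) stop("analysis window exceeds the epoch")
  has_mod <- spec$modulation$pattern != "none"
  if (has_mod && !all(c("happy", "fearful") %in% conditions))
    stop("modulated models need both happy and fearful conditions")
  sel <- which(time >= 0 & time <= window[2])
  tsel <- time[sel]
  keep_dt <- diff(tsel[1:2])
  if (is.null(likelihood_dt)) likelihood_dt <- keep_dt
  lik_by <- round(likelihood_dt / keep_dt)
  stopifnot(lik_by >= 1, abs(lik_by * keep_dt - likelihood_dt) < 1e-9)
  # predictions are computed on an extended horizon so the zero-phase
  # filter has interior support at the window's right edge (the data were
  # filtered on the whole epoch), and — when an acquisition rate is given —
  # on the acquisition-rate grid, so the observation operators (jitter
  # smear, band-pass, decimation) are exactly those the data went through
  ext_end <- min(window[2] + 120, max(time))
  pred_dt <- if (is.null(filter_fs)) keep_dt else 1000 / filter_fs
  t_pred <- seq(0, ext_end, by = pred_dt)
  lik_times <- tsel[seq(1, length(sel), by = lik_by)]
  lik_idx <- match(round(lik_times, 6), round(t_pred, 6))
  stopifnot(!any(is.na(lik_idx)))
  Y_full <- lapply(conditions, function(cn) erfs[[cn]][, sel, drop = FALSE])
  n_sens <- nrow(Y_full[[1]])
  n_modes <- min(n_modes, n_sens)
  # spatial reduction on the concatenated condition ERFs
  U <- svd(do.call(cbind, Y_full), nu = n_modes)$u
  lik_data <- seq(1, length(sel), by = lik_by)
  Ym <- lapply(Y_full, function(Y) crossprod(U, Y)[, lik_data, drop = FALSE])
  # unit-RMS data scaling: keeps the noise log-precision hyperprior's
  # implied residual scale commensurate with the data
  sc_y <- sqrt(mean(unlist(Ym)^2)); if (sc_y <= 0) sc_y <- 1
  y <- unlist(lapply(Ym, function(Y) as.numeric(t(Y)))) / sc_y
  Lm <- crossprod(U, leadfield$gain)                        # modes x 3nsrc
  sc_l <- sqrt(mean(Lm^2)); Lm <- Lm / sc_l
  n_src <- leadfield$n_sources

  par <- dcm_parameters(spec, n_modes)
  cond_mod <- if (has_mod) conditions else "shared"
  pred_filter_full <- make_prediction_filter(band, 1000 / pred_dt,
                                             length(t_pred),
                                             smear = latency_smear)
  pred_filter <- function(M) pred_filter_full(M)[lik_idx, , drop = FALSE]

  # lean integration path: masks and constants hoisted out of the VL loop
  n_src_g <- nrow(spec$sources)
  fwd_mask <- spec$graph$forward
  bwd_mask <- spec$graph$backward
  b_mask <- spec$modulation$b_mask
  input_mask <- spec$graph$input
  self_inhib <- as.numeric(spec$self_inhib)
  pv <- unlist(nm[c("H_e", "H_i", "tau_e", "tau_i", "gamma_1", "gamma_2",
                    "gamma_3", "gamma_4", "rho_1", "rho_2")])
  pv[c("tau_e", "tau_i")] <- pv[c("tau_e", "tau_i")] / 1000
  # integration step: largest divisor of the prediction grid not above dt
  dt_int <- pred_dt / ceiling(pred_dt / dt)
  n_steps <- round(ext_end / dt_int)
  keep_every <- round(pred_dt / dt_int)
  stim_width <- stimulus_params()$width / 1000
  stim_amp <- stimulus_params()$amplitude

  integrate_theta <- function(theta) {
    lf_m <- fwd_mask * 0; lf_m[par$fe] <- theta[par$idx_f]
    lb_m <- bwd_mask * 0; lb_m[par$be] <- theta[par$idx_b]
    gin <- rep(0, n_src_g); gin[par$input_nodes] <- theta[par$idx_in]
    gin <- exp(gin) * input_mask
    out <- lapply(cond_mod, function(cn) {
      lff <- lf_m; lbb <- lb_m
      if (cn == "fearful" && length(par$idx_bb)) {
        bmat <- b_mask * 0; bmat[par$bm] <- theta[par$idx_bb]
        lff <- lff + bmat * b_mask
        lbb <- lbb + bmat * b_mask
      }
      AF <- 32 * exp(lff) * fwd_mask
      AB <- 16 * exp(lbb) * bwd_mask
      arr <- integrate_nm_cpp(AF, AB, as.numeric(gin), self_inhib, pv,
                              theta[par$idx_lat] / 1000, stim_width,
                              stim_amp, 16 / 1000, dt_int / 1000, n_steps,
                              keep_every)
      arr[, , 1]
    })
    names(out) <- cond_mod
    out
  }

  project <- function(trajs, theta) {
    mom <- matrix(theta[par$idx_mom], 3, n_src)
    G <- sapply(seq_len(n_src), function(s)
      Lm[, 3 * (s - 1) + 1:3, drop = FALSE] %*% mom[, s])
    G <- matrix(G, n_modes, n_src)
    unlist(lapply(conditions, function(cn) {
      tr <- if (has_mod) trajs[[cn]] else trajs[["shared"]]
      as.numeric(pred_filter(tr %*% t(G)))
    }))
  }

  generative <- function(theta) project(integrate_theta(theta), theta)

  jacobian <- function(theta) {
    trajs0 <- integrate_theta(theta)
    y0 <- project(trajs0, theta)
    J <- matrix(0, length(y0), length(theta))
    h <- 1e-3
    for (k in seq_len(par$n_dyn)) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      J[, k] <- (project(integrate_theta(tp), tp) -
                   project(integrate_theta(tm), tm)) / (2 * h)
    }
    # moments enter linearly: analytic columns (through the same linear
    # prediction filter)
    for (s in seq_len(n_src)) {
      for (k in 1:3) {
        col <- unlist(lapply(conditions, function(cn) {
          tr <- if (has_mod) trajs0[[cn]] else trajs0[["shared"]]
          as.numeric(pred_filter(tr[, s] %o% Lm[, 3 * (s - 1) + k]))
        }))
        J[, par$idx_mom[3 * (s - 1) + k]] <- col
      }
    }
    J
  }

  priors <- prior_spec(par$mean, par$variance)
  fit <- variational_laplace(generative, priors, y, jacobian = jacobian,
                             max_iter = max_iter)
  fit$spec <- spec
  fit$window <- window
  fit$conditions <- conditions
  fit$n_modes <- n_modes
  fit$time <- lik_times
  fit$time_full <- t_pred
  fit$lik_idx <- lik_idx
  fit$scale <- list(data = sc_y, leadfield = sc_l)
  fit$modes <- U
  fit$data <- y
  fit$par <- par
  fit$Lm <- Lm
  fit$band <- band
  fit$latency_smear <- latency_smear
  fit$likelihood_dt <- likelihood_dt
  class(fit) <- c("subdcm_fit", "vl_fit")
  fit
}

#' Free energy of a fitted model
#' @param object a fitted object.
#' @param ... unused.
#' @export
free_energy <- function(object, ...) UseMethod("free_energy")

#' @export
free_energy.vl_fit <- function(object, ...) object$free_energy

#' @export
coef.vl_fit <- function(object, ...) object$mean

#' @export
vcov.vl_fit <- function(object, ...) object$cov

#' @export
logLik.vl_fit <- function(object, ...) {
  structure(object$free_energy, df = length(object$mean), class = "logLik")
}

#' @export
print.subdcm_fit <- function(x, ...) {
  cat(sprintf("DCM fit: %s, window 0-%g ms, %d modes\n",
              x$spec$name, x$window[2], x$n_modes))
  cat(sprintf("  free energy %.2f nats (%s after %d iterations)\n",
              x$free_energy,
              if (x$converged) "converged" else "not converged",
              length(x$trace)))
  invisible(x)
}

#' @export
summary.subdcm_fit <- function(object, ...) {
  sd <- sqrt(diag(object$cov))
  tab <- data.frame(estimate = object$mean, sd = sd,
                    prior_mean = object$par$mean,
                    row.names = names(object$mean))
  out <- list(model = object$spec$name, window = object$window,
              free_energy = object$free_energy, coefficients = tab,
              converged = object$converged)
  class(out) <- "summary.subdcm_fit"
  out
}

#' @export
print.summary.subdcm_fit <- function(x, ...) {
  cat(sprintf("DCM fit: %s, window 0-%g ms, F = %.2f nats\n",
              x$model, x$window[2], x$free_energy))
  print(utils::head(x$coefficients[order(-abs(x$coefficients$estimate)), ], 12))
  invisible(x)
}

#' Predicted sensor-space (mode-space) evoked response
#' @param object a \code{subdcm_fit}.
#' @param type "modes" for the reduced data space, "sensors" for the sensor
#'   projection.
#' @param ... unused.
#' @export
predict.subdcm_fit <- function(object, type = c("modes", "sensors"), ...) {
  type <- match.arg(type)
  pred <- refit_prediction(object, object$mean)
  if (type == "modes") return(pred)
  lapply(pred, function(P) object$modes %*% t(P) * object$scale$data)
}

refit_prediction <- function(object, theta) {
  n_t <- length(object$time)
  yhat <- rebuild_generative(object)(theta)
  per <- n_t * object$n_modes
  out <- lapply(seq_along(object$conditions), function(i)
    matrix(yhat[(i - 1) * per + seq_len(per)], n_t, object$n_modes))
  names(out) <- object$conditions
  out
}

# reconstruct the generative closure of a fit (used by predict/residuals/
# simulate and by the contribution analysis)
rebuild_generative <- function(object) {
  spec <- object$spec
  par <- object$par
  has_mod <- spec$modulation$pattern != "none"
  cond_mod <- if (has_mod) object$conditions else "shared"
  time_full <- if (!is.null(object$time_full)) object$time_full
               else object$time
  lik_idx <- if (!is.null(object$lik_idx)) object$lik_idx
             else seq_along(time_full)
  keep_dt <- diff(time_full[1:2])
  Lm <- object$Lm
  n_src <- nrow(spec$sources)
  n_modes <- object$n_modes
  pred_filter_full <- make_prediction_filter(object$band, 1000 / keep_dt,
                                             length(time_full),
                                             smear = object$latency_smear)
  pred_filter <- function(M) pred_filter_full(M)[lik_idx, , drop = FALSE]
  function(theta) {
    cp <- theta_to_coupling(theta, par, spec)
    stim <- stimulus_params(onset_latency = theta[par$idx_lat])
    trajs <- lapply(cond_mod, function(cn) {
      cond <- if (cn == "shared") "happy" else cn
      tr <- integrate_network(spec, cp = cp, stim = stim, condition = cond,
                              duration = max(time_full),
                              dt = keep_dt / ceiling(keep_dt), keep_dt = keep_dt)
      tr$data[, , "principal", drop = FALSE][, , 1]
    })
    names(trajs) <- cond_mod
    mom <- matrix(theta[par$idx_mom], 3, n_src)
    G <- sapply(seq_len(n_src), function(s)
      Lm[, 3 * (s - 1) + 1:3, drop = FALSE] %*% mom[, s])
    G <- matrix(G, n_modes, n_src)
    unlist(lapply(object$conditions, function(cn) {
      tr <- if (has_mod) trajs[[cn]] else trajs[["shared"]]
      as.numeric(pred_filter(tr %*% t(G)))
    }))
  }
}

#' @export
residuals.subdcm_fit <- function(object, ...) {
  pred <- unlist(refit_prediction(object, object$mean))
  object$data - pred
}

#' Simulate source activity from a fitted DCM
#'
#' Integrates the network at the posterior mean (or at user-supplied
#' parameters) and returns per-condition source trajectories.
#'
#' @param object a \code{subdcm_fit}.
#' @param nsim unused (single deterministic trajectory per condition).
#' @param seed unused.
#' @param theta parameter vector (default posterior mean).
#' @param duration integration time, ms (default the fit window).
#' @param ... unused.
#' @export
simulate.subdcm_fit <- function(object, nsim = 1, seed = NULL,
                                theta = object$mean,
                                duration = object$window[2], ...) {
  spec <- object$spec
  cp <- theta_to_coupling(theta, object$par, spec)
  stim <- stimulus_params(onset_latency = theta[object$par$idx_lat])
  out <- lapply(object$conditions, function(cn)
    integrate_network(spec, cp = cp, stim = stim, condition = cn,
                      duration = duration, keep_dt = 1))
  names(out) <- object$conditions
  out
}

#' @export
plot.subdcm_fit <- function(x, modes = 1:min(4, x$n_modes), ...) {
  pred <- refit_prediction(x, x$mean)
  n_t <- length(x$time)
  per <- n_t * x$n_modes
  old <- graphics::par(mfrow = c(length(modes), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (m in modes) {
    i <- 1
    Y <- matrix(x$data[seq_len(per)], n_t, x$n_modes)
    graphics::plot(x$time, Y[, m], type = "l", ylab = paste("mode", m),
                   xlab = "time (ms)", ...)
    graphics::lines(x$time, pred[[1]][, m], col = 2)
  }
  invisible(x)
}
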