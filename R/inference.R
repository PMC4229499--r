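#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over model frequencies: subject-wise model
#' assignments \code{u_nk} proportional to
#' \code{exp(log_evidence_nk + psi(alpha_k) - psi(sum(alpha)))} and counts
#' \code{alpha_k = alpha0 + sum_n u_nk}, iterated to convergence. Only
#' within-subject evidence differences matter: adding a constant to one
#' subject's row leaves the result unchanged.
#'
#' @param log_evidence subjects x models matrix of log model evidences
#'   (free energies), nats.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param tol convergence on \code{max |delta alpha|}.
#' @param n_samples Monte-Carlo samples for K > 2 exceedance.
#' @param seed seed for the exceedance sampler.
#' @return List of class \code{"bms_result"}: \code{alpha},
#'   \code{expected_prob}, \code{exceedance_prob}, \code{u} (subject
#'   assignment weights), \code{n_samples}.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-4,
                    n_samples = 1e6, seed = 1) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence))) stop("non-finite log evidences")
  N <- nrow(log_evidence); K <- ncol(log_evidence)
  stopifnot(N >= 1, K >= 2)
  alpha <- rep(alpha0, K)
  for (it in 1:512) {
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    u <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  out <- list(alpha = stats::setNames(alpha, colnames(log_evidence)),
              expected_prob = stats::setNames(alpha / sum(alpha),
                                              colnames(log_evidence)),
              exceedance_prob = exceedance(alpha, n_samples = n_samples,
                                           seed = seed),
              u = u, n_samples = n_samples)
  if (!is.null(colnames(log_evidence)))
    names(out$exceedance_prob) <- colnames(log_evidence)
  class(out) <- "bms_result"
  out
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability that each model's frequency exceeds all others under a
#' Dirichlet distribution. Analytic (regularized incomplete Beta) for two
#' models; Monte-Carlo Dirichlet sampling otherwise.
#'
#' @param alpha Dirichlet parameters (> 0).
#' @param n_samples Monte-Carlo sample count for K > 2.
#' @param seed RNG seed for the sampler.
#' @param method "auto" (analytic for K = 2, sampling otherwise),
#'   "analytic" (K = 2 only) or "sampling".
#' @export
exceedance <- function(alpha, n_samples = 1e6, seed = 1,
                       method = c("auto", "analytic", "sampling")) {
  stopifnot(all(alpha > 0))
  method <- match.arg(method)
  K <- length(alpha)
  if (method == "analytic" && K != 2)
    stop("analytic exceedance only available for two models")
  if (K == 2 && method != "sampling") {
    p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(stats::setNames(c(p1, 1 - p1), names(alpha)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  win <- max.col(g)
  stats::setNames(tabulate(win, K) / n_samples, names(alpha))
}

#' Family-level model comparison
#'
#' Pools model evidence within families under a uniform within-family prior
#' (log-mean-exp of member evidences per subject), then runs random-effects
#' BMS over the families.
#'
#' @param log_evidence subjects x models matrix.
#' @param partition list mapping family name -> column indices or names.
#' @param ... passed to \code{\link{rfx_bms}}.
#' @export
family_compare <- function(log_evidence, partition, ...) {
  log_evidence <- as.matrix(log_evidence)
  cols <- seq_len(ncol(log_evidence))
  idx <- lapply(partition, function(m) {
    i <- if (is.character(m)) match(m, colnames(log_evidence)) else m
    if (any(is.na(i)) || length(i) == 0) stop("empty or unknown family")
    i
  })
  if (length(unique(unlist(idx))) != length(unlist(idx)) ||
      !setequal(unlist(idx), cols))
    stop("partition must cover all models disjointly")
  fam_ev <- sapply(idx, function(i) {
    x <- log_evidence[, i, drop = FALSE]
    m <- apply(x, 1, max)
    m + log(rowMeans(exp(x - m)))
  })
  fam_ev <- matrix(fam_ev, nrow = nrow(log_evidence),
                   dimnames = list(NULL, names(partition)))
  rfx_bms(fam_ev, ...)
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$alpha), "models/families\n")
  print(data.frame(alpha = round(x$alpha, 2),
                   expected = round(x$expected_prob, 4),
                   exceedance = round(x$exceedance_prob, 4)))
  invisible(x)
}

#' Window-wise family and model comparison (the time-resolved sweep)
#'
#' For each post-stimulus window, runs family-level BMS (dual-route vs
#' cortical-only) and model-level BMS, tabulating expected and exceedance
#' probabilities as a function of window length.
#'
#' @param evidence subjects x models x windows array of free energies, with
#'   model names on dimension 2 and window labels (T in ms) on dimension 3.
#' @param partition family partition (see \code{\link{family_compare}}).
#' @param ... passed to \code{\link{rfx_bms}}.
#' @return Object of class \code{"sweep_result"}: data.frame \code{family}
#'   (window, family, expected, exceedance), data.frame \code{model}, and
#'   the per-window \code{bms} objects.
#' @export
window_sweep <- function(evidence, partition, ...) {
  stopifnot(length(dim(evidence)) == 3)
  if (any(!is.finite(evidence))) {
    bad <- which(!is.finite(evidence), arr.ind = TRUE)
    stop("missing evidence cells (subject, model, window): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  wins <- dimnames(evidence)[[3]]
  if (is.null(wins)) wins <- as.character(seq_len(dim(evidence)[3]))
  fam_rows <- list(); mod_rows <- list(); bms_list <- list()
  for (w in seq_along(wins)) {
    ev <- evidence[, , w, drop = FALSE][, , 1]
    ev <- matrix(ev, dim(evidence)[1], dim(evidence)[2],
                 dimnames = dimnames(evidence)[1:2])
    fb <- family_compare(ev, partition, ...)
    mb <- rfx_bms(ev, ...)
    fam_rows[[w]] <- data.frame(window = wins[w], family = names(fb$alpha),
                                expected = unname(fb$expected_prob),
                                exceedance = unname(fb$exceedance_prob))
    mod_rows[[w]] <- data.frame(window = wins[w], model = names(mb$alpha),
                                expected = unname(mb$expected_prob),
                                exceedance = unname(mb$exceedance_prob))
    bms_list[[wins[w]]] <- list(family = fb, model = mb)
  }
  out <- list(family = do.call(rbind, fam_rows),
              model = do.call(rbind, mod_rows), bms = bms_list)
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Window sweep, family level:\n")
  print(stats::reshape(x$family[, c("window", "family", "exceedance")],
                       direction = "wide", idvar = "window",
                       timevar = "family"))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, which = c("exceedance", "expected"), ...) {
  which <- match.arg(which)
  fams <- unique(x$family$family)
  wins <- unique(x$family$window)
  wn <- as.numeric(wins)
  graphics::plot(range(wn), c(0, 1), type = "n", xlab = "window end (ms)",
                 ylab = paste("family", which), ...)
  for (i in seq_along(fams)) {
    y <- x$family[[which]][x$family$family == fams[i]]
    graphics::lines(wn, y, col = i, lwd = 2)
    graphics::points(wn, y, col = i, pch = 16)
  }
  graphics::legend("right", legend = fams, col = seq_along(fams), lwd = 2,
                   bty = "n")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Connectivity contribution (perturbation) analysis
#'
#' Simulates the change in source activity caused by a small enforced
#' increase in the pulvinar-to-amygdala connection: each fitted model is
#' integrated at its posterior mean with and without the increment added to
#' the PUL->AMY forward log-coupling, and the source-level differences are
#' averaged over models and participants.
#'
#' @param fits list of \code{subdcm_fit} objects from the dual-route family
#'   (subjects x models).
#' @param increment additive change to the PUL->AMY forward log-scaling
#'   (default 0.0025).
#' @param duration simulation length, ms (default 300).
#' @param drop_backward optional n x 2 character matrix of backward edges
#'   (from, to) whose coupling is forced to zero in both simulations (used
#'   to probe mediation by recurrent feedback).
#' @return Object of class \code{"contribution_result"}: \code{delta}
#'   (time x sources x populations, averaged over fits and conditions),
#'   \code{per_condition}, \code{time}, \code{increment}, \code{n_fits}.
#' @export
contribution_analysis <- function(fits, increment = 0.0025, duration = 300,
                                  drop_backward = NULL) {
  if (inherits(fits, "subdcm_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  acc <- NULL; acc_cond <- NULL; n <- 0
  for (fit in fits) {
    spec <- fit$spec
    pul_amy <- which(spec$graph$forward &
                       outer(spec$sources$structure == "PUL",
                             spec$sources$structure == "AMY"), arr.ind = TRUE)
    if (nrow(pul_amy) == 0)
      stop("model has no pulvinar-to-amygdala connection")
    if (!is.null(drop_backward)) {
      for (r in seq_len(nrow(drop_backward)))
        spec$graph$backward[drop_backward[r, 1], drop_backward[r, 2]] <- FALSE
    }
    theta <- fit$mean
    cp <- theta_to_coupling(theta, fit$par, spec)
    cp_pert <- cp
    cp_pert$log_forward[pul_amy] <- cp_pert$log_forward[pul_amy] + increment
    stim <- stimulus_params(onset_latency = theta[fit$par$idx_lat])
    for (cond in fit$conditions) {
      base <- integrate_network(spec, cp = cp, stim = stim, condition = cond,
                                duration = duration, keep_dt = 1)
      pert <- integrate_network(spec, cp = cp_pert, stim = stim,
                                condition = cond, duration = duration,
                                keep_dt = 1)
      d <- pert$data - base$data
      if (is.null(acc)) {
        acc <- d * 0
        acc_cond <- stats::setNames(
          rep(list(d * 0), length(fit$conditions)), fit$conditions)
        time <- base$time
      }
      acc <- acc + d
      acc_cond[[cond]] <- acc_cond[[cond]] + d
      n <- n + 1
    }
  }
  per_cond <- lapply(acc_cond, function(a) a / (n / length(acc_cond)))
  out <- list(delta = acc / n, per_condition = per_cond, time = time,
              increment = increment, n_fits = length(fits))
  class(out) <- "contribution_result"
  out
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("Contribution analysis: increment %+g on PUL->AMY, %d fits\n",
              x$increment, x$n_fits))
  pk <- apply(abs(x$delta[, , "principal"]), 2, max)
  print(round(pk, 6))
  invisible(x)
}

#' @export
plot.contribution_result <- function(x, sources = c("PUL.L", "AMY.L"), ...) {
  old <- graphics::par(mfrow = c(length(sources), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  pops <- dimnames(x$delta)[[3]]
  for (s in sources) {
    yl <- range(x$delta[, s, ])
    graphics::plot(x$time, x$delta[, s, 1], type = "l", col = 2, ylim = yl,
                   main = s, xlab = "time (ms)", ylab = "delta (mV)")
    for (p in 2:length(pops))
      graphics::lines(x$time, x$delta[, s, p], col = c(2, 4, 3)[p])
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
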