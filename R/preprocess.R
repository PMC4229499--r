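# -- IIR filter design ------------------------------------------------------
# Butterworth low/high-pass via the bilinear transform. Hand-rolled because
# no DSP package ships with the runtime; contracts are asserted in the tests
# (passband flatness, stopband attenuation, zero DC gain of the high-pass).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth low- or high-pass of order \code{n} with cutoff
#' \code{fc} (Hz) at sampling rate \code{fs}, designed by bilinear transform
#' of the analog prototype.
#'
#' @param n filter order.
#' @param fc cutoff frequency, Hz; \code{fs} sampling rate, Hz.
#' @param type "low" or "high".
#' @return List with numerator \code{b} and denominator \code{a}.
#' @export
butter_design <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fc < fs / 2)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))     # unit LHP prototype poles
  warped <- 2 * fs * tan(pi * fc / fs)
  if (type == "low") {
    ps <- warped * p
    zs <- complex(0)
  } else {
    ps <- warped / p
    zs <- rep(0 + 0i, n)
  }
  bilin <- function(s) (2 * fs + s) / (2 * fs - s)
  pz <- bilin(ps)
  zz <- c(bilin(zs), rep(-1 + 0i, n - length(zs)))
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  # normalize gain at the reference frequency (DC for low-pass, Nyquist for
  # high-pass)
  if (type == "low") {
    g <- sum(b) / sum(a)
  } else {
    s <- rep_len(c(1, -1), length(b))
    g <- sum(b * s) / sum(a * rep_len(c(1, -1), length(a)))
  }
  list(b = b / g, a = a)
}

# direct-form IIR along rows of a matrix (time in rows, channels in columns)
iir_filter <- function(b, a, x) {
  if (is.null(dim(x))) x <- matrix(x)
  nb <- length(b); na <- length(a)
  y <- matrix(0, nrow(x), ncol(x))
  for (t in seq_len(nrow(x))) {
    acc <- b[1] * x[t, ]
    for (j in seq_len(min(nb, t))[-1]) acc <- acc + b[j] * x[t - j + 1, ]
    for (j in seq_len(min(na, t))[-1]) acc <- acc - a[j] * y[t - j + 1, ]
    y[t, ] <- acc / a[1]
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter twice, once forward and once time-reversed, with odd
#' reflection padding at both ends, giving zero phase distortion and the
#' squared magnitude response.
#'
#' @param b,a filter coefficients (see \code{\link{butter_design}}).
#' @param x numeric vector or matrix (time in rows).
#' @export
filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x)
  npad <- 3 * (max(length(a), length(b)) - 1)
  stopifnot(nrow(x) > npad)
  top <- 2 * x[rep(1, npad), , drop = FALSE] - x[npad + 2L - seq_len(npad), , drop = FALSE]
  nr <- nrow(x)
  bot <- 2 * x[rep(nr, npad), , drop = FALSE] - x[nr - seq_len(npad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_filter(b, a, xp)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- iir_filter(b, a, y)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- y[npad + seq_len(nr), , drop = FALSE]
  if (vec) y[, 1] else y
}

# -- containers -------------------------------------------------------------

#' Continuous multichannel recording
#' @param data samples x channels matrix.
#' @param fs sampling rate, Hz.
#' @param sensors optional sensor metadata (data.frame).
#' @export
meg_recording <- function(data, fs, sensors = NULL) {
  stopifnot(is.matrix(data), fs > 0, all(is.finite(data)))
  r <- list(data = data, fs = fs, sensors = sensors)
  class(r) <- "meg_recording"
  r
}

#' Epoched trial set
#'
#' @param data trials x sensors x samples array (fT).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample relative to stimulus onset, ms.
#' @param labels per-trial condition labels (neutral/happy/fearful).
#' @param sensors sensor metadata data.frame with at least a
#'   \code{hemisphere} column.
#' @return List of class \code{"epoch_set"}; \code{time} holds the sample
#'   times in ms.
#' @export
epoch_set <- function(data, fs, t0, labels, sensors = NULL) {
  stopifnot(length(dim(data)) == 3, all(is.finite(data)),
            length(labels) == dim(data)[1],
            all(labels %in% c("neutral", "happy", "fearful")))
  e <- list(data = data, fs = fs, t0 = t0,
            time = t0 + (seq_len(dim(data)[3]) - 1) * 1000 / fs,
            labels = as.character(labels), sensors = sensors)
  class(e) <- "epoch_set"
  e
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d sensors x %d samples @ %g Hz, t in [%g, %g] ms\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time)))
  print(table(x$labels))
  invisible(x)
}

# -- pipeline stages --------------------------------------------------------

#' Band-pass filter and downsample a continuous recording
#'
#' Zero-phase 4th-order Butterworth high-pass and low-pass cascade followed
#' by integer-factor decimation (the 30 Hz low-pass is the anti-alias filter
#' for the 200 Hz target rate).
#'
#' @param rec a \code{\link{meg_recording}}.
#' @param band c(high-pass, low-pass) corner frequencies, Hz.
#' @param fs_out target sampling rate, Hz (must divide \code{rec$fs}).
#' @export
bandpass_and_downsample <- function(rec, band = c(0.5, 30), fs_out = 200) {
  stopifnot(inherits(rec, "meg_recording"))
  if (rec$fs < 2 * band[2])
    stop("sampling rate violates Nyquist for the requested band")
  factor <- rec$fs / fs_out
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs_out must divide the input sampling rate")
  x <- filter_band(rec$data, rec$fs, band)
  idx <- seq(1, nrow(x), by = round(factor))
  meg_recording(x[idx, , drop = FALSE], fs_out, rec$sensors)
}

filter_band <- function(x, fs, band = c(0.5, 30), order = 4) {
  hp <- butter_design(order, band[1], fs, "high")
  lp <- butter_design(order, band[2], fs, "low")
  filtfilt(lp$b, lp$a, filtfilt(hp$b, hp$a, x))
}

#' Epoch a continuous recording with baseline correction
#'
#' @param rec a \code{\link{meg_recording}}.
#' @param events data.frame with \code{sample} (stimulus-onset sample index)
#'   and \code{label} columns.
#' @param window epoch window in ms relative to onset (both endpoints
#'   included).
#' @param baseline baseline window in ms; the per-trial, per-sensor mean over
#'   it is subtracted.
#' @export
epoch_and_baseline <- function(rec, events, window = c(-200, 600),
                               baseline = c(-200, 0)) {
  fs <- rec$fs
  i0 <- round(window[1] * fs / 1000)
  i1 <- round(window[2] * fs / 1000)
  n_samp <- i1 - i0 + 1
  n_tr <- nrow(events)
  if (any(events$sample + i0 < 1) || any(events$sample + i1 > nrow(rec$data)))
    stop("event too close to the recording edge for the epoch window")
  data <- array(0, c(n_tr, ncol(rec$data), n_samp))
  for (k in seq_len(n_tr))
    data[k, , ] <- t(rec$data[events$sample[k] + i0:i1, , drop = FALSE])
  e <- epoch_set(data, fs, t0 = i0 * 1000 / fs, labels = events$label,
                 sensors = rec$sensors)
  baseline_correct(e, baseline)
}

baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  sel <- epochs$time >= baseline[1] & epochs$time <= baseline[2]
  mu <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(mu)   # recycles over samples
  epochs
}

#' Filter, downsample and baseline-correct an epoched set
#'
#' Epoch-wise counterpart of \code{\link{bandpass_and_downsample}} for data
#' that is generated (or imported) already epoched at the acquisition rate.
#'
#' @param epochs an \code{\link{epoch_set}} at the raw rate.
#' @inheritParams bandpass_and_downsample
#' @param baseline baseline window, ms.
#' @export
preprocess_epochs <- function(epochs, band = c(0.5, 30), fs_out = 200,
                              baseline = c(-200, 0)) {
  fs <- epochs$fs
  if (fs < 2 * band[2]) stop("sampling rate violates Nyquist")
  factor <- round(fs / fs_out)
  stopifnot(abs(fs / fs_out - factor) < 1e-9)
  d <- dim(epochs$data)
  idx <- seq(1, d[3], by = factor)
  out <- array(0, c(d[1], d[2], length(idx)))
  for (k in seq_len(d[1])) {
    x <- t(epochs$data[k, , ])               # samples x sensors
    out[k, , ] <- t(filter_band(x, fs, band)[idx, , drop = FALSE])
  }
  e <- epoch_set(out, fs_out, epochs$t0, epochs$labels, epochs$sensors)
  baseline_correct(e, baseline)
}

#' Robust (outlier-weighted) trial averaging
#'
#' Iteratively reweighted mean per sensor and sample across trials with a
#' bisquare weight function (tuning constant 4.685) on residuals scaled by
#' 1.4826 * MAD, so artifact-laden trial segments are down-weighted rather
#' than rejected wholesale.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param condition condition label to average, or NULL for all trials.
#' @param max_iter,tol iteration controls.
#' @return List with \code{erf} (sensors x samples weighted mean) and
#'   \code{weights} (trials x sensors x samples, in [0, 1]).
#' @export
robust_average <- function(epochs, condition = NULL, max_iter = 20,
                           tol = 1e-6) {
  sel <- if (is.null(condition)) rep(TRUE, length(epochs$labels))
         else epochs$labels == condition
  if (sum(sel) < 2) stop("robust averaging needs at least 2 trials")
  x <- epochs$data[sel, , , drop = FALSE]
  d <- dim(x)
  xm <- matrix(x, d[1])                      # trials x (sensors*samples)
  cw <- 4.685
  # robust start: the column median survives gross artifact trials that
  # would contaminate an initial arithmetic mean
  mu <- apply(xm, 2, stats::median)
  w <- matrix(1, d[1], ncol(xm))
  for (it in seq_len(max_iter)) {
    r <- xm - rep(mu, each = d[1])
    s <- 1.4826 * apply(abs(r), 2, stats::median)
    s[s < .Machine$double.eps] <- Inf        # degenerate: all weights 1
    u <- abs(r) / rep(cw * s, each = d[1])
    w_new <- ifelse(u < 1, (1 - u^2)^2, 0)
    delta <- max(abs(w_new - w))
    w <- w_new
    cs <- colSums(w)
    bad <- cs < 1e-10          # total collapse: fall back to uniform weights
    if (any(bad)) { w[, bad] <- 1; cs[bad] <- d[1] }
    mu <- colSums(w * xm) / cs
    if (delta < tol) break
  }
  list(erf = matrix(mu, d[2], d[3]),
       weights = array(w, d))
}

#' Select sensors of interest (SOI)
#'
#' A sensor is selected when the group-level condition-average response
#' differs from baseline (one-sample two-sided t-test, p < alpha,
#' uncorrected) over a contiguous window of at least \code{min_duration} ms
#' centred on that sensor's peak response within the search window. Because
#' selection sees only the condition average it is orthogonal to condition
#' contrasts.
#'
#' @param group_erfs subjects x sensors x samples array of condition-average
#'   ERFs.
#' @param time sample times, ms.
#' @param alpha significance level.
#' @param min_duration minimal significant span, ms.
#' @param search_window peak search window, ms.
#' @return List of class \code{"soi_set"}: \code{index}, \code{polarity},
#'   \code{alpha}, \code{peak_sample}.
#' @export
select_soi <- function(group_erfs, time, alpha = 0.05, min_duration = 25,
                       search_window = c(0, 300)) {
  d <- dim(group_erfs)
  stopifnot(d[1] >= 2, length(time) == d[3])
  fs <- 1000 / diff(time[1:2])
  n_req <- round(min_duration * fs / 1000) + 1
  if (n_req < 2) stop("min_duration not representable at this sampling rate")
  mu <- apply(group_erfs, c(2, 3), mean)
  se <- apply(group_erfs, c(2, 3), stats::sd) / sqrt(d[1])
  tstat <- mu / pmax(se, .Machine$double.eps)
  pval <- 2 * stats::pt(-abs(tstat), df = d[1] - 1)
  in_win <- which(time >= search_window[1] & time <= search_window[2])
  idx <- integer(0); pol <- integer(0); pk <- integer(0)
  lo_off <- floor((n_req - 1) / 2); hi_off <- ceiling((n_req - 1) / 2)
  for (s in seq_len(d[2])) {
    peak <- in_win[which.max(abs(mu[s, in_win]))]
    span <- (peak - lo_off):(peak + hi_off)
    if (min(span) < 1 || max(span) > d[3]) next
    if (all(pval[s, span] < alpha)) {
      idx <- c(idx, s)
      pol <- c(pol, sign(mu[s, peak]))
      pk <- c(pk, peak)
    }
  }
  out <- list(index = idx, polarity = pol, alpha = alpha, peak_sample = pk)
  class(out) <- "soi_set"
  out
}

#' Mean ERF over the sensors of interest
#'
#' Averages each subject's per-condition ERF over the SOI sensors after
#' flipping the sign of right-hemisphere sensors so that dipolar field
#' polarities match across hemispheres.
#'
#' @param erfs subjects x conditions x sensors x samples array (dimnames on
#'   the condition axis) or a list of per-subject lists of
#'   sensors x samples matrices.
#' @param soi a \code{\link{soi_set}}.
#' @param hemisphere character vector of per-sensor hemisphere tags
#'   ("left"/"right").
#' @return subjects x conditions x samples array.
#' @export
mean_soi_erf <- function(erfs, soi, hemisphere) {
  if (length(soi$index) == 0) stop("empty SOI set")
  stopifnot(length(dim(erfs)) == 4)
  d <- dim(erfs)
  flip <- ifelse(hemisphere == "right", -1, 1)
  out <- array(0, c(d[1], d[2], d[4]),
               dimnames = list(NULL, dimnames(erfs)[[2]], NULL))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      x <- erfs[i, j, soi$index, , drop = FALSE] * flip[soi$index]
      out[i, j, ] <- apply(array(x, c(length(soi$index), d[4])), 2, mean)
    }
  out
}

#' Paired condition contrasts on the SOI-mean ERF
#'
#' Averages the SOI-mean ERF over the analysis window per subject and
#' condition, then runs two-sided paired t-tests between condition pairs.
#'
#' @param soi_means subjects x conditions x samples array (condition
#'   dimnames required).
#' @param time sample times, ms.
#' @param window averaging window, ms (default the 150-190 ms peak window).
#' @param pairs list of length-2 condition-name vectors.
#' @return data.frame with columns pair, t, df, p.
#' @export
condition_contrast <- function(soi_means, time,
                               window = c(150, 190),
                               pairs = list(c("fearful", "happy"),
                                            c("fearful", "neutral"))) {
  stopifnot(dim(soi_means)[1] >= 2)
  sel <- time >= window[1] & time <= window[2]
  scal <- apply(soi_means[, , sel, drop = FALSE], c(1, 2), mean)
  res <- lapply(pairs, function(p) {
    d <- scal[, p[1]] - scal[, p[2]]
    n <- length(d)
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = n - 1, p.value = 1)
    } else {
      tt <- stats::t.test(scal[, p[1]], scal[, p[2]], paired = TRUE)
    }
    data.frame(pair = paste(p, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, res)
}

#' Mass-univariate paired tests over sensors and samples
#'
#' Paired t-test at every sensor/sample between two conditions with
#' Bonferroni correction over all sensors x samples comparisons.
#'
#' @param a,b subjects x sensors x samples arrays (paired by subject).
#' @param alpha family-wise error level.
#' @param correction only "bonferroni".
#' @return List with \code{t}, \code{p} (sensors x samples),
#'   \code{significant} (logical), \code{n_comparisons},
#'   \code{threshold}.
#' @export
sensorwise_tests <- function(a, b, alpha = 0.05,
                             correction = c("bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(all(dim(a) == dim(b)), dim(a)[1] >= 2)
  d <- a - b
  n <- dim(d)[1]
  mu <- apply(d, c(2, 3), mean)
  se <- apply(d, c(2, 3), stats::sd) / sqrt(n)
  tstat <- mu / pmax(se, .Machine$double.eps)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  n_comp <- prod(dim(mu))
  thr <- alpha / n_comp
  list(t = tstat, p = p, significant = p < thr,
       n_comparisons = n_comp, threshold = thr)
}

#' Write an epoched set to CSV
#'
#' Long-format serialization (columns trial, sensor, time_ms, condition,
#' value) with the sampling metadata in a JSON sidecar, readable again with
#' \code{\link{read_epochs_csv}}.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param file CSV path; the sidecar is written to \code{<file>.meta.json}.
#' @export
write_epochs_csv <- function(epochs, file) {
  d <- dim(epochs$data)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    sensor = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(epochs$time, each = d[1] * d[2]),
    condition = rep(epochs$labels, times = d[2] * d[3]),
    value = as.numeric(epochs$data)
  )
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(
    list(fs = epochs$fs, t0 = epochs$t0,
         hemisphere = epochs$sensors$hemisphere),
    paste0(file, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an epoched set written by \code{\link{write_epochs_csv}}
#' @param file CSV path.
#' @export
read_epochs_csv <- function(file) {
  df <- utils::read.csv(file)
  meta <- jsonlite::fromJSON(paste0(file, ".meta.json"))
  d <- c(max(df$trial), max(df$sensor), length(unique(df$time_ms)))
  data <- array(df$value[order(df$time_ms, df$sensor, df$trial)], d)
  labels <- df$condition[order(df$time_ms, df$sensor, df$trial)][seq_len(d[1])]
  sensors <- if (!is.null(meta$hemisphere))
    data.frame(hemisphere = meta$hemisphere)
  epoch_set(data, meta$fs, meta$t0, labels, sensors)
}
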