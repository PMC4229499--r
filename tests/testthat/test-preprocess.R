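test_that("band-pass and downsampling meet the declared frequency response", {
  fs <- 600
  t <- seq(0, 5, by = 1 / fs)
  bb <- function(x) filter_band(matrix(x), fs)[, 1]
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  # DC rejected by the 0.5 Hz high-pass
  dc <- bb(rep(1, length(t)))
  expect_lt(abs(mean(dc[mid])), 0.01)
  # 50 Hz attenuated by at least 20 dB
  a50 <- max(abs(bb(sin(2 * pi * 50 * t))[mid]))
  expect_lt(20 * log10(a50), -20)
  # 10 Hz passband preserved within 5%
  a10 <- max(abs(bb(sin(2 * pi * 10 * t))[mid]))
  expect_lt(abs(a10 - 1), 0.05)
  # decimation to 200 Hz
  rec <- meg_recording(cbind(sin(2 * pi * 10 * t), cos(2 * pi * 5 * t)), fs)
  out <- bandpass_and_downsample(rec, c(0.5, 30), 200)
  expect_equal(out$fs, 200)
  expect_equal(nrow(out$data), ceiling(length(t) / 3))
  expect_error(bandpass_and_downsample(meg_recording(matrix(rnorm(100)), 50),
                                       c(0.5, 30), 25), "Nyquist")
})

test_that("epoching gives 161 baseline-zero samples at 200 Hz", {
  fs <- 200
  set.seed(1)
  n <- 2000
  rec <- meg_recording(matrix(rnorm(3 * n), n, 3), fs)
  events <- data.frame(sample = c(200, 600, 1100), label = "happy")
  ep <- epoch_and_baseline(rec, events, window = c(-200, 600),
                           baseline = c(-200, 0))
  expect_equal(dim(ep$data), c(3, 3, 161))
  expect_equal(range(ep$time), c(-200, 600))
  sel <- ep$time >= -200 & ep$time <= 0
  expect_lt(max(abs(apply(ep$data[, , sel], c(1, 2), mean))), 1e-10)
  # event too close to the recording edge
  expect_error(epoch_and_baseline(rec, data.frame(sample = n, label = "happy")),
               "edge")
})

test_that("robust averaging reduces to the mean and suppresses artifact trials", {
  fs <- 200
  n_t <- 161
  time <- seq(-200, 600, by = 5)
  # identical trials: exact mean, unit weights
  base <- sin(2 * pi * (0:(n_t - 1)) / 40)
  ident <- aperm(array(rep(base, each = 50 * 2), c(50, 2, n_t)), c(1, 2, 3))
  ep <- epoch_set(ident, fs, -200, rep("happy", 50),
                  data.frame(hemisphere = c("left", "right")))
  ra <- robust_average(ep, "happy")
  expect_equal(ra$erf[1, ], base, tolerance = 1e-12)
  expect_true(all(ra$weights == 1))
  # 49 clean + 1 gross artifact trial
  set.seed(7)
  clean <- array(rnorm(49 * 2 * n_t, 0, 0.1), c(49, 2, n_t)) +
    rep(base, each = 49 * 2)
  bad <- array(50 * rep(base, each = 2), c(1, 2, n_t)) +
    rnorm(2 * n_t, 0, 0.1)
  x <- array(0, c(50, 2, n_t))
  x[1:49, , ] <- clean; x[50, , ] <- bad
  ep2 <- epoch_set(x, fs, -200, rep("happy", 50),
                   data.frame(hemisphere = c("left", "right")))
  ra2 <- robust_average(ep2, "happy")
  expect_true(all(ra2$weights >= 0 & ra2$weights <= 1))
  big <- abs(base) > 0.5          # samples where the artifact is gross
  expect_lt(max(ra2$weights[50, , big]), 0.1)
  clean_mean <- apply(clean, c(2, 3), mean)
  scale_ref <- max(abs(clean_mean))
  expect_lt(max(abs(ra2$erf - clean_mean)[, big]), 0.02 * scale_ref)
  expect_error(robust_average(ep2, "absent"), "at least 2")
})

test_that("SOI selection needs a sustained response and ignores condition labels", {
  fs <- 200
  time <- seq(-200, 600, by = 5)
  n_t <- length(time)
  n_sub <- 8
  set.seed(11)
  g <- array(rnorm(n_sub * 3 * n_t, 0, 0.05), c(n_sub, 3, n_t))
  bump <- function(center, width) exp(-0.5 * ((time - center) / width)^2)
  # sensor 1: strong sustained 40 ms response; sensor 2: 10 ms blip;
  # sensor 3: noise only
  g[, 1, ] <- g[, 1, ] + 5 * rep(bump(150, 20), each = n_sub)
  g[, 2, ] <- g[, 2, ] + 5 * rep(bump(150, 2), each = n_sub)
  soi <- select_soi(g, time, alpha = 0.05, min_duration = 25,
                    search_window = c(0, 300))
  expect_true(1 %in% soi$index)
  expect_false(2 %in% soi$index)
  expect_false(3 %in% soi$index)
  expect_true(all(soi$polarity %in% c(-1, 1)))
  expect_error(select_soi(g, time, min_duration = 2), "representable")
  # selection sees only the condition average: permuting labels changes
  # nothing
  conds <- array(rnorm(n_sub * 3 * 3 * n_t, 0, 0.05), c(n_sub, 3, 3, n_t))
  conds[, , 1, ] <- conds[, , 1, ] + 4 * rep(bump(150, 20), each = n_sub * 3)
  avg1 <- apply(conds, c(1, 3, 4), mean)
  perm <- conds[, c(3, 1, 2), , ]
  avg2 <- apply(perm, c(1, 3, 4), mean)
  s1 <- select_soi(avg1, time)
  s2 <- select_soi(avg2, time)
  expect_identical(s1, s2)
})

test_that("SOI-mean ERF flips right-hemisphere polarity", {
  time <- seq(-200, 600, by = 5)
  n_t <- length(time)
  wave <- sin(2 * pi * (seq_len(n_t)) / 50)
  # subjects x conditions x sensors x samples; mirrored pair with opposite
  # polarity
  erfs <- array(0, c(2, 2, 2, n_t),
                dimnames = list(NULL, c("happy", "fearful"), NULL, NULL))
  for (s in 1:2) for (j in 1:2) {
    erfs[s, j, 1, ] <- wave
    erfs[s, j, 2, ] <- -wave
  }
  soi <- list(index = 1:2, polarity = c(1, -1), alpha = 0.05)
  class(soi) <- "soi_set"
  m <- mean_soi_erf(erfs, soi, hemisphere = c("left", "right"))
  expect_equal(m[1, "happy", ], wave, tolerance = 1e-12)   # not cancelled
  # single left sensor passes through unchanged
  soi1 <- list(index = 1, polarity = 1); class(soi1) <- "soi_set"
  m1 <- mean_soi_erf(erfs, soi1, hemisphere = c("left", "right"))
  expect_equal(m1[1, "happy", ], wave)
  # all-zero data gives an all-zero mean
  m0 <- mean_soi_erf(erfs * 0, soi, hemisphere = c("left", "right"))
  expect_true(all(m0 == 0))
  expect_error(mean_soi_erf(erfs, list(index = integer(0)), "left"), "empty")
})

test_that("condition contrast reproduces the paired-t formula with df = n - 1", {
  time <- seq(-200, 600, by = 5)
  n_t <- length(time)
  n_sub <- 12
  set.seed(13)
  delta <- 0.4; sigma <- 0.8
  base <- rnorm(n_sub, 0, 1)
  m <- array(0, c(n_sub, 3, n_t),
             dimnames = list(NULL, c("neutral", "happy", "fearful"), NULL))
  for (s in seq_len(n_sub)) {
    m[s, "neutral", ] <- base[s]
    m[s, "happy", ] <- base[s] + rnorm(1, 0, sigma)
    m[s, "fearful", ] <- base[s] + delta + rnorm(1, 0, sigma)
  }
  res <- condition_contrast(m, time, window = c(150, 190))
  expect_equal(res$df, c(11, 11))
  d <- m[, "fearful", 1] - m[, "happy", 1]
  t_manual <- mean(d) / (sd(d) / sqrt(n_sub))
  expect_equal(res$t[res$pair == "fearful vs happy"], t_manual,
               tolerance = 1e-10)
  # identical conditions: t = 0, p = 1
  m2 <- m; m2[, "fearful", ] <- m2[, "happy", ]
  res2 <- condition_contrast(m2, time)
  expect_equal(res2$t[res2$pair == "fearful vs happy"], 0)
  expect_equal(res2$p[res2$pair == "fearful vs happy"], 1)
})

test_that("mass-univariate tests use the full Bonferroni correction", {
  # correction factor for the full design
  n_comp <- 274 * 161
  expect_equal(n_comp, 44114)
  set.seed(17)
  a <- array(rnorm(6 * 4 * 10), c(6, 4, 10))
  b <- array(rnorm(6 * 4 * 10), c(6, 4, 10))
  res <- sensorwise_tests(a, b, alpha = 0.05)
  expect_equal(res$n_comparisons, 40)
  expect_equal(res$threshold, 0.05 / 40)
  # a huge effect at one cell survives correction
  b2 <- b; b2[, 2, 5] <- b2[, 2, 5] + 50
  res2 <- sensorwise_tests(a, b2)
  expect_true(res2$significant[2, 5])
  # family-wise error control on null data over repeated simulations
  n_sim <- 200
  any_sig <- logical(n_sim)
  set.seed(19)
  for (k in seq_len(n_sim)) {
    x <- array(rnorm(6 * 3 * 5), c(6, 3, 5))
    y <- array(rnorm(6 * 3 * 5), c(6, 3, 5))
    any_sig[k] <- any(sensorwise_tests(x, y)$significant)
  }
  fwe <- mean(any_sig)
  expect_lte(fwe, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("epoch sets round-trip through CSV", {
  set.seed(21)
  x <- array(rnorm(4 * 3 * 11), c(4, 3, 11))
  ep <- epoch_set(x, 200, -10, c("happy", "fearful", "neutral", "happy"),
                  data.frame(hemisphere = c("left", "right", "left")))
  f <- tempfile(fileext = ".csv")
  write_epochs_csv(ep, f)
  back <- read_epochs_csv(f)
  expect_equal(back$data, ep$data)
  expect_identical(back$labels, ep$labels)
  expect_equal(back$fs, ep$fs)
  expect_equal(back$time, ep$time)
  expect_identical(back$sensors$hemisphere, ep$sensors$hemisphere)
  unlink(c(f, paste0(f, ".meta.json")))
})
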