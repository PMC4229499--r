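#' Study configuration
#'
#' Bundles every stage's constants: preprocessing band and rates, epoch and
#' baseline windows, SOI selection, the condition-contrast window, the
#' analysis-window set for the model-comparison sweep, and the contribution
#' increment. Validated for mutual consistency before any computation.
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param band band-pass corners, Hz; \code{fs_out} analysis rate, Hz.
#' @param baseline baseline window, ms.
#' @param soi_min_duration minimal significant span for SOI selection, ms.
#' @param soi_search SOI peak search window, ms.
#' @param contrast_window condition-contrast averaging window, ms.
#' @param windows list of \code{c(0, T)} analysis windows (default the
#'   desk-scale subset 0-180/0-240/0-300 of the 0-60..0-300 grid).
#' @param patterns modulation patterns fitted per family.
#' @param increment contribution-analysis increment on the PUL->AMY
#'   log-coupling.
#' @param n_modes spatial modes retained in inversion.
#' @param dt_fit integration step used during inversion, ms (<= 1).
#' @param likelihood_dt spacing of likelihood samples, ms (matched to the
#'   band-pass noise bandwidth; see \code{\link{dcm_fit}}).
#' @param fit_max_iter iteration cap per inversion (desk-scale concession;
#'   free energies are stable well before the cap).
#' @param seed study-level seed (cohort seed and Monte-Carlo exceedance
#'   derive from it).
#' @export
study_config <- function(cohort = scaled_down_config(),
                         band = c(0.5, 30), fs_out = 200,
                         baseline = c(-200, 0),
                         soi_min_duration = 25, soi_search = c(0, 300),
                         contrast_window = c(150, 190),
                         windows = list(c(0, 180), c(0, 240), c(0, 300)),
                         patterns = "none",
                         increment = 0.0025, n_modes = 6, dt_fit = 1,
                         likelihood_dt = 10, fit_max_iter = 48, seed = 1) {
  cfg <- as.list(environment())
  epoch <- cohort$epoch_window
  if (baseline[1] < epoch[1] || baseline[2] > epoch[2])
    stop("baseline window outside the epoch")
  if (soi_search[1] < epoch[1] || soi_search[2] > epoch[2])
    stop("SOI search window outside the epoch")
  if (contrast_window[1] < soi_search[1] || contrast_window[2] > soi_search[2])
    stop("contrast window outside the SOI search window")
  for (w in windows)
    if (w[1] != 0 || w[2] > epoch[2])
      stop("analysis window outside the epoch")
  cfg$cohort$seed <- seed
  class(cfg) <- "study_config"
  cfg
}

settings_hash <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "cohort")]), collapse = "")
  txt <- paste0(txt, paste(deparse(unclass(cfg$cohort)), collapse = ""))
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the full study end-to-end
#'
#' Synthesize the cohort, preprocess each subject (filter, downsample,
#' baseline, robust averaging), run the sensor-space statistics (SOI
#' selection, condition contrasts), fit every model to every subject over
#' every analysis window, run the family-level window sweep and the
#' modulation-pattern comparison, and the pulvinar-to-amygdala contribution
#' analysis on the fitted dual-route models.
#'
#' @param cfg a \code{\link{study_config}}.
#' @param out_dir optional directory for the report bundle (CSV/JSON tables
#'   and figures).
#' @param cache_dir optional directory caching the model-evidence grid by
#'   configuration hash (the fit grid dominates runtime).
#' @param verbose print stage progress.
#' @return List of class \code{"study_result"} with elements
#'   \code{cohort_truth}, \code{soi}, \code{contrast}, \code{evidence}
#'   (subjects x models x windows), \code{sweep}, \code{modulation_bms},
#'   \code{contribution}, \code{fits}, \code{settings}.
#' @export
run_study <- function(cfg, out_dir = NULL, cache_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- settings_hash(cfg)
  say("study %s: generating cohort (%d subjects)", hash,
      cfg$cohort$n_subjects)
  cohort <- generate_cohort(cfg$cohort)
  n_sub <- cfg$cohort$n_subjects
  conditions <- c("neutral", "happy", "fearful")

  say("preprocessing")
  erfs <- vector("list", n_sub)      # per subject: condition -> sensors x T
  for (s in seq_len(n_sub)) {
    ep <- preprocess_epochs(cohort$subjects[[s]], band = cfg$band,
                            fs_out = cfg$fs_out, baseline = cfg$baseline)
    erfs[[s]] <- lapply(stats::setNames(conditions, conditions),
                        function(cn) robust_average(ep, cn)$erf)
    if (s == 1) time <- ep$time
  }
  n_sens <- nrow(erfs[[1]][[1]])
  n_t <- length(time)

  # group sensor statistics on the condition average (orthogonal selection)
  avg <- array(0, c(n_sub, n_sens, n_t))
  byc <- array(0, c(n_sub, 3, n_sens, n_t),
               dimnames = list(NULL, conditions, NULL, NULL))
  for (s in seq_len(n_sub)) {
    for (j in seq_along(conditions)) byc[s, j, , ] <- erfs[[s]][[j]]
    avg[s, , ] <- apply(byc[s, , , ], c(2, 3), mean)
  }
  soi <- select_soi(avg, time, alpha = 0.05,
                    min_duration = cfg$soi_min_duration,
                    search_window = cfg$soi_search)
  say("SOI: %d of %d sensors", length(soi$index), n_sens)
  contrast <- NULL
  soi_means <- NULL
  if (length(soi$index) > 0) {
    hemi <- cohort$subjects[[1]]$sensors$hemisphere
    soi_means <- mean_soi_erf(byc, soi, hemi)
    contrast <- condition_contrast(soi_means, time,
                                   window = cfg$contrast_window)
  }

  models <- build_families(patterns = cfg$patterns)
  wins <- cfg$windows
  win_lab <- sapply(wins, function(w) as.character(w[2]))
  evidence <- array(NA_real_, c(n_sub, length(models), length(wins)),
                    dimnames = list(NULL, names(models), win_lab))
  fits_dual <- list()
  cache_file <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0("evidence-", hash, ".json"))
  if (!is.null(cache_file) && file.exists(cache_file)) {
    say("loading cached evidence grid")
    cached <- jsonlite::fromJSON(cache_file)
    evidence[] <- array(cached$evidence, dim(evidence))
  } else {
    say("fitting %d models x %d windows x %d subjects",
        length(models), length(wins), n_sub)
    for (s in seq_len(n_sub)) {
      for (m in seq_along(models)) {
        for (w in seq_along(wins)) {
          fit <- dcm_fit(models[[m]], erfs[[s]], time, cohort$leadfield,
                         window = wins[[w]], n_modes = cfg$n_modes,
                         dt = cfg$dt_fit, band = cfg$band,
                         latency_smear = cfg$cohort$trial_latency_jitter,
                         likelihood_dt = cfg$likelihood_dt,
                         max_iter = cfg$fit_max_iter)
          evidence[s, m, w] <- fit$free_energy
          if (models[[m]]$family == "dual_route" && w == length(wins))
            fits_dual[[length(fits_dual) + 1]] <- fit
        }
      }
      say("  subject %d/%d done", s, n_sub)
    }
    if (!is.null(cache_file)) {
      dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(list(evidence = as.numeric(evidence)), cache_file,
                           digits = NA)
    }
  }

  partition <- list(
    dual_route = grep("^dual_route", names(models), value = TRUE),
    cortical_only = grep("^cortical_only", names(models), value = TRUE))
  say("window sweep (family-level RFX BMS)")
  sweep <- window_sweep(evidence, partition, seed = cfg$seed)

  # modulation-pattern comparison within the dual-route family (last window)
  modulation_bms <- NULL
  if (length(partition$dual_route) >= 2) {
    ev <- evidence[, partition$dual_route, length(wins)]
    modulation_bms <- rfx_bms(ev, seed = cfg$seed)
  }

  contribution <- NULL
  if (length(fits_dual) > 0) {
    say("contribution analysis (%d fitted dual-route models)",
        length(fits_dual))
    contribution <- contribution_analysis(fits_dual,
                                          increment = cfg$increment,
                                          duration = 300)
  }

  res <- list(cohort_truth = cohort$truth, soi = soi, contrast = contrast,
              soi_means = soi_means, time = time, evidence = evidence,
              sweep = sweep, modulation_bms = modulation_bms,
              contribution = contribution, fits = fits_dual,
              settings = list(hash = hash, seed = cfg$seed, config = cfg))
  class(res) <- "study_result"
  if (!is.null(out_dir)) report(res, out_dir)
  res
}

#' Write the report bundle
#'
#' Tabulates the window sweep (family- and model-level), the source-distance
#' table with the canonical dipole geometry, the condition contrasts, and
#' the contribution-analysis peak effects as CSV/JSON plus figures.
#'
#' @param results a \code{\link{run_study}} result.
#' @param out_dir output directory (created if needed).
#' @export
report <- function(results, out_dir) {
  stopifnot(inherits(results, "study_result"))
  if (is.null(results$sweep) || nrow(results$sweep$family) == 0)
    stop("empty sweep: nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$sweep$family,
                   file.path(out_dir, "sweep_family.csv"), row.names = FALSE)
  utils::write.csv(results$sweep$model,
                   file.path(out_dir, "sweep_model.csv"), row.names = FALSE)
  src <- build_source_set()
  pairs <- utils::combn(nrow(src), 2)
  dist <- data.frame(
    a = src$name[pairs[1, ]], b = src$name[pairs[2, ]],
    distance_mm = apply(pairs, 2, function(ij)
      dipole_distance(src[ij[1], ], src[ij[2], ])))
  utils::write.csv(dist, file.path(out_dir, "dipole_distances.csv"),
                   row.names = FALSE)
  if (!is.null(results$contrast))
    utils::write.csv(results$contrast,
                     file.path(out_dir, "condition_contrast.csv"),
                     row.names = FALSE)
  summary_json <- list(
    seed = results$settings$seed,
    settings_hash = results$settings$hash,
    n_soi = length(results$soi$index),
    windows = dimnames(results$evidence)[[3]],
    family_exceedance = stats::reshape(
      results$sweep$family[, c("window", "family", "exceedance")],
      direction = "wide", idvar = "window", timevar = "family"))
  if (!is.null(results$contribution)) {
    pk <- apply(abs(results$contribution$delta[, , "principal"]), 2, max)
    summary_json$contribution_peak_principal <- as.list(pk)
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  grDevices::png(file.path(out_dir, "sweep_exceedance.png"), 800, 500)
  plot(results$sweep)
  grDevices::dev.off()
  if (!is.null(results$contribution)) {
    grDevices::png(file.path(out_dir, "contribution.png"), 800, 600)
    plot(results$contribution)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study result (settings", x$settings$hash, ")\n")
  cat("SOI sensors:", length(x$soi$index), "\n")
  if (!is.null(x$contrast)) print(x$contrast)
  print(x$sweep)
  invisible(x)
}
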