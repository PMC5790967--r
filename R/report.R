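#' Compare a measured value to an acceptance limit
#'
#' @param value measured value.
#' @param limit acceptance limit.
#' @param comparator `">="` (value must reach the limit) or `"<="` (value
#'   must not exceed it); the boundary is inclusive.
#' @return list `(value, limit, comparator, pass)`; the triple is echoed so
#'   every pass/fail flag in a report is traceable.
#' @examples
#' compare_to_limits(72, 68, ">=")$pass
#' @export
compare_to_limits <- function(value, limit, comparator) {
  if (!comparator %in% c(">=", "<="))
    stop("unknown comparator '", comparator, "'; use \">=\" or \"<=\"")
  pass <- if (comparator == ">=") value >= limit else value <= limit
  list(value = value, limit = limit, comparator = comparator, pass = pass)
}

.suite_metrics <- function(results) {
  m <- list()
  if (!is.null(results$sensitivity))
    m$sensitivity_S0_cps_kBq <- results$sensitivity$S0_cps_kBq
  if (!is.null(results$countrate)) {
    m$SF_pct <- results$countrate$summary$SF_reported_pct
    m$NECR_peak_kcps <- results$countrate$summary$NECR_peak_kcps
    m$a_at_peak_kBq_cc <- results$countrate$summary$a_at_peak_kBq_cc
  }
  if (!is.null(results$accuracy))
    m$max_count_loss_error_pct <- results$accuracy$max_abs_pct_error_below_peak
  if (!is.null(results$iq)) {
    m$lung_residual_pct <- results$iq$lung_residual_pct
    m$mean_hot_contrast_pct <- results$iq$mean_hot_contrast_pct
  }
  if (!is.null(results$resolution)) {
    m$mean_fwhm_mm <- mean(results$resolution$fwhm_mm)
  }
  m
}

#' Run the full performance suite from a configuration
#'
#' Executes the requested NU2 test stages — each either on simulated
#' fixtures (a `simulate:` block, forwarded to the matching generator) or on
#' files written by the package's own writers (`file:`) — and assembles a
#' consolidated performance report with pass/fail flags against
#' user-supplied acceptance limits. No limits are built in: the `limits`
#' block of the config is the only source.
#'
#' Config structure (YAML file path or an equivalent nested list):
#' \preformatted{
#' scanner: "scanner label"
#' seed: 0
#' resolution:
#'   simulate: {fwhm: [4.8, 4.8, 5.3], positions: [[10,0,0],[100,0,0]],
#'              voxel_size: 1, total_counts: 100000}
#' sensitivity:
#'   simulate: {S0: 22.2, mu_alu: 0.05, activity_kBq: 5000,
#'              frame_duration_s: 60}
#' countrate:
#'   simulate: {sf: 0.434, necr_peak_kcps: 218, a_peak_kBq_cc: 17.7}
#'   # optional size overrides: n_frames, n_slices, n_bins, n_angles
#' accuracy:
#'   max_bias_pct: 3.4        # reuses the countrate fixture with a bias
#' iq:
#'   simulate: {hot_contrasts_pct: [56, 72, 78, 85],
#'              cold_contrasts_pct: [75, 75], lung_residual_pct: 1.2}
#' limits:
#'   - {metric: sensitivity_S0_cps_kBq, comparator: ">=", limit: 21.97}
#'   - {metric: SF_pct, comparator: "<=", limit: 45}
#' }
#'
#' @param config path to a YAML file, or a nested list.
#' @param out_dir optional directory: writes `report.json` and a
#'   `metrics.csv` table.
#' @param seed overrides the config seed.
#' @return object of class `performance_report`: `scanner`, `results` (the
#'   per-stage result objects), `metrics` (named numeric list), `checks`
#'   data frame (`metric`, `value`, `comparator`, `limit`, `pass`), `pass`
#'   (all checks passed), `provenance` (seed, package version).
#' @export
run_suite <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0L)
    stop("usage error: config must name at least one test stage")
  stages <- intersect(names(config),
                      c("resolution", "sensitivity", "countrate", "accuracy",
                        "iq"))
  if (length(stages) == 0L)
    stop("usage error: config enables no test stage")
  if (is.null(seed)) seed <- config$seed %||% 0
  results <- list()

  if ("resolution" %in% stages) {
    rc <- config$resolution
    vols <- if (!is.null(rc$simulate)) {
      sc <- rc$simulate
      lapply(sc$positions, function(p)
        make_point_source_volume(unlist(p), unlist(sc$fwhm),
                                 sc$voxel_size %||% 1,
                                 sc$total_counts %||% 1e5))
    } else {
      lapply(rc$file, read_volume)
    }
    results$resolution <- resolution_report(vols)
  }

  if ("sensitivity" %in% stages) {
    sc <- config$sensitivity
    acq <- if (!is.null(sc$simulate)) {
      s <- sc$simulate
      make_sleeve_series(s$S0, s$mu_alu %||% 0.05,
                         s$activity_kBq %||% 5000,
                         s$frame_duration_s %||% 60,
                         s$start_times_s %||% seq(0, 1200, by = 300),
                         noise = s$noise %||% "none", seed = seed)
    } else {
      read_sleeves(sc$file)
    }
    results$sensitivity <- system_sensitivity(acq)
  }

  cr_acq <- NULL
  if ("countrate" %in% stages) {
    cc <- config$countrate
    cr_acq <- if (!is.null(cc$simulate)) {
      s <- cc$simulate
      model <- calibrate_countrate_model(s$sf, s$necr_peak_kcps,
                                         s$a_peak_kBq_cc,
                                         k_R = s$k_R %||% 1)
      make_countrate_series(model,
                            n_frames = s$n_frames %||% 30,
                            n_slices = s$n_slices %||% 81,
                            n_bins = s$n_bins %||% 256,
                            n_angles = s$n_angles %||% 128,
                            noise = s$noise %||% "none", seed = seed)
    } else {
      read_countrate(cc$file)
    }
    curves <- compute_curves(cr_acq)
    pk <- find_necr_peak(curves)
    curves$summary$NECR_peak_kcps <- pk$NECR_peak_kcps
    curves$summary$a_at_peak_kBq_cc <- pk$a_at_peak_kBq_cc
    curves$summary$SF_at_peak_pct <- curves$frames$SF_pct[pk$frame]
    results$countrate <- curves
  }

  if ("accuracy" %in% stages) {
    ac <- config$accuracy
    acc_curves <- if (!is.null(ac$max_bias_pct) && !is.null(config$countrate$simulate)) {
      s <- config$countrate$simulate
      model <- calibrate_countrate_model(s$sf, s$necr_peak_kcps,
                                         s$a_peak_kBq_cc,
                                         k_R = s$k_R %||% 1)
      op <- attr(model, "operating_point")
      sched <- countrate_schedule(n_frames = s$n_frames %||% 30)
      bias <- make_bias_profile(ac$max_bias_pct, sched$activity_MBq,
                                op$a_peak_MBq)
      acq <- make_countrate_series(model,
                                   n_frames = s$n_frames %||% 30,
                                   n_slices = s$n_slices %||% 81,
                                   n_bins = s$n_bins %||% 256,
                                   n_angles = s$n_angles %||% 128,
                                   bias_profile = bias, seed = seed)
      compute_curves(acq)
    } else if (!is.null(results$countrate)) {
      results$countrate
    } else if (!is.null(ac$file)) {
      compute_curves(read_countrate(ac$file))
    } else {
      stop("accuracy stage requires a countrate stage or an input file")
    }
    results$accuracy <- randoms_accuracy(acc_curves)
  }

  if ("iq" %in% stages) {
    ic <- config$iq
    vol <- if (!is.null(ic$simulate)) {
      s <- ic$simulate
      ratios <- c(ratio_for_hot_contrast(unlist(s$hot_contrasts_pct)),
                  ratio_for_cold_contrast(unlist(s$cold_contrasts_pct)))
      make_iq_image(1, ratios, (s$lung_residual_pct %||% 0) / 100,
                    voxel_size_mm = s$voxel_size %||% 2,
                    noise_cv_voxel = s$noise_cv_voxel %||% 0, seed = seed)
    } else {
      read_volume(ic$file)
    }
    results$iq <- iq_report(vol)
  }

  metrics <- .suite_metrics(results)
  checks <- data.frame(metric = character(), value = numeric(),
                       comparator = character(), limit = numeric(),
                       pass = logical(), stringsAsFactors = FALSE)
  for (lim in config$limits) {
    if (is.null(metrics[[lim$metric]])) {
      warning("limit references unknown metric '", lim$metric, "'; skipped")
      next
    }
    chk <- compare_to_limits(metrics[[lim$metric]], lim$limit,
                             lim$comparator)
    checks <- rbind(checks, data.frame(metric = lim$metric,
                                       value = chk$value,
                                       comparator = chk$comparator,
                                       limit = chk$limit, pass = chk$pass))
  }
  report <- structure(list(
    scanner = config$scanner %||% "unlabelled scanner",
    results = results,
    metrics = metrics,
    checks = checks,
    pass = nrow(checks) == 0L || all(checks$pass),
    provenance = list(seed = seed,
                      package_version = as.character(utils::packageVersion("petperf")))
  ), class = "performance_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(scanner = report$scanner, metrics = metrics,
           checks = checks, pass = report$pass,
           provenance = report$provenance),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    mdf <- data.frame(metric = names(metrics),
                      value = unlist(metrics, use.names = FALSE))
    utils::write.csv(mdf, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.performance_report <- function(x, ...) {
  cat("PET performance report —", x$scanner, "\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %-28s %.4g\n", nm, x$metrics[[nm]]))
  if (nrow(x$checks)) {
    cat("Acceptance checks:\n")
    df <- x$checks
    df$value <- signif(df$value, 4)
    print.data.frame(df, row.names = FALSE)
  }
  cat(if (isTRUE(x$pass)) "PASS\n" else "FAIL\n")
  invisible(x)
}
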