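#' Read a run configuration
#'
#' A run configuration holds paths (bin scheme, proxy table, occurrence
#' table) or a synthetic-data section, the screening thresholds and
#' calibrations, Monte Carlo sizes, the seed, and the analysis switches
#' (Big-Five bin list, deep-water handling, estimator). YAML files are
#' merged over the documented defaults.
#'
#' @param path Path to a YAML config file, or a named list of overrides.
#' @return A list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    bin_scheme = NULL,            # NULL = packaged 45-bin scheme
    proxy_table = NULL,           # CSV path (optional)
    occurrence_table = NULL,      # CSV path (optional)
    synth = NULL,                 # list of synthetic_config overrides
    thresholds = default_thresholds(),
    event = list(endpoint_group_size = 3L, min_samples = 4L,
                 mc_draws = 500L, max_reversal_frac = 1 / 3,
                 smooth_window = 3L),
    classify = list(mag = 5.2, rate = 10, span = 0.4),
    min_density = 2,
    n_boot = 100L,
    estimator = "gf",
    big_five_bins = c("Or5", "D4", "P5", "T5", "K8"),
    drop_deep_water = FALSE,
    seed = 1L
  )
  if (is.character(path)) path <- yaml::read_yaml(path)
  if (is.list(path)) cfg <- utils::modifyList(cfg, path)
  structure(cfg, class = "run_config")
}

#' Run the full climate-extinction pipeline
#'
#' Executes the analysis chain: load bins; obtain per-bin temperature
#' series (from a proxy table after screening and SST conversion, or from
#' the synthetic generator); apply the resolution screen; detect, average
#' and classify the largest excursion per bin with Monte Carlo
#' uncertainties; compute gap-filler and three-timer extinction rates with
#' bootstrap uncertainties from the occurrence records; and run the
#' correlation suite, warming-vs-cooling comparison and autocorrelation
#' checks. Without occurrence data an events-only partial run is returned
#' and the statistics stage is skipped with a notice.
#'
#' @param config A \code{run_config} (see \code{\link{read_run_config}}), a
#'   YAML path, or a list of overrides.
#' @param series Optional named list of \code{\link{temperature_series}}
#'   (bypasses the proxy/synthetic stages).
#' @param occurrences Optional occurrence data.frame (bypasses the table /
#'   synthetic stages).
#' @return An object of class \code{thermext_run}; see
#'   \code{\link{print.thermext_run}}, \code{summary}, \code{plot}.
#' @export
run_pipeline <- function(config = read_run_config(), series = NULL,
                         occurrences = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  set.seed(config$seed)
  notices <- character()
  bins <- load_bin_scheme(config$bin_scheme)

  truth <- NULL
  synth_cfg <- NULL
  if (!is.null(config$synth)) {
    synth_args <- utils::modifyList(list(bins = bins, seed = config$seed),
                                    config$synth)
    synth_cfg <- do.call(synthetic_config, synth_args)
  }

  screen_log <- NULL
  if (is.null(series)) {
    if (!is.null(config$proxy_table)) {
      conv <- convert_proxy_table(config$proxy_table, bins,
                                  thresholds = config$thresholds,
                                  seed = config$seed)
      series <- conv$series
      screen_log <- conv$screen_log
    } else if (!is.null(synth_cfg)) {
      gen <- generate_climate_series(synth_cfg)
      series <- gen$series
      truth <- gen$truth
    } else {
      stop("stage 'series': no proxy table, synthetic config or series supplied")
    }
  }

  ev_cfg <- do.call(event_config, c(config$event, list(seed = config$seed)))
  events <- list()
  excluded_bins <- character()
  for (b in seq_len(nrow(bins))) {
    bid <- bins$bin_id[b]
    ser_b <- series[names(series) == bid]
    ser_b <- Filter(function(s) {
      resolution_check(nrow(s), bins[b, ], config$min_density)$pass
    }, ser_b)
    if (length(ser_b) == 0L) {
      excluded_bins <- c(excluded_bins, bid)
      next
    }
    evs <- lapply(ser_b, function(s) {
      e <- detect_largest_event(s, ev_cfg)
      if (is.null(e)) return(NULL)
      event_uncertainty_mc(s, e, ev_cfg)
    })
    evs <- Filter(Negate(is.null), evs)
    if (length(evs) == 0L) {
      excluded_bins <- c(excluded_bins, bid)
      next
    }
    e <- average_events(unname(evs))
    e <- assign_event_bin(e, bins)
    e$bin_id <- bid  # averaged event reported under its source bin
    events[[bid]] <- e
  }
  event_table <- events_to_table(events)
  cls <- lapply(events, classify_event, thresholds = config$classify)
  event_table$class <- vapply(cls, `[[`, character(1), "class")
  event_table$short_timespan <- vapply(cls, `[[`, logical(1), "short_timespan")

  rates <- rates_no_deep <- NULL
  cors <- comparison <- acfs <- NULL
  filter_counts <- NULL
  if (is.null(occurrences)) {
    if (!is.null(config$occurrence_table)) {
      occurrences <- read_occurrences(config$occurrence_table)
    } else if (!is.null(synth_cfg)) {
      occurrences <- generate_occurrences(synth_cfg, truth)$records
    }
  }
  if (is.null(occurrences)) {
    notices <- c(notices, "no occurrence table: events-only partial run, statistics skipped")
  } else {
    # occurrence data may extend beyond the temperature window (padding
    # bins from the generator, or a real download): count against the
    # extended scheme so the edge bins keep defined rates
    rate_bins <- if (isTRUE(attr(occurrences, "padded"))) {
      pad_bin_scheme(bins)
    } else bins
    filtered <- filter_occurrences(occurrences,
                                   drop_deep_water = isTRUE(config$drop_deep_water))
    filter_counts <- attr(filtered, "removal_counts")
    rates <- extinction_rates(filtered, rate_bins)
    focal <- match(bins$bin_id, rate_bins$bin_id)
    boot <- lapply(focal, function(i) {
      rate_uncertainty(filtered, rate_bins, i, n_boot = config$n_boot,
                       seed = config$seed + i)
    })
    rates <- rates[rates$bin_id %in% bins$bin_id, , drop = FALSE]
    rates$sd_gf <- vapply(boot, `[[`, numeric(1), "sd_gf")
    rates$sd_3t <- vapply(boot, `[[`, numeric(1), "sd_3t")
    if (!isTRUE(config$drop_deep_water) &&
        any(occurrences$environment == "deep")) {
      rn <- extinction_rates(
        filter_occurrences(occurrences, drop_deep_water = TRUE), rate_bins)
      rates_no_deep <- rn[rn$bin_id %in% bins$bin_id, , drop = FALSE]
    }
    cors <- correlation_suite(event_table, rates, bins,
                              big_five_bins = config$big_five_bins,
                              estimator = config$estimator,
                              rate_threshold = config$classify$rate,
                              rates_no_deep = rates_no_deep)
    w <- cors[cors$label == "warming_dT", ]
    k <- cors[cors$label == "cooling_dT", ]
    comparison <- if (isTRUE(w$defined) && isTRUE(k$defined)) {
      compare_correlations(w$rho, w$n, k$rho, k$n)
    } else NULL
    rc <- if (config$estimator == "gf") "r_gf" else "r_3t"
    joined <- merge(event_table, rates[, c("bin_id", rc)], by = "bin_id")
    acfs <- list(
      extinction = tryCatch(acf_series(joined[[rc]], label = "extinction"),
                            error = function(e) NULL),
      delta_T = tryCatch(acf_series(abs(joined$delta_T_c), label = "delta_T"),
                         error = function(e) NULL),
      log_R = tryCatch(acf_series(log(abs(joined$rate_c_per_myr)), label = "log_R"),
                       error = function(e) NULL))
  }

  structure(list(bins = bins, series = series, truth = truth,
                 screen_log = screen_log,
                 events = events, event_table = event_table,
                 excluded_bins = excluded_bins,
                 occurrences = occurrences, filter_counts = filter_counts,
                 rates = rates, rates_no_deep = rates_no_deep,
                 correlations = cors, comparison = comparison, acfs = acfs,
                 notices = notices, config = config, seed = config$seed),
            class = "thermext_run")
}

#' Convert and screen a proxy measurement table
#'
#' Reads a proxy CSV (one row per measurement; GDGT abundances in
#' \code{gdgt0...br_IIIa} columns), screens every row, converts retained
#' rows to SST (conodont/carbonate delta-18-O through the linear calibration
#' with Monte Carlo parameter uncertainty; TEX86 through a configurable
#' linear calibration), and assembles per-bin temperature series.
#'
#' @param path CSV path or data.frame.
#' @param bins A \code{time_bins} scheme.
#' @param thresholds Screening thresholds.
#' @param calibrations Named list of \code{\link{calibration_params}} per
#'   proxy kind (defaults: conodont calibration; TEX86 linear 58.6*TEX - 11.7).
#' @param ice_state,sw_overrides Passed to \code{\link{seawater_d18o}}.
#' @param mc_draws Draws per measurement.
#' @param seed Integer seed.
#' @return List with \code{series} (named list of temperature_series; one
#'   per bin x source_label) and \code{screen_log} (per-row retained flag
#'   and reasons).
#' @export
convert_proxy_table <- function(path, bins, thresholds = default_thresholds(),
                                calibrations = NULL, ice_state = character(),
                                sw_overrides = numeric(), mc_draws = 1000L,
                                seed = 1L) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(calibrations)) {
    calibrations <- list(
      conodont_d18O = conodont_calibration(),
      carbonate_d18O = calibration_params(16.1, -4.64, 0.6, 0.1),
      tex86 = calibration_params(-11.7, 58.6, 2.0, 2.5),
      generic_linear = calibration_params(0, 1)
    )
  }
  set.seed(seed)
  rows <- vector("list", nrow(df))
  log <- data.frame(sample_id = character(), retained = logical(),
                    reasons = character(), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(df))) {
    gd <- NULL
    if (!is.na(df$proxy_kind[r]) && df$proxy_kind[r] == "tex86" &&
        "gdgt0" %in% names(df) && !is.na(df$gdgt0[r])) {
      gd <- gdgt_composition(df$gdgt0[r], df$gdgt1[r], df$gdgt2[r], df$gdgt3[r],
                             df$cren[r], df$cren_prime[r],
                             br_Ia = df$br_Ia[r] %|na|% 0,
                             br_IIa = df$br_IIa[r] %|na|% 0,
                             br_IIIa = df$br_IIIa[r] %|na|% 0)
    }
    flags <- if ("facies_flags" %in% names(df) && !is.na(df$facies_flags[r]) &&
                 nzchar(df$facies_flags[r])) {
      strsplit(df$facies_flags[r], ";")[[1]]
    } else character()
    m <- proxy_measurement(df$sample_id[r], df$bin_id[r], df$proxy_kind[r],
                           value = df$value[r] %|na|% NA_real_,
                           paleolatitude = df$paleolatitude[r] %|na|% 0,
                           mn_ppm = if ("mn_ppm" %in% names(df)) df$mn_ppm[r] else NA_real_,
                           sr_ppm = if ("sr_ppm" %in% names(df)) df$sr_ppm[r] else NA_real_,
                           facies_flags = flags, gdgt = gd)
    qc <- screen_measurement(m, thresholds)
    log <- rbind(log, data.frame(sample_id = m$sample_id, retained = qc$retained,
                                 reasons = paste(qc$reject_reasons, collapse = ";"),
                                 stringsAsFactors = FALSE))
    if (!qc$retained) next
    kind <- m$proxy_kind
    value <- if (kind == "tex86" && !is.null(gd)) tex86_from_gdgt(gd) else m$value
    if (kind %in% c("conodont_d18O", "carbonate_d18O")) {
      sw <- seawater_d18o(m$bin_id, ice_state, sw_overrides, bins)
      value <- value - sw
    }
    est <- linear_sst_mc(value, calibrations[[kind]], n = mc_draws)
    rows[[r]] <- data.frame(bin_id = m$bin_id,
                            source = if ("source_label" %in% names(df))
                              df$source_label[r] else kind,
                            age = df$age_ma[r], sst = est$mean_sst,
                            sst_sd = est$sd_sst, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  series <- list()
  if (!is.null(tab)) {
    for (key in unique(paste(tab$bin_id, tab$source, sep = "\r"))) {
      parts <- strsplit(key, "\r")[[1]]
      sub <- tab[tab$bin_id == parts[1] & tab$source == parts[2], ]
      ser <- temperature_series(parts[1], sub$age, sub$sst, sub$sst_sd,
                                source_label = parts[2])
      series[[length(series) + 1L]] <- ser
      names(series)[length(series)] <- parts[1]
    }
  }
  list(series = series, screen_log = log)
}

`%|na|%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' @export
print.thermext_run <- function(x, ...) {
  cat("Climate-change / extinction pipeline run\n")
  cat(sprintf("  bins: %d (%s..%s), seed %d\n", nrow(x$bins),
              x$bins$bin_id[1], x$bins$bin_id[nrow(x$bins)], x$seed))
  cat(sprintf("  events detected: %d bins (%d excluded by resolution screen)\n",
              nrow(x$event_table), length(x$excluded_bins)))
  if (!is.null(x$rates)) {
    cat(sprintf("  extinction rates: %d bins defined (gap-filler)\n",
                sum(x$rates$gf_defined)))
  }
  if (!is.null(x$correlations)) {
    a <- x$correlations[x$correlations$label == "all_dT", ]
    cat(sprintf("  |delta_T| vs extinction: rho = %.3f, P = %.3g, n = %d\n",
                a$rho, a$p_value, a$n))
  }
  for (nt in x$notices) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
summary.thermext_run <- function(object, ...) {
  cat("== Events ==\n")
  print(object$event_table[, c("bin_id", "delta_T_c", "delta_t_myr",
                               "rate_c_per_myr", "direction", "class")],
        row.names = FALSE)
  if (!is.null(object$correlations)) {
    cat("\n== Correlations ==\n")
    print(object$correlations, row.names = FALSE)
  }
  if (!is.null(object$comparison)) {
    cat(sprintf("\nwarming vs cooling (delta_T): z = %.3f, P = %.3f [%s]\n",
                object$comparison$z, object$comparison$p_value,
                object$comparison$method))
  }
  invisible(object)
}

#' Diagnostic plots for a pipeline run
#'
#' Three stacked panels against bin midpoint age: |delta_T|, |R| (log
#' scale), and the chosen extinction rate — the standard summary view of
#' the compiled series.
#'
#' @param x A \code{thermext_run}.
#' @param ... Unused.
#' @export
plot.thermext_run <- function(x, ...) {
  et <- x$event_table
  mid <- (x$bins$t_old + x$bins$t_young) / 2
  names(mid) <- x$bins$bin_id
  age <- mid[et$bin_id]
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(age, abs(et$delta_T_c), xlim = rev(range(age)), pch = 19,
                 col = "darkcyan", xlab = "", ylab = "|dT| (C)")
  graphics::plot(age, abs(et$rate_c_per_myr), xlim = rev(range(age)), pch = 19,
                 col = "blue", log = "y", xlab = "", ylab = "|R| (C/Myr)")
  if (!is.null(x$rates)) {
    rc <- if (x$config$estimator == "gf") "r_gf" else "r_3t"
    r <- x$rates[[rc]][match(et$bin_id, x$rates$bin_id)]
    graphics::plot(age, r, xlim = rev(range(age)), pch = 19, col = "red",
                   xlab = "age (Ma)", ylab = "extinction rate")
  }
  invisible(x)
}
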