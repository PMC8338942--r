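#' Temperature series for one time bin
#'
#' @param bin_id Bin code.
#' @param age Ages in Ma (sorted internally to decrease toward the present).
#' @param sst SST in degC.
#' @param sst_sd Per-sample SST standard deviation, degC (default 0).
#' @param source_label Proxy/region tag (e.g. "conodont d18O, South China").
#' @param age_lower,age_upper Optional per-sample age bounds in Ma
#'   (older/younger), used by Monte Carlo event uncertainty.
#' @return A data.frame of class \code{temperature_series}, sorted oldest
#'   first, with attributes \code{bin_id} and \code{source_label}.
#' @export
temperature_series <- function(bin_id, age, sst, sst_sd = 0,
                               source_label = "", age_lower = NULL,
                               age_upper = NULL) {
  stopifnot(length(age) == length(sst))
  ser <- data.frame(age = age, sst = sst,
                    sst_sd = rep_len(sst_sd, length(age)))
  if (!is.null(age_lower)) ser$age_lower <- rep_len(age_lower, length(age))
  if (!is.null(age_upper)) ser$age_upper <- rep_len(age_upper, length(age))
  ser <- ser[order(-ser$age), , drop = FALSE]
  rownames(ser) <- NULL
  attr(ser, "bin_id") <- bin_id
  attr(ser, "source_label") <- source_label
  class(ser) <- c("temperature_series", "data.frame")
  ser
}

#' Event-detection configuration
#'
#' @param endpoint_group_size Samples averaged around each endpoint (k >= 1).
#' @param min_samples Minimum samples for a series to be event-eligible.
#' @param mc_draws Monte Carlo draws for event uncertainty (>= 2).
#' @param seed Integer seed.
#' @param max_reversal_frac Largest allowed counter-trend reversal of the
#'   smoothed series between candidate endpoints, as a fraction of the
#'   candidate magnitude.
#' @param smooth_window Running-median window (odd; 1 disables smoothing).
#' @param trim_frac Endpoint localisation: among candidate pairs whose
#'   magnitude is within a noise-sized slack of the maximum (capped at
#'   \code{trim_frac} of the maximum), the shortest-duration pair is
#'   chosen, so flat noisy approaches to the excursion do not inflate its
#'   duration; noise-free series keep the exact maximal pair.
#' @return A list of class \code{event_config}.
#' @export
event_config <- function(endpoint_group_size = 3L, min_samples = 4L,
                         mc_draws = 1000L, seed = NULL,
                         max_reversal_frac = 1 / 3, smooth_window = 3L,
                         trim_frac = 0.2) {
  stopifnot(endpoint_group_size >= 1L, mc_draws >= 2L, smooth_window >= 1L,
            smooth_window %% 2L == 1L, max_reversal_frac >= 0,
            trim_frac >= 0, trim_frac < 1)
  structure(list(endpoint_group_size = as.integer(endpoint_group_size),
                 min_samples = as.integer(min_samples),
                 mc_draws = as.integer(mc_draws), seed = seed,
                 max_reversal_frac = max_reversal_frac,
                 smooth_window = as.integer(smooth_window),
                 trim_frac = trim_frac),
            class = "event_config")
}

# indices of the k samples nearest in age to a target age
.nearest_k <- function(ages, target, k) {
  order(abs(ages - target))[seq_len(min(k, length(ages)))]
}

# k nearest samples on (or outside) one side of an endpoint: the T0 group
# sits at ages >= t0 (the approach), the T1 group at ages <= t1 (beyond the
# termination), so both average locally flat data rather than the ramp
.outer_k <- function(ages, target, k, side = c("older", "younger")) {
  side <- match.arg(side)
  cand <- if (side == "older") which(ages >= target - 1e-12)
          else which(ages <= target + 1e-12)
  cand[order(abs(ages[cand] - target))][seq_len(min(k, length(cand)))]
}

#' Detect the largest temperature excursion in a bin
#'
#' Scans every ordered pair of samples (older candidate onset, younger
#' candidate termination) of a lightly smoothed copy of the series (running
#' median, window 3 by default) and selects the pair maximising the absolute
#' smoothed temperature difference, subject to the excursion being close to
#' monotonic: between the endpoints the smoothed series may not reverse
#' against the trend by more than \code{max_reversal_frac} of the candidate
#' magnitude. Ties in magnitude are broken by the shorter duration (the
#' faster event).
#'
#' The endpoint temperatures T0 and T1 are then taken as means of the
#' \code{endpoint_group_size} raw samples nearest to each endpoint on its
#' outer side (at or older than the onset; at or younger than the
#' termination), so each group averages the locally flat approach rather
#' than the ramp itself, and the event quantities follow the definitions
#' \deqn{\Delta T = T_1 - T_0, \quad \Delta t = t_0 - t_1, \quad R = \Delta T / \Delta t}
#' with \eqn{t_0 > t_1} in Ma (duration positive), signed magnitude, and
#' direction warming when \eqn{\Delta T > 0}.
#'
#' @param series A \code{\link{temperature_series}}.
#' @param cfg An \code{\link{event_config}}.
#' @return A list of class \code{climate_event} with fields \code{bin_id},
#'   \code{t0}, \code{t1}, \code{T0}, \code{T1}, \code{delta_T},
#'   \code{delta_t}, \code{rate}, \code{direction}, \code{degenerate},
#'   \code{timespan_flag} and \code{NA} uncertainty slots (filled by
#'   \code{\link{event_uncertainty_mc}}); or \code{NULL} when the series has
#'   fewer than \code{min_samples} samples.
#' @export
detect_largest_event <- function(series, cfg = event_config()) {
  stopifnot(inherits(series, "temperature_series"))
  n <- nrow(series)
  if (n < cfg$min_samples) return(NULL)
  age <- series$age
  sst <- series$sst
  s <- if (cfg$smooth_window > 1L && n >= cfg$smooth_window) {
    as.numeric(stats::runmed(sst, cfg$smooth_window, endrule = "median"))
  } else sst

  # pass over all feasible (monotone-enough) ordered pairs, applying a
  # selection rule; run twice: first to find the maximum magnitude, then to
  # localise the endpoints as the shortest pair within trim_frac of it
  scan_pairs <- function(keep) {
    best <- NULL  # (i, j, |d|, dt)
    for (i in seq_len(n - 1L)) {
      run_max <- s[i]
      run_min <- s[i]
      max_drawdown <- 0  # largest drop below a prior high (against an up-trend)
      max_drawup <- 0    # largest rise above a prior low (against a down-trend)
      for (j in (i + 1L):n) {
        max_drawdown <- max(max_drawdown, run_max - s[j])
        max_drawup <- max(max_drawup, s[j] - run_min)
        run_max <- max(run_max, s[j])
        run_min <- min(run_min, s[j])
        dt <- age[i] - age[j]
        if (dt <= 0) next
        d <- s[j] - s[i]
        reversal <- if (d >= 0) max_drawdown else max_drawup
        if (abs(d) > 0 && reversal > cfg$max_reversal_frac * abs(d)) next
        best <- keep(best, i, j, abs(d), dt)
      }
    }
    best
  }
  by_magnitude <- function(best, i, j, ad, dt) {
    if (is.null(best) || ad > best[3L] + 1e-12 ||
        (abs(ad - best[3L]) <= 1e-12 && dt < best[4L])) c(i, j, ad, dt) else best
  }
  best <- scan_pairs(by_magnitude)
  # endpoint localisation slack: within noise of the maximum counts as the
  # same magnitude, so the shortest such pair marks the true endpoints; a
  # noise-free series gets zero slack and keeps the exact maximal pair
  sigma_hat <- stats::mad(diff(sst)) / sqrt(2)
  slack <- min(cfg$trim_frac * if (is.null(best)) 0 else best[3L], 3 * sigma_hat)
  if (!is.null(best) && best[3L] > 0 && slack > 0) {
    floor_mag <- best[3L] - slack
    by_duration <- function(b, i, j, ad, dt) {
      if (ad < floor_mag) return(b)
      if (is.null(b) || dt < b[4L] - 1e-12 ||
          (abs(dt - b[4L]) <= 1e-12 && ad > b[3L])) c(i, j, ad, dt) else b
    }
    best <- scan_pairs(by_duration)
  }
  if (is.null(best)) {
    # constant (or fully reversing) series: report a degenerate zero event
    best <- c(1L, 2L, 0, age[1L] - age[2L])
  }
  i <- best[1L]; j <- best[2L]
  t0 <- age[i]; t1 <- age[j]
  k <- cfg$endpoint_group_size
  g0 <- .outer_k(age, t0, k, "older")
  g1 <- .outer_k(age, t1, k, "younger")
  T0 <- mean(sst[g0])
  T1 <- mean(sst[g1])
  delta_T <- T1 - T0
  delta_t <- t0 - t1
  structure(list(bin_id = attr(series, "bin_id"),
                 t0 = t0, t1 = t1, T0 = T0, T1 = T1,
                 delta_T = delta_T, delta_t = delta_t,
                 rate = delta_T / delta_t,
                 direction = if (delta_T > 0) "warming" else "cooling",
                 degenerate = delta_T == 0,
                 timespan_flag = FALSE,
                 delta_T_sd = NA_real_, rate_sd = NA_real_,
                 delta_t_sd = NA_real_,
                 group0 = g0, group1 = g1,
                 source_label = attr(series, "source_label")),
            class = "climate_event")
}

#' Rate of a temperature event
#'
#' \code{R = delta_T / delta_t}, the signed rate of a single warming/cooling
#' event in degC per Myr.
#'
#' @param delta_T Signed magnitude, degC.
#' @param delta_t Duration, Myr (> 0).
#' @return Signed rate, degC/Myr.
#' @export
event_rate <- function(delta_T, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be positive")
  delta_T / delta_t
}

#' Monte Carlo uncertainty of an event's magnitude and rate
#'
#' Resamples each endpoint group with replacement, perturbs every resampled
#' SST by its per-sample standard deviation, and (when the series carries
#' per-sample age bounds) redraws each age uniformly within its bounds;
#' recomputes delta_T, delta_t and R for each draw and returns their standard
#' deviations. Draws whose duration becomes non-positive are dropped and
#' counted.
#'
#' @param series The \code{\link{temperature_series}} the event came from.
#' @param event A \code{\link{climate_event}} from
#'   \code{\link{detect_largest_event}}.
#' @param cfg An \code{\link{event_config}}; \code{mc_draws} and \code{seed}
#'   are used.
#' @return The event with \code{delta_T_sd}, \code{rate_sd}, \code{delta_t_sd}
#'   filled in, plus \code{mc_dropped} (non-positive-duration draws).
#' @export
event_uncertainty_mc <- function(series, event, cfg = event_config()) {
  stopifnot(inherits(series, "temperature_series"), inherits(event, "climate_event"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g0 <- event$group0
  g1 <- event$group1
  have_bounds <- all(c("age_lower", "age_upper") %in% names(series))
  draw_ages <- function(idx) {
    if (!have_bounds) return(series$age[idx])
    lo <- series$age_upper[idx]  # younger bound
    hi <- series$age_lower[idx]  # older bound
    ifelse(hi > lo, stats::runif(length(idx), lo, hi), series$age[idx])
  }
  resample <- function(x) x[sample.int(length(x), length(x), replace = TRUE)]
  dT <- numeric(cfg$mc_draws)
  dt <- numeric(cfg$mc_draws)
  for (r in seq_len(cfg$mc_draws)) {
    i0 <- resample(g0)
    i1 <- resample(g1)
    s0 <- series$sst[i0] + stats::rnorm(length(i0), 0, series$sst_sd[i0])
    s1 <- series$sst[i1] + stats::rnorm(length(i1), 0, series$sst_sd[i1])
    dT[r] <- mean(s1) - mean(s0)
    dt[r] <- mean(draw_ages(i0)) - mean(draw_ages(i1))
  }
  ok <- dt > 0
  event$delta_T_sd <- stats::sd(dT)
  event$delta_t_sd <- stats::sd(dt)
  event$rate_sd <- if (sum(ok) >= 2L) stats::sd(dT[ok] / dt[ok]) else NA_real_
  event$mc_dropped <- sum(!ok)
  event
}

#' Assign an event to a time bin
#'
#' Events wholly inside one bin belong to it. Events crossing a bin boundary
#' belong to the bin containing the onset (the older bin) — short boundary
#' excursions such as the Permian-Triassic warming start near the end of the
#' older bin and impact its fauna — and are flagged. An onset exactly on a
#' shared boundary age belongs to the older bin (half-open convention).
#'
#' @param event A \code{\link{climate_event}}.
#' @param bins A \code{time_bins} scheme.
#' @return The event with \code{bin_id} set and \code{timespan_flag} TRUE when
#'   the event crosses out of its bin.
#' @export
assign_event_bin <- function(event, bins) {
  stopifnot(inherits(event, "climate_event"), inherits(bins, "time_bins"))
  i0 <- .bin_index_of_age(event$t0, bins)
  i1 <- .bin_index_of_age(event$t1, bins)
  if (is.na(i0)) stop("event onset age ", event$t0, " Ma outside the binning scheme")
  event$bin_id <- bins$bin_id[i0]
  event$timespan_flag <- is.na(i1) || i1 != i0
  event
}

#' Classify an event against the mass-extinction thresholds
#'
#' The Big Five mass extinctions fall in the region |delta_T| > 5.2 degC and
#' |R| > 10 degC/Myr; no background or minor extinction exceeds either.
#' Classification uses strict inequalities on both magnitude and rate; the
#' short-timespan condition (delta_t < 0.4 Myr) is reported as a separate
#' flag, not a classification criterion.
#'
#' @param event A \code{\link{climate_event}}.
#' @param thresholds List with \code{mag} (degC), \code{rate} (degC/Myr),
#'   \code{span} (Myr).
#' @return List with \code{class} ("big_five_regime" or "background") and
#'   \code{short_timespan} (logical).
#' @export
classify_event <- function(event,
                           thresholds = list(mag = 5.2, rate = 10, span = 0.4)) {
  stopifnot(inherits(event, "climate_event"))
  cls <- if (abs(event$delta_T) > thresholds$mag &&
             abs(event$rate) > thresholds$rate) "big_five_regime" else "background"
  list(class = cls, short_timespan = event$delta_t < thresholds$span)
}

#' Average events from multiple series covering one bin
#'
#' When two proxies or regions cover the same bin, events are detected per
#' series and their delta_T, delta_t and R averaged (arithmetic means of the
#' signed values); standard deviations combine in quadrature divided by the
#' series count. Conflicting directions trigger a warning and are averaged on
#' signed values.
#'
#' @param events List of \code{climate_event}s for one bin.
#' @return A single averaged \code{climate_event}.
#' @export
average_events <- function(events) {
  stopifnot(is.list(events), length(events) >= 1L,
            all(vapply(events, inherits, logical(1), "climate_event")))
  if (length(events) == 1L) return(events[[1L]])
  dirs <- vapply(events, `[[`, character(1), "direction")
  if (length(unique(dirs)) > 1L) {
    warning("averaging events with conflicting directions; using signed values")
  }
  m <- length(events)
  avg <- function(f) mean(vapply(events, `[[`, numeric(1), f))
  quad <- function(f) {
    v <- vapply(events, `[[`, numeric(1), f)
    if (all(is.na(v))) NA_real_ else sqrt(sum(v^2, na.rm = TRUE)) / m
  }
  out <- events[[1L]]
  out$delta_T <- avg("delta_T")
  out$delta_t <- avg("delta_t")
  out$rate <- avg("rate")
  out$t0 <- avg("t0"); out$t1 <- avg("t1")
  out$T0 <- avg("T0"); out$T1 <- avg("T1")
  out$delta_T_sd <- quad("delta_T_sd")
  out$rate_sd <- quad("rate_sd")
  out$delta_t_sd <- quad("delta_t_sd")
  out$direction <- if (out$delta_T > 0) "warming" else "cooling"
  out$degenerate <- out$delta_T == 0
  out$source_label <- paste(vapply(events, `[[`, character(1), "source_label"),
                            collapse = " + ")
  out
}

#' @export
print.climate_event <- function(x, ...) {
  cat(sprintf("Climate event [%s]%s\n", x$bin_id %||% "?",
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  cat(sprintf("  t0 = %.3f Ma -> t1 = %.3f Ma (delta_t = %.3f Myr)\n",
              x$t0, x$t1, x$delta_t))
  cat(sprintf("  T0 = %.2f C -> T1 = %.2f C (delta_T = %+.2f C, %s)\n",
              x$T0, x$T1, x$delta_T, x$direction))
  cat(sprintf("  R = %+.2f C/Myr\n", x$rate))
  if (!is.na(x$delta_T_sd)) {
    cat(sprintf("  sd(delta_T) = %.2f C, sd(R) = %.2f C/Myr\n",
                x$delta_T_sd, x$rate_sd))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten a list of climate_events into the standard event table
events_to_table <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(bin_id = character(), t0_ma = numeric(), t1_ma = numeric(),
                      T0_c = numeric(), T1_c = numeric(), delta_T_c = numeric(),
                      delta_t_myr = numeric(), rate_c_per_myr = numeric(),
                      direction = character(), delta_T_sd = numeric(),
                      rate_sd = numeric(), delta_t_sd = numeric(),
                      degenerate = logical(), timespan_flag = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(bin_id = e$bin_id %||% NA_character_,
               t0_ma = e$t0, t1_ma = e$t1, T0_c = e$T0, T1_c = e$T1,
               delta_T_c = e$delta_T, delta_t_myr = e$delta_t,
               rate_c_per_myr = e$rate, direction = e$direction,
               delta_T_sd = e$delta_T_sd, rate_sd = e$rate_sd,
               delta_t_sd = e$delta_t_sd,
               degenerate = e$degenerate, timespan_flag = e$timespan_flag,
               stringsAsFactors = FALSE)
  }))
}
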