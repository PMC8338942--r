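#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions emulated by the generators: a bin scheme, a
#' baseline SST with per-bin ramp excursions (signed magnitude, duration,
#' onset), measurement noise and sampling density for the climate series;
#' genus-level survival/sampling probabilities, with extinction optionally
#' coupled to the injected |delta_T| through a logistic link on the
#' standardised magnitudes,
#' \code{q_b = plogis(qlogis(base_q) + coupling * z(|delta_T_b|))}, for the
#' occurrence generator; and a contamination fraction for the GDGT
#' generator.
#'
#' @param bins A \code{time_bins} scheme (default: packaged 45-bin scheme).
#' @param baseline_sst Baseline SST, degC.
#' @param events Data.frame with columns \code{bin_id}, \code{magnitude}
#'   (signed degC), \code{duration} (Myr), \code{onset} (Ma; \code{NA} puts
#'   the onset at 60\% of the way through the bin). Bins absent from the
#'   table get no injected excursion.
#' @param noise_sd Gaussian measurement noise, degC.
#' @param sampling_density Background samples per Myr (> 0).
#' @param event_oversampling Samples per ramp duration in the
#'   high-resolution window spanning an injected event (emulates the dense
#'   sections geochemists measure across boundary events).
#' @param age_jitter Uniform age jitter half-width, Myr.
#' @param n_genera Standing richness for the occurrence simulation.
#' @param base_extinction_prob Per-bin extinction probability when
#'   \code{coupling = 0}.
#' @param sampling_prob Probability an extant genus is sampled in a bin.
#' @param coupling Logistic coupling of extinction probability to
#'   |delta_T| (>= 0, per degC).
#' @param contamination_frac Fraction of generated GDGT samples built to
#'   fail exactly one screening rule.
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(bins = load_bin_scheme(), baseline_sst = 24,
                             events = NULL, noise_sd = 0.5,
                             sampling_density = 3, event_oversampling = 8,
                             age_jitter = 0,
                             n_genera = 400, base_extinction_prob = 0.2,
                             sampling_prob = 0.9, coupling = 0,
                             contamination_frac = 0, seed = 1L) {
  stopifnot(inherits(bins, "time_bins"), sampling_density > 0,
            event_oversampling >= 2,
            noise_sd >= 0, age_jitter >= 0, n_genera >= 1,
            base_extinction_prob > 0, base_extinction_prob < 1,
            sampling_prob >= 0, sampling_prob <= 1, coupling >= 0,
            contamination_frac >= 0, contamination_frac <= 1)
  if (is.null(events)) {
    events <- data.frame(bin_id = character(), magnitude = numeric(),
                         duration = numeric(), onset = numeric(),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("bin_id", "magnitude", "duration") %in% names(events)))
  if (!"onset" %in% names(events)) events$onset <- NA_real_
  bad <- setdiff(events$bin_id, bins$bin_id)
  if (length(bad) > 0L) stop("event spec references unknown bin(s): ",
                             paste(bad, collapse = ", "))
  for (r in seq_len(nrow(events))) {
    b <- bins[bins$bin_id == events$bin_id[r], ]
    if (events$duration[r] >= b$duration) {
      stop(sprintf("injected event in %s lasts %.2f Myr but the bin is only %.2f Myr",
                   events$bin_id[r], events$duration[r], b$duration))
    }
  }
  structure(list(bins = bins, baseline_sst = baseline_sst, events = events,
                 noise_sd = noise_sd, sampling_density = sampling_density,
                 event_oversampling = event_oversampling,
                 age_jitter = age_jitter, n_genera = as.integer(n_genera),
                 base_extinction_prob = base_extinction_prob,
                 sampling_prob = sampling_prob, coupling = coupling,
                 contamination_frac = contamination_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic SST signal at age a (Ma) for one bin: baseline until onset,
# linear ramp of `magnitude` over `duration`, a plateau at the excursion
# level, then partial linear recovery (60%) toward baseline. The partial
# recovery keeps the recovery limb strictly smaller than the ramp, so the
# injected ramp is unambiguously the largest excursion.
.signal_sst <- function(age, baseline, magnitude, duration, onset, t_young) {
  if (is.na(magnitude) || magnitude == 0) return(rep(baseline, length(age)))
  t_end <- onset - duration          # termination (younger)
  hold <- min(duration, (t_end - t_young) / 2)
  t_hold <- t_end - hold             # plateau end
  recov_end <- max(t_young, t_hold - 2 * duration)
  post <- baseline + 0.4 * magnitude # level after partial recovery
  sst <- numeric(length(age))
  for (k in seq_along(age)) {
    a <- age[k]
    sst[k] <- if (a >= onset) {
      baseline
    } else if (a >= t_end) {
      baseline + magnitude * (onset - a) / duration
    } else if (a >= t_hold) {
      baseline + magnitude
    } else if (a >= recov_end && recov_end < t_hold) {
      post + (magnitude - 0.4 * magnitude) * (a - recov_end) / (t_hold - recov_end)
    } else {
      post
    }
  }
  sst
}

#' Generate per-bin temperature series with known ground truth
#'
#' Each bin's series is baseline SST plus an injected ramp excursion (when
#' specified) plus Gaussian noise, sampled at \code{sampling_density}
#' samples/Myr on a jittered regular grid. The shape is plateau -> ramp ->
#' short plateau -> recovery, so the endpoint groups used by
#' \code{\link{detect_largest_event}} sit on locally flat data. The truth
#' table records the injected (delta_T, delta_t, R) per bin (zeros for
#' bins without an excursion).
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return A list with \code{series} (named list of
#'   \code{\link{temperature_series}}) and \code{truth} (data.frame
#'   \code{bin_id}, \code{delta_T}, \code{delta_t}, \code{rate}).
#' @export
generate_climate_series <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  bins <- cfg$bins
  series <- vector("list", nrow(bins))
  names(series) <- bins$bin_id
  truth <- data.frame(bin_id = bins$bin_id, delta_T = 0, delta_t = NA_real_,
                      rate = 0, onset = NA_real_, stringsAsFactors = FALSE)
  for (b in seq_len(nrow(bins))) {
    t_old <- bins$t_old[b]; t_young <- bins$t_young[b]
    n <- max(2L, round(cfg$sampling_density * (t_old - t_young)))
    grid <- seq(t_old, t_young, length.out = n)
    if (cfg$age_jitter > 0) {
      grid <- grid + stats::runif(n, -cfg$age_jitter, cfg$age_jitter)
      grid <- pmin(pmax(grid, t_young), t_old)
    }
    ev <- cfg$events[cfg$events$bin_id == bins$bin_id[b], , drop = FALSE]
    if (nrow(ev) > 0L) {
      onset <- ev$onset[1L]
      if (is.na(onset)) onset <- t_old - 0.6 * (t_old - t_young)
      # onset must leave room for the ramp inside the bin
      onset <- min(max(onset, t_young + ev$duration[1L] + 1e-9), t_old)
      # boundary-event sections are studied at high resolution: oversample
      # a window spanning the ramp and its flanking plateaus
      dur <- ev$duration[1L]
      t_end <- onset - dur
      hold <- min(dur, (t_end - t_young) / 2)
      w_old <- min(onset + hold, t_old)
      w_young <- max(t_end - hold, t_young)
      spacing <- dur / cfg$event_oversampling
      dense <- seq(w_old, w_young, by = -spacing)
      grid <- sort(unique(c(grid, dense)), decreasing = TRUE)
      n <- length(grid)
      sig <- .signal_sst(grid, cfg$baseline_sst, ev$magnitude[1L],
                         ev$duration[1L], onset, t_young)
      truth$delta_T[b] <- ev$magnitude[1L]
      truth$delta_t[b] <- ev$duration[1L]
      truth$rate[b] <- ev$magnitude[1L] / ev$duration[1L]
      truth$onset[b] <- onset
    } else {
      sig <- rep(cfg$baseline_sst, n)
    }
    sst <- sig + stats::rnorm(n, 0, cfg$noise_sd)
    series[[b]] <- temperature_series(bins$bin_id[b], grid, sst,
                                      sst_sd = cfg$noise_sd,
                                      source_label = "synthetic")
  }
  list(series = series, truth = truth)
}

#' Generate genus-level occurrence records with known extinction schedule
#'
#' Simulates genus lifespans forward through the bins: a genus extant in bin
#' b goes extinct before bin b+1 with probability \code{q_b}; origination
#' tops richness back up to \code{n_genera} each bin, so richness is
#' stationary and the extinction signal is isolated. Each extant genus is
#' sampled (emits an occurrence record) with probability
#' \code{sampling_prob}. With \code{coupling > 0} and a delta_T truth table,
#' \code{q_b = plogis(qlogis(base_q) + coupling * z_b)} where \code{z_b} is
#' the standardised |delta_T_b| across bins.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param truth_delta_T Optional data.frame (\code{bin_id}, \code{delta_T}),
#'   e.g. the truth table from \code{\link{generate_climate_series}}.
#' @param seed Optional seed override (defaults to \code{cfg$seed + 1}).
#' @param pad Also simulate one bin before and two after the scheme (ids
#'   \code{pre1}, \code{post1}, \code{post2}, at the base extinction
#'   probability), mirroring a real occurrence database that extends beyond
#'   the temperature window; with padding the edge bins of the scheme have
#'   defined rates. Count cohorts against \code{\link{pad_bin_scheme}}.
#' @return List with \code{records} (data.frame \code{genus},
#'   \code{higher_taxa}, \code{bin_id}, \code{environment}) and \code{truth}
#'   (data.frame \code{bin_id}, \code{q}; focal bins only).
#' @export
generate_occurrences <- function(cfg, truth_delta_T = NULL, seed = NULL,
                                 pad = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  bins <- cfg$bins
  nb <- nrow(bins)
  q <- rep(cfg$base_extinction_prob, nb)
  if (!is.null(truth_delta_T) && cfg$coupling > 0) {
    dT <- abs(truth_delta_T$delta_T[match(bins$bin_id, truth_delta_T$bin_id)])
    dT[is.na(dT)] <- 0
    # logistic link on standardised magnitude: q stays away from the
    # degenerate 0/1 ends (where cohort counts vanish) whatever the degC
    # scale of the injected events, and beta keeps a unit-free meaning
    z <- if (stats::sd(dT) > 0) (dT - mean(dT)) / stats::sd(dT) else rep(0, nb)
    q <- stats::plogis(stats::qlogis(cfg$base_extinction_prob) +
                         cfg$coupling * z)
  }
  bin_ids <- bins$bin_id
  if (pad) {
    bin_ids <- c("pre1", bin_ids, "post1", "post2")
    q <- c(cfg$base_extinction_prob, q,
           rep(cfg$base_extinction_prob, 2L))
  }
  nbt <- length(bin_ids)
  n <- cfg$n_genera
  next_id <- n + 1L
  alive <- seq_len(n)
  rec_genus <- vector("list", nbt)
  for (b in seq_len(nbt)) {
    sampled <- alive[stats::runif(length(alive)) < cfg$sampling_prob]
    rec_genus[[b]] <- sampled
    dies <- stats::runif(length(alive)) < q[b]
    survivors <- alive[!dies]
    n_new <- n - length(survivors)
    newcomers <- if (n_new > 0L) seq.int(next_id, next_id + n_new - 1L) else integer()
    next_id <- next_id + n_new
    alive <- c(survivors, newcomers)
  }
  counts <- lengths(rec_genus)
  records <- data.frame(
    genus = paste0("g", unlist(rec_genus)),
    higher_taxa = "SyntheticClade",
    bin_id = rep(bin_ids, counts),
    environment = "shallow",
    stringsAsFactors = FALSE
  )
  attr(records, "padded") <- pad
  focal <- bin_ids %in% bins$bin_id
  list(records = records,
       truth = data.frame(bin_id = bin_ids[focal], q = q[focal],
                          stringsAsFactors = FALSE))
}

#' Extend a bin scheme with synthetic padding bins
#'
#' Adds one bin before and two after the scheme (\code{pre1}, \code{post1},
#' \code{post2}) so that cohort counts — which need neighbours at \code{i-1}
#' and \code{i+2} — are defined at the scheme's edge bins when the
#' occurrence data extend beyond the temperature window (as a real
#' occurrence download does). The padding bins are synthetic bookkeeping
#' intervals, not part of the analysis window.
#'
#' @param bins A \code{time_bins} scheme.
#' @return A \code{time_bins} scheme with the padding bins added.
#' @export
pad_bin_scheme <- function(bins) {
  stopifnot(inherits(bins, "time_bins"))
  nb <- nrow(bins)
  y <- bins$t_young[nb]  # youngest edge; split the remaining time in thirds
  pad <- data.frame(
    bin_id = c("pre1", "post1", "post2"),
    stages = "synthetic padding",
    t_old = c(bins$t_old[1] + 10, y, 2 * y / 3),
    t_young = c(bins$t_old[1], 2 * y / 3, y / 3),
    duration = NA_real_, stringsAsFactors = FALSE)
  pad$duration <- pad$t_old - pad$t_young
  out <- rbind(pad[1, ], as.data.frame(bins), pad[2:3, ])
  rownames(out) <- NULL
  class(out) <- c("time_bins", "data.frame")
  out
}

# a GDGT composition comfortably inside every screening rule:
# BIT 0, MI 0.385, %GDGT-0 43.0, fCren' 0.0625, and gdgt0 solved so that
# RI_sample matches RI_TEX at TEX86 = 0.545 (dRI ~ 0)
.clean_gdgt <- function() {
  gdgt_composition(gdgt0 = 2.264, gdgt1 = 1, gdgt2 = 0.7, gdgt3 = 0.3,
                   cren = 3, cren_prime = 0.2)
}

#' Generate GDGT compositions with known screening labels
#'
#' Clean samples are drawn near a composition that passes every screening
#' rule; contaminated samples are the clean composition altered to violate
#' exactly one named rule each (cycled through the five GDGT rules). Labels
#' are returned so screening can be checked against construction.
#'
#' @param cfg A \code{\link{synthetic_config}}; \code{contamination_frac}
#'   and \code{seed} are used.
#' @param n Number of samples.
#' @return Data.frame with \code{sample_id}, \code{expected_reason}
#'   (\code{"clean"} or rule name) and a list-column \code{gdgt} of
#'   \code{\link{gdgt_composition}} objects.
#' @export
generate_gdgt <- function(cfg, n = 20L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  n_bad <- round(cfg$contamination_frac * n)
  rules <- c("terrestrial_input", "methane_index", "ring_index",
             "gdgt0_excess", "cren_isomer_excess")
  labels <- c(rep("clean", n - n_bad),
              rules[(seq_len(n_bad) - 1L) %% length(rules) + 1L])
  base <- .clean_gdgt()
  # Contaminated variants are exact constructions checked against every
  # index: each trips its own rule while every other index keeps a margin
  # to its cut-off. Clean samples get a small multiplicative jitter (which
  # the margins of the clean composition absorb); the constructed variants
  # are emitted as-is so their single-rule property is guaranteed.
  make <- function(label) {
    if (label == "clean") {
      jit <- function(v) v * stats::runif(1, 0.97, 1.03)
      return(gdgt_composition(gdgt0 = jit(base$gdgt0), gdgt1 = jit(base$gdgt1),
                              gdgt2 = jit(base$gdgt2), gdgt3 = jit(base$gdgt3),
                              cren = jit(base$cren),
                              cren_prime = jit(base$cren_prime)))
    }
    switch(label,
           terrestrial_input = {         # BIT 0.667
             g <- base; g$br_Ia <- 2 * g$cren; g
           },
           methane_index =               # MI 0.678, TEX86 unchanged
             gdgt_composition(gdgt0 = base$gdgt0, gdgt1 = 4 * base$gdgt1,
                              gdgt2 = 4 * base$gdgt2, gdgt3 = 4 * base$gdgt3,
                              cren = base$cren,
                              cren_prime = 4 * base$cren_prime),
           ring_index = {                # cren-heavy: dRI ~ 1.0
             g <- base; g$cren <- 4 * base$cren; g
           },
           gdgt0_excess =                # %GDGT-0 69.7, dRI 0.247
             gdgt_composition(gdgt0 = 6.9, gdgt1 = 3, gdgt2 = 0, gdgt3 = 0,
                              cren = 3, cren_prime = 0.8),
           cren_isomer_excess = {        # fCren' 0.286
             g <- base; g$cren_prime <- 0.4 * base$cren; g
           })
  }
  out <- data.frame(sample_id = sprintf("gdgt_%03d", seq_len(n)),
                    expected_reason = labels, stringsAsFactors = FALSE)
  out$gdgt <- lapply(labels, make)
  out
}
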