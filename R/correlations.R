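# Rank-correlation machinery for the climate-extinction analyses.
#
# The two-sided P value is computed by a t approximation for n >= 10 and by
# exact enumeration of all n! rank permutations for n < 10 (tie-aware:
# rho is Pearson's correlation of average ranks throughout).

# all permutations of 1..n as an (n! x n) matrix, n <= 9
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- seq.int(row, row + nrow(sub) - 1L)
    out[block, pos] <- n
    out[block, -pos] <- sub
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample P value
#'
#' Computes Spearman's rho as Pearson's correlation of average ranks (so
#' ties are handled), with a two-sided P value from the t approximation
#' \code{t = rho * sqrt((n-2)/(1-rho^2))} for \code{n >= 10} and from exact
#' enumeration of all rank permutations for \code{n < 10}. Pairs with a
#' missing entry are dropped and \code{n} reflects the drop.
#'
#' @param x,y Numeric vectors of equal length.
#' @param label Subset name carried into the result.
#' @return A list of class \code{correlation_result} with \code{label},
#'   \code{rho}, \code{p_value}, \code{n}, \code{method}.
#' @export
spearman <- function(x, y, label = "") {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(structure(list(label = label, rho = NA_real_, p_value = NA_real_,
                          n = n, method = "undefined"),
                     class = "correlation_result"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    perms <- .permutations(n)
    # rho is monotone in S = sum(rx * ry[perm]) for fixed marginal ranks
    S_obs <- sum(rx * ry)
    S_all <- as.numeric(perms_stat(perms, rx, ry))
    mu <- n * mean(rx) * mean(ry)
    p <- mean(abs(S_all - mu) >= abs(S_obs - mu) - 1e-9)
    method <- "exact-permutation"
  }
  structure(list(label = label, rho = rho, p_value = p, n = n, method = method),
            class = "correlation_result")
}

# sum(rx[pos] * ry[perm[pos]]) for every permutation row
perms_stat <- function(perms, rx, ry) {
  matrix(ry[perms], nrow = nrow(perms)) %*% rx
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: rho = %.3f, P = %.4g, n = %d (%s)\n",
              if (nzchar(x$label)) x$label else "spearman",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Correlation suite over climate events and extinction rates
#'
#' Joins the per-bin event table to the per-bin extinction rates and runs the
#' standard set of rank correlations: all bins (|delta_T| vs extinction rate
#' and |R| vs extinction rate), warming-only and cooling-only subsets (the
#' cooling subset correlates the signed, negative magnitudes, so an
#' extinction-increases-with-cooling signal appears as negative rho),
#' excluding the Big-Five bins, restricting to bins with |R| below the rate
#' threshold, and the two confound checks (bin duration vs extinction rate;
#' |delta_T| vs event timespan). When rates computed without deep-water
#' records are supplied, the deep-water-exclusion correlations are added.
#'
#' @param events Event table (\code{bin_id}, \code{delta_T_c},
#'   \code{rate_c_per_myr}, \code{delta_t_myr}, \code{direction}), e.g. from
#'   \code{\link{run_pipeline}}.
#' @param rates Extinction-rate table from \code{\link{extinction_rates}}.
#' @param bins A \code{time_bins} scheme (for the duration confound check).
#' @param big_five_bins Character vector of bin codes treated as the Big Five.
#' @param estimator \code{"gf"} or \code{"3t"}.
#' @param rate_threshold Rate cut for the low-rate subset, degC/Myr.
#' @param rates_no_deep Optional rate table computed with
#'   \code{drop_deep_water = TRUE}.
#' @return Data.frame with columns \code{label}, \code{rho}, \code{p_value},
#'   \code{n}, \code{defined}.
#' @export
correlation_suite <- function(events, rates, bins, big_five_bins = character(),
                              estimator = c("gf", "3t"), rate_threshold = 10,
                              rates_no_deep = NULL) {
  estimator <- match.arg(estimator)
  rate_col <- if (estimator == "gf") "r_gf" else "r_3t"
  df <- merge(events, rates[, c("bin_id", rate_col)], by = "bin_id")
  df <- merge(df, bins[, c("bin_id", "duration")], by = "bin_id")
  df$ext <- df[[rate_col]]
  df$abs_dT <- abs(df$delta_T_c)
  df$abs_R <- abs(df$rate_c_per_myr)

  run <- function(sub, xcol, label) {
    sub <- sub[is.finite(sub$ext), , drop = FALSE]
    if (nrow(sub) < 3L) {
      return(data.frame(label = label, rho = NA_real_, p_value = NA_real_,
                        n = nrow(sub), defined = FALSE, stringsAsFactors = FALSE))
    }
    r <- spearman(sub[[xcol]], sub$ext, label)
    data.frame(label = label, rho = r$rho, p_value = r$p_value, n = r$n,
               defined = TRUE, stringsAsFactors = FALSE)
  }

  warming <- df[df$direction == "warming", ]
  cooling <- df[df$direction == "cooling", ]
  no_b5 <- df[!df$bin_id %in% big_five_bins, ]
  low_rate <- df[df$abs_R < rate_threshold, ]

  out <- rbind(
    run(df, "abs_dT", "all_dT"),
    run(df, "abs_R", "all_R"),
    run(warming, "delta_T_c", "warming_dT"),
    run(warming, "rate_c_per_myr", "warming_R"),
    run(cooling, "delta_T_c", "cooling_dT"),
    run(cooling, "rate_c_per_myr", "cooling_R"),
    run(no_b5, "abs_dT", "excl_big_five_dT"),
    run(no_b5, "abs_R", "excl_big_five_R"),
    run(low_rate, "abs_R", "rate_below_10_R"),
    run(df, "duration", "duration_vs_ext")
  )
  # |delta_T| vs event timespan: checks magnitude is not a timespan artefact
  ts <- df[is.finite(df$abs_dT) & is.finite(df$delta_t_myr), ]
  ts_row <- if (nrow(ts) >= 3L) {
    r <- spearman(ts$abs_dT, ts$delta_t_myr, "dT_vs_timespan")
    data.frame(label = "dT_vs_timespan", rho = r$rho, p_value = r$p_value,
               n = r$n, defined = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(label = "dT_vs_timespan", rho = NA_real_, p_value = NA_real_,
               n = nrow(ts), defined = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(out, ts_row)
  if (!is.null(rates_no_deep)) {
    df2 <- merge(events, rates_no_deep[, c("bin_id", rate_col)], by = "bin_id")
    df2$ext <- df2[[rate_col]]
    df2$abs_dT <- abs(df2$delta_T_c)
    df2$abs_R <- abs(df2$rate_c_per_myr)
    out <- rbind(out,
                 run(df2, "abs_dT", "excl_deep_water_dT"),
                 run(df2, "abs_R", "excl_deep_water_R"))
  }
  rownames(out) <- NULL
  out
}

#' Compare two correlation coefficients from disjoint subsets
#'
#' \code{fisher_independent} (default): Fisher-z test for correlations from
#' independent samples,
#' \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))}.
#' \code{pearson_filon}: the classical large-sample statistic built on the
#' Pearson-Filon variance of r,
#' \code{z = (r1 - r2) / sqrt((1-r1^2)^2/(n1-1) + (1-r2^2)^2/(n2-1))}.
#' Both return a two-sided normal P value.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @param method \code{"fisher_independent"} or \code{"pearson_filon"}.
#' @return A list of class \code{comparison_result} with \code{z},
#'   \code{p_value}, \code{method}.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 method = c("fisher_independent", "pearson_filon")) {
  method <- match.arg(method)
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- if (method == "fisher_independent") {
    (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    (r1 - r2) / sqrt((1 - r1^2)^2 / (n1 - 1) + (1 - r2^2)^2 / (n2 - 1))
  }
  structure(list(z = z, p_value = 2 * stats::pnorm(-abs(z)), method = method),
            class = "comparison_result")
}

#' Sample autocorrelation function
#'
#' Overall-mean sample ACF (lag-0 autocorrelation is 1), used to check that
#' the extinction-rate, delta_T and log|R| series are free of serial
#' correlation before interpreting their cross correlations.
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag (default \code{10*log10(n)} as in standard
#'   practice, capped at \code{n - 2}).
#' @param label Series name.
#' @return A list of class \code{acf_result} with a data.frame \code{lags}
#'   (\code{lag}, \code{acf}).
#' @export
acf_series <- function(series, max_lag = NULL, label = "") {
  series <- series[is.finite(series)]
  n <- length(series)
  if (is.null(max_lag)) max_lag <- min(n - 2L, floor(10 * log10(n)))
  stopifnot(n > max_lag + 1L)
  if (stats::sd(series) == 0) stop("ACF undefined beyond lag 0 for a constant series")
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(label = label,
                 lags = data.frame(lag = 0:max_lag, acf = as.numeric(a$acf))),
            class = "acf_result")
}

#' Does an extinction horizon fall within a climate event?
#'
#' \code{"within"} when the extinction-age interval intersects the event
#' interval [t1, t0]; \code{"indeterminate"} when either uncertainty spans
#' the whole containing bin (no temporal resolution); \code{"outside"}
#' otherwise.
#'
#' @param event A \code{\link{climate_event}} (or list with \code{t0},
#'   \code{t1}).
#' @param extinction_age Best age of the extinction horizon, Ma.
#' @param age_lower,age_upper Older/younger bounds of the horizon age, Ma.
#' @param bin Optional single-bin slice (\code{t_old}, \code{t_young}) used
#'   for the indeterminacy check.
#' @return One of \code{"within"}, \code{"outside"}, \code{"indeterminate"}.
#' @export
timing_overlap <- function(event, extinction_age,
                           age_lower = extinction_age,
                           age_upper = extinction_age, bin = NULL) {
  stopifnot(age_lower >= age_upper)
  if (!is.null(bin)) {
    span <- bin$t_old - bin$t_young
    if ((age_lower - age_upper) >= span ||
        (event$t0 - event$t1) >= span) {
      return("indeterminate")
    }
  }
  # intervals in Ma: event [t1, t0], horizon [age_upper, age_lower]
  if (age_lower >= event$t1 && age_upper <= event$t0) "within" else "outside"
}
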