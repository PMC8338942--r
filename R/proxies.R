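#' Conodont oxygen-isotope thermometer
#'
#' Converts conodont apatite delta-18-O to sea-surface temperature using the
#' phosphate calibration
#' \deqn{SST = 118.7 - 4.22 (\delta^{18}O_{con} - \delta^{18}O_{sw})}
#' with both delta values in per mil. Printed calibration uncertainties
#' (intercept 118.7 +/- 4.9 degC, slope 4.22 +/- 0.20 degC per mil) are
#' propagated separately by \code{\link{linear_sst_mc}}.
#'
#' @param d18o_con Conodont apatite delta-18-O, per mil VSMOW.
#' @param d18o_sw Seawater delta-18-O, per mil VSMOW (see
#'   \code{\link{seawater_d18o}}).
#' @return SST in degrees Celsius (vectorised).
#' @examples
#' conodont_sst(18.7, -1)   # 35.566
#' @export
conodont_sst <- function(d18o_con, d18o_sw) {
  118.7 - 4.22 * (d18o_con - d18o_sw)
}

#' Linear calibration parameters with Gaussian uncertainty
#'
#' Container for a linear proxy-to-SST calibration
#' \code{SST = intercept + slope * value}, each coefficient carrying a
#' standard deviation used in Monte Carlo propagation. The conodont
#' thermometer corresponds to intercept 118.7 (sd 4.9), slope -4.22 (sd 0.20)
#' applied to \code{value = d18o_con - d18o_sw}. Central tendencies of
#' Bayesian carbonate (BAYFOX-type) or TEX86 (BAYSPAR-type) calibrations can
#' be emulated by supplying the matching coefficients.
#'
#' @param intercept Intercept, degC.
#' @param slope Slope, degC per proxy unit.
#' @param intercept_sd,slope_sd Standard deviations (>= 0).
#' @param d18o_sw Optional seawater delta-18-O carried with the calibration,
#'   per mil VSMOW.
#' @return A list of class \code{calibration_params}.
#' @export
calibration_params <- function(intercept, slope, intercept_sd = 0, slope_sd = 0,
                               d18o_sw = NA_real_) {
  stopifnot(intercept_sd >= 0, slope_sd >= 0)
  structure(list(intercept = intercept, slope = slope,
                 intercept_sd = intercept_sd, slope_sd = slope_sd,
                 d18o_sw = d18o_sw),
            class = "calibration_params")
}

#' Conodont calibration with published parameter uncertainties
#' @return A \code{\link{calibration_params}} object for
#'   \code{value = d18o_con - d18o_sw}.
#' @export
conodont_calibration <- function() {
  calibration_params(intercept = 118.7, slope = -4.22,
                     intercept_sd = 4.9, slope_sd = 0.20)
}

#' Monte Carlo SST from a linear calibration
#'
#' Draws intercept and slope independently from normal distributions with the
#' calibration's means and standard deviations, evaluates the calibration for
#' each draw, and summarises the resulting SST distribution. This propagates
#' calibration-parameter uncertainty into each temperature estimate; for a
#' linear Gaussian combination the Monte Carlo sd converges to
#' \code{sqrt(intercept_sd^2 + (slope_sd * value)^2)}.
#'
#' @param value Proxy value on the calibration's input scale (e.g.
#'   \code{d18o_con - d18o_sw} in per mil, or a TEX86 value).
#' @param params A \code{\link{calibration_params}} object.
#' @param n Number of draws (>= 2).
#' @param seed Optional integer seed.
#' @return A list of class \code{sst_estimate} with \code{mean_sst},
#'   \code{sd_sst} (degC) and \code{n_draws}.
#' @export
linear_sst_mc <- function(value, params, n = 10000L, seed = NULL) {
  stopifnot(inherits(params, "calibration_params"), length(value) == 1L)
  if (n < 2) stop("n must be >= 2 (sd undefined for fewer draws)")
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rnorm(n, params$intercept, params$intercept_sd)
  b <- stats::rnorm(n, params$slope, params$slope_sd)
  sst <- a + b * value
  structure(list(mean_sst = mean(sst), sd_sst = stats::sd(sst),
                 n_draws = as.integer(n)),
            class = "sst_estimate")
}

#' Seawater delta-18-O for a time bin
#'
#' Ice-volume convention: -1 per mil (VSMOW) for ice-free intervals and
#' +1 per mil during glacial-maximum intervals (e.g. the Pennsylvanian
#' Glacial Maximum). Explicit per-bin overrides take precedence.
#'
#' @param bin_id Bin code (must be present in \code{bins}).
#' @param ice_state Named character vector mapping bin_id to
#'   \code{"ice_free"} or \code{"glacial_maximum"}; unlisted bins default to
#'   ice-free.
#' @param overrides Optional named numeric vector of per-bin values, per mil.
#' @param bins A \code{time_bins} scheme (default: packaged scheme).
#' @return Seawater delta-18-O, per mil VSMOW.
#' @export
seawater_d18o <- function(bin_id, ice_state = character(),
                          overrides = numeric(), bins = load_bin_scheme()) {
  if (!bin_id %in% bins$bin_id) stop("unknown bin_id: ", bin_id)
  if (bin_id %in% names(overrides)) return(unname(overrides[[bin_id]]))
  state <- if (bin_id %in% names(ice_state)) ice_state[[bin_id]] else "ice_free"
  switch(state,
         ice_free = -1,
         glacial_maximum = 1,
         stop("unknown ice_state: ", state))
}

#' GDGT composition
#'
#' Relative abundances of the isoprenoid GDGTs (GDGT-0 to GDGT-3,
#' crenarchaeol and its regioisomer) and the branched GDGTs (Ia, IIa, IIIa)
#' used by TEX86 and its screening indices. Abundances are non-negative and
#' need not be normalised: every index is a ratio and is invariant to overall
#' scale.
#'
#' @param gdgt0,gdgt1,gdgt2,gdgt3 Isoprenoid GDGT abundances.
#' @param cren Crenarchaeol abundance.
#' @param cren_prime Crenarchaeol regioisomer abundance.
#' @param br_Ia,br_IIa,br_IIIa Branched GDGT abundances.
#' @return A list of class \code{gdgt_composition}.
#' @export
gdgt_composition <- function(gdgt0 = 0, gdgt1 = 0, gdgt2 = 0, gdgt3 = 0,
                             cren = 0, cren_prime = 0,
                             br_Ia = 0, br_IIa = 0, br_IIIa = 0) {
  vals <- c(gdgt0, gdgt1, gdgt2, gdgt3, cren, cren_prime, br_Ia, br_IIa, br_IIIa)
  if (any(vals < 0)) stop("GDGT abundances must be non-negative")
  if (sum(gdgt0, gdgt1, gdgt2, gdgt3, cren, cren_prime) <= 0) {
    stop("at least one isoprenoid GDGT abundance must be positive")
  }
  structure(list(gdgt0 = gdgt0, gdgt1 = gdgt1, gdgt2 = gdgt2, gdgt3 = gdgt3,
                 cren = cren, cren_prime = cren_prime,
                 br_Ia = br_Ia, br_IIa = br_IIa, br_IIIa = br_IIIa),
            class = "gdgt_composition")
}

#' TEX86 from a GDGT composition
#'
#' \code{TEX86 = (GDGT-2 + GDGT-3 + cren') / (GDGT-1 + GDGT-2 + GDGT-3 + cren')}.
#'
#' @param g A \code{\link{gdgt_composition}}.
#' @return TEX86 value in [0, 1].
#' @export
tex86_from_gdgt <- function(g) {
  stopifnot(inherits(g, "gdgt_composition"))
  den <- g$gdgt1 + g$gdgt2 + g$gdgt3 + g$cren_prime
  if (den <= 0) stop("TEX86 undefined: GDGT-1 + GDGT-2 + GDGT-3 + cren' is zero")
  (g$gdgt2 + g$gdgt3 + g$cren_prime) / den
}

# Ring-index constants (abundance-weighted ring counts and the published
# quadratic in TEX86); overridable via the thresholds config.
.default_ri_tex_coef <- c(a = -0.77, b = 3.32, c = 1.59)

#' GDGT quality-control indices
#'
#' Computes the screening indices used to flag TEX86 measurements compromised
#' by non-thermal overprints: BIT (terrestrial input), MI (methane cycling),
#' \%GDGT-0 (methanogen contribution), fCren' (regioisomer excess) and the
#' ring-index offset dRI = |RI_sample - RI_TEX|, where RI_sample is the
#' abundance-weighted mean ring count of the isoprenoid GDGTs and RI_TEX the
#' published quadratic in TEX86.
#'
#' An index whose denominator is zero is reported as \code{NA} (undefined) and
#' its screening rule is skipped.
#'
#' @param g A \code{\link{gdgt_composition}}.
#' @param tex Optional TEX86 value; computed from \code{g} when possible.
#' @param ri_tex_coef Quadratic coefficients (a, b, c) of
#'   \code{RI_TEX = a*TEX86 + b*TEX86^2 + c}.
#' @return A list with \code{bit}, \code{mi}, \code{pct_gdgt0}, \code{f_cren},
#'   \code{ri_sample}, \code{ri_tex}, \code{delta_ri}.
#' @export
compute_qc_indices <- function(g, tex = NULL, ri_tex_coef = .default_ri_tex_coef) {
  stopifnot(inherits(g, "gdgt_composition"))
  br <- g$br_Ia + g$br_IIa + g$br_IIIa
  bit <- if (br + g$cren > 0) br / (br + g$cren) else NA_real_
  mi_den <- g$gdgt1 + g$gdgt2 + g$gdgt3 + g$cren + g$cren_prime
  mi <- if (mi_den > 0) (g$gdgt1 + g$gdgt2 + g$gdgt3) / mi_den else NA_real_
  pct_gdgt0 <- if (g$gdgt0 + g$cren > 0) 100 * g$gdgt0 / (g$gdgt0 + g$cren) else NA_real_
  f_cren <- if (g$cren_prime + g$cren > 0) g$cren_prime / (g$cren_prime + g$cren) else NA_real_
  iso <- g$gdgt0 + g$gdgt1 + g$gdgt2 + g$gdgt3 + g$cren + g$cren_prime
  ri_sample <- if (iso > 0) {
    (0 * g$gdgt0 + 1 * g$gdgt1 + 2 * g$gdgt2 + 3 * g$gdgt3 +
       4 * g$cren + 4 * g$cren_prime) / iso
  } else NA_real_
  if (is.null(tex)) {
    tex <- tryCatch(tex86_from_gdgt(g), error = function(e) NA_real_)
  }
  ri_tex <- if (is.na(tex)) NA_real_ else {
    ri_tex_coef[["a"]] * tex + ri_tex_coef[["b"]] * tex^2 + ri_tex_coef[["c"]]
  }
  delta_ri <- if (is.na(ri_sample) || is.na(ri_tex)) NA_real_ else abs(ri_sample - ri_tex)
  list(bit = bit, mi = mi, pct_gdgt0 = pct_gdgt0, f_cren = f_cren,
       ri_sample = ri_sample, ri_tex = ri_tex, delta_ri = delta_ri, tex86 = tex)
}

#' Default screening thresholds
#'
#' Cut-offs applied by \code{\link{screen_measurement}}: carbonate diagenesis
#' on trace elements (Mn > 250 ppm together with Sr < 400 ppm), GDGT indices
#' (BIT > 0.4, MI > 0.5, dRI > 0.3, \%GDGT-0 > 67, fCren' > 0.25) and the
#' tropical/subtropical latitude window (|paleolatitude| > 40 deg). All rules
#' use strict inequalities: a value exactly at the cut-off is retained.
#'
#' @return Named list of thresholds and switches.
#' @export
default_thresholds <- function() {
  list(mn_ppm = 250, sr_ppm = 400,
       bit = 0.4, mi = 0.5, delta_ri = 0.3, pct_gdgt0 = 67, f_cren = 0.25,
       abs_paleolat = 40,
       mn_sr_conjunction = TRUE,  # reject on (Mn > .) AND (Sr < .); FALSE = OR
       latitude_overrides = character())  # sample_ids exempt from the latitude rule
}

#' Build a proxy measurement
#'
#' @param sample_id Sample identifier.
#' @param bin_id Time-bin code.
#' @param proxy_kind One of \code{"carbonate_d18O"}, \code{"conodont_d18O"},
#'   \code{"tex86"}, \code{"generic_linear"}.
#' @param value Raw proxy value (per mil for isotopes; dimensionless TEX86).
#' @param paleolatitude Degrees, +N/-S.
#' @param age Optional \code{\link{age_constraint}}.
#' @param mn_ppm,sr_ppm Trace-element concentrations (carbonate only).
#' @param facies_flags Character vector from
#'   \code{c("evaporite", "upwelling", "deep_water")}.
#' @param gdgt Optional \code{\link{gdgt_composition}} (TEX86 only).
#' @return A list of class \code{proxy_measurement}.
#' @export
proxy_measurement <- function(sample_id, bin_id, proxy_kind, value = NA_real_,
                              paleolatitude = 0, age = NULL,
                              mn_ppm = NA_real_, sr_ppm = NA_real_,
                              facies_flags = character(), gdgt = NULL) {
  proxy_kind <- match.arg(proxy_kind,
                          c("carbonate_d18O", "conodont_d18O", "tex86", "generic_linear"))
  if (abs(paleolatitude) > 90) stop("paleolatitude must lie in [-90, 90]")
  bad_flags <- setdiff(facies_flags, c("evaporite", "upwelling", "deep_water"))
  if (length(bad_flags) > 0L) stop("unknown facies flag(s): ", paste(bad_flags, collapse = ", "))
  structure(list(sample_id = sample_id, bin_id = bin_id, proxy_kind = proxy_kind,
                 value = value, paleolatitude = paleolatitude, age = age,
                 mn_ppm = mn_ppm, sr_ppm = sr_ppm,
                 facies_flags = facies_flags, gdgt = gdgt),
            class = "proxy_measurement")
}

#' Screen a proxy measurement
#'
#' Applies every screening rule relevant to the measurement's proxy kind and
#' reports which (if any) fired. Carbonate trace-element rules apply only to
#' carbonate measurements; GDGT index rules only to TEX86 measurements;
#' abnormal-salinity facies (evaporite, upwelling) and the latitude window
#' apply to all. The \code{deep_water} flag is carried through untouched (it
#' matters to extinction-rate sensitivity checks, not to SST). Rules with
#' missing inputs are skipped and listed in \code{skipped}.
#'
#' @param m A \code{\link{proxy_measurement}}.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return A list of class \code{qc_report}: \code{retained},
#'   \code{reject_reasons}, \code{skipped}, \code{indices} (GDGT indices or
#'   \code{NULL}).
#' @export
screen_measurement <- function(m, thresholds = default_thresholds()) {
  stopifnot(inherits(m, "proxy_measurement"))
  th <- utils::modifyList(default_thresholds(), thresholds)
  reasons <- character()
  skipped <- character()
  indices <- NULL

  if ("evaporite" %in% m$facies_flags || "upwelling" %in% m$facies_flags) {
    reasons <- c(reasons, "abnormal_salinity")
  }
  if (is.na(m$paleolatitude)) {
    skipped <- c(skipped, "latitude")
  } else if (abs(m$paleolatitude) > th$abs_paleolat &&
             !(m$sample_id %in% th$latitude_overrides)) {
    reasons <- c(reasons, "extratropical")
  }

  if (m$proxy_kind %in% c("carbonate_d18O")) {
    if (is.na(m$mn_ppm) || is.na(m$sr_ppm)) {
      skipped <- c(skipped, "diagenesis")
    } else {
      mn_hit <- m$mn_ppm > th$mn_ppm
      sr_hit <- m$sr_ppm < th$sr_ppm
      fired <- if (isTRUE(th$mn_sr_conjunction)) mn_hit && sr_hit else mn_hit || sr_hit
      if (fired) reasons <- c(reasons, "diagenesis")
    }
  }

  if (m$proxy_kind == "tex86") {
    if (is.null(m$gdgt)) {
      skipped <- c(skipped, "gdgt_indices")
    } else {
      indices <- compute_qc_indices(m$gdgt)
      rule <- function(idx, cutoff, name, gt = TRUE) {
        if (is.na(idx)) { skipped <<- c(skipped, name); return() }
        hit <- if (gt) idx > cutoff else idx < cutoff
        if (hit) reasons <<- c(reasons, name)
      }
      rule(indices$bit,       th$bit,       "terrestrial_input")
      rule(indices$mi,        th$mi,        "methane_index")
      rule(indices$delta_ri,  th$delta_ri,  "ring_index")
      rule(indices$pct_gdgt0, th$pct_gdgt0, "gdgt0_excess")
      rule(indices$f_cren,    th$f_cren,    "cren_isomer_excess")
    }
  }

  structure(list(retained = length(reasons) == 0L,
                 reject_reasons = unique(reasons),
                 skipped = unique(skipped),
                 indices = indices,
                 sample_id = m$sample_id),
            class = "qc_report")
}

#' Sampling-resolution check for a time bin
#'
#' A bin's temperature series is usable only if its measurement density is at
#' least 2 per Myr; low-resolution bins cannot resolve the largest excursion
#' and are excluded.
#'
#' @param n_measurements Number of retained measurements in the bin (or a
#'   data.frame of measurements, in which case its row count is used).
#' @param bin A single-row slice of a \code{time_bins} scheme (or a list with
#'   \code{t_old} and \code{t_young}).
#' @param min_density Minimum measurements per Myr (default 2).
#' @return List with \code{pass} (logical) and \code{density} (per Myr).
#' @export
resolution_check <- function(n_measurements, bin, min_density = 2) {
  if (is.data.frame(n_measurements)) n_measurements <- nrow(n_measurements)
  duration <- bin$t_old - bin$t_young
  stopifnot(duration > 0)
  density <- n_measurements / duration
  list(pass = density >= min_density, density = density)
}
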