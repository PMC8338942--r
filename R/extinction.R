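#' Read genus-level fossil occurrence records
#'
#' Accepts either a Paleobiology-Database-style download (columns
#' \code{accepted_name} or \code{genus}, \code{class}, \code{phylum},
#' \code{environment}, and an explicit \code{bin_id} assignment column) or
#' the simplified 4-column dialect \code{genus, group, bin_id, environment}.
#' Genus names carrying open-nomenclature qualifiers (\code{aff.},
#' \code{cf.}, \code{?}, quotes) are dropped; rows lacking a bin assignment
#' are flagged and dropped with a count.
#'
#' @param path CSV path or a data.frame.
#' @return A data.frame with columns \code{genus}, \code{higher_taxa}
#'   (semicolon-joined), \code{bin_id}, \code{environment}; attributes
#'   \code{n_dropped_qualified} and \code{n_dropped_unbinned}.
#' @export
read_occurrences <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  genus <- if ("genus" %in% nm) df$genus else if ("accepted_name" %in% nm) {
    vapply(strsplit(as.character(df$accepted_name), "\\s+"), `[`, character(1), 1L)
  } else stop("occurrence table needs a 'genus' or 'accepted_name' column")
  higher <- if ("group" %in% nm) as.character(df$group) else {
    cls <- if ("class" %in% nm) as.character(df$class) else ""
    phy <- if ("phylum" %in% nm) as.character(df$phylum) else ""
    trimws(paste(cls, phy, sep = ";"))
  }
  if (!"bin_id" %in% nm) stop("occurrence table needs an explicit 'bin_id' column")
  env <- if ("environment" %in% nm) as.character(df$environment) else "unknown"
  env[!env %in% c("shallow", "deep")] <- "unknown"
  out <- data.frame(genus = as.character(genus), higher_taxa = higher,
                    bin_id = as.character(df$bin_id), environment = env,
                    stringsAsFactors = FALSE)
  qualified <- is.na(out$genus) | out$genus == "" |
    grepl('aff\\.|cf\\.|\\?|"', out$genus)
  unbinned <- is.na(out$bin_id) | out$bin_id == ""
  attr_q <- sum(qualified)
  attr_u <- sum(unbinned & !qualified)
  out <- out[!qualified & !unbinned, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_qualified") <- attr_q
  attr(out, "n_dropped_unbinned") <- attr_u
  out
}

#' Filter occurrence records before rate estimation
#'
#' Removes records belonging to the excluded higher taxa (by default
#' Arachnida, Insecta, Ostracoda and Tetrapoda — largely terrestrial groups
#' that nonetheless appear in marine strata), records with empty genus
#' names, and optionally deep-water records (for the sensitivity analysis
#' that checks the climate-extinction correlation without deep-water
#' faunas).
#'
#' @param records Occurrence data.frame (see \code{\link{read_occurrences}}).
#' @param excluded_taxa Character vector of higher-taxon names to drop.
#' @param drop_deep_water Drop records with \code{environment == "deep"}.
#' @return Filtered records; attribute \code{removal_counts} logs how many
#'   rows each filter removed.
#' @export
filter_occurrences <- function(records,
                               excluded_taxa = c("Arachnida", "Insecta",
                                                 "Ostracoda", "Tetrapoda"),
                               drop_deep_water = FALSE) {
  stopifnot(is.data.frame(records))
  n0 <- nrow(records)
  empty <- is.na(records$genus) | records$genus == ""
  records <- records[!empty, , drop = FALSE]
  taxa_list <- strsplit(records$higher_taxa, ";")
  hit <- vapply(taxa_list, function(tx) any(trimws(tx) %in% excluded_taxa), logical(1))
  n_taxa <- sum(hit)
  records <- records[!hit, , drop = FALSE]
  n_deep <- 0L
  if (drop_deep_water) {
    deep <- records$environment == "deep"
    n_deep <- sum(deep)
    records <- records[!deep, , drop = FALSE]
  }
  rownames(records) <- NULL
  attr(records, "removal_counts") <- c(empty_genus = sum(empty),
                                       excluded_taxa = n_taxa,
                                       deep_water = n_deep,
                                       kept = nrow(records), input = n0)
  records
}

#' Genus-by-bin presence matrix
#'
#' \code{presence[g, b]} is TRUE iff genus \code{g} has at least one
#' occurrence in bin \code{b}; duplicated records change nothing. Columns
#' follow the bin scheme's oldest-to-youngest order.
#'
#' @param records Filtered occurrence records.
#' @param bins A \code{time_bins} scheme.
#' @return Logical matrix, genera in rows (alphabetical), bins in columns.
#' @export
build_presence_matrix <- function(records, bins) {
  stopifnot(is.data.frame(records), inherits(bins, "time_bins"))
  unknown <- setdiff(unique(records$bin_id), bins$bin_id)
  if (length(unknown) > 0L) {
    bad <- which(records$bin_id %in% unknown)[1L]
    stop(sprintf("record %d (genus %s) has unknown bin_id '%s'",
                 bad, records$genus[bad], records$bin_id[bad]))
  }
  genera <- sort(unique(records$genus))
  m <- matrix(FALSE, nrow = length(genera), ncol = nrow(bins),
              dimnames = list(genera, bins$bin_id))
  if (nrow(records) > 0L) {
    m[cbind(match(records$genus, genera), match(records$bin_id, bins$bin_id))] <- TRUE
  }
  m
}

#' Cohort counts for one bin
#'
#' Counts the genus cohorts feeding the gap-filler and three-timer rate
#' formulas, for focal bin \code{i} (1-based, oldest first):
#' \itemize{
#'   \item two-timer \code{2T_i}: present in bins \code{i-1} and \code{i};
#'   \item three-timer \code{3T}: present in \code{i-1}, \code{i}, \code{i+1};
#'   \item part-timer \code{pT}: present in \code{i-1} and \code{i+1} but
#'     not \code{i};
#'   \item gap-filler \code{GF}: present in \code{i-1} and \code{i+2} but
#'     not \code{i+1} (by default regardless of presence in \code{i};
#'     \code{gf_condition_on_focal = TRUE} additionally requires absence in
#'     \code{i}).
#' }
#' Counts whose neighbour bins fall off the edge of the scheme are
#' \code{NA} (undefined), not zero.
#'
#' @param mat Logical presence matrix from
#'   \code{\link{build_presence_matrix}}.
#' @param i Focal bin index (1-based).
#' @param gf_condition_on_focal See above.
#' @return A list of class \code{cohort_counts} with \code{two_timer},
#'   \code{three_timer}, \code{part_timer}, \code{gap_filler}, \code{i}.
#' @export
count_cohorts <- function(mat, i, gf_condition_on_focal = FALSE) {
  stopifnot(is.matrix(mat), is.logical(mat))
  nb <- ncol(mat)
  stopifnot(i >= 1L, i <= nb)
  two <- if (i >= 2L) sum(mat[, i - 1L] & mat[, i]) else NA_integer_
  three <- if (i >= 2L && i + 1L <= nb) {
    sum(mat[, i - 1L] & mat[, i] & mat[, i + 1L])
  } else NA_integer_
  part <- if (i >= 2L && i + 1L <= nb) {
    sum(mat[, i - 1L] & !mat[, i] & mat[, i + 1L])
  } else NA_integer_
  gf <- if (i >= 2L && i + 2L <= nb) {
    sel <- mat[, i - 1L] & mat[, i + 2L] & !mat[, i + 1L]
    if (gf_condition_on_focal) sel <- sel & !mat[, i]
    sum(sel)
  } else NA_integer_
  structure(list(i = i, two_timer = two, three_timer = three,
                 part_timer = part, gap_filler = gf),
            class = "cohort_counts")
}

#' Gap-filler extinction rate
#'
#' \deqn{r_{GF} = \log\left(\frac{2T + pT}{3T + pT + GF}\right)}
#' with natural logarithm. The gap-filler correction makes the estimator
#' robust to poor sampling. Negative values (possible when GF is large) are
#' reported as-is and flagged; \code{clamp_zero = TRUE} floors them at 0.
#'
#' @param counts A \code{\link{count_cohorts}} result.
#' @param clamp_zero Floor negative rates at zero.
#' @return A list with \code{rate}, \code{defined}, \code{negative}.
#' @export
gf_rate <- function(counts, clamp_zero = FALSE) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (anyNA(c(counts$two_timer, counts$three_timer, counts$part_timer,
              counts$gap_filler))) {
    return(list(rate = NA_real_, defined = FALSE, negative = NA))
  }
  num <- counts$two_timer + counts$part_timer
  den <- counts$three_timer + counts$part_timer + counts$gap_filler
  if (num <= 0 || den <= 0) {
    return(list(rate = NA_real_, defined = FALSE, negative = NA))
  }
  r <- log(num / den)
  neg <- r < 0
  if (clamp_zero && neg) r <- 0
  list(rate = r, defined = TRUE, negative = neg)
}

#' Three-timer extinction rate
#'
#' \deqn{r_{3T} = \log\left(\frac{2T_i}{3T}\right) +
#'       \log\left(\frac{3T}{3T + pT}\right)}
#' with natural logarithm; the second term is the part-timer sampling
#' correction. Algebraically this equals \code{log(2T_i) - log(3T + pT)};
#' both forms are computed and must agree to machine precision.
#'
#' @param counts A \code{\link{count_cohorts}} result.
#' @return A list with \code{rate}, \code{defined}, \code{negative}.
#' @export
tt_rate <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (anyNA(c(counts$two_timer, counts$three_timer, counts$part_timer))) {
    return(list(rate = NA_real_, defined = FALSE, negative = NA))
  }
  if (counts$three_timer <= 0 || counts$two_timer <= 0) {
    return(list(rate = NA_real_, defined = FALSE, negative = NA))
  }
  r1 <- log(counts$two_timer / counts$three_timer) +
    log(counts$three_timer / (counts$three_timer + counts$part_timer))
  r2 <- log(counts$two_timer) - log(counts$three_timer + counts$part_timer)
  stopifnot(isTRUE(all.equal(r1, r2, tolerance = 1e-12)))
  list(rate = r1, defined = TRUE, negative = r1 < 0)
}

#' Per-bin extinction rates for a whole scheme
#'
#' @param records Filtered occurrence records.
#' @param bins A \code{time_bins} scheme.
#' @param gf_condition_on_focal,clamp_zero Passed through.
#' @return Data.frame with one row per bin: \code{bin_id}, the four cohort
#'   counts, \code{r_gf}, \code{r_3t} and their defined flags.
#' @export
extinction_rates <- function(records, bins, gf_condition_on_focal = FALSE,
                             clamp_zero = FALSE) {
  m <- build_presence_matrix(records, bins)
  out <- lapply(seq_len(nrow(bins)), function(i) {
    cc <- count_cohorts(m, i, gf_condition_on_focal)
    g <- gf_rate(cc, clamp_zero)
    t3 <- tt_rate(cc)
    data.frame(bin_id = bins$bin_id[i],
               two_timer = cc$two_timer, three_timer = cc$three_timer,
               part_timer = cc$part_timer, gap_filler = cc$gap_filler,
               r_gf = g$rate, gf_defined = g$defined,
               r_3t = t3$rate, tt_defined = t3$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap standard deviations of the extinction rates
#'
#' Resamples occurrence records with replacement, rebuilds the presence
#' matrix, recounts cohorts and recomputes both rates for bin \code{i};
#' returns the standard deviation over draws. Draws where a rate is
#' undefined are dropped and counted. (The displayed error bars of the
#' source analysis state no procedure; record-level bootstrap is this
#' package's choice.)
#'
#' @param records Filtered occurrence records.
#' @param bins A \code{time_bins} scheme.
#' @param i Focal bin index.
#' @param n_boot Bootstrap draws (>= 2).
#' @param seed Optional integer seed.
#' @return List with \code{sd_gf}, \code{sd_3t}, \code{n_dropped_gf},
#'   \code{n_dropped_3t}.
#' @export
rate_uncertainty <- function(records, bins, i, n_boot = 200L, seed = NULL) {
  stopifnot(n_boot >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  r_gf_v <- numeric(n_boot)
  r_3t_v <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    res <- records[sample.int(n, n, replace = TRUE), , drop = FALSE]
    m <- build_presence_matrix(res, bins)
    cc <- count_cohorts(m, i)
    r_gf_v[b] <- gf_rate(cc)$rate
    r_3t_v[b] <- tt_rate(cc)$rate
  }
  list(sd_gf = if (sum(!is.na(r_gf_v)) >= 2L) stats::sd(r_gf_v, na.rm = TRUE) else NA_real_,
       sd_3t = if (sum(!is.na(r_3t_v)) >= 2L) stats::sd(r_3t_v, na.rm = TRUE) else NA_real_,
       n_dropped_gf = sum(is.na(r_gf_v)),
       n_dropped_3t = sum(is.na(r_3t_v)))
}
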