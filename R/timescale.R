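#' Load a stage-level time-bin scheme
#'
#' Reads and validates an ordered binning scheme of the Phanerozoic used to
#' partition proxy data and fossil occurrences. The packaged scheme
#' (\code{bins_gts2012.csv}) holds 45 bins from the Katian--Hirnantian
#' (\code{Or5}) to the Aquitanian--Burdigalian (\code{Ng1}), each defined by
#' one or several neighbouring geologic stages with boundary ages keyed to the
#' 2012 geologic time scale. The scheme is data, not code: any table obeying
#' the same invariants can be substituted.
#'
#' Ages are in Ma before present and decrease toward the present. Bins are
#' ordered oldest to youngest; membership of a point age follows the
#' half-open convention \code{t_old >= age > t_young}, except that an age
#' exactly on a shared boundary belongs to the older bin (see
#' \code{\link{assign_event_bin}}).
#'
#' @param table Path to a CSV with columns \code{bin_id}, \code{stages}
#'   (semicolon-separated stage names), \code{t_old_ma}, \code{t_young_ma};
#'   or a data.frame with those columns; or \code{NULL} (default) for the
#'   packaged 45-bin scheme.
#' @return A data.frame of class \code{time_bins} with columns \code{bin_id},
#'   \code{stages}, \code{t_old}, \code{t_young}, \code{duration} (Myr),
#'   ordered oldest first.
#' @examples
#' bins <- load_bin_scheme()
#' nrow(bins)            # 45
#' mean(bins$duration)   # ~9.71 Myr
#' @export
load_bin_scheme <- function(table = NULL) {
  if (is.null(table)) {
    table <- system.file("extdata", "bins_gts2012.csv", package = "thermext",
                         mustWork = TRUE)
  }
  if (is.character(table)) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  need <- c("bin_id", "stages", "t_old_ma", "t_young_ma")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop("bin scheme table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("bin scheme table is empty")
  bins <- data.frame(
    bin_id  = as.character(table$bin_id),
    stages  = as.character(table$stages),
    t_old   = as.numeric(table$t_old_ma),
    t_young = as.numeric(table$t_young_ma),
    stringsAsFactors = FALSE
  )
  if (anyNA(bins$t_old) || anyNA(bins$t_young)) stop("non-numeric boundary age in bin scheme")
  if (anyDuplicated(bins$bin_id)) stop("duplicated bin_id in scheme")
  bad <- which(!(bins$t_old > bins$t_young & bins$t_young > 0))
  if (length(bad) > 0L) {
    stop("bin(s) with non-decreasing or non-positive boundaries: ",
         paste(bins$bin_id[bad], collapse = ", "))
  }
  if (nrow(bins) > 1L) {
    for (i in seq_len(nrow(bins) - 1L)) {
      if (bins$t_young[i] < bins$t_old[i + 1L]) {
        stop(sprintf("bins overlap or are unordered: %s and %s",
                     bins$bin_id[i], bins$bin_id[i + 1L]))
      }
    }
  }
  bins$duration <- bins$t_old - bins$t_young
  class(bins) <- c("time_bins", "data.frame")
  bins
}

#' Build an age constraint
#'
#' An age constraint couples a best age with its bounds and the dating method
#' that produced it. Bounds follow the Ma-decreasing convention:
#' \code{lower} is the older (numerically larger) bound, \code{upper} the
#' younger one, so \code{lower >= best >= upper}.
#'
#' @param best_age Best age, Ma.
#' @param lower Older bound, Ma.
#' @param upper Younger bound, Ma.
#' @param method One of \code{"isotope-geochronology"}, \code{"astrochronology"},
#'   \code{"biostratigraphy"}.
#' @param position_note Free-text stratigraphic position (e.g. within a biozone).
#' @return A list of class \code{age_constraint}.
#' @export
age_constraint <- function(best_age, lower = best_age, upper = best_age,
                           method = c("isotope-geochronology", "astrochronology",
                                      "biostratigraphy"),
                           position_note = "") {
  method <- match.arg(method)
  stopifnot(is.numeric(best_age), is.numeric(lower), is.numeric(upper))
  if (!(lower >= best_age && best_age >= upper)) {
    stop("age constraint requires lower >= best_age >= upper (ages in Ma)")
  }
  structure(list(best_age = best_age, lower = lower, upper = upper,
                 method = method, position_note = position_note),
            class = "age_constraint")
}

.age_method_priority <- c("isotope-geochronology" = 1L,
                          "astrochronology"       = 2L,
                          "biostratigraphy"       = 3L)

#' Resolve competing age constraints
#'
#' Applies the dating-method priority order (isotope geochronology over
#' astrochronology over biostratigraphy). Ties within a priority level are
#' broken by the narrowest bound width.
#'
#' @param constraints A single \code{age_constraint} or a list of them.
#' @return The winning \code{age_constraint}.
#' @export
resolve_age <- function(constraints) {
  if (inherits(constraints, "age_constraint")) constraints <- list(constraints)
  if (!is.list(constraints) || length(constraints) == 0L) {
    stop("at least one age constraint required")
  }
  stopifnot(all(vapply(constraints, inherits, logical(1), "age_constraint")))
  pri <- vapply(constraints, function(a) .age_method_priority[[a$method]], integer(1))
  width <- vapply(constraints, function(a) a$lower - a$upper, numeric(1))
  best <- order(pri, width)[1L]
  constraints[[best]]
}

#' Draw ages from an age constraint
#'
#' Ages are drawn i.i.d. uniform on the constraint's bounds, reflecting a
#' uniform prior on position within the dated interval. A zero-width
#' constraint returns its point age for every draw.
#'
#' @param constraint An \code{age_constraint}.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of \code{n} ages in Ma.
#' @export
sample_ages <- function(constraint, n, seed = NULL) {
  stopifnot(inherits(constraint, "age_constraint"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (constraint$lower == constraint$upper) {
    return(rep(constraint$best_age, n))
  }
  stats::runif(n, min = constraint$upper, max = constraint$lower)
}

# bin index (1-based, oldest first) containing each age, boundary -> older bin.
# Returns NA for ages outside the scheme.
.bin_index_of_age <- function(age, bins) {
  idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(bins))) {
    hit <- if (b == 1L) {
      age <= bins$t_old[b] & age >= bins$t_young[b]
    } else {
      age < bins$t_old[b] & age >= bins$t_young[b]
    }
    idx[is.na(idx) & hit] <- b
  }
  idx
}
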