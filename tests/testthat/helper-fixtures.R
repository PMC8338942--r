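# shared fixtures and independent oracles used across test files

# a small contiguous 5-bin scheme for extinction tests
toy_bins <- function() {
  load_bin_scheme(data.frame(
    bin_id = c("B1", "B2", "B3", "B4", "B5"),
    stages = letters[1:5],
    t_old_ma = c(100, 90, 80, 70, 60),
    t_young_ma = c(90, 80, 70, 60, 50)
  ))
}

# independent cohort-count oracle: per-genus explicit set logic
oracle_cohorts <- function(m, i) {
  nb <- ncol(m)
  two <- three <- part <- gf <- NA_integer_
  if (i >= 2) {
    two <- 0L
    for (g in seq_len(nrow(m))) if (m[g, i - 1] && m[g, i]) two <- two + 1L
  }
  if (i >= 2 && i + 1 <= nb) {
    three <- part <- 0L
    for (g in seq_len(nrow(m))) {
      if (m[g, i - 1] && m[g, i] && m[g, i + 1]) three <- three + 1L
      if (m[g, i - 1] && !m[g, i] && m[g, i + 1]) part <- part + 1L
    }
  }
  if (i >= 2 && i + 2 <= nb) {
    gf <- 0L
    for (g in seq_len(nrow(m))) {
      if (m[g, i - 1] && m[g, i + 2] && !m[g, i + 1]) gf <- gf + 1L
    }
  }
  list(two_timer = two, three_timer = three, part_timer = part, gap_filler = gf)
}

# independent permutation generator (lexicographic successor algorithm),
# distinct from the recursive generator inside the package
next_perm <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

all_perms_lex <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    p <- next_perm(p)
    if (is.null(p)) break
    out[[length(out) + 1L]] <- p
  }
  out
}

# standard synthetic study: five extreme bins on the Big-Five time bins
# (magnitudes as compiled for those events) over a low-amplitude background
study_event_spec <- function(bins, seed = 99) {
  big5 <- c("Or5", "D4", "P5", "T5", "K8")
  evs <- data.frame(bin_id = big5,
                    magnitude = c(-8.4, -5.8, 10.4, 7.4, -6.2),
                    duration = c(0.35, 0.3, 0.2, 0.25, 0.3))
  set.seed(seed)
  other <- setdiff(bins$bin_id, big5)
  bg <- data.frame(bin_id = other,
                   magnitude = stats::runif(length(other), 1, 4) *
                     sample(c(-1, 1), length(other), TRUE),
                   duration = stats::runif(length(other), 1, 4))
  rbind(evs, bg)
}
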