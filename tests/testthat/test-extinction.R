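test_that("occurrence reader handles PBDB-style and simple dialects", {
  pbdb <- data.frame(
    accepted_name = c("Lingula sp.", "Atrypa reticularis", "cf. Spirifer",
                      "Productus x", ""),
    class = c("Lingulata", "Rhynchonellata", "Rhynchonellata", "Strophomenata",
              "Trilobita"),
    phylum = "Brachiopoda",
    bin_id = c("D4", "D4", "D5", "", "D5"),
    environment = c("shallow", "deep", "shallow", "shallow", "reef"),
    stringsAsFactors = FALSE)
  occ <- read_occurrences(pbdb)
  # cf.-qualified and empty genus dropped; unbinned dropped
  expect_identical(occ$genus, c("Lingula", "Atrypa"))
  expect_identical(attr(occ, "n_dropped_qualified"), 2L)
  expect_identical(attr(occ, "n_dropped_unbinned"), 1L)
  expect_identical(occ$environment, c("shallow", "deep"))

  simple <- data.frame(genus = "Atrypa", group = "Brachiopoda",
                       bin_id = "D4", environment = "shallow")
  expect_identical(read_occurrences(simple)$higher_taxa, "Brachiopoda")
  expect_error(read_occurrences(data.frame(x = 1)), "genus")
})

test_that("taxonomic and environmental filters remove the documented groups", {
  recs <- data.frame(
    genus = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
    higher_taxa = c("Brachiopoda", "Insecta", "Anthozoa", "Arachnida",
                    "Bivalvia", "Ostracoda;Crustacea", "Gastropoda",
                    "Tetrapoda", "Trilobita", "Cephalopoda"),
    bin_id = "B2",
    environment = c("shallow", "shallow", "deep", "shallow", "deep",
                    "shallow", "shallow", "shallow", "shallow", "unknown"),
    stringsAsFactors = FALSE)
  kept <- filter_occurrences(recs)
  expect_identical(nrow(kept), 6L)            # 4 excluded groups removed
  expect_false(any(c("B", "D", "F", "H") %in% kept$genus))
  # brachiopod kept when deep water retained
  expect_true("A" %in% kept$genus)
  both <- filter_occurrences(recs, drop_deep_water = TRUE)
  expect_identical(nrow(both), 4L)            # hand count: 10 - 4 - 2
  counts <- attr(both, "removal_counts")
  expect_identical(unname(counts["excluded_taxa"]), 4L)
  expect_identical(unname(counts["deep_water"]), 2L)
})

test_that("presence matrix is deterministic, idempotent, and validates bins", {
  bins <- toy_bins()
  recs <- data.frame(
    genus = c("a", "a", "b", "c", "d", "d"),
    higher_taxa = "X",
    bin_id = c("B1", "B2", "B2", "B3", "B1", "B5"),
    environment = "shallow", stringsAsFactors = FALSE)
  m <- build_presence_matrix(recs, bins)
  expect_identical(dim(m), c(4L, 5L))
  truth <- matrix(FALSE, 4, 5, dimnames = list(c("a", "b", "c", "d"),
                                               bins$bin_id))
  truth["a", c("B1", "B2")] <- TRUE
  truth["b", "B2"] <- TRUE
  truth["c", "B3"] <- TRUE
  truth["d", c("B1", "B5")] <- TRUE
  expect_identical(m, truth)
  # duplication changes nothing
  expect_identical(build_presence_matrix(rbind(recs, recs), bins), m)
  # empty input -> empty matrix
  expect_identical(nrow(build_presence_matrix(recs[0, ], bins)), 0L)
  bad <- recs; bad$bin_id[3] <- "Zz"
  expect_error(build_presence_matrix(bad, bins), "Zz")
})

test_that("cohort counts match exhaustive set enumeration on random matrices", {
  set.seed(42)
  for (rep in 1:60) {
    ng <- sample(1:30, 1)
    nb <- sample(4:10, 1)
    m <- matrix(runif(ng * nb) < runif(1, 0.2, 0.8), ng, nb,
                dimnames = list(paste0("g", 1:ng), paste0("b", 1:nb)))
    for (i in sample(nb, min(nb, 4))) {
      got <- count_cohorts(m, i)
      want <- oracle_cohorts(m, i)
      expect_identical(got$two_timer, want$two_timer)
      expect_identical(got$three_timer, want$three_timer)
      expect_identical(got$part_timer, want$part_timer)
      expect_identical(got$gap_filler, want$gap_filler)
    }
  }
  # documented membership patterns
  m <- matrix(c(TRUE, TRUE, TRUE, TRUE,    # ever-present genus
                TRUE, TRUE, FALSE, TRUE),  # present i-1, i; absent i+1; present i+2
              nrow = 2, byrow = TRUE)
  cc <- count_cohorts(m, 2)
  expect_identical(cc$two_timer, 2L)
  expect_identical(cc$three_timer, 1L)
  expect_identical(cc$part_timer, 0L)
  expect_identical(cc$gap_filler, 1L)
  # empty matrix: zero counts
  e <- count_cohorts(matrix(logical(0), 0, 5), 2)
  expect_identical(e$two_timer, 0L)
  expect_identical(e$gap_filler, 0L)
})

test_that("rate formulas evaluate exactly and agree with their algebraic forms", {
  cc <- function(two, three, part, gf) {
    structure(list(i = 2L, two_timer = two, three_timer = three,
                   part_timer = part, gap_filler = gf),
              class = "cohort_counts")
  }
  expect_equal(gf_rate(cc(10, 10, 0, 0))$rate, 0)
  expect_equal(gf_rate(cc(10, 8, 1, 1))$rate, log(11 / 10))
  expect_equal(tt_rate(cc(12, 8, 2, 0))$rate, log(1.5) + log(0.8))
  expect_equal(tt_rate(cc(10, 8, 2, 0))$rate, 0)       # 2T = 3T + pT cancels
  expect_equal(tt_rate(cc(10, 10, 0, 0))$rate, 0)
  # negative gap-filler rates are flagged, clamp available
  neg <- gf_rate(cc(5, 5, 0, 3))
  expect_true(neg$negative)
  expect_lt(neg$rate, 0)
  expect_identical(gf_rate(cc(5, 5, 0, 3), clamp_zero = TRUE)$rate, 0)
  # undefined cases flagged, not zero
  expect_false(gf_rate(cc(0, 0, 0, 0))$defined)
  expect_false(tt_rate(cc(5, 0, 2, 0))$defined)
  und <- count_cohorts(matrix(TRUE, 3, 5), 1)
  expect_false(gf_rate(und)$defined)
  expect_false(tt_rate(und)$defined)

  # end-to-end on random matrices: rates equal formulas applied to oracle
  # counts, and are invariant under genus relabelling
  set.seed(7)
  bins <- toy_bins()
  for (rep in 1:20) {
    ng <- sample(5:25, 1)
    pres <- matrix(runif(ng * 5) < 0.6, ng, 5)
    idx <- which(pres, arr.ind = TRUE)
    recs <- data.frame(genus = paste0("g", idx[, 1]), higher_taxa = "X",
                       bin_id = bins$bin_id[idx[, 2]], environment = "shallow",
                       stringsAsFactors = FALSE)
    r <- extinction_rates(recs, bins)
    m <- build_presence_matrix(recs, bins)
    for (i in 2:3) {
      o <- oracle_cohorts(m, i)
      want_gf <- if (o$two_timer + o$part_timer > 0 &&
                     o$three_timer + o$part_timer + o$gap_filler > 0) {
        log((o$two_timer + o$part_timer) /
              (o$three_timer + o$part_timer + o$gap_filler))
      } else NA_real_
      expect_equal(r$r_gf[i], want_gf)
    }
    # relabel genera: rates unchanged
    perm <- sample(ng)
    relab <- recs
    relab$genus <- paste0("h", perm[idx[, 1]])
    expect_equal(extinction_rates(relab, bins)$r_gf, r$r_gf)
    # duplicate every record: rates unchanged
    expect_equal(extinction_rates(rbind(recs, recs), bins)$r_gf, r$r_gf)
  }
})

test_that("estimators track the true extinction probability and localise spikes", {
  bins <- load_bin_scheme()
  pbins <- pad_bin_scheme(bins)
  # perfect sampling: mean gap-filler rate ~ -ln(1 - q)
  cfg <- synthetic_config(sampling_prob = 1, base_extinction_prob = 0.2,
                          n_genera = 400, seed = 11)
  vals <- vapply(1:6, function(s) {
    occ <- generate_occurrences(cfg, seed = s)
    r <- extinction_rates(occ$records, pbins)
    mean(r$r_gf[r$bin_id %in% bins$bin_id], na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(vals), -log(0.8), tolerance = 0.1)

  # monotone in q
  means_q <- vapply(c(0.1, 0.25, 0.4), function(q) {
    cfgq <- synthetic_config(sampling_prob = 1, base_extinction_prob = q,
                             n_genera = 300, seed = 21)
    occ <- generate_occurrences(cfgq, seed = 5)
    r <- extinction_rates(occ$records, pbins)
    mean(r$r_gf[r$bin_id %in% bins$bin_id], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means_q) > 0))

  # a spiked bin carries the peak of both estimators
  toy <- toy_bins()
  hits <- vapply(1:10, function(s) {
    cfgs <- synthetic_config(bins = toy, sampling_prob = 0.95,
                             base_extinction_prob = 0.1, n_genera = 500,
                             seed = s)
    occ <- generate_occurrences(cfgs, seed = s)
    # spike B3 by thinning survivors: emulate via coupling table instead
    cfgs2 <- synthetic_config(bins = toy, sampling_prob = 0.95,
                              base_extinction_prob = 0.1, n_genera = 500,
                              coupling = 2, seed = s,
                              events = data.frame(bin_id = "B3", magnitude = 9,
                                                  duration = 1))
    tr <- data.frame(bin_id = toy$bin_id,
                     delta_T = ifelse(toy$bin_id == "B3", 9, 0))
    occ2 <- generate_occurrences(cfgs2, tr, seed = s)
    r <- extinction_rates(occ2$records, pad_bin_scheme(toy))
    r <- r[r$bin_id %in% toy$bin_id, ]
    c(which.max(r$r_gf), which.max(r$r_3t))
  }, numeric(2))
  expect_gte(mean(hits[1, ] == 3), 0.8)
  expect_gte(mean(hits[2, ] == 3), 0.8)
})

test_that("bootstrap rate uncertainty is reproducible and shrinks with data", {
  bins <- toy_bins()
  set.seed(9)
  mk_recs <- function(mult) {
    ng <- 40 * mult
    pres <- matrix(runif(ng * 5) < 0.5, ng, 5)
    idx <- which(pres, arr.ind = TRUE)
    data.frame(genus = paste0("g", idx[, 1]), higher_taxa = "X",
               bin_id = bins$bin_id[idx[, 2]], environment = "shallow",
               stringsAsFactors = FALSE)
  }
  r1 <- mk_recs(1); r4 <- mk_recs(4); r16 <- mk_recs(16)
  u1 <- rate_uncertainty(r1, bins, 3, n_boot = 80, seed = 1)
  u4 <- rate_uncertainty(r4, bins, 3, n_boot = 80, seed = 1)
  u16 <- rate_uncertainty(r16, bins, 3, n_boot = 80, seed = 1)
  expect_true(u1$sd_gf > u4$sd_gf && u4$sd_gf > u16$sd_gf)
  expect_gte(u1$sd_gf, 0)
  again <- rate_uncertainty(r4, bins, 3, n_boot = 80, seed = 1)
  expect_identical(u4$sd_gf, again$sd_gf)
  expect_identical(u4$sd_3t, again$sd_3t)
  # single-genus matrix: sd zero or undefined, never negative
  solo <- data.frame(genus = "only", higher_taxa = "X",
                     bin_id = c("B2", "B3", "B4"), environment = "shallow",
                     stringsAsFactors = FALSE)
  us <- rate_uncertainty(solo, bins, 3, n_boot = 50, seed = 2)
  expect_true(is.na(us$sd_gf) || us$sd_gf >= 0)
})
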