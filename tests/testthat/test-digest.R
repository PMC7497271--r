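test_that("site finding matches a naive scan, including overlapping motifs", {
  expect_length(find_sites("AAAATTTT", "BglII"), 0)
  tpl <- rdna_templates(seed = 2)
  expect_equal(find_sites(tpl$S, "BglII"), c(3850L, 5185L))
  # overlapping-motif stress: ACGCGT inside ACGCGCGT-like runs
  stress <- "ACGCGCGTACGCGTACGCGT"
  motif <- "ACGCGT"
  naive <- which(vapply(1:(nchar(stress) - 5), function(i)
    substr(stress, i, i + 5) == motif, TRUE))
  expect_equal(find_sites(stress, "MluI"), naive)
  # self-overlapping motif handled by the lookahead scan
  run <- strrep("AGA", 6)
  enzyme_aga <- list(name = "x", motif = "AGAAGA", meth_rule = "insensitive")
  naive2 <- which(vapply(1:(nchar(run) - 5), function(i)
    substr(run, i, i + 5) == "AGAAGA", TRUE))
  expect_equal(find_sites(run, enzyme_aga), naive2)
})

test_that("tandem digestion computes inter-site and junction fragments", {
  # S-unit BglII arithmetic: 5185 - 3850 = 1335 and 9215 - 1335 = 7880
  pat <- digest_tandem(9215, c(3850, 5185), n_units = 12)
  expect_equal(pat$length, c(1335L, 7880L))
  expect_equal(pat$count, c(12L, 12L))
  expect_equal(sum(pat$length * pat$count), 12 * 9215)
  # D-unit BglII: 1335 bp and 6749 bp (the 1.3-kb / 6.7-kb bands)
  patD <- digest_tandem(8084, c(3850, 5185), n_units = 1)
  expect_equal(patD$length, c(1335L, 6749L))
  # single site: one fragment class of the full unit length
  one <- digest_tandem(5000, 1200, n_units = 8)
  expect_equal(one$length, 5000L)
  expect_equal(one$count, 8L)
  # no sites: a single uncut high-molecular-weight class
  zero <- digest_tandem(5000, integer(0), n_units = 8)
  expect_equal(zero$class, "uncut_high_MW")
  expect_equal(zero$length, 40000L)
  expect_error(digest_tandem(5000, 6000), "within")
})

test_that("methylation-sensitivity rules follow each enzyme's logic", {
  sites <- 1:20
  # BglII: insensitive, cuts even at full methylation
  expect_true(all(apply_methylation(sites, "BglII", 1, seed = 1)))
  # PstI (CTGCAG, Cs at motif positions 1 and 5): blocked by either C
  flags_first_only <- cbind(rep(TRUE, 3), rep(FALSE, 3))
  expect_false(any(apply_methylation(1:3, "PstI", flags_first_only)))
  flags_none <- cbind(rep(FALSE, 3), rep(FALSE, 3))
  expect_true(all(apply_methylation(1:3, "PstI", flags_none)))
  # XhoI (CTCGAG, Cs at 1 and 3): only the second C (position 3) blocks
  flags_nondesignated <- cbind(rep(TRUE, 3), rep(FALSE, 3))
  expect_true(all(apply_methylation(1:3, "XhoI", flags_nondesignated)))
  flags_designated <- cbind(rep(FALSE, 3), rep(TRUE, 3))
  expect_false(any(apply_methylation(1:3, "XhoI", flags_designated)))
  # stochastic mode is seeded
  expect_identical(apply_methylation(sites, "PstI", 0.5, seed = 9),
                   apply_methylation(sites, "PstI", 0.5, seed = 9))
})

test_that("increasing methylation never cuts more sites (common random numbers)", {
  sites <- 1:500
  cuts <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(m) {
    # common uniforms across m: same seed, threshold comparison
    sum(apply_methylation(sites, "XhoI", m, seed = 4))
  }, 0)
  expect_true(all(diff(cuts) <= 0))
})

test_that("single-site methylated arrays follow the geometric fragment law", {
  unit <- small_unit(seed = 101,
                     site_plan = data.frame(enzyme = "XhoI", start = 400L))
  L <- unit$length
  m <- 0.5                      # XhoI block probability b = m = 0.5
  fd <- fragment_distribution(unit, "XhoI", m, n_units = 150,
                              n_simulations = 60, seed = 5)
  expect_equal(fd$block_prob, 0.5)
  expect_equal(fd$sites_per_unit, 1L)
  # conservation per simulated array holds in aggregate
  total <- sum(fd$simulated$length * fd$simulated$count)
  expect_equal(total, 150 * L * 60)
  n_frag <- sum(fd$simulated$count[!is.na(fd$simulated$freq)])
  for (k in 1:4) {
    p <- (1 - 0.5) * 0.5^(k - 1)
    obs <- fd$simulated$freq[fd$simulated$length == k * L]
    if (length(obs) == 0) obs <- 0
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_frag))
  }
  # frequency of the 2L class near b(1-b) = 0.25
  expect_equal(fd$simulated$freq[fd$simulated$length == 2 * L], 0.25,
               tolerance = 0.05)
  # degenerate ends: b = 0 all unit-length, b = 1 all uncut
  fd0 <- fragment_distribution(unit, "XhoI", 0, n_units = 20,
                               n_simulations = 3, seed = 6)
  expect_equal(fd0$simulated$length, L)
  fd1 <- fragment_distribution(unit, "XhoI", 1, n_units = 20,
                               n_simulations = 3, seed = 7)
  expect_equal(fd1$simulated$length, 20 * L)
})

test_that("geometric-law goodness of fit passes a chi-square test", {
  unit <- small_unit(seed = 102,
                     site_plan = data.frame(enzyme = "XhoI", start = 400L))
  fd <- fragment_distribution(unit, "XhoI", 0.4, n_units = 120,
                              n_simulations = 60, seed = 11)
  sim <- fd$simulated[!is.na(fd$simulated$freq), ]
  k <- sim$length / unit$length
  keep <- k <= 5
  counts <- c(sim$count[keep], sum(sim$count[!keep]))
  b <- 0.4
  probs <- c((1 - b) * b^(0:4), b^5)
  p <- suppressWarnings(chisq.test(counts, p = probs)$p.value)
  expect_gt(p, 0.001)
})

test_that("CAPS band prediction reproduces the diagnostic lane counts", {
  tpl <- rdna_templates(seed = 3)
  its1 <- c(D = substr(tpl$D$sequence, 1811, 2040),
            S = substr(tpl$S$sequence, 1811, 2040))
  expect_length(find_sites(its1[["D"]], "MluI"), 1)
  expect_length(find_sites(its1[["S"]], "MluI"), 0)
  caps <- caps_predict(its1, "MluI", expressed = "D")
  # both homoeologues in the genomic lane: 3 bands; D-only cDNA lane: 2
  expect_equal(caps$n_bands_gdna, 3)
  expect_equal(caps$n_bands_cdna, 2)
  # per-amplicon length conservation
  expect_equal(sum(caps$per_amplicon$D), nchar(its1[["D"]]))
  expect_equal(sum(caps$per_amplicon$S), nchar(its1[["S"]]))
  # amplicons without sites: one band each, at amplicon length
  no_site <- c(A = random_read(300), B = random_read(200))
  expect_equal(caps_predict(no_site, "MluI")$per_amplicon,
               list(A = 300L, B = 200L))
})
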