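test_that("diagnostic window selection maximizes divergence (brute-force check)", {
  set.seed(81)
  d <- random_read(230)
  # plant 5 differences inside one 50-bp stretch
  s_chars <- strsplit(d, "")[[1]]
  pos <- 100 + c(3, 12, 25, 38, 49)
  for (p in pos) s_chars[p] <- setdiff(c("A", "C", "G", "T"), s_chars[p])[1]
  s <- paste(s_chars, collapse = "")
  w <- select_diagnostic_window(d, s, width = 50)
  expect_equal(w$divergence, 0.10)
  expect_equal(hamming(w$d_consensus, w$s_consensus), 5)
  # exhaustive scan oracle
  divs <- vapply(1:(230 - 49), function(i)
    hamming(substr(d, i, i + 49), substr(s, i, i + 49)), 0)
  expect_equal(w$divergence, max(divs) / 50)
  expect_equal(w$start, which.max(divs))
  # identical inputs: zero divergence with a warning
  expect_warning(w0 <- select_diagnostic_window(d, d), "identical")
  expect_equal(w0$divergence, 0)
  expect_true(w0$identical_flag)
  expect_error(select_diagnostic_window("ACGT", "ACGA", width = 50), "shorter")
})

test_that("fragment recruitment is sensitive and specific on labelled reads", {
  set.seed(82)
  win <- window_pair(seed = 82, n_diff = 5)
  # reads fully containing the D window at a random offset
  n <- 80
  embed <- function(core) paste0(random_read(sample(5:30, 1)), core,
                                 random_read(sample(5:30, 1)))
  seqs <- c(vapply(1:n, function(i) embed(win$d_consensus), ""),
            vapply(1:20, function(i) random_read(100), ""))
  reads <- read_set(paste0("r", seq_along(seqs)), seqs,
                    vapply(nchar(seqs), function(k) qual_for(0.001, k), ""),
                    truth = c(rep("D", n), rep("background", 20)))
  got <- recruit_fragments(reads, win)
  # >= 99% sensitivity on error-free reads containing the window
  expect_gte(sum(got$truth == "D"), ceiling(0.99 * n))
  expect_true(all(got$fragment[got$truth == "D"] == win$d_consensus))
  # reads with no 50-nt homologous stretch are not recruited
  expect_equal(sum(got$truth == "background"), 0)
  # reads with an ambiguous base are discarded
  rN <- read_set("n1", paste0("N", win$d_consensus), qual_for(0.001, 51))
  expect_equal(nrow(recruit_fragments(rN, win)), 0)
})

test_that("fragment subsampling is seeded, exact and hypergeometric", {
  frags <- structure(
    data.frame(read_id = paste0("f", 1:200),
               fragment = rep(c("AAAA", "TTTT"), c(120, 80)),
               truth = rep(c("D", "S"), c(120, 80)),
               stringsAsFactors = FALSE),
    class = c("fragment_sample", "data.frame"))
  all_of_them <- sample_fragments(frags, 200, seed = 1)
  expect_setequal(all_of_them$read_id, frags$read_id)
  s1 <- sample_fragments(frags, 60, seed = 5)
  s2 <- sample_fragments(frags, 60, seed = 5)
  expect_identical(s1, s2)
  expect_error(sample_fragments(frags, 201), "exceeds")
  # hypergeometric 3-sigma check on the label proportion
  k <- sum(s1$truth == "D")
  m <- 120; nn <- 80; n_draw <- 60
  mu <- n_draw * m / 200
  sigma <- sqrt(n_draw * (m / 200) * (nn / 200) * (200 - n_draw) / 199)
  expect_lt(abs(k - mu), 3 * sigma)
})

test_that("nearest-consensus classification separates the families", {
  win <- window_pair(seed = 83, n_diff = 5)
  frags <- structure(
    data.frame(read_id = c("a", "b", "c"),
               fragment = c(win$d_consensus, win$s_consensus,
                            mutate_at_k(win$d_consensus, 1)),
               truth = c("D", "S", "D"), stringsAsFactors = FALSE),
    class = c("fragment_sample", "data.frame"))
  cls <- classify_fragments(frags, win)
  expect_equal(cls$sample$label, c("D", "S", "D"))
  expect_equal(cls$pct_D + cls$pct_S, 100)
  # equidistant fragment is left unassigned: of the 5 diagnostic sites,
  # take 2 S alleles, 2 D alleles, and a third base at the fifth
  half <- strsplit(win$d_consensus, "")[[1]]
  sc <- strsplit(win$s_consensus, "")[[1]]
  diffs <- which(half != sc)
  half[diffs[1:2]] <- sc[diffs[1:2]]
  half[diffs[3]] <- setdiff(c("A", "C", "G", "T"),
                            c(half[diffs[3]], sc[diffs[3]]))[1]
  # distances: dD = 2 + 1 = 3, dS = 2 + 1 = 3
  eq <- structure(
    data.frame(read_id = "e", fragment = paste(half, collapse = ""),
               truth = NA_character_, stringsAsFactors = FALSE),
    class = c("fragment_sample", "data.frame"))
  cls_eq <- classify_fragments(eq, win)
  dD <- hamming(eq$fragment, win$d_consensus)
  dS <- hamming(eq$fragment, win$s_consensus)
  expect_equal(dD, dS)
  expect_equal(cls_eq$sample$label, "unassigned")
})

test_that("homoeologue ratios are recovered across the observed range", {
  win <- window_pair(seed = 84, n_diff = 5)
  for (s_frac in c(0.07, 0.26, 0.39)) {
    set.seed(round(1000 * s_frac))
    n <- 222
    n_s <- round(n * s_frac); n_d <- n - n_s
    frags <- structure(
      data.frame(read_id = paste0("f", 1:n),
                 fragment = c(noisy_fragments(win$d_consensus, n_d, 0.01),
                              noisy_fragments(win$s_consensus, n_s, 0.01)),
                 truth = rep(c("D", "S"), c(n_d, n_s)),
                 stringsAsFactors = FALSE),
      class = c("fragment_sample", "data.frame"))
    cls <- classify_fragments(frags, win)
    sigma <- sqrt(n * s_frac * (1 - s_frac))
    expect_lt(abs(cls$n_S - n_s), 3 * sigma)
  }
})

test_that("haplotype diversity counts identity classes", {
  expect_equal(haplotype_diversity(c("AA", "AA", "AT", "TT"))$diversity, 0.75)
  expect_equal(haplotype_diversity(rep("ACGT", 10))$diversity, 1 / 10)
  expect_equal(haplotype_diversity(c("AA", "AT", "TA", "TT"))$diversity, 1)
  expect_error(haplotype_diversity(character()), "empty")
  # invariant under reordering
  set.seed(85)
  frags <- sample(c("AAA", "AAT", "ATT"), 30, TRUE)
  expect_equal(haplotype_diversity(frags)$diversity,
               haplotype_diversity(rev(frags))$diversity)
})

test_that("diversity comparison is the textbook Pearson chi-square", {
  a <- haplotype_diversity(c(rep("A", 70), paste0("B", 1:30)))
  expect_equal(a$n_haplotypes, 31)
  st1 <- list(n_haplotypes = 30, n_sequences = 100)
  st2 <- list(n_haplotypes = 50, n_sequences = 100)
  got <- compare_diversity(st1, st2)
  O <- matrix(c(30, 70, 50, 50), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$chi_square, sum((O - E)^2 / E))
  expect_equal(got$p_value, pchisq(got$chi_square, 1, lower.tail = FALSE))
  # identical tables: chi-square 0, p = 1
  same <- compare_diversity(st1, st1)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_diversity(list(n_haplotypes = 0, n_sequences = 0),
                                 st1), "degenerate")
})
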