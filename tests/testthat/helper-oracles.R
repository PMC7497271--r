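# Independent oracles and shared fixtures for the test suite.

# small annotated unit (1 kb) for mapping-heavy tests
small_unit <- function(seed = 1L, label = "D",
                       site_plan = data.frame(enzyme = c("BglII", "XhoI", "PstI"),
                                              start = c(600L, 850L, 920L))) {
  build_unit_template(
    label,
    subregion_lengths = c("18S" = 300, "ITS1" = 100, "5.8S" = 50,
                          "ITS2" = 50, "25S" = 300, "IGS" = 200),
    site_plan = site_plan, forbid = character(), seed = seed)
}

# constant-quality Phred+33 string for an error probability
qual_for <- function(p_err, n) {
  strrep(intToUtf8(round(-10 * log10(p_err)) + 33L), n)
}

# brute-force modified-Mott: maximize sum(limit - p_err) over all substrings,
# leftmost then shortest tie-break
mott_oracle <- function(seq, qual, limit = 0.05) {
  n <- nchar(seq)
  score <- limit - qual_to_perr(qual)
  best <- 0; bs <- 0L; be <- -1L
  for (i in seq_len(n)) for (j in i:n) {
    s <- sum(score[i:j])
    if (s > best + 1e-12) { best <- s; bs <- i; be <- j }
  }
  if (be < bs) "" else substr(seq, bs, be)
}

# dense-matrix local-alignment DP in plain R: match +1, mismatch -mc,
# read-insertion -ic, reference-deletion -dc, floor 0; returns the optimal
# score (0 when nothing positive aligns)
dp_oracle_score <- function(read, ref, mc = 2, ic = 3, dc = 3) {
  m <- nchar(read); n <- nchar(ref)
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  H <- matrix(0, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    H[i + 1, j + 1] <- max(0,
      H[i, j] + if (a[i] == b[j]) 1 else -mc,
      H[i, j + 1] - ic,
      H[i + 1, j] - dc)
  }
  max(H)
}

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# distance matrix of an additive 4-taxon tree ((A:1,B:2):1.5,(C:3,D:4))
additive_4taxon <- function() {
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5.5
  D["A", "D"] <- D["D", "A"] <- 6.5
  D["B", "C"] <- D["C", "B"] <- 6.5
  D["B", "D"] <- D["D", "B"] <- 7.5
  D["C", "D"] <- D["D", "C"] <- 7
  D
}

# mutate a sequence at exactly k distinct positions
mutate_at_k <- function(seqs, k) {
  x <- strsplit(seqs, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

# fragments drawn from a consensus with per-base substitution error
noisy_fragments <- function(consensus, n, error_rate) {
  vapply(seq_len(n), function(i) {
    x <- strsplit(consensus, "")[[1]]
    hit <- which(runif(length(x)) < error_rate)
    for (p in hit) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    paste(x, collapse = "")
  }, "")
}

# a 50-bp diagnostic window pair differing at exactly n_diff positions
window_pair <- function(seed = 1L, n_diff = 5L, width = 50L) {
  set.seed(seed)
  d <- random_read(width)
  s <- mutate_at_k(d, n_diff)
  list(width = width, start = 1L, d_consensus = d, s_consensus = s,
       divergence = n_diff / width, identical_flag = FALSE)
}
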