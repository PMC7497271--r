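test_that("Jukes-Cantor distance matches its closed form and saturates", {
  s <- strrep("A", 50)
  expect_equal(jc_distance(s, s), 0, ignore_attr = TRUE)
  # p = 0.10: d = -(3/4) ln(1 - 4*0.1/3)
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(c(rep("C", 5), rep("A", 45)), collapse = "")
  d <- jc_distance(a, b)
  expect_equal(as.numeric(d), -0.75 * log(1 - 0.4 / 3))
  expect_equal(as.numeric(d), 0.1073256, tolerance = 1e-6)
  expect_false(attr(d, "saturated"))
  # d >= p on (0, 0.75) and d -> p as p -> 0
  for (k in c(1, 5, 15, 30)) {
    bb <- paste(c(rep("C", k), rep("A", 50 - k)), collapse = "")
    expect_gte(as.numeric(jc_distance(a, bb)), k / 50)
  }
  expect_equal(as.numeric(jc_distance(a, paste(c("C", rep("A", 49)),
                                               collapse = ""))),
               1 / 50, tolerance = 0.02)
  # saturation: p >= 0.75 capped and flagged
  sat <- jc_distance(strrep("A", 40), strrep("C", 40), max_distance = 7)
  expect_equal(as.numeric(sat), 7)
  expect_true(attr(sat, "saturated"))
  # pairwise deletion: gap/N columns excluded
  expect_equal(as.numeric(jc_distance("AC-GN", "ACTGA")), 0)
  expect_error(jc_distance("---", "AAA"), "comparable")
  expect_error(jc_distance("AA", "AAA"), "equal length")
})

test_that("distance matrix agrees with an independent JC implementation", {
  set.seed(91)
  base <- random_read(120)
  seqs <- setNames(vapply(1:6, function(i) mutate_at_k(base, sample(5:25, 1)), ""),
                   paste0("t", 1:6))
  D <- jc_distance_matrix(seqs)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(s, "")[[1]])))
  Dape <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[rownames(D), colnames(D)]),
               tolerance = 1e-9)
})

test_that("three-taxon neighbour joining solves the closed-form branch lengths", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
  expect_equal(tip_edge(tr, "a"), 0.1)
  expect_equal(tip_edge(tr, "b"), 0.2)
  expect_equal(tip_edge(tr, "c"), 0.4)
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
  D_asym <- D; D_asym[1, 2] <- 1
  expect_error(nj_tree(D_asym), "symmetric")
})

test_that("neighbour joining is exact on an additive four-taxon metric", {
  D <- additive_4taxon()
  tr <- nj_tree(D)
  # patristic distances reproduce the input exactly
  C <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(C), unname(D), tolerance = 1e-9)
  # topology: AB | CD split recovered
  truth <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # branch length multiset {1, 2, 3, 4, 1.5}
  expect_equal(sort(tr$edge.length), c(1, 1.5, 2, 3, 4))
})

test_that("neighbour joining matches the reference implementation on random matrices", {
  set.seed(92)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    X <- matrix(runif(n * n, 0.05, 1), n)
    D <- (X + t(X)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- nj_tree(D)
    theirs <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ultrametric two-cluster data joins the closest pair first", {
  # two tight clusters: the within-cluster cherry must exist in the topology
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.02
  D[3, 4] <- D[4, 3] <- 0.04
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- nj_tree(D)
  truth <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports a clean two-cluster split at 100 and is seeded", {
  set.seed(93)
  d0 <- random_read(60)
  s0 <- mutate_at_k(d0, 12)
  seqs <- c(setNames(noisy_fragments(d0, 5, 0.01), paste0("D", 1:5)),
            setNames(noisy_fragments(s0, 5, 0.01), paste0("S", 1:5)))
  tr1 <- bootstrap_support(seqs, n_replicates = 50, seed = 7)
  tr2 <- bootstrap_support(seqs, n_replicates = 50, seed = 7)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the D/S bipartition edge must be maximally supported
  assign_lab <- branch_assign(tr1, "D1", "S1")
  expect_true(max(sup) == 100)
  expect_equal(unname(assign_lab[paste0("D", 1:5)]), rep("D", 5))
  expect_equal(unname(assign_lab[paste0("S", 1:5)]), rep("S", 5))
})

test_that("newick round-trip preserves topology, lengths and supports", {
  set.seed(94)
  seqs <- c(setNames(noisy_fragments(random_read(60), 4, 0.05), paste0("a", 1:4)),
            setNames(noisy_fragments(random_read(60), 4, 0.05), paste0("b", 1:4)))
  tr <- bootstrap_support(seqs, n_replicates = 20, seed = 3)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("branch assignment agrees with the nearest-consensus classifier", {
  set.seed(95)
  win <- window_pair(seed = 95, n_diff = 5)
  n_d <- 20; n_s <- 12
  frags <- structure(
    data.frame(read_id = c(paste0("D", 1:n_d), paste0("S", 1:n_s)),
               fragment = c(noisy_fragments(win$d_consensus, n_d, 0),
                            noisy_fragments(win$s_consensus, n_s, 0)),
               truth = rep(c("D", "S"), c(n_d, n_s)),
               stringsAsFactors = FALSE),
    class = c("fragment_sample", "data.frame"))
  # error-free fragments collapse within family; jitter one base on a few
  # so the tree has internal structure
  frags$fragment[c(2, 25)] <- vapply(frags$fragment[c(2, 25)], mutate_at_k,
                                     "", k = 1)
  cls <- classify_fragments(frags, win)
  tr <- nj_tree(jc_distance_matrix(setNames(
    paste0(frags$fragment, ""), frags$read_id)))
  lab <- branch_assign(tr, "D1", "S1")
  agree <- mean(lab[frags$read_id] == cls$sample$label)
  expect_gte(agree, 0.99)
})
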