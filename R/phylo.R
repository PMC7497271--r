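#' Jukes-Cantor distance between two aligned sequences
#'
#' d = -(3/4) ln(1 - 4p/3) with p the mismatch fraction over comparable
#' columns (pairwise deletion: columns where either sequence has a gap or
#' ambiguous base are excluded). Saturated pairs (p >= 0.75, where the
#' formula diverges) are set to `max_distance` and flagged.
#'
#' @param seq_a,seq_b aligned sequences (equal length).
#' @param max_distance distance assigned to saturated pairs (default 10).
#' @return the distance; attribute `saturated` is TRUE when capped.
#' @export
jc_distance <- function(seq_a, seq_b, max_distance = 10) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned (equal length)")
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(ok)) stop("no comparable columns between the sequences")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) return(structure(max_distance, saturated = TRUE))
  structure(-0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' Jukes-Cantor distance matrix for an alignment
#'
#' @param seqs named character vector of aligned sequences (or a
#'   `fragment_sample`, using read ids as labels).
#' @param max_distance cap for saturated pairs.
#' @return symmetric matrix with zero diagonal and the labels as dimnames.
#' @export
jc_distance_matrix <- function(seqs, max_distance = 10) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$fragment, seqs$read_id)
  n <- length(seqs)
  labels <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  M <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  okM <- matrix(M %in% DNA_BASES, nrow = n)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- okM[i, ] & okM[j, ]
    if (!any(ok)) stop("no comparable columns between sequences ", i, " and ", j)
    p <- mean(M[i, ok] != M[j, ok])
    D[i, j] <- D[j, i] <- if (p >= 0.75) max_distance
                          else -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining with the Studier-Keppler Q-criterion;
#' ties in Q resolve to the pair first in the current label order, so the
#' result is deterministic. Negative branch lengths are clamped to zero
#' (attribute `clamped`).
#'
#' @param D symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels                 # newick substrings for active clusters
  clamped <- FALSE
  clamp <- function(v) {
    if (v < 0) { clamped <<- TRUE; 0 } else v
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], vi, nodes[j], vj)
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], sprintf("int%d", m))
    D <- D2
  }
  v1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], v1, nodes[2], v2, nodes[3], v3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# leaf-label bipartition induced by each internal node (excluding the root),
# canonicalized as the sorted side not containing the first leaf label
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  root <- ntip + 1L
  anchor <- sort(tips)[1]
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0L) return(tips[node])
    unlist(lapply(kids, desc))
  }
  internal <- setdiff(unique(tree$edge[, 1]), root)
  internal <- sort(internal)
  out <- lapply(internal, function(nd) {
    side <- desc(nd)
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NULL)
    paste(sort(side), collapse = "|")
  })
  names(out) <- as.character(internal)
  out[!vapply(out, is.null, TRUE)]
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' replicate, and scores each internal edge of the reference tree by the
#' percentage of replicates recovering its leaf bipartition. Supports are
#' attached as internal node labels.
#'
#' @param seqs named character vector of aligned sequences (or
#'   `fragment_sample`).
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @param max_distance saturation cap passed to the distance computation.
#' @return the reference `phylo` tree with `node.label` holding supports
#'   (root label empty).
#' @export
bootstrap_support <- function(seqs, n_replicates = 100L, seed = 1L,
                              max_distance = 10) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$fragment, seqs$read_id)
  ref <- nj_tree(jc_distance_matrix(seqs, max_distance))
  parts <- tree_bipartitions(ref)
  hits <- setNames(numeric(length(parts)), unlist(parts))
  L <- nchar(seqs[[1]])
  M <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- setNames(apply(M[, cols, drop = FALSE], 1, paste, collapse = ""),
                       names(seqs))
      bt <- nj_tree(jc_distance_matrix(boot, max_distance))
      bp <- unique(unlist(tree_bipartitions(bt)))
      seen <- names(hits) %in% bp
      hits[seen] <- hits[seen] + 1
    }
  })
  support <- 100 * hits / n_replicates
  ntip <- length(ref$tip.label)
  labels <- character(ref$Nnode)
  for (k in seq_along(parts)) {
    nd <- as.integer(names(parts)[k])
    labels[nd - ntip] <- sprintf("%g", support[[parts[[k]]]])
  }
  ref$node.label <- labels
  ref
}

#' Assign leaves to homoeologous families by tree branch
#'
#' Cuts the longest internal edge on the path between the two reference
#' leaves (under the two-cluster structure of the diagnostic window, the
#' long edge separating the D and S clades) and labels every leaf by the
#' side it falls on.
#'
#' @param tree a `phylo`.
#' @param reference_leaf_D,reference_leaf_S tip labels anchoring the two
#'   families.
#' @return named character vector mapping every tip to `"D"` or `"S"`.
#' @export
branch_assign <- function(tree, reference_leaf_D, reference_leaf_S) {
  tips <- tree$tip.label
  iD <- match(reference_leaf_D, tips)
  iS <- match(reference_leaf_S, tips)
  if (is.na(iD) || is.na(iS)) stop("reference leaf not present in the tree")
  if (length(tips) == 2L)
    return(setNames(c("D", "S")[match(tips, c(reference_leaf_D, reference_leaf_S))],
                    tips))
  ntip <- length(tips)
  path <- ape::nodepath(tree, iD, iS)
  onpath <- cbind(path[-length(path)], path[-1])
  internal <- onpath[, 1] > ntip & onpath[, 2] > ntip
  if (!any(internal)) stop("reference leaves are not separable by an internal edge")
  # branch length of each path edge
  eidx <- apply(onpath, 1, function(e) {
    which((tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2]) |
          (tree$edge[, 1] == e[2] & tree$edge[, 2] == e[1]))[1]
  })
  lens <- tree$edge.length[eidx]
  lens[!internal] <- -Inf
  cut <- which.max(lens)
  a <- onpath[cut, 1]; b <- onpath[cut, 2]
  # BFS from the D reference avoiding the cut edge
  adj <- rbind(tree$edge, tree$edge[, 2:1])
  reach <- rep(FALSE, ntip + tree$Nnode)
  queue <- iD; reach[iD] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[adj[, 1] == v, 2]
    for (w in nb) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!reach[w]) { reach[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  setNames(ifelse(reach[seq_len(ntip)], "D", "S"), tips)
}

#' Newick and PHYLIP output
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname write_newick
#' @param D distance matrix.
#' @export
write_phylip_matrix <- function(D, path) {
  D <- as.matrix(D)
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}
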