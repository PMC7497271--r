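#' Select the diagnostic ITS1 window
#'
#' Scans two positionally aligned ITS1 consensus sequences (equal length,
#' gaps allowed) for the width-bp window with the highest column-wise
#' divergence — the short diagnostic fragment used to tell the two
#' homoeologous rDNA families apart (about 10% divergence between the D and
#' S consensuses in the defaults).
#'
#' @param d_its1,s_its1 aligned ITS1 consensus sequences (equal length).
#' @param width window width in bp (default 50).
#' @return object of class `diagnostic_window`: `width`, `start` (1-based in
#'   ITS1 coordinates), `d_consensus`, `s_consensus`, `divergence`,
#'   `identical_flag` (TRUE when the inputs never differ).
#' @export
select_diagnostic_window <- function(d_its1, s_its1, width = 50L) {
  if (nchar(d_its1) != nchar(s_its1))
    stop("ITS1 sequences must be aligned to equal length")
  L <- nchar(d_its1)
  if (L < width) stop("ITS1 shorter than the window width")
  d <- seq_chars(d_its1); s <- seq_chars(s_its1)
  diff <- as.integer(d != s)
  cs <- c(0L, cumsum(diff))
  wdiff <- cs[(width + 1):(L + 1)] - cs[1:(L - width + 1)]
  best <- which.max(wdiff)  # leftmost maximum
  flag <- sum(diff) == 0L
  if (flag) warning("ITS1 sequences are identical; window is not diagnostic")
  structure(
    list(width = as.integer(width), start = as.integer(best),
         d_consensus = substr(d_its1, best, best + width - 1L),
         s_consensus = substr(s_its1, best, best + width - 1L),
         divergence = wdiff[best] / width,
         identical_flag = flag),
    class = "diagnostic_window")
}

#' @export
print.diagnostic_window <- function(x, ...) {
  cat(sprintf("diagnostic_window: %d bp at ITS1 position %d, divergence %.1f%%\n",
              x$width, x$start, 100 * x$divergence))
  cat("D:", x$d_consensus, "\nS:", x$s_consensus, "\n")
  invisible(x)
}

hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

# distance of a fragment to a consensus: Hamming when positionally aligned,
# unit-cost edit distance (gaps count as mismatches) when lengths differ
fragment_distance <- function(fragment, consensus) {
  if (nchar(fragment) == nchar(consensus)) hamming(fragment, consensus)
  else as.integer(utils::adist(fragment, consensus))
}

#' Recruit window-anchored fragments from reads
#'
#' Aligns each read against both window consensuses and keeps those whose
#' better local alignment covers at least `min_overlap` window columns,
#' trimmed to window coordinates. Reads containing an ambiguous base are
#' discarded.
#'
#' @param reads a [read_set()].
#' @param window a [select_diagnostic_window()] result.
#' @param min_overlap minimum window columns covered (default the window
#'   width, i.e. full coverage).
#' @param config an [aligner_config()].
#' @return a `fragment_sample`: data.frame with `read_id`, `fragment`,
#'   `truth`.
#' @export
recruit_fragments <- function(reads, window, min_overlap = window$width,
                              config = aligner_config()) {
  ids <- character(0); frags <- character(0); truth <- character(0)
  for (k in seq_len(nrow(reads))) {
    sq <- reads$seq[k]
    if (grepl("N", sq, fixed = TRUE)) next
    pd <- align_read(sq, window$d_consensus, config)
    ps <- align_read(sq, window$s_consensus, config)
    p <- if (is.null(ps)) pd
         else if (is.null(pd)) ps
         else if (pd$score >= ps$score) pd else ps
    if (is.null(p)) next
    ref_cols <- p$ref_end - p$ref_start + 1L
    if (ref_cols < min_overlap) next
    frag <- substr(sq, p$read_start, p$read_end)
    ids <- c(ids, reads$id[k]); frags <- c(frags, frag)
    truth <- c(truth, reads$truth[k])
  }
  structure(
    data.frame(read_id = ids, fragment = frags, truth = truth,
               stringsAsFactors = FALSE),
    class = c("fragment_sample", "data.frame"))
}

#' Subsample fragments
#'
#' Uniform random subsample without replacement, seeded.
#'
#' @param sample a `fragment_sample`.
#' @param n subsample size (`n <=` available fragments).
#' @param seed integer RNG seed.
#' @return a `fragment_sample`.
#' @export
sample_fragments <- function(sample, n, seed = 1L) {
  if (n > nrow(sample)) stop("n exceeds the number of available fragments")
  with_seed(seed, {
    out <- as.data.frame(sample)[sort(sample.int(nrow(sample), n)), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("fragment_sample", "data.frame"))
  })
}

#' Classify fragments into homoeologous families
#'
#' Each fragment is labelled by the smaller distance to the D vs the S
#' window consensus (Hamming for window-length fragments, unit-cost edit
#' distance otherwise); exact ties are left unassigned. Percentages are
#' taken over assigned fragments.
#'
#' @param sample a `fragment_sample`.
#' @param window a [select_diagnostic_window()] result.
#' @return object of class `homoeologue_ratio`: the labelled `sample` plus
#'   `n_D`, `n_S`, `n_unassigned`, `pct_D`, `pct_S`.
#' @export
classify_fragments <- function(sample, window) {
  lab <- character(nrow(sample))
  for (i in seq_len(nrow(sample))) {
    dD <- fragment_distance(sample$fragment[i], window$d_consensus)
    dS <- fragment_distance(sample$fragment[i], window$s_consensus)
    lab[i] <- if (dD < dS) "D" else if (dS < dD) "S" else "unassigned"
  }
  out <- as.data.frame(sample)
  out$label <- lab
  n_D <- sum(lab == "D"); n_S <- sum(lab == "S")
  assigned <- n_D + n_S
  structure(
    list(sample = structure(out, class = c("fragment_sample", "data.frame")),
         n_D = n_D, n_S = n_S, n_unassigned = sum(lab == "unassigned"),
         pct_D = if (assigned) 100 * n_D / assigned else NA_real_,
         pct_S = if (assigned) 100 * n_S / assigned else NA_real_),
    class = "homoeologue_ratio")
}

#' @export
print.homoeologue_ratio <- function(x, ...) {
  cat(sprintf(
    "homoeologue_ratio: %d D (%.1f%%), %d S (%.1f%%), %d unassigned\n",
    x$n_D, x$pct_D, x$n_S, x$pct_S, x$n_unassigned))
  invisible(x)
}

#' Haplotype diversity of a fragment sample
#'
#' Number of distinct full-length sequences divided by the number of
#' sequences.
#'
#' @param sample a `fragment_sample` or character vector of sequences.
#' @return object of class `diversity_stat`: `n_sequences`, `n_haplotypes`,
#'   `diversity`.
#' @export
haplotype_diversity <- function(sample) {
  seqs <- if (is.data.frame(sample)) sample$fragment else as.character(sample)
  if (length(seqs) == 0L) stop("empty sample")
  structure(
    list(n_sequences = length(seqs),
         n_haplotypes = length(unique(seqs)),
         diversity = length(unique(seqs)) / length(seqs)),
    class = "diversity_stat")
}

#' @export
print.diversity_stat <- function(x, ...) {
  cat(sprintf("diversity_stat: %d haplotypes / %d sequences = %.3f\n",
              x$n_haplotypes, x$n_sequences, x$diversity))
  invisible(x)
}

#' Compare haplotype diversity between two families
#'
#' Pearson chi-square (no continuity correction, df = 1) on the 2x2 table
#' of haplotype vs non-haplotype sequence counts per family.
#'
#' @param statA,statB [haplotype_diversity()] results.
#' @return list with `chi_square`, `p_value`, `table`.
#' @export
compare_diversity <- function(statA, statB) {
  tab <- rbind(c(statA$n_haplotypes, statA$n_sequences - statA$n_haplotypes),
               c(statB$n_haplotypes, statB$n_sequences - statB$n_haplotypes))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}

#' Write fragments as FASTA
#' @param sample a `fragment_sample`.
#' @param path output path.
#' @export
write_fragments_fasta <- function(sample, path) {
  lines <- character(2L * nrow(sample))
  if (nrow(sample)) {
    idx <- seq_len(nrow(sample))
    lines[2 * idx - 1] <- paste0(">", sample$read_id)
    lines[2 * idx] <- sample$fragment
  }
  writeLines(lines, path)
  invisible(path)
}
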