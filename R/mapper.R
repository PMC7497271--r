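#' Mapper configuration
#'
#' The mapping cost model: mismatch cost 2, insertion cost 3, deletion cost
#' 3, with a placement accepted when at least `length_fraction` of the read
#' aligns and the identity over aligned columns reaches
#' `similarity_fraction` (both inclusive).
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive edit costs.
#' @param length_fraction,similarity_fraction acceptance fractions in (0, 1].
#' @export
aligner_config <- function(mismatch_cost = 2, insertion_cost = 3,
                           deletion_cost = 3, length_fraction = 0.5,
                           similarity_fraction = 0.8) {
  stopifnot(mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1)
  structure(list(mismatch_cost = mismatch_cost,
                 insertion_cost = insertion_cost,
                 deletion_cost = deletion_cost,
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction),
            class = "aligner_config")
}

#' Align one read against a reference
#'
#' Optimal local placement under the cost model of [aligner_config()]
#' (match +1, mismatch -2, insertion -3, deletion -3 by default): reference
#' flanks are free and unaligned read ends are soft-clipped, counting
#' against the aligned read fraction. For tandem-array mapping pass the
#' doubled unit sequence as `reference` so junction-spanning reads align
#' contiguously ([map_reads()] does this and folds coordinates back).
#'
#' @param read read sequence (character).
#' @param reference reference sequence (character).
#' @param config an [aligner_config()].
#' @return a `placement` (list with `ref_start`, `ref_end`, `read_start`,
#'   `read_end`, `cigar`, `total_cost`, `score`, match/mismatch/indel
#'   counts, `aligned_read_fraction`, `identity_fraction`) or `NULL` when
#'   the read is empty or nothing aligns.
#' @export
align_read <- function(read, reference, config = aligner_config()) {
  if (is.null(read) || !nzchar(read)) return(NULL)
  hit <- align_read_cpp(read, reference, config$mismatch_cost,
                        config$insertion_cost, config$deletion_cost)
  if (is.null(hit)) return(NULL)
  m <- nchar(read)
  cols <- hit$n_match + hit$n_mismatch + hit$n_ins + hit$n_del
  structure(
    c(hit, list(
      total_cost = hit$cost,
      aligned_read_fraction = (hit$read_end - hit$read_start + 1) / m,
      identity_fraction = hit$n_match / cols)),
    class = "placement")
}

#' Accept or reject a placement
#'
#' @param placement a placement from [align_read()].
#' @param config an [aligner_config()].
#' @return `TRUE` iff aligned read fraction >= `length_fraction` and
#'   identity >= `similarity_fraction` (inclusive thresholds).
#' @export
accept_placement <- function(placement, config = aligner_config()) {
  if (is.null(placement)) return(FALSE)
  tol <- 1e-9
  placement$aligned_read_fraction >= config$length_fraction - tol &&
    placement$identity_fraction >= config$similarity_fraction - tol
}

fold_pos <- function(p, L) ((p - 1L) %% L) + 1L

parse_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Map a read set onto a tandem rDNA unit
#'
#' Aligns each read against the unit sequence concatenated to itself (so
#' reads spanning the IGS/18S array junction map contiguously), keeps the
#' best placement per read, applies the acceptance thresholds, and folds
#' coverage and per-position allele tallies back onto unit coordinates
#' `[1, L]`. Each read is counted at most once.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param unit_reference an [rdna_unit][build_unit_template] or a character
#'   reference sequence.
#' @param config an [aligner_config()].
#' @return a `mapping_result`: `placements` (data.frame), `mapped_read_count`,
#'   `total_read_count`, `coverage` (length-L integer), `tallies` (5 x L
#'   matrix, rows A/C/G/T/del), `insertions` (data.frame pos/seq, one row
#'   per event, left-anchored), `reference`, `unit`.
#' @export
map_reads <- function(reads, unit_reference, config = aligner_config()) {
  unit <- NULL
  if (inherits(unit_reference, "rdna_unit")) {
    unit <- unit_reference
    reference <- unit$sequence
  } else reference <- as.character(unit_reference)
  L <- nchar(reference)
  doubled <- paste0(reference, reference)
  refc <- seq_chars(reference)

  if (is.character(reads)) reads <- read_set(
    sprintf("read_%06d", seq_along(reads)), reads,
    strrep("I", nchar(reads)))
  n <- nrow(reads)

  tallies <- matrix(0L, nrow = 5, ncol = L,
                    dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  coverage <- integer(L)
  ins_pos <- integer(0); ins_seq <- character(0)
  pl <- vector("list", n)
  mapped <- 0L

  for (k in seq_len(n)) {
    p <- align_read(reads$seq[k], doubled, config)
    if (is.null(p)) next
    ok <- accept_placement(p, config)
    start_folded <- fold_pos(p$ref_start, L)
    pl[[k]] <- data.frame(
      read_id = reads$id[k], ref_start = start_folded, cigar = p$cigar,
      cost = p$total_cost, score = p$score,
      identity = p$identity_fraction,
      aligned_fraction = p$aligned_read_fraction,
      accepted = ok, stringsAsFactors = FALSE)
    if (!ok) next
    mapped <- mapped + 1L
    ops <- parse_cigar(p$cigar)
    rpos <- 1L                      # position in read
    fpos <- p$ref_start             # position in doubled reference
    readc <- seq_chars(reads$seq[k])
    for (o in seq_len(nrow(ops))) {
      w <- ops$len[o]
      switch(ops$op[o],
        S = { rpos <- rpos + w },
        M = {
          cols <- fold_pos(fpos:(fpos + w - 1L), L)
          coverage[cols] <- coverage[cols] + 1L
          b <- readc[rpos:(rpos + w - 1L)]
          known <- b %in% DNA_BASES
          if (any(known)) {
            idx <- cbind(match(b[known], rownames(tallies)), cols[known])
            for (r in seq_len(nrow(idx)))
              tallies[idx[r, 1], idx[r, 2]] <- tallies[idx[r, 1], idx[r, 2]] + 1L
          }
          rpos <- rpos + w; fpos <- fpos + w
        },
        D = {
          cols <- fold_pos(fpos:(fpos + w - 1L), L)
          coverage[cols] <- coverage[cols] + 1L
          tallies["del", cols] <- tallies["del", cols] + 1L
          fpos <- fpos + w
        },
        I = {
          ins_pos <- c(ins_pos, fold_pos(fpos - 1L, L))
          ins_seq <- c(ins_seq, paste(readc[rpos:(rpos + w - 1L)], collapse = ""))
          rpos <- rpos + w
        })
    }
  }

  placements <- if (length(pl)) do.call(rbind, pl[!vapply(pl, is.null, TRUE)])
                else NULL
  if (is.null(placements))
    placements <- data.frame(read_id = character(), ref_start = integer(),
                             cigar = character(), cost = numeric(),
                             score = numeric(), identity = numeric(),
                             aligned_fraction = numeric(),
                             accepted = logical(), stringsAsFactors = FALSE)
  structure(
    list(placements = placements, mapped_read_count = mapped,
         total_read_count = n, coverage = coverage, tallies = tallies,
         insertions = data.frame(pos = ins_pos, seq = ins_seq,
                                 stringsAsFactors = FALSE),
         reference = reference, unit = unit),
    class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result: %d/%d reads mapped to a %d-bp unit\n",
              x$mapped_read_count, x$total_read_count, nchar(x$reference)))
  cat(sprintf("coverage: min %d, mean %.1f, max %d\n",
              min(x$coverage), mean(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Binned coverage summary
#'
#' Minimum, mean and maximum coverage per non-overlapping bin tiling the
#' unit (the last bin may be short) — the aggregation used to display
#' coverage along the unit.
#'
#' @param mapping a [map_reads()] result.
#' @param bin_width bin width in bp (>= 1).
#' @return data.frame with `start`, `end`, `min`, `mean`, `max`.
#' @export
coverage_summary <- function(mapping, bin_width) {
  stopifnot(bin_width >= 1)
  cov <- mapping$coverage
  L <- length(cov)
  starts <- seq(1L, L, by = bin_width)
  ends <- pmin(starts + bin_width - 1L, L)
  data.frame(
    start = starts, end = ends,
    min = vapply(seq_along(starts), function(i) min(cov[starts[i]:ends[i]]), 0),
    mean = vapply(seq_along(starts), function(i) mean(cov[starts[i]:ends[i]]), 0),
    max = vapply(seq_along(starts), function(i) max(cov[starts[i]:ends[i]]), 0))
}

#' Consensus sequence from a mapping
#'
#' Per position, the majority base among the A/C/G/T tallies; exact ties and
#' zero-coverage positions fall back to the reference base.
#'
#' @param mapping a [map_reads()] result.
#' @param reference reference sequence; defaults to the mapping's.
#' @return consensus sequence (character, same length as the reference).
#' @export
consensus_from_mapping <- function(mapping, reference = NULL) {
  if (is.null(reference)) reference <- mapping$reference
  refc <- seq_chars(reference)
  bases <- mapping$tallies[c("A", "C", "G", "T"), , drop = FALSE]
  out <- refc
  tot <- colSums(bases)
  for (j in which(tot > 0)) {
    col <- bases[, j]
    top <- which(col == max(col))
    if (length(top) == 1L && col[top] > 0) out[j] <- rownames(bases)[top]
  }
  paste(out, collapse = "")
}
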