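#' Trimming configuration
#'
#' @param quality_limit error-probability limit P for modified-Mott trimming
#'   (default 0.05).
#' @param min_length minimum retained read length in bp (100 for the
#'   100-nt-read libraries, 150 for the 150-nt ones).
#' @param drop_ambiguous drop reads containing any ambiguous base (N).
#' @export
trim_config <- function(quality_limit = 0.05, min_length = 100L,
                        drop_ambiguous = TRUE) {
  if (quality_limit <= 0 || quality_limit >= 1)
    stop("quality_limit must be in (0, 1)")
  if (min_length < 1) stop("min_length must be >= 1")
  structure(list(quality_limit = quality_limit,
                 min_length = as.integer(min_length),
                 drop_ambiguous = isTRUE(drop_ambiguous)),
            class = "trim_config")
}

#' Quality-trim one read (modified Mott)
#'
#' Assigns each base the score `quality_limit - p_err` and keeps the
#' contiguous substring with the maximum score sum; equal-scoring substrings
#' resolve to the leftmost (then shortest). Returns an empty read when no
#' substring scores positive.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string (same length as `seq`).
#' @param quality_limit error-probability limit (default 0.05).
#' @return list with `seq`, `qual`, `start`, `end` of the retained segment
#'   (`start = 0` for an empty result).
#' @export
trim_read <- function(seq, qual, quality_limit = 0.05) {
  if (is.null(qual) || !nzchar(qual)[1] && nzchar(seq)[1])
    stop("read has no base qualities")
  n <- nchar(seq)
  if (n == 0L) return(list(seq = "", qual = "", start = 0L, end = 0L))
  if (nchar(qual) != n) stop("sequence/quality length mismatch")
  score <- quality_limit - qual_to_perr(qual)
  # best-sum substring via prefix sums; leftmost-then-shortest tie-break
  cs <- cumsum(score)
  best <- 0; bs <- 0L; be <- -1L
  min_pref <- 0; min_at <- 0L
  eps <- 1e-12
  for (j in seq_len(n)) {
    cand <- cs[j] - min_pref
    if (cand > best + eps) {
      best <- cand; bs <- min_at + 1L; be <- j
    }
    if (cs[j] < min_pref - eps) {
      min_pref <- cs[j]; min_at <- j
    }
  }
  if (be < bs) return(list(seq = "", qual = "", start = 0L, end = 0L))
  list(seq = substr(seq, bs, be), qual = substr(qual, bs, be),
       start = bs, end = be)
}

#' Quality-filter a read set
#'
#' Applies modified-Mott trimming, then removes reads that contain any
#' ambiguous base (N) in the retained segment or fall short of the minimum
#' length. Removal counts are reported by reason (first triggered:
#' ambiguous, then short; a fully trimmed-away read counts as short).
#'
#' @param reads a [read_set()].
#' @param config a [trim_config()].
#' @return list with `kept` (a trimmed [read_set()]) and `report`
#'   (data.frame reason/count; reasons `input`, `kept`, `ambiguous`,
#'   `short`).
#' @export
filter_reads <- function(reads, config = trim_config()) {
  n <- nrow(reads)
  keep <- logical(n)
  reason <- character(n)
  seqs <- reads$seq; quals <- reads$qual
  for (i in seq_len(n)) {
    tr <- trim_read(seqs[i], quals[i], config$quality_limit)
    seqs[i] <- tr$seq; quals[i] <- tr$qual
    if (config$drop_ambiguous && grepl("N", tr$seq, fixed = TRUE)) {
      reason[i] <- "ambiguous"
    } else if (nchar(tr$seq) < config$min_length) {
      reason[i] <- "short"
    } else {
      keep[i] <- TRUE
    }
  }
  kept <- read_set(reads$id[keep], seqs[keep], quals[keep], reads$truth[keep])
  report <- data.frame(
    reason = c("input", "kept", "ambiguous", "short"),
    count = c(n, sum(keep), sum(reason == "ambiguous"), sum(reason == "short")),
    stringsAsFactors = FALSE
  )
  list(kept = kept, report = report)
}
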