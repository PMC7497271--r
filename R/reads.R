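#' Read sets
#'
#' A `read_set` is a data.frame with columns `id`, `seq`, `qual` (Sanger
#' Phred+33 quality string) and `truth` (ground-truth origin label `"D"`,
#' `"S"` or `"background"`, `NA` when unknown), with class `read_set`.
#'
#' @param id,seq,qual,truth character vectors of equal length.
#' @return a `read_set`.
#' @export
read_set <- function(id, seq, qual, truth = NA_character_) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality lengths differ")
  structure(
    data.frame(id = as.character(id), seq = as.character(seq),
               qual = as.character(qual),
               truth = rep_len(as.character(truth), length(id)),
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", lengths %d-%d", min(nchar(x$seq)), max(nchar(x$seq))))
    tl <- table(x$truth, useNA = "no")
    if (length(tl))
      cat("; truth: ", paste(names(tl), tl, sep = "=", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# Phred+33 quality string <-> per-base error probabilities
qual_to_perr <- function(qual) {
  10^(-(utf8ToInt(qual) - 33L) / 10)
}

phred_char <- function(q) intToUtf8(as.integer(q) + 33L)

#' Simulate Illumina-like reads from a tandem rDNA array
#'
#' Reads are drawn from a circularized tandem-unit model: each rDNA read is a
#' wrap-around substring of its source unit (so reads may span the IGS/18S
#' junction, as in a real tandem array). Optional background reads are
#' i.i.d. uniform random sequence; a read is rDNA-derived with probability
#' `W / (W + background_genome_size)` where `W` is the total weighted rDNA
#' space, which makes the genome proportion of the library controllable.
#' Substitution errors are applied per base at `error_rate`; qualities encode
#' the nominal error rate as a constant Phred score.
#'
#' @param units character vector of unit sequences (e.g. from
#'   [mutate_units()]).
#' @param unit_weights non-negative copy weights, one per unit (default
#'   equal).
#' @param n_reads number of reads (> 0).
#' @param read_length read length in nt; must not exceed the shortest unit.
#' @param error_rate per-base substitution error probability.
#' @param background_genome_size non-rDNA genome space in bp contributing
#'   background reads (0 = pure rDNA library).
#' @param labels ground-truth label per unit; defaults to the generating
#'   template's genome label when `units` carries one.
#' @param seed integer RNG seed.
#' @return a [read_set()] with truth labels.
#' @export
simulate_reads <- function(units, unit_weights = NULL, n_reads,
                           read_length = 100L, error_rate = 0.001,
                           background_genome_size = 0, labels = NULL,
                           seed = 1L) {
  units <- as.character(units)
  nu <- length(units)
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (is.null(unit_weights)) unit_weights <- rep(1, nu)
  if (any(unit_weights < 0) || sum(unit_weights) <= 0)
    stop("unit_weights must be >= 0 with positive sum")
  lens <- nchar(units)
  if (read_length > min(lens))
    stop("read_length exceeds unit length")
  if (is.null(labels)) {
    tmpl <- attr(units, "template")
    labels <- if (!is.null(tmpl)) rep(tmpl$genome_label, nu) else rep("D", nu)
  }
  labels <- rep_len(labels, nu)

  W <- sum(unit_weights * lens)
  p_rdna <- W / (W + background_genome_size)
  doubled <- vapply(units, function(u) paste0(u, u), "", USE.NAMES = FALSE)

  q <- if (error_rate > 0) max(2L, min(40L, round(-10 * log10(error_rate)))) else 40L
  qual1 <- strrep(phred_char(q), read_length)

  with_seed(seed, {
    is_rdna <- runif(n_reads) < p_rdna
    src <- integer(n_reads)
    src[is_rdna] <- sample.int(nu, sum(is_rdna), replace = TRUE,
                               prob = unit_weights * lens)
    seqs <- character(n_reads)
    for (i in which(is_rdna)) {
      s <- sample.int(lens[src[i]], 1L)
      seqs[i] <- substr(doubled[src[i]], s, s + read_length - 1L)
    }
    for (i in which(!is_rdna)) seqs[i] <- random_dna(read_length)
    if (error_rate > 0) {
      for (i in which(is_rdna)) {
        x <- seq_chars(seqs[i])
        hit <- which(runif(read_length) < error_rate)
        for (j in hit) x[j] <- sample(setdiff(DNA_BASES, x[j]), 1L)
        if (length(hit)) seqs[i] <- paste(x, collapse = "")
      }
    }
    truth <- ifelse(is_rdna, labels[pmax(src, 1L)], "background")
    read_set(sprintf("read_%06d", seq_len(n_reads)), seqs,
             rep(qual1, n_reads), truth)
  })
}

#' Mix D- and S-derived reads at a controlled ratio
#'
#' Emulates an allopolyploid library in which the two homoeologous rDNA
#' families contribute reads at a chosen ratio. Either give `s_fraction`
#' (the S share of `n_total`, S count = round(n_total * s_fraction), halves
#' away from zero) or explicit per-family counts `n_d`/`n_s`.
#'
#' @param d_reads,s_reads [read_set()]s of D- and S-derived reads.
#' @param s_fraction fraction of reads drawn from `s_reads` (in `[0, 1]`).
#' @param n_total total mixture size.
#' @param n_d,n_s explicit per-family counts (overrides `s_fraction`).
#' @param seed integer RNG seed.
#' @return a [read_set()] with truth labels `"D"`/`"S"` preserved.
#' @export
build_mixture <- function(d_reads, s_reads, s_fraction = NULL, n_total = NULL,
                          n_d = NULL, n_s = NULL, seed = 1L) {
  if (is.null(n_d) || is.null(n_s)) {
    if (is.null(s_fraction) || is.null(n_total))
      stop("give either s_fraction + n_total or explicit n_d + n_s")
    if (s_fraction < 0 || s_fraction > 1) stop("s_fraction must be in [0, 1]")
    n_s <- as.integer(round_half_up(n_total * s_fraction))
    n_d <- as.integer(n_total) - n_s
  }
  if (n_d > nrow(d_reads) || n_s > nrow(s_reads))
    stop("insufficient source reads for the requested mixture")
  with_seed(seed, {
    di <- sample.int(nrow(d_reads), n_d)
    si <- sample.int(nrow(s_reads), n_s)
    out <- rbind(as.data.frame(d_reads)[di, ], as.data.frame(s_reads)[si, ])
    out <- out[sample.int(nrow(out)), ]
    out$id <- make.unique(out$id, sep = "_")
    rownames(out) <- NULL
    structure(out, class = c("read_set", "data.frame"))
  })
}

#' Write and read FASTQ (Sanger Phred+33)
#'
#' @param reads a [read_set()].
#' @param path file path.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   [read_set()] (truth labels `NA`).
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads)) {
    idx <- seq_len(nrow(reads))
    lines[4 * idx - 3] <- paste0("@", reads$id)
    lines[4 * idx - 2] <- reads$seq
    lines[4 * idx - 1] <- "+"
    lines[4 * idx]     <- reads$qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(names(x), as.character(x),
           as.character(S4Vectors::mcols(x)$qualities))
}

#' Write truth labels as TSV
#' @param reads a [read_set()].
#' @param path file path.
#' @export
write_truth_labels <- function(reads, path) {
  write.table(data.frame(read_id = reads$id, label = reads$truth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
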