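# all (possibly overlapping) 1-based start positions of motif in sequence
find_motif <- function(sequence, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Find restriction sites
#'
#' All exact recognition-motif occurrences (including overlapping ones),
#' sorted ascending. Palindromic motifs are scanned on one strand.
#'
#' @param sequence a character sequence or an
#'   [rdna_unit][build_unit_template].
#' @param enzyme enzyme name (see [enzyme_table()]) or a list with `motif`.
#' @return integer vector of 1-based motif start positions.
#' @export
find_sites <- function(sequence, enzyme) {
  if (inherits(sequence, "rdna_unit")) sequence <- sequence$sequence
  find_motif(sequence, get_enzyme(enzyme)$motif)
}

#' Predicted fragments of a digested tandem array
#'
#' For a tandem array of `n_units` identical units cut at `cut_positions`
#' (motif starts within one unit), fragment lengths are start-to-start
#' distances between consecutive sites; the fragment spanning the unit
#' junction has length `unit_length - (last - first)`. With no cuts the
#' whole array is one high-molecular-weight class.
#'
#' @param unit_length unit length in bp.
#' @param cut_positions 1-based motif starts within `[1, unit_length]`.
#' @param n_units number of tandem units.
#' @return a `digest_pattern` data.frame: `length`, `count`, `class`.
#' @export
digest_tandem <- function(unit_length, cut_positions, n_units = 1L) {
  cut_positions <- sort(unique(as.integer(cut_positions)))
  if (length(cut_positions) &&
      (min(cut_positions) < 1L || max(cut_positions) > unit_length))
    stop("cut positions must lie within [1, unit_length]")
  if (length(cut_positions) == 0L) {
    out <- data.frame(length = n_units * unit_length, count = 1L,
                      class = "uncut_high_MW", stringsAsFactors = FALSE)
  } else {
    lens <- c(diff(cut_positions),
              unit_length - (max(cut_positions) - min(cut_positions)))
    tab <- table(lens)
    out <- data.frame(length = as.integer(names(tab)),
                      count = as.integer(tab) * n_units,
                      class = "unmethylated_cut", stringsAsFactors = FALSE)
  }
  structure(out[order(out$length), , drop = FALSE], class = c("digest_pattern", "data.frame"))
}

# positions (1-based, within the motif) of every C, used by the
# methylation-sensitivity rules
motif_c_positions <- function(motif) which(seq_chars(motif) == "C")

# per-site cut-blocking probability for independent per-C methylation at
# probability m
block_prob <- function(enzyme, m) {
  e <- get_enzyme(enzyme)
  switch(e$meth_rule,
         insensitive = 0,
         second_C = m,
         either_C = 1 - (1 - m)^2)
}

#' Apply methylation-sensitivity rules to restriction sites
#'
#' BglII is never blocked; XhoI is blocked iff the second cytosine of its
#' motif is methylated; PstI is blocked iff either cytosine is methylated.
#' Methylation can be stochastic (per-cytosine probability `m`) or explicit
#' (logical matrix of per-site, per-cytosine flags, cytosines in motif
#' order).
#'
#' @param sites integer vector of site positions (length defines the number
#'   of sites).
#' @param enzyme enzyme name or definition.
#' @param methyl_state either a single probability in `[0, 1]` or a logical
#'   matrix `length(sites)` x number-of-cytosines-in-motif.
#' @param seed integer RNG seed (stochastic mode).
#' @return logical vector: TRUE where the site is cut.
#' @export
apply_methylation <- function(sites, enzyme, methyl_state, seed = 1L) {
  e <- get_enzyme(enzyme)
  ns <- length(sites)
  cpos <- motif_c_positions(e$motif)
  flags <- if (is.matrix(methyl_state)) {
    stopifnot(nrow(methyl_state) == ns, ncol(methyl_state) == length(cpos))
    methyl_state
  } else {
    m <- as.numeric(methyl_state)
    if (m < 0 || m > 1) stop("methylation probability must be in [0, 1]")
    with_seed(seed,
      matrix(runif(ns * length(cpos)) < m, nrow = ns, ncol = length(cpos)))
  }
  switch(e$meth_rule,
         insensitive = rep(TRUE, ns),
         second_C = !flags[, 2],
         either_C = !apply(flags, 1, any))
}

#' Fragment-length distribution of a methylated tandem array
#'
#' Simulates digestion of a circular tandem array whose sites are blocked
#' independently with the enzyme's methylation rule at per-cytosine
#' probability `m`. In the one-site-per-unit case a fragment spanning k
#' units has expected frequency (1-b) b^(k-1) with b the per-site blocking
#' probability (geometric law); the analytic expectation is returned
#' alongside the simulation for that case.
#'
#' @param unit an [rdna_unit][build_unit_template] or unit sequence; used
#'   together with `enzyme` to locate sites.
#' @param enzyme enzyme name or definition.
#' @param m per-cytosine methylation probability.
#' @param n_units units per simulated array.
#' @param n_simulations number of simulated arrays.
#' @param seed integer RNG seed.
#' @return list with `simulated` (data.frame length/count/freq),
#'   `expected` (data.frame k/length/freq, single-site case only, `NULL`
#'   otherwise), `block_prob`, `sites_per_unit`.
#' @export
fragment_distribution <- function(unit, enzyme, m, n_units = 200L,
                                  n_simulations = 50L, seed = 1L) {
  seqs <- if (inherits(unit, "rdna_unit")) unit$sequence else as.character(unit)
  L <- nchar(seqs)
  sites <- find_sites(seqs, enzyme)
  k_sites <- length(sites)
  if (k_sites == 0L) stop("no site for ", get_enzyme(enzyme)$name, " in the unit")
  b <- block_prob(enzyme, m)
  abs_sites <- as.vector(outer(sites, (seq_len(n_units) - 1L) * L, "+"))
  abs_sites <- sort(abs_sites)
  total <- n_units * L
  lens_all <- integer(0)
  uncut <- 0L
  with_seed(seed, {
    for (s in seq_len(n_simulations)) {
      cut <- apply_methylation(abs_sites, enzyme, m, seed = NULL)
      cut_at <- abs_sites[cut]
      if (length(cut_at) == 0L) { uncut <- uncut + 1L; next }
      lens <- c(diff(cut_at), total - (max(cut_at) - min(cut_at)))
      lens_all <- c(lens_all, lens)
    }
  })
  sim <- if (length(lens_all)) {
    tab <- table(lens_all)
    data.frame(length = as.integer(names(tab)), count = as.integer(tab),
               freq = as.integer(tab) / length(lens_all),
               stringsAsFactors = FALSE)
  } else data.frame(length = integer(), count = integer(), freq = numeric())
  if (uncut > 0L)
    sim <- rbind(sim, data.frame(length = total, count = uncut, freq = NA_real_))
  expected <- NULL
  if (k_sites == 1L) {
    kmax <- max(1L, if (length(lens_all)) max(lens_all) %/% L else 1L)
    k <- seq_len(kmax)
    expected <- data.frame(k = k, length = k * L, freq = (1 - b) * b^(k - 1))
  }
  list(simulated = sim, expected = expected, block_prob = b,
       sites_per_unit = k_sites)
}

# merge band lengths within a relative tolerance (gel resolution emulation)
merge_bands <- function(lengths, tol = 0.01) {
  lengths <- sort(unique(as.numeric(lengths)))
  if (length(lengths) == 0L) return(numeric(0))
  out <- lengths[1]
  for (x in lengths[-1]) {
    if (x > out[length(out)] * (1 + tol)) out <- c(out, x)
  }
  out
}

#' Predict CAPS band patterns
#'
#' Linear digestion of labelled PCR amplicons; a lane's band pattern is the
#' set of distinct fragment lengths (merged within `merge_tol` relative
#' length, emulating gel resolution) over the amplicons loaded in it. The
#' gDNA lane pools all amplicons; the cDNA lane pools only the expressed
#' labels (D only under uniparental rDNA expression).
#'
#' @param amplicons named character vector (names = labels, e.g. `D`, `S`)
#'   of amplicon sequences.
#' @param enzyme enzyme name or definition (MluI for the ITS1 assay).
#' @param expressed labels present in the cDNA lane (default `"D"`).
#' @param merge_tol relative length tolerance for band merging.
#' @return list with `per_amplicon` (fragment lengths per label), `gDNA`
#'   and `cDNA` (band length vectors), `n_bands_gdna`, `n_bands_cdna`.
#' @export
caps_predict <- function(amplicons, enzyme, expressed = "D",
                         merge_tol = 0.01) {
  stopifnot(!is.null(names(amplicons)))
  frag1 <- function(seqs) {
    L <- nchar(seqs)
    sites <- find_sites(seqs, enzyme)
    lens <- diff(c(1L, sites, L + 1L))
    lens[lens > 0L]
  }
  per <- lapply(amplicons, frag1)
  gdna <- merge_bands(unlist(per), merge_tol)
  cdna <- merge_bands(unlist(per[names(per) %in% expressed]), merge_tol)
  list(per_amplicon = per, gDNA = gdna, cDNA = cdna,
       n_bands_gdna = length(gdna), n_bands_cdna = length(cdna))
}

#' Text rendering of a virtual gel lane
#'
#' @param bands numeric band lengths (bp).
#' @param width character width of the rendering.
#' @return character vector of lines (one per band, largest on top).
#' @export
render_gel <- function(bands, width = 40L) {
  bands <- sort(bands, decreasing = TRUE)
  if (!length(bands)) return("(no bands)")
  pos <- round((1 - log10(bands) / log10(max(bands) * 1.5)) * (width - 8))
  vapply(seq_along(bands), function(i)
    sprintf("%s== %d bp", strrep(" ", max(0, pos[i])), as.integer(bands[i])), "")
}
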