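#' Restriction enzymes known to the package
#'
#' Built-in enzyme table: recognition motif and methylation-sensitivity rule.
#' BglII cuts AGATCT and is methylation insensitive; XhoI cuts CTCGAG and is
#' blocked when the second cytosine of the motif is methylated; PstI cuts
#' CTGCAG and is blocked when either cytosine is methylated. MluI (ACGCGT) is
#' used here only on PCR amplicons, which carry no methylation, and is
#' registered as insensitive.
#'
#' @format data.frame with columns `name`, `motif`,
#'   `meth_rule` (one of `insensitive`, `second_C`, `either_C`).
#' @export
enzyme_table <- function() {
  data.frame(
    name      = c("BglII",  "XhoI",   "PstI",   "MluI"),
    motif     = c("AGATCT", "CTCGAG", "CTGCAG", "ACGCGT"),
    meth_rule = c("insensitive", "second_C", "either_C", "insensitive"),
    stringsAsFactors = FALSE
  )
}

get_enzyme <- function(enzyme) {
  tab <- enzyme_table()
  if (is.list(enzyme) && all(c("name", "motif", "meth_rule") %in% names(enzyme)))
    return(enzyme[c("name", "motif", "meth_rule")])
  i <- match(enzyme, tab$name)
  if (is.na(i)) stop("unknown enzyme: ", enzyme)
  as.list(tab[i, ])
}

SUBREGION_ORDER <- c("18S", "ITS1", "5.8S", "ITS2", "25S", "IGS")

default_subregion_lengths <- function(genome_label) {
  # 18S fixed at 1810 bp (the 1.81-kb reference length); coding 5.8S/25S
  # lengths are typical grass values; spacers absorb the remainder so the
  # totals are the 8084-bp (D) and 9215-bp (S) consensus unit lengths.
  # The families share all boundaries up to the 25S end (so homologous
  # subregions sit at identical coordinates, as after a positional
  # alignment); the unit-length difference is carried by the IGS, where
  # real tandem-repeat length variation concentrates.
  if (genome_label == "D") {
    c("18S" = 1810, "ITS1" = 230, "5.8S" = 164,
      "ITS2" = 220, "25S" = 3360, "IGS" = 2300)
  } else {
    c("18S" = 1810, "ITS1" = 230, "5.8S" = 164,
      "ITS2" = 220, "25S" = 3360, "IGS" = 3431)
  }
}

default_site_plan <- function(genome_label) {
  # Both families carry the two BglII sites inside the 25S gene at the
  # S-genome consensus coordinates (3850-3855 and 5185-5190); start-to-start
  # spacing 1335 bp reproduces the 1.3-kb / 6.7-kb D-genome BglII fragments.
  # Only the D family carries the diagnostic MluI site in ITS1.
  plan <- data.frame(
    enzyme = c("BglII", "BglII", "XhoI", "PstI"),
    start  = c(3850L, 5185L, 6200L, 7000L),
    stringsAsFactors = FALSE
  )
  if (genome_label == "D") {
    plan <- rbind(plan, data.frame(enzyme = "MluI", start = 1910L))
  }
  plan[order(plan$start), , drop = FALSE]
}

#' Build an annotated 35S rDNA unit template
#'
#' Generates a random unit sequence of the requested length, tiled by the six
#' canonical subregions (18S-ITS1-5.8S-ITS2-25S-IGS, in order, no gaps), with
#' each planned restriction motif stamped exactly at its planned start and
#' scrubbed from every other position.
#'
#' @param genome_label `"D"` or `"S"` (the two homoeologous unit families of
#'   the allopolyploid; D is the shorter 8084-bp unit, S the 9215-bp one).
#' @param total_length unit length in bp; defaults to 8084 (D) / 9215 (S).
#' @param subregion_lengths named numeric vector over
#'   `c("18S","ITS1","5.8S","ITS2","25S","IGS")` summing to `total_length`.
#' @param site_plan data.frame with columns `enzyme`, `start` (1-based motif
#'   start positions to plant).
#' @param forbid character vector of enzyme names whose motifs must not occur
#'   anywhere in the sequence.
#' @param seed integer RNG seed.
#' @return an object of class `rdna_unit` with fields `sequence`,
#'   `genome_label`, `length`, `subregions` (data.frame name/start/end,
#'   1-based inclusive) and `site_plan`.
#' @export
build_unit_template <- function(genome_label = c("D", "S"),
                                total_length = NULL,
                                subregion_lengths = NULL,
                                site_plan = NULL,
                                forbid = if (genome_label == "S") "MluI" else character(),
                                seed = 1L) {
  genome_label <- match.arg(genome_label)
  if (is.null(subregion_lengths))
    subregion_lengths <- default_subregion_lengths(genome_label)
  if (is.null(total_length)) total_length <- sum(subregion_lengths)
  if (is.null(site_plan)) site_plan <- default_site_plan(genome_label)

  if (!identical(sort(names(subregion_lengths)), sort(SUBREGION_ORDER)))
    stop("subregion_lengths must name exactly: ",
         paste(SUBREGION_ORDER, collapse = ", "))
  subregion_lengths <- subregion_lengths[SUBREGION_ORDER]
  if (sum(subregion_lengths) != total_length)
    stop("subregion lengths sum to ", sum(subregion_lengths),
         ", not total_length = ", total_length)
  if (any(subregion_lengths <= 0)) stop("all subregion lengths must be > 0")

  ends <- cumsum(subregion_lengths)
  subregions <- data.frame(
    name  = SUBREGION_ORDER,
    start = c(1L, head(ends, -1L) + 1L),
    end   = as.integer(ends),
    stringsAsFactors = FALSE
  )

  site_plan <- site_plan[order(site_plan$start), , drop = FALSE]
  rownames(site_plan) <- NULL
  motifs <- vapply(site_plan$enzyme, function(e) get_enzyme(e)$motif, "")
  site_plan$motif <- unname(motifs)
  s0 <- site_plan$start
  e0 <- s0 + nchar(site_plan$motif) - 1L
  if (any(s0 < 1L) || any(e0 > total_length))
    stop("planned site falls outside the unit")
  if (nrow(site_plan) > 1L && any(s0[-1L] <= e0[-nrow(site_plan)]))
    stop("impossible placement: planned motifs overlap")

  seqc <- with_seed(seed, {
    x <- sample(DNA_BASES, total_length, replace = TRUE)
    for (i in seq_len(nrow(site_plan)))
      x[s0[i]:e0[i]] <- seq_chars(site_plan$motif[i])
    scrub_motifs(x, site_plan, forbid)
  })

  structure(
    list(sequence = paste(seqc, collapse = ""),
         genome_label = genome_label,
         length = as.integer(total_length),
         subregions = subregions,
         site_plan = site_plan),
    class = "rdna_unit"
  )
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat(sprintf("35S rDNA unit template (%s family), %d bp\n",
              x$genome_label, x$length))
  cat("subregions:\n")
  print(x$subregions, row.names = FALSE)
  cat("planned restriction sites:\n")
  print(x$site_plan, row.names = FALSE)
  invisible(x)
}

# invariant checks used by tests and by run_profile validation
validate_rdna_unit <- function(unit) {
  stopifnot(inherits(unit, "rdna_unit"), unit$length > 0,
            nchar(unit$sequence) == unit$length)
  sr <- unit$subregions
  stopifnot(identical(sr$name, SUBREGION_ORDER),
            sr$start[1] == 1L, sr$end[nrow(sr)] == unit$length,
            all(sr$start[-1] == sr$end[-nrow(sr)] + 1L))
  for (i in seq_len(nrow(unit$site_plan))) {
    p <- unit$site_plan[i, ]
    stopifnot(substr(unit$sequence, p$start,
                     p$start + nchar(p$motif) - 1L) == p$motif)
  }
  invisible(TRUE)
}

# interval of a named subregion, as c(start, end)
subregion_interval <- function(unit, name) {
  i <- match(name, unit$subregions$name)
  if (is.na(i)) stop("no such subregion: ", name)
  c(unit$subregions$start[i], unit$subregions$end[i])
}

# extract a subregion's sequence
subregion_seq <- function(unit, name) {
  iv <- subregion_interval(unit, name)
  substr(unit$sequence, iv[1], iv[2])
}

# Remove accidental occurrences of the planned (and forbidden) motifs from
# a base vector, leaving planned placements intact. Uses the ambient RNG
# stream; callers wrap in with_seed().
scrub_motifs <- function(x, site_plan, forbid = character()) {
  s0 <- site_plan$start
  e0 <- s0 + nchar(site_plan$motif) - 1L
  planned_pos <- if (nrow(site_plan))
    unlist(mapply(seq, s0, e0, SIMPLIFY = FALSE)) else integer(0)
  scrub <- unique(c(site_plan$motif,
                    vapply(forbid, function(e) get_enzyme(e)$motif, "")))
  for (iter in 1:100) {
    dirty <- FALSE
    for (m in scrub) {
      hits <- find_motif(paste(x, collapse = ""), m)
      allowed <- site_plan$start[site_plan$motif == m]
      for (h in setdiff(hits, allowed)) {
        span <- setdiff(h:(h + nchar(m) - 1L), planned_pos)
        if (length(span) == 0L)
          stop("impossible placement: accidental motif inside planned sites")
        j <- span[1L]
        x[j] <- sample(setdiff(DNA_BASES, x[j]), 1L)
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  x
}

#' Default pair of homoeologous unit templates
#'
#' Builds the D (8084 bp) and S (9215 bp) family templates. The coding
#' subregions (18S, 5.8S, 25S) of S are copied from D with
#' `coding_divergence` random substitutions per site, emulating their
#' conservation between the progenitors (so reads from either family map to
#' a shared 18S reference). The S-family ITS1 is derived from the D ITS1 by
#' substituting `its1_divergence` of its positions, one of them forced
#' inside the D MluI motif so the S ITS1 carries no MluI site — reproducing
#' the diagnostic D/S CAPS polymorphism and the roughly 10% ITS1 divergence
#' between the families. ITS2 and the IGS stay family-specific random
#' sequence (the divergent spacers).
#'
#' @param seed integer RNG seed.
#' @param its1_divergence fraction of ITS1 positions substituted between the
#'   two families (default 0.10).
#' @param coding_divergence per-site substitution rate between the two
#'   families' coding regions (default 0.01).
#' @return list with elements `D` and `S`, each an [rdna_unit][build_unit_template].
#' @export
rdna_templates <- function(seed = 1L, its1_divergence = 0.10,
                           coding_divergence = 0.01) {
  d <- build_unit_template("D", seed = derive_seed(seed, 1L))
  s <- build_unit_template("S", seed = derive_seed(seed, 2L))
  seqc <- seq_chars(s$sequence)
  planned <- unlist(mapply(
    function(st, mo) st:(st + nchar(mo) - 1L),
    s$site_plan$start, s$site_plan$motif, SIMPLIFY = FALSE))

  # conserved coding regions: copy from D, then diverge slightly
  seqc <- with_seed(derive_seed(seed, 5L), {
    for (nm in c("18S", "5.8S", "25S")) {
      ivd <- subregion_interval(d, nm); ivs <- subregion_interval(s, nm)
      stopifnot(diff(ivd) == diff(ivs))
      seqc[ivs[1]:ivs[2]] <- seq_chars(subregion_seq(d, nm))
      pos <- ivs[1]:ivs[2]
      pos <- setdiff(pos[runif(length(pos)) < coding_divergence], planned)
      for (p in pos) seqc[p] <- sample(setdiff(DNA_BASES, seqc[p]), 1L)
    }
    seqc
  })

  # diagnostic ITS1: D-derived with ~its1_divergence substitutions, MluI broken
  d_its1 <- seq_chars(subregion_seq(d, "ITS1"))
  n <- length(d_its1)
  k <- max(1L, round(its1_divergence * n))
  mlui <- d$site_plan$start[d$site_plan$enzyme == "MluI"][1] -
    subregion_interval(d, "ITS1")[1] + 1L
  s_its1 <- with_seed(derive_seed(seed, 3L), {
    pos <- sample(setdiff(seq_len(n), mlui:(mlui + 5L)), k - 1L)
    pos <- c(pos, mlui + sample(0:5, 1L))  # break the MluI motif in S
    x <- d_its1
    for (p in pos) x[p] <- sample(setdiff(DNA_BASES, x[p]), 1L)
    x
  })
  iv <- subregion_interval(s, "ITS1")
  seqc[iv[1]:iv[2]] <- s_its1

  seqc <- with_seed(derive_seed(seed, 4L),
                    scrub_motifs(seqc, s$site_plan, forbid = "MluI"))
  s$sequence <- paste(seqc, collapse = "")
  validate_rdna_unit(s)
  list(D = d, S = s)
}

#' Mutation model for intragenomic rDNA heterogeneity
#'
#' @param mode `"spacer_biased"` (substitutions confined to ITS1/ITS2/IGS —
#'   the signature of concerted evolution homogenizing the coding regions) or
#'   `"uniform"` (position-independent, the pseudogene-like landscape).
#' @param per_site_rate per-site substitution probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @export
mutation_model <- function(mode = c("spacer_biased", "uniform"),
                           per_site_rate = 0.005, seed = 1L) {
  mode <- match.arg(mode)
  if (per_site_rate < 0 || per_site_rate > 1)
    stop("per_site_rate must be in [0, 1]")
  structure(list(mode = mode, per_site_rate = per_site_rate, seed = seed),
            class = "mutation_model")
}

#' Generate unit variants under a mutation model
#'
#' Draws `n_units` copies of the template, substituting each eligible
#' position independently with the model's per-site rate. Eligible positions
#' are the spacer subregions (ITS1, ITS2, IGS) in `spacer_biased` mode and
#' every position in `uniform` mode.
#'
#' @param template an [rdna_unit][build_unit_template].
#' @param n_units number of unit copies to draw (>= 1).
#' @param model a [mutation_model()].
#' @return character vector of `n_units` sequences; attribute `"mutations"`
#'   is a list of data.frames (pos, ref, alt) recording each unit's planted
#'   substitutions, and attribute `"template"` carries the template.
#' @export
mutate_units <- function(template, n_units, model) {
  stopifnot(inherits(template, "rdna_unit"), inherits(model, "mutation_model"))
  if (n_units < 1) stop("n_units must be >= 1")
  tmpl <- seq_chars(template$sequence)
  eligible <- if (model$mode == "uniform") {
    seq_len(template$length)
  } else {
    sr <- template$subregions
    spacers <- sr[sr$name %in% c("ITS1", "ITS2", "IGS"), ]
    unlist(mapply(seq, spacers$start, spacers$end, SIMPLIFY = FALSE))
  }
  with_seed(model$seed, {
    muts <- vector("list", n_units)
    out <- character(n_units)
    for (i in seq_len(n_units)) {
      x <- tmpl
      hit <- eligible[runif(length(eligible)) < model$per_site_rate]
      alt <- character(length(hit))
      for (j in seq_along(hit)) {
        alt[j] <- sample(setdiff(DNA_BASES, x[hit[j]]), 1L)
        x[hit[j]] <- alt[j]
      }
      muts[[i]] <- data.frame(pos = hit, ref = tmpl[hit], alt = alt,
                              stringsAsFactors = FALSE)
      out[i] <- paste(x, collapse = "")
    }
    names(out) <- paste0(template$genome_label, "_unit_", seq_len(n_units))
    attr(out, "mutations") <- muts
    attr(out, "template") <- template
    out
  })
}

#' Write unit templates as FASTA with a companion subregion table
#'
#' @param units a single [rdna_unit][build_unit_template] or list of them.
#' @param fasta_path FASTA output path.
#' @param bed_path optional TSV path for the subregion annotation
#'   (unit, name, start, end; 1-based inclusive).
#' @export
write_units_fasta <- function(units, fasta_path, bed_path = NULL) {
  if (inherits(units, "rdna_unit")) units <- list(units)
  nm <- vapply(units, function(u)
    sprintf("rDNA_%s_unit_%dbp", u$genome_label, u$length), "")
  writeLines(unlist(lapply(seq_along(units), function(i)
    c(paste0(">", nm[i]), units[[i]]$sequence))), fasta_path)
  if (!is.null(bed_path)) {
    ann <- do.call(rbind, lapply(seq_along(units), function(i)
      cbind(unit = nm[i], units[[i]]$subregions)))
    write.table(ann, bed_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
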