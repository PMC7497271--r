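#' Variant-calling thresholds
#'
#' Defaults follow the basic variant-detection setting used for rDNA SNP
#' profiling: minimum read coverage 300, minimum supporting read count 30,
#' and a minimum allele frequency of 10% (high-frequency SNPs) or 1%
#' (low-frequency SNPs).
#'
#' @param min_coverage minimum countable-read coverage at the position.
#' @param min_count minimum reads supporting the allele.
#' @param min_frequency minimum allele frequency (count / coverage).
#' @export
variant_config <- function(min_coverage = 300, min_count = 30,
                           min_frequency = 0.10) {
  stopifnot(min_coverage >= 0, min_count >= 0, min_frequency >= 0)
  structure(list(min_coverage = min_coverage, min_count = min_count,
                 min_frequency = min_frequency),
            class = "variant_config")
}

subregion_of <- function(unit, pos) {
  if (is.null(unit)) return(rep(NA_character_, length(pos)))
  sr <- unit$subregions
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(sr)))
    out[pos >= sr$start[i] & pos <= sr$end[i]] <- sr$name[i]
  out
}

#' Call intragenomic variants from a mapping
#'
#' Emits one call per (position, alternative allele) where coverage, count
#' and frequency all reach their thresholds. Coverage at a position counts
#' every read whose alignment spans it (including reads deleted there);
#' frequency is per alternative allele, not pooled. Deletions are reported
#' per spanned position; insertions are left-anchored to the base before
#' the inserted sequence.
#'
#' @param mapping a [map_reads()] result.
#' @param config a [variant_config()].
#' @return data.frame with columns `position`, `subregion`, `ref`, `alt`,
#'   `type` (`substitution`/`InDel`), `count`, `coverage`, `frequency`.
#' @export
call_variants <- function(mapping, config = variant_config()) {
  refc <- seq_chars(mapping$reference)
  L <- length(refc)
  tal <- mapping$tallies
  covpos <- colSums(tal)

  pos <- integer(0); ref <- character(0); alt <- character(0)
  typ <- character(0); cnt <- integer(0); cov <- numeric(0)

  emit <- function(p, r, a, ty, n) {
    if (covpos[p] >= config$min_coverage && n >= config$min_count &&
        n / covpos[p] >= config$min_frequency - 1e-12) {
      pos <<- c(pos, p); ref <<- c(ref, r); alt <<- c(alt, a)
      typ <<- c(typ, ty); cnt <<- c(cnt, n); cov <<- c(cov, covpos[p])
    }
  }

  for (p in which(covpos > 0)) {
    for (b in DNA_BASES) {
      if (b == refc[p]) next
      n <- tal[b, p]
      if (n > 0) emit(p, refc[p], b, "substitution", n)
    }
    nd <- tal["del", p]
    if (nd > 0) emit(p, refc[p], "-", "InDel", nd)
  }
  if (nrow(mapping$insertions)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(mapping$insertions))),
                            mapping$insertions[c("pos", "seq")], sum)
    for (i in seq_len(nrow(agg)))
      emit(agg$pos[i], refc[agg$pos[i]],
           paste0("+", agg$seq[i]), "InDel", agg$count[i])
  }

  out <- data.frame(position = pos,
                    subregion = subregion_of(mapping$unit, pos),
                    ref = ref, alt = alt, type = typ, count = cnt,
                    coverage = cov, frequency = cnt / pmax(cov, 1),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$alt), , drop = FALSE]
}

#' Windowed variant counts
#'
#' Tallies calls into non-overlapping windows (1-100, 101-200, ...) tiling
#' the unit — the per-100-bp SNP columns of the heterogeneity profile —
#' and reports the maximum per-window count.
#'
#' @param variants a [call_variants()] data.frame.
#' @param window_width window width in bp (default 100).
#' @param unit_length unit length in bp.
#' @return list with `windows` (data.frame start/end/count) and `max_count`.
#' @export
window_counts <- function(variants, window_width = 100L, unit_length) {
  stopifnot(window_width >= 1)
  starts <- seq(1L, unit_length, by = window_width)
  ends <- pmin(starts + window_width - 1L, unit_length)
  idx <- ((variants$position - 1L) %/% window_width) + 1L
  counts <- tabulate(idx, nbins = length(starts))
  list(windows = data.frame(start = starts, end = ends, count = counts),
       max_count = if (length(counts)) max(counts) else 0L)
}

#' Partition calls into substitutions and InDels
#'
#' @param variants a [call_variants()] data.frame.
#' @return named vector `c(n_substitutions, n_indels)`.
#' @export
classify_variant_types <- function(variants) {
  c(n_substitutions = sum(variants$type == "substitution"),
    n_indels = sum(variants$type == "InDel"))
}

#' Write variant calls
#'
#' `write_variants_vcf` emits a minimal VCF v4.2 (INFO fields DP, AD, AF);
#' `write_variants_tsv` the flat per-call table.
#'
#' @param variants a [call_variants()] data.frame.
#' @param path output path.
#' @param chrom reference (unit) name for the CHROM column.
#' @export
write_variants_vcf <- function(variants, path, chrom = "rDNA_unit") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Coverage\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Allele depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(variants)) {
    ref <- variants$ref; alt <- variants$alt
    # VCF indel convention needs the anchor base; deletions/insertions are
    # encoded with symbolic-ish alleles built from the flat table
    alt_v <- ifelse(startsWith(alt, "+"), paste0(ref, sub("^\\+", "", alt)),
             ifelse(alt == "-", "<DEL>", alt))
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d;AF=%.6f",
                    chrom, variants$position, ref, alt_v,
                    as.integer(variants$coverage), variants$count,
                    variants$frequency)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
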