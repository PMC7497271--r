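#' Genome proportion of mapped reads
#'
#' GP = 100 x mapped / total, the percentage of library reads mapping to
#' the rDNA reference. Full precision is retained; round only when
#' reporting.
#'
#' @param mapped_reads,total_reads read counts (`mapped <= total`,
#'   `total > 0`).
#' @return GP in percent (unrounded).
#' @export
genome_proportion <- function(mapped_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(mapped_reads > total_reads)) stop("mapped_reads exceeds total_reads")
  100 * mapped_reads / total_reads
}

#' Genome space occupied by the rDNA family
#'
#' GS = genome size (Mb) x GP / 100, in Mb; computed on the unrounded GP.
#'
#' @param gp_percent unrounded GP in percent.
#' @param genome_size_mb 1C genome size in Mb.
#' @return GS in Mb (unrounded).
#' @export
genome_space <- function(gp_percent, genome_size_mb) {
  if (any(genome_size_mb <= 0)) stop("genome_size_mb must be > 0")
  genome_size_mb * gp_percent / 100
}

#' rDNA copy number per 1C
#'
#' copies = GS / reference unit size, computed on unrounded intermediates
#' and rounded half-away-from-zero to the nearest integer. The reference
#' unit is the 1.81-kb 18S rRNA gene (0.00181 Mb) by definition of the
#' read-proportion scheme.
#'
#' @param gs_mb unrounded GS in Mb.
#' @param reference_unit_mb reference unit size in Mb (default 0.00181).
#' @return integer copies per 1C.
#' @export
copy_number <- function(gs_mb, reference_unit_mb = 0.00181) {
  if (any(reference_unit_mb <= 0)) stop("reference_unit_mb must be > 0")
  as.integer(round_half_up(gs_mb / reference_unit_mb))
}

#' Convert genome size from picograms to megabases
#'
#' 1 pg = 978 Mb.
#'
#' @param picograms DNA amount per 1C in pg (>= 0).
#' @return genome size in Mb (unrounded).
#' @export
pg_to_mb <- function(picograms) {
  if (any(picograms < 0)) stop("picograms must be >= 0")
  picograms * 978
}

#' Estimate rDNA copy number from reads
#'
#' Composes the full chain: map the library against the 18S reference,
#' take the genome proportion of accepted reads, convert to genome space
#' and to copies per 1C. All intermediates are kept unrounded.
#'
#' @param reads a [read_set()] (or character sequences).
#' @param reference_18s the 18S subregion sequence (character) or an
#'   [rdna_unit][build_unit_template] whose 18S subregion is used.
#' @param genome_size_mb 1C genome size in Mb.
#' @param config an [aligner_config()].
#' @param reference_unit_mb reference unit size in Mb (default 0.00181).
#' @return object of class `copy_number_estimate` with fields
#'   `mapped_reads`, `total_reads`, `gp_percent`, `genome_size_mb`,
#'   `gs_mb`, `reference_unit_mb`, `copies_per_1c`, and the underlying
#'   `mapping`.
#' @export
estimate_copies <- function(reads, reference_18s, genome_size_mb,
                            config = aligner_config(),
                            reference_unit_mb = 0.00181) {
  if (inherits(reference_18s, "rdna_unit"))
    reference_18s <- subregion_seq(reference_18s, "18S")
  mapping <- map_reads(reads, reference_18s, config)
  gp <- genome_proportion(mapping$mapped_read_count, mapping$total_read_count)
  gs <- genome_space(gp, genome_size_mb)
  structure(
    list(mapped_reads = mapping$mapped_read_count,
         total_reads = mapping$total_read_count,
         gp_percent = gp, genome_size_mb = genome_size_mb, gs_mb = gs,
         reference_unit_mb = reference_unit_mb,
         copies_per_1c = copy_number(gs, reference_unit_mb),
         mapping = mapping),
    class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "copy_number_estimate: %d/%d reads mapped\nGP = %.2f %%, GS = %.2f Mb (genome %.0f Mb), copies per 1C = %d\n",
    x$mapped_reads, x$total_reads, round(x$gp_percent, 2),
    round(x$gs_mb, 2), x$genome_size_mb, x$copies_per_1c))
  invisible(x)
}
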