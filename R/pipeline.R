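#' End-to-end run configuration
#'
#' Bundles the per-stage parameters of a full simulated profiling run. The
#' defaults are the study conditions of the analysis the package
#' implements: two unit families (8084/9215 bp), spacer-biased
#' heterogeneity at 0.5% per site, 100-nt reads at 0.1% substitution
#' error, a 26% S-genome share, a 222-fragment homoeologue sample and 100
#' bootstrap replicates.
#'
#' @param seed global integer seed, fanned out deterministically to every
#'   stage.
#' @param n_units unit copies simulated per family.
#' @param mutation_mode,mutation_rate intragenomic heterogeneity model.
#' @param n_reads,read_length,error_rate,background_genome_size read
#'   simulation parameters.
#' @param s_fraction S-family share of the simulated library.
#' @param genome_size_mb 1C genome size in Mb (required when copy number is
#'   estimated).
#' @param estimate_copy_number run the dosage stage.
#' @param trim a [trim_config()].
#' @param aligner an [aligner_config()].
#' @param variants a [variant_config()].
#' @param window_width SNP summary window (bp).
#' @param n_fragments homoeologue sample size.
#' @param n_bootstrap bootstrap replicates for the NJ tree (0 skips the
#'   tree).
#' @param enzymes enzyme names for tandem-digest prediction.
#' @param outdir output directory (created; `NULL` = no files written).
#' @export
run_config <- function(seed = 1L, n_units = 40L,
                       mutation_mode = "spacer_biased", mutation_rate = 0.005,
                       n_reads = 2000L, read_length = 100L,
                       error_rate = 0.001, background_genome_size = 0,
                       s_fraction = 0.26, genome_size_mb = NULL,
                       estimate_copy_number = !is.null(genome_size_mb),
                       trim = trim_config(min_length = 50L),
                       aligner = aligner_config(),
                       variants = variant_config(min_coverage = 10,
                                                 min_count = 3,
                                                 min_frequency = 0.01),
                       window_width = 100L, n_fragments = 222L,
                       n_bootstrap = 100L, enzymes = "BglII",
                       outdir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

log_stage <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full in-silico rDNA profile
#'
#' Executes simulate -> trim -> map -> variants -> (dosage) -> homoeologue
#' ratio -> digest in a fixed order with per-stage seeds derived from the
#' global one, writes per-stage artifacts and a machine-readable summary
#' (JSON) when `outdir` is set, and returns the summary. Stage failures
#' abort with the stage name.
#'
#' @param config a [run_config()].
#' @return the summary list (invisibly when `outdir` is set).
#' @export
run_profile <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$estimate_copy_number && is.null(config$genome_size_mb))
    stop("validation: genome_size_mb is required when copy number is requested")
  if (config$s_fraction < 0 || config$s_fraction > 1)
    stop("validation: s_fraction must be in [0, 1]")
  outdir <- config$outdir
  logfile <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(outdir, "run.log")
    cat("", file = logfile)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_stage(logfile, "stage %-12s done in %.2f s", name,
              proc.time()[["elapsed"]] - t0)
    out
  }
  seed_of <- function(k) derive_seed(config$seed, k)

  tpl <- stage("templates", rdna_templates(seed = seed_of(10)))

  sim <- stage("simulate", {
    mkmodel <- function(k) mutation_model(config$mutation_mode,
                                          config$mutation_rate,
                                          seed = seed_of(k))
    d_units <- mutate_units(tpl$D, config$n_units, mkmodel(20))
    s_units <- mutate_units(tpl$S, config$n_units, mkmodel(21))
    nd <- config$n_reads  # oversample both families, mix down below
    d_reads <- simulate_reads(d_units, n_reads = nd,
                              read_length = config$read_length,
                              error_rate = config$error_rate,
                              background_genome_size = config$background_genome_size,
                              seed = seed_of(22))
    s_reads <- simulate_reads(s_units, n_reads = nd,
                              read_length = config$read_length,
                              error_rate = config$error_rate,
                              background_genome_size = config$background_genome_size,
                              seed = seed_of(23))
    mix <- build_mixture(d_reads, s_reads, s_fraction = config$s_fraction,
                         n_total = config$n_reads, seed = seed_of(24))
    if (!is.null(outdir)) {
      write_fastq(mix, file.path(outdir, "reads.fastq"))
      write_truth_labels(mix, file.path(outdir, "truth_labels.tsv"))
    }
    list(mix = mix, d_units = d_units, s_units = s_units)
  })

  kept <- stage("trim", {
    fl <- filter_reads(sim$mix, config$trim)
    if (!is.null(outdir))
      write.table(fl$report, file.path(outdir, "trim_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    fl$kept
  })

  mapping <- stage("map", {
    mp <- map_reads(kept, tpl$D, config$aligner)
    if (!is.null(outdir)) {
      write.table(mp$placements, file.path(outdir, "placements.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(c(">consensus_D", consensus_from_mapping(mp)),
                 file.path(outdir, "consensus.fasta"))
      cs <- coverage_summary(mp, config$window_width)
      write.table(cs, file.path(outdir, "coverage_bins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mp
  })

  vars <- stage("variants", {
    v <- call_variants(mapping, config$variants)
    if (!is.null(outdir)) {
      write_variants_tsv(v, file.path(outdir, "variants.tsv"))
      write_variants_vcf(v, file.path(outdir, "variants.vcf"),
                         chrom = "rDNA_D_unit")
    }
    v
  })
  wc <- window_counts(vars, config$window_width, tpl$D$length)

  dosage <- NULL
  if (config$estimate_copy_number) {
    dosage <- stage("dosage",
      estimate_copies(kept, tpl$D, config$genome_size_mb, config$aligner))
  }

  hom <- stage("homoeologue", {
    win <- select_diagnostic_window(subregion_seq(tpl$D, "ITS1"),
                                    subregion_seq(tpl$S, "ITS1"))
    frags <- recruit_fragments(kept, win)
    n <- min(config$n_fragments, nrow(frags))
    if (n < 2) {
      warning("fewer than 2 fragments cover the diagnostic window; ",
              "homoeologue ratios not estimated")
      list(window = win, classification = NULL, diversity = NULL,
           comparison = NULL, tree = NULL)
    } else {
    samp <- sample_fragments(frags, n, seed = seed_of(30))
    cls <- classify_fragments(samp, win)
    labelled <- cls$sample
    div <- lapply(c(D = "D", S = "S"), function(g) {
      sub <- labelled$fragment[labelled$label == g]
      if (length(sub)) haplotype_diversity(sub) else NULL
    })
    cmp <- if (!is.null(div$D) && !is.null(div$S))
      tryCatch(compare_diversity(div$D, div$S),
               error = function(e) NULL) else NULL
    tree <- NULL
    if (config$n_bootstrap > 0 && n >= 4) {
      seqs <- setNames(labelled$fragment, labelled$read_id)
      keep50 <- nchar(seqs) == win$width
      seqs <- seqs[keep50]
      if (sum(keep50) >= 4) {
        tree <- bootstrap_support(seqs, config$n_bootstrap, seed = seed_of(31))
        if (!is.null(outdir)) write_newick(tree, file.path(outdir, "its1_nj.nwk"))
      }
    }
    if (!is.null(outdir))
      write_fragments_fasta(labelled, file.path(outdir, "fragments.fasta"))
    list(window = win, classification = cls, diversity = div,
         comparison = cmp, tree = tree)
    }
  })

  dig <- stage("digest", {
    lapply(setNames(config$enzymes, config$enzymes), function(enz) {
      lapply(list(D = tpl$D, S = tpl$S), function(u)
        digest_tandem(u$length, find_sites(u, enz), n_units = config$n_units))
    })
  })
  caps <- caps_predict(
    c(D = subregion_seq(tpl$D, "ITS1"), S = subregion_seq(tpl$S, "ITS1")),
    "MluI")

  summary <- list(
    seed = config$seed,
    reads = list(simulated = config$n_reads, kept = nrow(kept),
                 mapped = mapping$mapped_read_count),
    copy_number = if (!is.null(dosage)) list(
      gp_percent = round(dosage$gp_percent, 2),
      gs_mb = round(dosage$gs_mb, 2),
      copies_per_1c = dosage$copies_per_1c),
    variants = list(
      n_calls = nrow(vars),
      types = as.list(classify_variant_types(vars)),
      max_per_window = wc$max_count),
    homoeologue = list(
      window_divergence = hom$window$divergence,
      n_D = if (!is.null(hom$classification)) hom$classification$n_D,
      n_S = if (!is.null(hom$classification)) hom$classification$n_S,
      pct_D = if (!is.null(hom$classification)) hom$classification$pct_D,
      pct_S = if (!is.null(hom$classification)) hom$classification$pct_S,
      diversity_D = if (!is.null(hom$diversity$D)) hom$diversity$D$diversity,
      diversity_S = if (!is.null(hom$diversity$S)) hom$diversity$S$diversity,
      diversity_p = if (!is.null(hom$comparison)) hom$comparison$p_value),
    digest = lapply(dig, function(enz) lapply(enz, function(p)
      list(lengths = p$length, counts = p$count))),
    caps = list(n_bands_gdna = caps$n_bands_gdna,
                n_bands_cdna = caps$n_bands_cdna))

  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(outdir)) summary else invisible(summary)
}

#' Copy-number report table
#'
#' Builds the per-genotype copy-number table (GP to 2 decimals, GS to 2
#' decimals, copies per 1C as integer; all computed on unrounded
#' intermediates).
#'
#' @param rows data.frame with columns `label`, `mapped`, `total`,
#'   `genome_mb`.
#' @param path optional TSV output path.
#' @return data.frame with columns `label`, `mapped`, `total`, `gp_percent`,
#'   `gs_mb`, `copies_per_1c`.
#' @export
table1_report <- function(rows, path = NULL) {
  stopifnot(all(c("label", "mapped", "total", "genome_mb") %in% names(rows)))
  out <- if (nrow(rows)) {
    gp <- genome_proportion(rows$mapped, rows$total)
    gs <- genome_space(gp, rows$genome_mb)
    data.frame(label = rows$label, mapped = rows$mapped, total = rows$total,
               gp_percent = round(gp, 2), gs_mb = round(gs, 2),
               copies_per_1c = copy_number(gs), stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(), mapped = numeric(), total = numeric(),
               gp_percent = numeric(), gs_mb = numeric(),
               copies_per_1c = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
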