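#' Whole-run configuration
#'
#' Bundles the per-stage configurations with the grouping level and output
#' directory. The master `seed` is pushed into every stochastic stage so a
#' run is reproducible end to end.
#'
#' @param panel a [panel_config()] (or list of its arguments).
#' @param reads a [read_sim_params()] (or list of its arguments).
#' @param filters a [filter_params()] (or list of its arguments).
#' @param level grouping level for discovery, `"subspecies"` or `"species"`.
#' @param outgroup group treated as the other species at species level.
#' @param outdir output directory.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(panel = panel_config(),
                       reads = read_sim_params(),
                       filters = filter_params(),
                       level = "subspecies",
                       outgroup = "Rainbow",
                       outdir = tempfile("rrsnp_run_"),
                       seed = 1L) {
  if (!inherits(panel, "panel_config"))
    panel <- do.call(panel_config, as.list(panel))
  if (!inherits(reads, "read_sim_params"))
    reads <- do.call(read_sim_params, as.list(reads))
  if (!inherits(filters, "filter_params"))
    filters <- do.call(filter_params, as.list(filters))
  stopifnot_scalar_number(seed, "seed", min = 0, integerish = TRUE)
  panel$seed <- as.integer(seed)
  reads$seed <- as.integer(seed)
  structure(list(panel = panel, reads = reads, filters = filters,
                 level = match.arg(level, c("subspecies", "species")),
                 outgroup = outgroup, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ww <- y$filters$window_weights
  if (!is.null(ww)) y$filters$window_weights <- as.data.frame(ww)
  run_config(panel = y$panel %||% list(),
             reads = y$reads %||% list(),
             filters = if (length(y$filters)) do.call(filter_params, y$filters)
                       else filter_params(),
             level = y$level %||% "subspecies",
             outgroup = y$outgroup %||% "Rainbow",
             outdir = y$outdir %||% tempfile("rrsnp_run_"),
             seed = y$seed %||% 1L)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  y <- lapply(config[c("panel", "reads", "filters")], function(x) {
    x <- unclass(x)
    if (!is.null(x$window_weights))
      x$window_weights <- as.list(as.data.frame(x$window_weights))
    x
  })
  y$level <- config$level; y$outgroup <- config$outgroup
  y$outdir <- config$outdir; y$seed <- config$seed
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- run-report arithmetic -------------------------------------------------
## Small, deliberately explicit helpers; every derived number the report
## prints goes through one of them.

#' Run-report arithmetic helpers
#'
#' The summary numbers a discovery run reports: the count of primer-eligible
#' SNPs after mask exclusion, a validation rate as a whole-number percent,
#' a percentage fraction, the combined variance of leading ordination axes,
#' and the assay count of a chip layout.
#'
#' @param n_pass_filters candidates passing the sequence filters (C1-C5).
#' @param n_masked of those, how many the repeat/mtDNA masks exclude.
#' @name report-arithmetic
#' @export
primer_eligible <- function(n_pass_filters, n_masked) {
  n_pass_filters - n_masked
}

#' @rdname report-arithmetic
#' @param n_validated loci that genotyped cleanly.
#' @param n_designed assays designed.
#' @export
validation_rate <- function(n_validated, n_designed) {
  round(100 * n_validated / n_designed)
}

#' @rdname report-arithmetic
#' @param part,total numerator and denominator of a percentage.
#' @export
fraction_pct <- function(part, total) round(100 * part / total)

#' @rdname report-arithmetic
#' @param ord a [pcoa()] result, or a numeric vector of per-axis
#'   variance-explained percentages.
#' @param axes number of leading axes to combine.
#' @export
combined_variance <- function(ord, axes = 2L) {
  v <- if (is.list(ord)) ord$variance_explained else ord
  sum(v[seq_len(min(axes, length(v)))])
}

#' @rdname report-arithmetic
#' @param chips number of genotyping chips.
#' @param wells assays per chip (96 on the nanofluidic arrays emulated here).
#' @export
assays_designed <- function(chips, wells = 96L)
  as.integer(chips) * as.integer(wells)

## ---------------------------------------------------------------------------

#' Run the whole pipeline: simulate, demultiplex, pile up, discover, summarize
#'
#' Stages run in a fixed order under one seed: panel simulation, in-silico
#' digestion and size selection, read simulation, MID demultiplexing,
#' truth-alignment pileup, the seven-criterion SNP discovery, and the
#' genotype-level diversity summaries on the validated loci. All outputs are
#' plain text under `config$outdir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return a `run_report` list: per-stage counts, the discovery funnel,
#'   attrition-derived summary numbers, and output paths.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  within_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## simulate
  panel <- within_stage("simulate", simulate_panel(config$panel))
  frags <- within_stage("simulate", digest_panel(panel))
  kept <- within_stage("simulate", size_select(frags, config$reads))
  sim <- within_stage("simulate",
                      simulate_reads(panel, kept, config$reads))
  paths$reference <- file.path(config$outdir, "reference.fasta")
  paths$reads <- file.path(config$outdir, "reads.fastq")
  paths$alignments <- file.path(config$outdir, "truth.sam")
  paths$masks <- file.path(config$outdir, "masks.bed")
  paths$truth_snps <- file.path(config$outdir, "truth_snps.tsv")
  write_fasta(panel$contigs, paths$reference)
  write_fastq(sim$reads, paths$reads)
  write_sam(sim$alignments, panel$contigs, paths$alignments)
  write_bed(panel$masks, paths$masks, panel$contigs)
  write_truth_tsv(panel$truth_snps, paths$truth_snps)
  retained_bases <- sum(kept$end - kept$start)
  log_line("simulate: %d fragments kept (%d bases, %.1f%% of genome), %d reads",
           nrow(kept), retained_bases,
           100 * retained_bases / sum(nchar(panel$contigs)), nrow(sim$reads))

  ## demultiplex (round trip through the FASTQ on disk)
  fq <- within_stage("demux", read_fastq(paths$reads))
  demux <- within_stage("demux", demultiplex(fq, sim$barcode_map))
  if (demux$counts[["unassigned"]] > 0L)
    warning(sprintf("%d reads left unassigned by demultiplexing",
                    demux$counts[["unassigned"]]))
  log_line("demux: %d assigned, %d unassigned",
           sum(demux$counts) - demux$counts[["unassigned"]],
           demux$counts[["unassigned"]])

  ## pileup from the truth SAM
  parsed <- within_stage("pileup",
                         parse_alignments(paths$alignments, panel$contigs))
  scheme <- group_scheme(panel$group_map)
  if (config$level == "species")
    scheme <- pool_to_species(scheme, config$outgroup)
  pile <- within_stage("pileup", build_pileup(parsed$placed, panel$contigs))
  log_line("pileup: %d covered positions", nrow(pile$site))

  ## discovery
  disc <- within_stage("discover",
                       discover_snps(pile, panel$contigs, scheme,
                                     panel$masks, config$filters))
  paths$audit <- file.path(config$outdir, "candidates_audit.tsv")
  paths$loci <- file.path(config$outdir, "validated_loci.tsv")
  paths$loci_vcf <- file.path(config$outdir, "validated_loci.vcf")
  paths$pairwise <- file.path(config$outdir, "pairwise_counts.csv")
  paths$assay_sheet <- file.path(config$outdir, "assay_sheet.csv")
  fwrite(disc$audit, paths$audit, sep = "\t")
  fwrite(disc$loci, paths$loci, sep = "\t")
  write.csv(disc$pairwise, paths$pairwise)
  log_line("discover: funnel %s",
           paste(sprintf("%s=%d", names(disc$funnel), disc$funnel),
                 collapse = " "))

  ## diversity on the validated loci
  maf <- NULL; summary <- NULL; ord <- NULL; admix <- NULL
  if (nrow(disc$loci)) {
    # verification panel: top each lineage up to ~10 genotyped individuals,
    # with diagnostic alleles nearly fixed (0.9) in their focal lineage and
    # rare (0.02) elsewhere, as wild verification samples tend to be
    extra <- max(0L, 10L - min(table(panel$group_map)))
    geno <- within_stage("diversity",
                         panel_genotypes(panel, disc$loci,
                                         extra_per_group = extra,
                                         focal_allele_freq = 0.9,
                                         offtarget_allele_freq = 0.02,
                                         seed = config$seed))
    maf <- within_stage("diversity", compute_maf(geno))
    summary <- within_stage("diversity", summarize_polymorphism(maf))
    dmat <- within_stage("diversity", allele_sharing_distance(geno))
    ord <- within_stage("diversity",
                        tryCatch(pcoa(dmat), error = function(e) NULL))
    diag_loci <- disc$loci[!is.na(focal_group),
                           .(locus_id, focal_group)]
    admix <- within_stage("diversity", admixture_index(geno, diag_loci))
    paths$maf <- file.path(config$outdir, "maf_by_group.csv")
    paths$summary <- file.path(config$outdir, "diversity_summary.csv")
    paths$distance <- file.path(config$outdir, "distance_matrix.csv")
    paths$coordinates <- file.path(config$outdir, "pcoa_coordinates.csv")
    paths$admixture <- file.path(config$outdir, "admixture_report.csv")
    fwrite(maf, paths$maf)
    fwrite(summary, paths$summary)
    write.csv(dmat, paths$distance)
    if (!is.null(ord)) {
      hdr <- paste0("# variance_explained_pct: ",
                    paste(sprintf("%.4f", ord$variance_explained),
                          collapse = ","))
      writeLines(hdr, paths$coordinates)
      suppressWarnings(write.table(ord$coordinates, paths$coordinates,
                                   sep = ",", col.names = NA, append = TRUE))
    }
    fwrite(admix, paths$admixture)
    write_assay_sheet(disc$loci, paths$assay_sheet, maf = maf,
                      flank_len = config$filters$flank_len)
    write_vcf_minimal(disc$loci, paths$loci_vcf,
                      group_af = if (!is.null(maf))
                        maf[, .(locus_id, group, af = maf)])
  }

  funnel <- disc$funnel
  report <- structure(list(
    config = config,
    counts = list(
      individuals = length(panel$individuals),
      contigs = length(panel$contigs),
      genome_bases = sum(nchar(panel$contigs)),
      fragments_total = nrow(frags),
      fragments_kept = nrow(kept),
      retained_bases = retained_bases,
      reads = nrow(sim$reads),
      reads_assigned = sum(demux$counts) - demux$counts[["unassigned"]],
      reads_unassigned = unname(demux$counts[["unassigned"]]),
      covered_positions = nrow(pile$site)),
    funnel = funnel,
    summary = list(
      primer_eligible = primer_eligible(
        funnel[["pass_c1to5"]],
        funnel[["pass_c1to5"]] - funnel[["pass_mask"]]),
      combined_variance_pct = if (!is.null(ord))
        combined_variance(ord, 2L) else NA_real_),
    maf = maf, diversity_summary = summary, ordination = ord,
    admixture = admix, pairwise = disc$pairwise,
    paths = paths,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  log_line("done in %.1f s", report$elapsed_sec)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("rrsnp run report\n")
  cat(sprintf("  genome: %s bases in %d contigs; %d individuals\n",
              format(x$counts$genome_bases, big.mark = ","),
              x$counts$contigs, x$counts$individuals))
  cat(sprintf("  reduction: %d/%d fragments kept (%.1f%% of genome)\n",
              x$counts$fragments_kept, x$counts$fragments_total,
              100 * x$counts$retained_bases / x$counts$genome_bases))
  cat(sprintf("  reads: %d (%d assigned, %d unassigned)\n",
              x$counts$reads, x$counts$reads_assigned,
              x$counts$reads_unassigned))
  cat("  funnel: ",
      paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " -> "),
      "\n", sep = "")
  cat(sprintf("  primer-eligible SNPs: %d\n", x$summary$primer_eligible))
  if (!is.na(x$summary$combined_variance_pct))
    cat(sprintf("  PCo1+PCo2 variance: %.1f%%\n",
                x$summary$combined_variance_pct))
  invisible(x)
}
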