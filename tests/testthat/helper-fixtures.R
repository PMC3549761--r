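suppressPackageStartupMessages(library(data.table))

# Small, fast panel + read settings used across tests. A relaxed size window
# (150-600 bp, vs the production default 450-600) keeps enough fragments on
# a desk-scale genome for the filters to have something to chew on.
tiny_config <- function(genome_length = 50000, n_groups = 4,
                        individuals_per_group = 3, seed = 101, ...) {
  panel_config(n_groups = n_groups,
               individuals_per_group = individuals_per_group,
               genome_length = genome_length,
               n_contigs = max(3L, genome_length %/% 12000),
               autapomorphic_rate = 1.0, shared_poly_rate = 1.0,
               within_group_rate = 0.5, repeat_fraction = 0.08,
               mtdna_contig = TRUE, paralog_rate = 0, seed = seed, ...)
}

tiny_read_params <- function(seed = 101, sub_error_rate = 0,
                             homopolymer_indel_rate = 0, mean_depth = 5,
                             ...) {
  read_sim_params(size_min = 150, size_max = 600, mean_depth = mean_depth,
                  sub_error_rate = sub_error_rate,
                  homopolymer_indel_rate = homopolymer_indel_rate,
                  seed = seed, ...)
}

# simulate panel -> reads -> placed reads ready for build_pileup()
tiny_simulation <- function(cfg = tiny_config(), ps = tiny_read_params()) {
  panel <- simulate_panel(cfg)
  kept <- size_select(digest_panel(panel), ps)
  sim <- simulate_reads(panel, kept, ps)
  placed <- sim$alignments[, .(read_id = qname, individual,
                               contig = rname, start = pos1 - 1L,
                               cigar, seq)]
  list(panel = panel, kept = kept, sim = sim, placed = placed)
}

# Hand-built placed-read table for pileup unit tests.
placed_reads <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r)
    data.table(read_id = r[[1]], individual = r[[2]], contig = r[[3]],
               start = as.integer(r[[4]]), cigar = r[[5]], seq = r[[6]])))
}

# A pileup built from explicit per-individual base counts at one position,
# by fabricating one 1-bp read per counted base.
pileup_from_counts <- function(counts, contig = "c1", pos0 = 100L,
                               contig_len = 400L) {
  rows <- list()
  k <- 0L
  for (ind in names(counts)) for (b in names(counts[[ind]])) {
    for (i in seq_len(counts[[ind]][[b]])) {
      k <- k + 1L
      rows[[k]] <- list(sprintf("%s|%04d", ind, k), ind, contig, pos0,
                        "1M", b)
    }
  }
  ref <- structure(strrep("A", contig_len), names = contig)
  build_pileup(do.call(placed_reads, rows), ref)
}
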