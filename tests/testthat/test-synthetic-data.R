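test_that("digest_genome reproduces hand-traced digests", {
  # no recognition sites
  f <- digest_genome("AAAA", "c1")
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 0L)
  expect_equal(f$end, 4L)
  expect_equal(f$left_end, "terminus")
  expect_equal(f$right_end, "terminus")

  # one EcoRI (G^AATTC) and one BfaI (C^TAG) site
  f <- digest_genome("AAAGAATTCAAACTAGAAA", "c1")
  expect_equal(f$start, c(0L, 4L, 13L))
  expect_equal(f$end, c(4L, 13L, 19L))
  expect_equal(f$left_end, c("terminus", "EcoRI", "BfaI"))
  expect_equal(f$right_end, c("EcoRI", "BfaI", "terminus"))

  # two EcoRI sites, cut after each leading G
  f <- digest_genome("GAATTCGAATTC", "c1")
  expect_equal(f$start, c(0L, 1L, 7L))
  expect_equal(f$end, c(1L, 7L, 12L))

  expect_equal(nrow(digest_genome("", "c1")), 0L)
  expect_error(digest_genome("ACGTX"), class = "rrsnp_config_error")
})

test_that("digest tiling conservation holds on random sequences", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:3000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    f <- digest_genome(s, "c")
    expect_equal(sum(f$end - f$start), n)
    expect_equal(f$start, c(0L, f$end[-nrow(f)]))   # contiguous, in order
    # concatenation of fragments reconstructs the sequence
    expect_identical(paste(substring(s, f$start + 1, f$end), collapse = ""), s)
  }
})

test_that("size_select applies inclusive bounds and mixed-end retention", {
  frags <- data.table::data.table(
    contig = "c", start = c(0L, 0L, 0L, 0L),
    end = c(450L, 449L, 500L, 600L),
    left_end = c("EcoRI", "EcoRI", "EcoRI", "BfaI"),
    right_end = c("BfaI", "BfaI", "EcoRI", "EcoRI"))
  ps <- read_sim_params(size_min = 450, size_max = 600)
  kept <- size_select(frags, ps)
  expect_equal(kept$end, c(450L, 600L))  # 449 below bound; EcoRI/EcoRI out
  ps2 <- read_sim_params(size_min = 450, size_max = 600,
                         mixed_ends_only = FALSE)
  expect_equal(nrow(size_select(frags, ps2)), 3L)
})

test_that("zero-rate panel has empty truth and reference haplotypes", {
  cfg <- panel_config(n_groups = 2, individuals_per_group = 2,
                      genome_length = 5000, n_contigs = 2,
                      autapomorphic_rate = 0, shared_poly_rate = 0,
                      within_group_rate = 0, repeat_fraction = 0,
                      mtdna_contig = FALSE, paralog_rate = 0, seed = 1)
  p <- simulate_panel(cfg)
  expect_equal(nrow(p$truth_snps), 0L)
  ind <- p$individuals[1]
  ctg <- names(p$contigs)[1]
  expect_identical(panel_haplotype(p, ind, ctg, 1), p$contigs[[ctg]])
  expect_identical(panel_haplotype(p, ind, ctg, 2), p$contigs[[ctg]])
})

test_that("same config and seed gives an identical panel", {
  cfg <- tiny_config(genome_length = 20000, seed = 5)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
})

test_that("planted variants land in the stated haplotypes", {
  cfg <- panel_config(n_groups = 2, individuals_per_group = 2,
                      genome_length = 8000, n_contigs = 2,
                      autapomorphic_rate = 0.5, shared_poly_rate = 0,
                      within_group_rate = 0, repeat_fraction = 0,
                      mtdna_contig = FALSE, paralog_rate = 0, seed = 9)
  p <- simulate_panel(cfg)
  auta <- p$truth_snps[class == "autapomorphic"]
  expect_gt(nrow(auta), 0L)
  at <- function(s, pos0) substring(s, pos0 + 1, pos0 + 1)
  for (k in seq_len(nrow(auta))) {
    s <- auta[k]
    for (ind in p$individuals) for (h in 1:2) {
      b <- at(panel_haplotype(p, ind, s$contig, h), s$pos0)
      if (p$group_map[[ind]] == s$focal_group)
        expect_identical(b, s$alt)   # fixed in the focal group
      else
        expect_identical(b, s$ref)   # absent everywhere else
    }
  }
})

test_that("truth consistency holds for every planted class", {
  p <- simulate_panel(tiny_config(genome_length = 30000, seed = 12))
  hv <- p$hap_variants
  key <- paste(hv$contig, hv$pos0)
  ts <- p$truth_snps
  # every haplotype variant corresponds to a truth row with matching alt
  m <- match(key, paste(ts$contig, ts$pos0))
  expect_false(anyNA(m))
  expect_identical(hv$alt, ts$alt[m])
  # shared polymorphisms segregate in >= 2 groups
  shared <- ts[class == "shared"]
  for (k in seq_len(min(nrow(shared), 25L))) {
    s <- shared[k]
    carriers <- hv[contig == s$contig & pos0 == s$pos0, unique(individual)]
    expect_gte(length(unique(p$group_map[carriers])), 2L)
  }
  # masks cover approximately repeat_fraction of the genome
  iv <- p$masks$intervals
  cov <- sum(iv$end - iv$start)
  expect_gt(cov / sum(nchar(p$contigs)), 0.4 * p$config$repeat_fraction)
  expect_lt(cov / sum(nchar(p$contigs)), 2.5 * p$config$repeat_fraction)
})

test_that("invalid configs name the offending field", {
  expect_error(panel_config(n_groups = 1), "n_groups",
               class = "rrsnp_config_error")
  expect_error(panel_config(genome_length = 5, n_contigs = 10),
               "genome_length", class = "rrsnp_config_error")
  expect_error(panel_config(autapomorphic_rate = -1), "autapomorphic_rate",
               class = "rrsnp_config_error")
  expect_error(read_sim_params(size_min = 700, size_max = 600), "size_min",
               class = "rrsnp_config_error")
})

test_that("zero-error reads match their haplotype at the truth placement", {
  sim <- tiny_simulation(tiny_config(genome_length = 20000, seed = 3),
                         tiny_read_params(seed = 3))
  al <- sim$sim$alignments
  expect_gt(nrow(al), 0L)
  expect_true(all(al$cigar == sprintf("%dM", nchar(al$seq))))
  idx <- sample(nrow(al), min(nrow(al), 40L))
  for (r in idx) {
    a <- al[r]
    hap1 <- panel_haplotype(sim$panel, a$individual, a$rname, 1,
                            start = a$pos1 - 1L,
                            end = a$pos1 - 1L + nchar(a$seq))
    hap2 <- panel_haplotype(sim$panel, a$individual, a$rname, 2,
                            start = a$pos1 - 1L,
                            end = a$pos1 - 1L + nchar(a$seq))
    expect_true(a$seq == hap1 || a$seq == hap2)
  }
  # reads carry their individual's barcode as a FASTQ prefix
  bm <- sim$sim$barcode_map
  expect_true(all(substr(sim$sim$reads$sequence, 1, 10) ==
                  bm[sim$sim$reads$individual]))
})

test_that("read yield and length behave as configured", {
  # mean_depth = 0 gives zero reads
  s0 <- tiny_simulation(tiny_config(genome_length = 15000, seed = 2),
                        tiny_read_params(mean_depth = 0, seed = 2))
  expect_equal(nrow(s0$sim$reads), 0L)

  # seeded defaults: empirical mean read length within 5% of 379
  cfg <- tiny_config(genome_length = 3e5, seed = 8)
  ps <- read_sim_params(seed = 8)  # production defaults incl. 450-600 window
  panel <- simulate_panel(cfg)
  kept <- size_select(digest_panel(panel), ps)
  sim <- simulate_reads(panel, kept, ps)
  expect_gt(nrow(sim$reads), 100L)
  m <- mean(nchar(sim$alignments$seq))
  expect_gt(m, 379 * 0.95)
  expect_lt(m, 379 * 1.05)

  # over-dispersion: per-individual totals vary
  tots <- table(sim$alignments$individual)
  expect_gt(max(tots) / max(1, min(tots)), 1.2)
})

test_that("barcode collisions are rejected", {
  p <- simulate_panel(tiny_config(genome_length = 12000, seed = 4))
  bm <- make_barcodes(p$individuals, length = 8, seed = 4)
  bm[[2]] <- substr(bm[[1]], 1, 4)   # make one a prefix of another
  expect_error(
    simulate_reads(p, size_select(digest_panel(p), tiny_read_params()),
                   tiny_read_params(), bm),
    "prefix", class = "rrsnp_config_error")
})

test_that("genome reduction retains a minority of the genome", {
  cfg <- tiny_config(genome_length = 3e5, seed = 8)
  panel <- simulate_panel(cfg)
  ps <- read_sim_params()  # production 450-600 window, mixed ends
  kept <- size_select(digest_panel(panel), ps)
  expect_lt(sum(kept$end - kept$start) / sum(nchar(panel$contigs)), 0.5)
})
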