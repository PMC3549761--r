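sch2 <- group_scheme(c(i1 = "WS", i2 = "YS"))

test_that("detect_candidates finds biallelic columns with fixed tie-breaks", {
  # monomorphic column: no candidate
  pl <- pileup_from_counts(list(i1 = c(A = 10)))
  expect_equal(nrow(detect_candidates(pl, sch2)), 0L)
  # 9 A / 1 T
  pl <- pileup_from_counts(list(i1 = c(A = 9), i2 = c(T = 1)))
  cand <- detect_candidates(pl, sch2)
  expect_equal(cand$major, "A")
  expect_equal(cand$minor, "T")
  # exact tie: A before C by base order
  pl <- pileup_from_counts(list(i1 = c(C = 5), i2 = c(A = 5)))
  cand <- detect_candidates(pl, sch2)
  expect_equal(cand$major, "A")
  expect_equal(cand$minor, "C")
})

test_that("classify_autapomorphy enforces strict uniqueness (criterion 1)", {
  # 19 reads of T in WS, none elsewhere -> focal WS
  pl <- pileup_from_counts(list(i1 = c(A = 20, T = 19), i2 = c(A = 20)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2)
  expect_equal(cand$focal_group, "WS")
  # 10 in WS but 2 in YS at tolerance 0 -> none
  pl <- pileup_from_counts(list(i1 = c(A = 20, T = 10), i2 = c(A = 20, T = 2)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2)
  expect_true(is.na(cand$focal_group))
  # ... but a tolerance of 2 rescues it
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2,
                                filter_params(other_group_tolerance_reads = 2))
  expect_equal(cand$focal_group, "WS")
})

test_that("species-level scheme flags species-specific SNPs", {
  gm <- c(c1i = "Westslope", c2i = "Yellowstone", ri = "Rainbow")
  pl <- pileup_from_counts(list(c1i = c(A = 10), c2i = c(A = 8),
                                ri = c(A = 1, G = 9)))
  spec <- pool_to_species(group_scheme(gm), "Rainbow")
  cand <- classify_autapomorphy(detect_candidates(pl, spec), pl, spec)
  expect_equal(cand$focal_group, "Rainbow")
})

test_that("criteria 2-5 evaluate at their printed boundaries", {
  ref <- c(c1 = strrep("A", 400))
  masks <- mask_set()
  params <- filter_params()
  audit_one <- function(counts_a, counts_b, params = filter_params()) {
    pl <- pileup_from_counts(list(i1 = counts_a, i2 = counts_b))
    cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2,
                                  params)
    audit_candidates(cand, pl, ref, sch2, masks, params)
  }
  # C4 boundary: 3/75 = 4.0% with 3 reads -> pass; 3/100 = 3% -> fail
  a <- audit_one(c(A = 72), c(C = 3))
  expect_true(a$C4)
  a <- audit_one(c(A = 97), c(C = 3))
  expect_false(a$C4)
  # fewer than 3 minor reads fails regardless of fraction
  a <- audit_one(c(A = 20), c(C = 2))
  expect_false(a$C4)
  # C2 boundary: pooled depth 8 passes, 7 fails
  a <- audit_one(c(A = 4), c(C = 4))
  expect_true(a$C2)
  a <- audit_one(c(A = 4), c(C = 3))
  expect_false(a$C2)
  # C5 boundary: focal identity 19/20 = 0.95 pass; 18/20 = 0.90 fail
  pl <- pileup_from_counts(list(i1 = c(C = 19, A = 1), i2 = c(A = 30)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2)
  expect_equal(cand$focal_group, "WS")  # C allele only in WS
  a <- audit_candidates(cand, pl, ref, sch2, masks, params)
  expect_true(a$C5)
  pl <- pileup_from_counts(list(i1 = c(C = 18, A = 2), i2 = c(A = 30)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2)
  a <- audit_candidates(cand, pl, ref, sch2, masks, params)
  expect_false(a$C5)
})

test_that("criterion 3 needs flanks on the contig and a clean zone", {
  params <- filter_params()
  sch <- sch2
  masks <- mask_set()
  # SNP at pos 100 of a 400 bp contig: flanks fine
  pl <- pileup_from_counts(list(i1 = c(A = 10), i2 = c(C = 5)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch), pl, sch, params)
  a <- audit_candidates(cand, pl, c(c1 = strrep("A", 400)), sch, masks, params)
  expect_true(a$C3)
  # same counts at pos 30: left flank too short
  pl <- pileup_from_counts(list(i1 = c(A = 10), i2 = c(C = 5)), pos0 = 30L)
  cand <- classify_autapomorphy(detect_candidates(pl, sch), pl, sch, params)
  a <- audit_candidates(cand, pl, c(c1 = strrep("A", 400)), sch, masks, params)
  expect_false(a$C3)
  # an indel-bearing read 15 bp away dirties the clean zone
  pl2b <- build_pileup(rbind(
    placed_reads(list("rI", "i1", "c1", 84, "1M1D1M", "AA")),
    data.table::data.table(read_id = sprintf("x%d", 1:15),
                           individual = rep(c("i1", "i2"), c(10, 5)),
                           contig = "c1", start = 100L, cigar = "1M",
                           seq = rep(c("A", "C"), c(10, 5)))),
    c(c1 = strrep("A", 400)))
  cand <- classify_autapomorphy(detect_candidates(pl2b, sch), pl2b, sch, params)
  cand <- cand[pos0 == 100L]
  a <- audit_candidates(cand, pl2b, c(c1 = strrep("A", 400)), sch, masks,
                        params)
  expect_false(a$C3)   # deletion at 85, |100 - 85| <= 20
})

test_that("window_score applies the banded weights and >=6 rejection", {
  p <- filter_params()
  expect_equal(window_score(integer(0), p), list(score = 0L, pass = TRUE))
  w <- window_score(c(3, 4), p)           # 3 + 3 = 6 -> reject
  expect_equal(w$score, 6L)
  expect_false(w$pass)
  w <- window_score(12, p)                # band 11-20 -> 1 < 6
  expect_equal(w$score, 1L)
  expect_true(w$pass)
  w <- window_score(c(2, 7, 15), p)       # 3 + 2 + 1 = 6 -> reject
  expect_false(w$pass)
  expect_error(window_score(0, p), "positive")
})

test_that("mask filter uses half-open intervals and mtDNA contigs", {
  ms <- mask_set(data.frame(contig = "c1", start = 100L, end = 200L),
                 mtdna_contigs = "cMT")
  cand <- data.table::data.table(contig = c("c1", "c1", "cMT"),
                                 pos0 = c(100L, 99L, 5L))
  expect_equal(mask_filter(cand, ms), c(FALSE, TRUE, FALSE))
})

test_that("one-per-contig selection keeps max depth, leftmost on ties", {
  ref <- c(cA = strrep("A", 500), cB = strrep("C", 500), cC = strrep("G", 500))
  mk <- function(contig, pos0, depth) data.table::data.table(
    contig = contig, pos0 = pos0, major = "A", minor = "G",
    n_major = depth - 3L, n_minor = 3L, depth_acgt = depth,
    depth_total = depth, focal_group = "G1",
    C1 = TRUE, C2 = TRUE, C3 = TRUE, C4 = TRUE, C5 = TRUE, C6 = TRUE,
    W = TRUE, w_score = 0L, pass_all = TRUE)
  passing <- rbind(mk("cA", 100L, 20L), mk("cA", 300L, 25L),
                   mk("cB", 50L, 15L), mk("cB", 400L, 15L),
                   mk("cC", 60L, 9L), mk("cC", 70L, 8L), mk("cC", 80L, 7L))
  loci <- select_one_per_contig(passing, ref)
  expect_equal(nrow(loci), 3L)                       # one per contig
  expect_equal(loci[contig == "cA", pos0], 300L)     # higher depth wins
  expect_equal(loci[contig == "cB", pos0], 50L)      # tie -> leftmost
  expect_equal(anyDuplicated(loci$contig), 0L)
  expect_true(all(nchar(loci$left_flank) == 50L))
  expect_true(all(nchar(loci$right_flank) == 50L))
})

test_that("flank extraction matches the coordinate contract", {
  ref <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")  # 200 bp
  fl <- extract_flanks(ref, 50L, "A", "G", 50L)
  expect_identical(fl$left, substring(ref, 1, 50))     # bases 0..49
  expect_identical(fl$right, substring(ref, 52, 101))
  expect_match(fl$bracket_context, "\\[A/G\\]", fixed = FALSE)
  expect_error(extract_flanks(ref, 49L, "A", "G", 50L), "overrun")
})

test_that("pairwise counts match brute force on a three-group toy", {
  sch3 <- group_scheme(c(a1 = "A", b1 = "B", c1i = "C"))
  # one SNP diagnostic for A (pos 100), two more for A and one for B
  pl <- build_pileup(rbind(
    placed_reads(
      list("a1|1", "a1", "c1", 95, "10M", "GGGGGTGGGG"),  # T at 100, A-only
      list("a1|2", "a1", "c1", 95, "10M", "GGGGGTGGGG"),
      list("b1|1", "b1", "c1", 95, "10M", "GGGGGGGGGG"),
      list("c1i|1", "c1i", "c1", 95, "10M", "GGGGGGGGGG"))),
    c(c1 = strrep("G", 300)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch3), pl, sch3)
  m <- pairwise_counts(cand, pl, sch3)
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["A", "C"], 1L)
  expect_equal(m["B", "A"], 0L)
  expect_true(is.na(m["A", "A"]))
  # no candidates -> all-zero matrix
  m0 <- pairwise_counts(cand[0], pl, sch3)
  expect_true(all(m0 == 0L, na.rm = TRUE))
})

test_that("audit records every criterion independently", {
  # candidate failing C2 and C4 still gets C3/C6 verdicts
  pl <- pileup_from_counts(list(i1 = c(A = 3), i2 = c(C = 1)))
  cand <- classify_autapomorphy(detect_candidates(pl, sch2), pl, sch2)
  a <- audit_candidates(cand, pl, c(c1 = strrep("A", 400)), sch2, mask_set(),
                        filter_params())
  expect_false(a$C2)
  expect_false(a$C4)
  expect_true(a$C3)
  expect_true(a$C6)
  expect_false(a$pass_all)
  expect_true(all(c("C1", "C2", "C3", "C4", "C5", "C6", "W") %in% names(a)))
})

test_that("filter monotonicity: tightening thresholds never adds passes", {
  sims <- tiny_simulation(tiny_config(genome_length = 40000, seed = 31),
                          tiny_read_params(seed = 31))
  pl <- build_pileup(sims$placed, sims$panel$contigs)
  sch <- group_scheme(sims$panel$group_map)
  base_params <- filter_params(min_depth = 4)
  cand <- classify_autapomorphy(detect_candidates(pl, sch), pl, sch,
                                base_params)
  n_pass <- function(params) {
    a <- audit_candidates(cand, pl, sims$panel$contigs, sch,
                          sims$panel$masks, params)
    sum(a$pass_all)
  }
  n0 <- n_pass(base_params)
  expect_lte(n_pass(filter_params(min_depth = 12)), n0)
  expect_lte(n_pass(filter_params(min_depth = 4, min_minor_reads = 6)), n0)
  expect_lte(n_pass(filter_params(min_depth = 4, min_minor_fraction = 0.2)),
             n0)
  expect_lte(n_pass(filter_params(min_depth = 4, min_group_identity = 1.0)),
             n0)
  # enlarging masks never increases the count
  big_masks <- mask_set(
    data.frame(contig = names(sims$panel$contigs)[1], start = 0L,
               end = nchar(sims$panel$contigs[[1]])),
    mtdna_contigs = sims$panel$masks$mtdna_contigs)
  a0 <- audit_candidates(cand, pl, sims$panel$contigs, sch,
                         sims$panel$masks, base_params)
  a1 <- audit_candidates(cand, pl, sims$panel$contigs, sch, big_masks,
                         base_params)
  expect_lte(sum(a1$pass_all), sum(a0$pass_all))
})
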