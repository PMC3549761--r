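#' Parameters of the seven-criterion diagnostic SNP filter
#'
#' Defaults are the published thresholds of the selection procedure:
#' pooled depth >= 8 (C2), 50 bp of flank with a 20 bp indel/ambiguity-free
#' zone (C3), minor allele >= 3 reads and >= 4% of alleles (C4), >= 95%
#' identity within the focal subspecies (C5). The position-weighted window
#' filter rejects at a total score >= 6; only that threshold is published --
#' the 20 bp radius and the banded weights (3 within 1-5 bp, 2 within
#' 6-10 bp, 1 within 11-20 bp) are this package's documented defaults and
#' are fully configurable.
#'
#' @param min_depth minimum pooled read depth at the SNP (C2).
#' @param flank_len required reference flank on either side, bases (C3).
#' @param clean_zone no indels/ambiguities within this many bases (C3).
#' @param min_minor_reads minimum minor-allele read count (C4).
#' @param min_minor_fraction minimum minor-allele fraction of called
#'   A/C/G/T alleles (C4).
#' @param min_group_identity minimum fraction of focal-group reads carrying
#'   the focal (variant) allele (C5).
#' @param window_radius window filter radius in bases.
#' @param window_weights data.frame with columns `from`, `to`, `weight`:
#'   score contributed by a polymorphic neighbor at each distance band.
#' @param window_reject_threshold reject when the summed score reaches this.
#' @param other_group_tolerance_reads reads of the variant allele tolerated
#'   in non-focal groups before uniqueness (C1) fails; strict 0 by default.
#' @param min_poly_reads a neighboring position counts as polymorphic for
#'   the window filter when >= 2 alleles each have this many reads
#'   (unguarded singletons are sequencing noise at 454 error rates).
#' @return a validated `filter_params` list.
#' @export
filter_params <- function(min_depth = 8L,
                          flank_len = 50L,
                          clean_zone = 20L,
                          min_minor_reads = 3L,
                          min_minor_fraction = 0.04,
                          min_group_identity = 0.95,
                          window_radius = 20L,
                          window_weights = data.frame(
                            from = c(1L, 6L, 11L),
                            to = c(5L, 10L, 20L),
                            weight = c(3L, 2L, 1L)),
                          window_reject_threshold = 6L,
                          other_group_tolerance_reads = 0L,
                          min_poly_reads = 2L) {
  for (f in c("min_depth", "flank_len", "clean_zone", "min_minor_reads",
              "window_radius", "window_reject_threshold",
              "other_group_tolerance_reads", "min_poly_reads"))
    stopifnot_scalar_number(get(f), f, min = 0, integerish = TRUE)
  stopifnot_scalar_number(min_minor_fraction, "min_minor_fraction",
                          min = 0, max = 1)
  stopifnot_scalar_number(min_group_identity, "min_group_identity",
                          min = 0, max = 1)
  if (window_radius > flank_len)
    config_error("window_radius", "must be <= flank_len")
  ww <- as.data.frame(window_weights)
  if (!all(c("from", "to", "weight") %in% names(ww)))
    config_error("window_weights", "needs columns from, to, weight")
  structure(list(min_depth = as.integer(min_depth),
                 flank_len = as.integer(flank_len),
                 clean_zone = as.integer(clean_zone),
                 min_minor_reads = as.integer(min_minor_reads),
                 min_minor_fraction = min_minor_fraction,
                 min_group_identity = min_group_identity,
                 window_radius = as.integer(window_radius),
                 window_weights = ww,
                 window_reject_threshold = as.integer(window_reject_threshold),
                 other_group_tolerance_reads =
                   as.integer(other_group_tolerance_reads),
                 min_poly_reads = as.integer(min_poly_reads)),
            class = "filter_params")
}

#' Detect candidate SNP columns
#'
#' Emits one candidate per covered position where at least two distinct
#' A/C/G/T bases are each supported by at least one read. The major allele
#' is the most frequent pooled base and the minor the second most frequent;
#' ties break by the fixed base order A < C < G < T.
#'
#' @param pileup a [build_pileup()] result.
#' @param scheme a [group_scheme()].
#' @return data.table: contig, pos0, major, minor, n_major, n_minor,
#'   depth_acgt (called-allele depth), depth_total (incl. N calls).
#' @export
detect_candidates <- function(pileup, scheme) {
  gb <- group_base_counts(pileup, scheme)
  pooled <- gb$pooled
  acgt <- pooled[base %in% BASES]
  # order so that the top rows per position are (highest n, first base)
  acgt[, base_rank := match(base, BASES)]
  setorder(acgt, contig, pos0, -n, base_rank)
  acgt[, idx := seq_len(.N), by = .(contig, pos0)]
  nallele <- acgt[, .(n_alleles = .N, depth_acgt = sum(n)),
                  by = .(contig, pos0)]
  empty <- data.table(contig = character(), pos0 = integer(),
                      major = character(), minor = character(),
                      n_major = integer(), n_minor = integer(),
                      depth_acgt = integer(), depth_total = integer())
  if (!any(nallele$n_alleles >= 2L)) return(empty)
  top2 <- data.table::dcast(acgt[idx <= 2L], contig + pos0 ~ idx,
                            value.var = c("base", "n"))
  cand <- merge(top2, nallele, by = c("contig", "pos0"))
  cand <- cand[n_alleles >= 2L]
  tot <- pooled[, .(depth_total = sum(n)), by = .(contig, pos0)]
  cand <- merge(cand, tot, by = c("contig", "pos0"))
  setnames(cand, c("base_1", "base_2", "n_1", "n_2"),
           c("major", "minor", "n_major", "n_minor"))
  setorder(cand, contig, pos0)
  cand[, .(contig, pos0, major, minor, n_major, n_minor,
           depth_acgt, depth_total)]
}

#' Classify candidate autapomorphy (criterion 1)
#'
#' A candidate is autapomorphic for group G when its minor (variant) allele
#' is observed in G and in every other group at no more than
#' `other_group_tolerance_reads` reads (strictly zero by default). Works for
#' subspecies-level schemes and, with a pooled species-level scheme, flags
#' species-diagnostic SNPs the same way.
#'
#' @param candidates from [detect_candidates()].
#' @param pileup the pileup the candidates came from.
#' @param scheme a [group_scheme()].
#' @param params a [filter_params()].
#' @return `candidates` with a `focal_group` column (`NA` when not unique to
#'   any single group).
#' @export
classify_autapomorphy <- function(candidates, pileup, scheme,
                                  params = filter_params()) {
  cand <- data.table::copy(candidates)
  if (nrow(cand) == 0L) {
    cand[, focal_group := character(0)]
    return(cand)
  }
  grouped <- group_base_counts(pileup, scheme)$grouped
  mg <- merge(cand[, .(contig, pos0, minor)],
              grouped, by = c("contig", "pos0"),
              allow.cartesian = TRUE)
  mg <- mg[base == minor]
  focal <- mg[, {
    o <- order(-n, group)
    top <- group[o[1]]
    others <- n[group != top]
    ok <- n[o[1]] >= 1L &&
      (length(others) == 0L || max(others) <= params$other_group_tolerance_reads)
    .(focal_group = if (ok) top else NA_character_)
  }, by = .(contig, pos0)]
  out <- merge(cand, focal, by = c("contig", "pos0"), all.x = TRUE)
  setorder(out, contig, pos0)
  out
}

#' Score the position-weighted window filter
#'
#' Every guarded polymorphism within the window contributes a score that
#' depends on its distance from the focal SNP; the filter fails (the SNP is
#' treated as residing in a misaligned or paralogous region) when the summed
#' score reaches the rejection threshold.
#'
#' @param distances positive integer distances (in bases) of neighboring
#'   polymorphic positions; must be <= `window_radius`.
#' @param params a [filter_params()].
#' @return list with `score` and `pass`.
#' @export
window_score <- function(distances, params = filter_params()) {
  if (length(distances) == 0L)
    return(list(score = 0L, pass = TRUE))
  if (any(distances <= 0L))
    stop("distance 0 is the SNP itself; window distances must be positive")
  if (any(distances > params$window_radius))
    stop("window distances must be <= window_radius")
  ww <- params$window_weights
  w <- vapply(distances, function(d) {
    hit <- which(d >= ww$from & d <= ww$to)
    if (length(hit)) ww$weight[hit[1]] else 0L
  }, numeric(1))
  score <- as.integer(sum(w))
  list(score = score, pass = score < params$window_reject_threshold)
}

#' Criterion-6 mask filter
#' @param candidates candidate table (contig, pos0).
#' @param masks a [mask_set()].
#' @return logical vector: TRUE = pass (not masked).
#' @export
mask_filter <- function(candidates, masks) {
  !in_mask(masks, candidates$contig, candidates$pos0)
}

#' Extract flanks and bracket context for one SNP
#'
#' @param reference_seq the contig sequence.
#' @param pos0 0-based SNP position.
#' @param major,minor alleles.
#' @param flank_len flank length.
#' @return list(left, right, bracket_context).
#' @export
extract_flanks <- function(reference_seq, pos0, major, minor,
                           flank_len = 50L) {
  n <- nchar(reference_seq)
  if (pos0 < flank_len || n - pos0 - 1L < flank_len)
    stop(sprintf(
      "flank of %d bases overruns the contig at pos0=%d (length %d)",
      flank_len, pos0, n))
  left <- substring(reference_seq, pos0 - flank_len + 1L, pos0)
  right <- substring(reference_seq, pos0 + 2L, pos0 + 1L + flank_len)
  list(left = left, right = right,
       bracket_context = paste0(left, "[", major, "/", minor, "]", right))
}

# Positions that count as "polymorphic" for the window filter: >= 2 called
# alleles each supported by >= min_poly_reads reads (pooled).
guarded_polymorphic_positions <- function(pileup, scheme, params) {
  pooled <- group_base_counts(pileup, scheme)$pooled
  pooled[base %in% BASES & n >= params$min_poly_reads,
         .(n_guarded = .N), by = .(contig, pos0)][n_guarded >= 2L,
                                                  .(contig, pos0)]
}

#' Run the full per-candidate filter audit
#'
#' Evaluates every criterion independently for every candidate (no
#' short-circuiting), so the audit trail records each verdict regardless of
#' the others. C5 needs a focal group and is `NA` where criterion 1 failed.
#'
#' @param candidates output of [classify_autapomorphy()] (focal_group set).
#' @param pileup the pileup.
#' @param reference named character vector of contigs.
#' @param scheme a [group_scheme()].
#' @param masks a [mask_set()].
#' @param params a [filter_params()].
#' @return `candidates` plus logical columns C1..C6, W (window), `w_score`,
#'   and `pass_all` (conjunction; `NA` counts as fail).
#' @export
audit_candidates <- function(candidates, pileup, reference, scheme, masks,
                             params = filter_params()) {
  cand <- data.table::copy(candidates)
  if (!"focal_group" %in% names(cand))
    stop("candidates must carry focal_group; run classify_autapomorphy() first")
  n <- nrow(cand)
  if (n == 0L) {
    for (col in c("C1", "C2", "C3", "C4", "C5", "C6", "W", "pass_all"))
      cand[, (col) := logical(0)]
    cand[, w_score := integer(0)]
    return(cand)
  }

  cand[, C1 := !is.na(focal_group)]
  cand[, C2 := depth_total >= params$min_depth]

  ## C3: flanks on the reference plus a clean zone in the pileup
  clen <- structure(nchar(reference), names = names(reference))
  has_flanks <- cand$pos0 >= params$flank_len &
    (clen[cand$contig] - cand$pos0 - 1L) >= params$flank_len
  dirty <- pileup$site[indel_evidence > 0L | ambiguous_evidence > 0L,
                       .(contig, pos0)]
  clean <- rep(TRUE, n)
  if (nrow(dirty)) {
    win <- cand[, .(contig, start = pos0 - params$clean_zone,
                    end = pos0 + params$clean_zone, idx = seq_len(n))]
    setkey(win, contig, start, end)
    pts <- dirty[, .(contig, start = pos0, end = pos0)]
    ov <- data.table::foverlaps(pts, win, type = "within",
                                by.x = c("contig", "start", "end"),
                                nomatch = NULL)
    clean[unique(ov$idx)] <- FALSE
  }
  cand[, C3 := has_flanks & clean]

  cand[, C4 := n_minor >= params$min_minor_reads &
         n_minor / depth_acgt >= params$min_minor_fraction]

  ## C5: identity of the focal group for the variant allele
  grouped <- group_base_counts(pileup, scheme)$grouped
  foc <- cand[!is.na(focal_group), .(contig, pos0, minor, focal_group)]
  cand[, C5 := NA]
  if (nrow(foc)) {
    fg <- merge(foc, grouped[base %in% BASES],
                by = c("contig", "pos0"), allow.cartesian = TRUE)
    fg <- fg[group == focal_group]
    ident <- fg[, .(identity = sum(n[base == minor]) / sum(n)),
                by = .(contig, pos0)]
    cand[ident, on = c("contig", "pos0"),
         C5 := i.identity >= params$min_group_identity]
  }

  cand[, C6 := mask_filter(cand, masks)]

  ## window filter
  poly <- guarded_polymorphic_positions(pileup, scheme, params)
  scores <- integer(n)
  if (nrow(poly)) {
    setkey(poly, contig, pos0)
    for (i in seq_len(n)) {
      nb <- poly[contig == cand$contig[i] &
                 pos0 >= cand$pos0[i] - params$window_radius &
                 pos0 <= cand$pos0[i] + params$window_radius &
                 pos0 != cand$pos0[i]]
      if (nrow(nb))
        scores[i] <- window_score(abs(nb$pos0 - cand$pos0[i]),
                                  params)$score
    }
  }
  cand[, w_score := scores]
  cand[, W := w_score < params$window_reject_threshold]

  cand[, pass_all := C1 & C2 & C3 & !is.na(C5) & C5 & C4 & C6 & W]
  cand[is.na(pass_all), pass_all := FALSE]
  setorder(cand, contig, pos0)
  cand
}

#' Criterion-7 selection: one locus per contig
#'
#' Among candidates passing every other criterion, keeps exactly one per
#' contig -- the one with maximum pooled depth, ties broken by the smallest
#' position -- and extracts its flanks from the reference.
#'
#' @param passing audited candidates with `pass_all == TRUE`.
#' @param reference named character vector of contigs.
#' @param params a [filter_params()].
#' @return validated locus table: locus_id, contig, pos0, focal_group,
#'   major, minor, depth, left_flank, right_flank, bracket_context.
#' @export
select_one_per_contig <- function(passing, reference,
                                  params = filter_params()) {
  passing <- as.data.table(passing)
  empty <- data.table(locus_id = character(), contig = character(),
                      pos0 = integer(), focal_group = character(),
                      major = character(), minor = character(),
                      depth = integer(), left_flank = character(),
                      right_flank = character(), bracket_context = character())
  if (nrow(passing) == 0L) return(empty)
  setorder(passing, contig, -depth_total, pos0)
  sel <- passing[, .SD[1L], by = contig]
  fl <- lapply(seq_len(nrow(sel)), function(i)
    extract_flanks(reference[[sel$contig[i]]], sel$pos0[i],
                   sel$major[i], sel$minor[i], params$flank_len))
  out <- sel[, .(locus_id = sprintf("%s_%d", contig, pos0 + 1L),
                 contig, pos0, focal_group, major, minor,
                 depth = depth_total)]
  out[, left_flank := vapply(fl, `[[`, character(1), "left")]
  out[, right_flank := vapply(fl, `[[`, character(1), "right")]
  out[, bracket_context := vapply(fl, `[[`, character(1), "bracket_context")]
  setorder(out, contig, pos0)
  out
}

#' Pairwise putative-SNP counts between groups
#'
#' Entry (A, B) counts candidates whose focal group is A and whose
#' group-consensus base in A differs from the consensus in B (groups with no
#' reads at the column contribute nothing). The diagonal is `NA`.
#'
#' @param candidates audited candidates (typically those passing C2-C5).
#' @param pileup the pileup.
#' @param scheme a [group_scheme()].
#' @return integer matrix, groups x groups.
#' @export
pairwise_counts <- function(candidates, pileup, scheme) {
  groups <- scheme$groups
  m <- matrix(0L, length(groups), length(groups),
              dimnames = list(groups, groups))
  diag(m) <- NA_integer_
  cand <- as.data.table(candidates)[!is.na(focal_group)]
  if (nrow(cand) == 0L) return(m)
  grouped <- group_base_counts(pileup, scheme)$grouped[base %in% BASES]
  cons <- grouped[, {
    o <- order(-n, match(base, BASES))
    .(consensus = base[o[1]])
  }, by = .(contig, pos0, group)]
  cc <- merge(cand[, .(contig, pos0, focal_group)], cons,
              by = c("contig", "pos0"), allow.cartesian = TRUE)
  focal_cons <- cc[group == focal_group,
                   .(contig, pos0, focal_group, focal_base = consensus)]
  other <- merge(cc[group != focal_group], focal_cons,
                 by = c("contig", "pos0", "focal_group"))
  diffs <- other[consensus != focal_base,
                 .(count = .N), by = .(focal_group, group)]
  for (k in seq_len(nrow(diffs)))
    m[diffs$focal_group[k], diffs$group[k]] <- diffs$count[k]
  m
}

#' Run the whole discovery procedure
#'
#' Candidate detection, autapomorphy classification, criteria 2-6, the
#' position-weighted window filter, and one-per-contig selection, with a
#' funnel of counts after each stage.
#'
#' @param pileup a [build_pileup()] result.
#' @param reference named character vector of contigs.
#' @param scheme a [group_scheme()].
#' @param masks a [mask_set()].
#' @param params a [filter_params()].
#' @return list: `audit` (per-candidate criterion table), `loci` (validated
#'   loci), `funnel` (named counts), `pairwise` (matrix).
#' @export
discover_snps <- function(pileup, reference, scheme, masks = mask_set(),
                          params = filter_params()) {
  cand <- detect_candidates(pileup, scheme)
  cand <- classify_autapomorphy(cand, pileup, scheme, params)
  audit <- audit_candidates(cand, pileup, reference, scheme, masks, params)
  pass25 <- audit$C1 & audit$C2 & audit$C3 & audit$C4 &
    !is.na(audit$C5) & audit$C5
  funnel <- c(
    candidates = nrow(audit),
    pass_c1 = sum(audit$C1),
    pass_c1to5 = sum(pass25),
    pass_mask = sum(pass25 & audit$C6),
    pass_window = sum(audit$pass_all),
    loci = NA_integer_)
  loci <- select_one_per_contig(audit[audit$pass_all == TRUE], reference,
                                params)
  funnel[["loci"]] <- nrow(loci)
  pairwise <- pairwise_counts(audit[pass25], pileup, scheme)
  list(audit = audit, loci = loci, funnel = funnel, pairwise = pairwise)
}
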