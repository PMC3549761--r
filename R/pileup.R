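#' Grouping scheme for individuals
#'
#' Maps each individual to a lineage group, either at subspecies level (the
#' default: every lineage its own group) or at species level, where all
#' ingroup lineages are pooled against the outgroup -- the comparison used to
#' call species-diagnostic rather than subspecies-diagnostic SNPs.
#'
#' @param group_of named character vector `individual -> group`.
#' @param level `"subspecies"` or `"species"`.
#' @return a `group_scheme` list.
#' @export
group_scheme <- function(group_of, level = c("subspecies", "species")) {
  level <- match.arg(level)
  if (is.null(names(group_of)) || anyDuplicated(names(group_of)))
    config_error("group_of", "must be named by unique individual ids")
  if (length(unique(group_of)) < 2L)
    config_error("group_of", "needs at least 2 groups")
  structure(list(level = level, group_of = group_of,
                 groups = unique(unname(group_of))),
            class = "group_scheme")
}

#' Pool a subspecies scheme to species level
#'
#' @param scheme a subspecies-level [group_scheme()].
#' @param outgroup the group label to keep separate (e.g. the rainbow-trout
#'   outgroup); all other groups are pooled under `pooled_label`.
#' @param pooled_label label for the pooled ingroup.
#' @export
pool_to_species <- function(scheme, outgroup, pooled_label = "Cutthroat") {
  if (!outgroup %in% scheme$groups)
    config_error("outgroup", sprintf("'%s' is not a group label", outgroup))
  g <- ifelse(scheme$group_of == outgroup, outgroup, pooled_label)
  names(g) <- names(scheme$group_of)
  group_scheme(g, level = "species")
}

# Parse a vector of CIGAR strings into per-read op tables.
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNS]", cigar)
  ops <- regmatches(cigar, m)
  lapply(ops, function(o) {
    if (length(o) == 0L || (length(o) == 1L && is.na(o)))
      format_error("unparseable CIGAR string")
    list(len = as.integer(sub(".$", "", o)), op = substring(o, nchar(o)))
  })
}

#' Build a per-position, per-individual allele-count pileup
#'
#' Walks every placed read's CIGAR and tallies A/C/G/T/N calls per reference
#' position per individual. Deletions contribute `indel_evidence` at every
#' deleted position but no base count; insertions add evidence at the
#' flanking reference position on each side; `N` calls count toward depth and
#' `ambiguous_evidence` but never toward an allele. Counts are raw: no base-
#' or mapping-quality weighting.
#'
#' @param placed data.table of placed reads (read_id, individual, contig,
#'   start [0-based], cigar, seq), e.g. from [parse_alignments()].
#' @param reference named character vector of contig sequences.
#' @return a `pileup` list: `counts` (contig, pos0, individual, base, n),
#'   `site` (contig, pos0, indel_evidence, ambiguous_evidence),
#'   `individuals`, `contig_lengths`.
#' @export
build_pileup <- function(placed, reference) {
  placed <- as.data.table(placed)
  clen <- structure(nchar(reference), names = names(reference))
  empty_counts <- data.table(contig = character(), pos0 = integer(),
                             individual = character(), base = character(),
                             n = integer())
  empty_site <- data.table(contig = character(), pos0 = integer(),
                           indel_evidence = integer(),
                           ambiguous_evidence = integer())
  if (nrow(placed) == 0L)
    return(structure(list(counts = empty_counts, site = empty_site,
                          individuals = character(0), contig_lengths = clen),
                     class = "pileup"))

  simple <- placed$cigar == sprintf("%dM", nchar(placed$seq))
  base_rows <- list()
  indel_rows <- list()

  check_overhang <- function(read_id, contig, start, ref_len) {
    over <- start + ref_len > clen[contig]
    if (any(over))
      format_error(sprintf("read '%s' overhangs the end of contig '%s'",
                           read_id[which(over)[1]], contig[which(over)[1]]))
  }

  if (any(simple)) {
    p <- placed[simple]
    len <- nchar(p$seq)
    check_overhang(p$read_id, p$contig, p$start, len)
    base_rows[[1L]] <- data.table(
      contig = rep(p$contig, len),
      pos0 = as.integer(sequence(len, from = p$start)),
      individual = rep(p$individual, len),
      base = unlist(strsplit(p$seq, "", fixed = TRUE), use.names = FALSE))
  }

  if (any(!simple)) {
    p <- placed[!simple]
    cig <- parse_cigar(p$cigar)
    for (r in seq_len(nrow(p))) {
      len <- cig[[r]]$len; op <- cig[[r]]$op
      bad <- setdiff(op, c("M", "I", "D", "N", "S"))
      if (length(bad))
        format_error(sprintf("unsupported CIGAR op '%s' in read '%s'",
                             bad[1], p$read_id[r]))
      ref_len <- sum(len[op %in% c("M", "D", "N")])
      check_overhang(p$read_id[r], p$contig[r], p$start[r], ref_len)
      rp <- p$start[r]   # reference cursor (0-based)
      qp <- 0L           # query cursor
      sv <- chars(p$seq[r])
      for (k in seq_along(op)) {
        l <- len[k]
        if (op[k] == "M") {
          base_rows[[length(base_rows) + 1L]] <- data.table(
            contig = p$contig[r], pos0 = rp + seq_len(l) - 1L,
            individual = p$individual[r], base = sv[qp + seq_len(l)])
          rp <- rp + l; qp <- qp + l
        } else if (op[k] == "D" || op[k] == "N") {
          if (op[k] == "D")
            indel_rows[[length(indel_rows) + 1L]] <- data.table(
              contig = p$contig[r], pos0 = rp + seq_len(l) - 1L)
          rp <- rp + l
        } else if (op[k] == "I") {
          # evidence on the flanking reference base to each side
          ev <- c(rp - 1L, rp)
          ev <- ev[ev >= 0L & ev < clen[p$contig[r]]]
          if (length(ev))
            indel_rows[[length(indel_rows) + 1L]] <- data.table(
              contig = p$contig[r], pos0 = ev)
          qp <- qp + l
        } else {  # S: clipped query bases
          qp <- qp + l
        }
      }
    }
  }

  allb <- rbindlist(base_rows)
  allb[, base := toupper(base)]
  allb[!base %in% BASES, base := "N"]
  counts <- allb[, .(n = .N), by = .(contig, pos0, individual, base)]
  setorder(counts, contig, pos0, individual, base)

  amb <- allb[base == "N", .(ambiguous_evidence = .N), by = .(contig, pos0)]
  ind <- if (length(indel_rows))
    rbindlist(indel_rows)[, .(indel_evidence = .N), by = .(contig, pos0)]
  else data.table(contig = character(), pos0 = integer(),
                  indel_evidence = integer())
  site <- merge(
    unique(counts[, .(contig, pos0)]),
    merge(ind, amb, by = c("contig", "pos0"), all = TRUE),
    by = c("contig", "pos0"), all = TRUE)
  site[is.na(indel_evidence), indel_evidence := 0L]
  site[is.na(ambiguous_evidence), ambiguous_evidence := 0L]
  setorder(site, contig, pos0)

  structure(list(counts = counts, site = site,
                 individuals = sort(unique(placed$individual)),
                 contig_lengths = clen),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d covered positions on %d contigs, %d individuals\n",
              nrow(x$site), length(unique(x$site$contig)),
              length(x$individuals)))
  invisible(x)
}

#' View one pileup column
#'
#' @param pileup a [build_pileup()] result.
#' @param contig,pos0 the position.
#' @return list with `counts_by_individual` (named list of named base-count
#'   vectors), `indel_evidence`, `ambiguous_evidence`, `depth`.
#' @export
pileup_column <- function(pileup, contig, pos0) {
  want_c <- contig; want_p <- pos0
  cc <- pileup$counts[pileup$counts[["contig"]] == want_c &
                      pileup$counts[["pos0"]] == want_p, ]
  by_ind <- split(cc, cc$individual)
  cbi <- lapply(by_ind, function(d) structure(d$n, names = d$base))
  s <- pileup$site[pileup$site[["contig"]] == want_c &
                   pileup$site[["pos0"]] == want_p, ]
  list(counts_by_individual = cbi,
       indel_evidence = if (nrow(s)) s$indel_evidence else 0L,
       ambiguous_evidence = if (nrow(s)) s$ambiguous_evidence else 0L,
       depth = sum(cc$n))
}

#' Per-group and pooled allele counts at one column
#'
#' Group counts are exact sums over member individuals; the pooled counts
#' equal the sum over groups.
#'
#' @param pileup a pileup.
#' @param contig,pos0 the position.
#' @param scheme a [group_scheme()]; every individual present in the column
#'   must appear in it.
#' @return list with `by_group` (named list of base-count vectors) and
#'   `pooled` (named base-count vector).
#' @export
column_group_counts <- function(pileup, contig, pos0, scheme) {
  want_c <- contig; want_p <- pos0
  cc <- pileup$counts[pileup$counts[["contig"]] == want_c &
                      pileup$counts[["pos0"]] == want_p, ]
  unknown <- setdiff(unique(cc$individual), names(scheme$group_of))
  if (length(unknown))
    config_error("scheme", paste("individual(s) missing from scheme:",
                                 paste(unknown, collapse = ", ")))
  cc$group <- scheme$group_of[cc$individual]
  g <- cc[, .(n = sum(n)), by = .(group, base)]
  by_group <- lapply(split(g, g$group), function(d)
    structure(d$n, names = d$base))
  pooled_dt <- cc[, .(n = sum(n)), by = base]
  list(by_group = by_group,
       pooled = structure(pooled_dt$n, names = pooled_dt$base))
}

# Vectorised group/pooled counts over every covered position.
# Returns list(pooled = DT(contig,pos0,base,n), grouped = DT(contig,pos0,
# group,base,n)). N calls are kept under base "N".
group_base_counts <- function(pileup, scheme) {
  cc <- data.table::copy(pileup$counts)
  unknown <- setdiff(unique(cc$individual), names(scheme$group_of))
  if (length(unknown))
    config_error("scheme", paste("individual(s) missing from scheme:",
                                 paste(unknown, collapse = ", ")))
  cc[, group := scheme$group_of[individual]]
  list(pooled = cc[, .(n = sum(n)), by = .(contig, pos0, base)],
       grouped = cc[, .(n = sum(n)), by = .(contig, pos0, group, base)])
}

#' Dump a pileup as TSV (debugging aid)
#' @param pileup a pileup.
#' @param scheme a [group_scheme()].
#' @param path output TSV.
#' @export
write_pileup_tsv <- function(pileup, scheme, path) {
  gb <- group_base_counts(pileup, scheme)$grouped
  wide <- data.table::dcast(gb, contig + pos0 ~ group + base,
                            value.var = "n", fill = 0L)
  wide <- merge(wide, pileup$site, by = c("contig", "pos0"))
  fwrite(wide, path, sep = "\t")
  invisible(path)
}
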