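#' Configuration for a simulated multi-lineage sequencing panel
#'
#' Describes the stated world that the simulator emulates: a set of diverged
#' lineage groups (nine cutthroat-trout-like lineages plus a rainbow-trout-like
#' outgroup by default), a reduced multi-contig genome, and three classes of
#' planted variation -- fixed lineage-diagnostic (autapomorphic) SNPs, shared
#' polymorphisms segregating in several groups, and rare within-group variants.
#'
#' @param n_groups number of lineage groups (>= 2). The last group is treated
#'   as the outgroup species when `group_names` is not supplied.
#' @param individuals_per_group either a single count or a vector of length
#'   `n_groups`. The default mirrors a discovery panel of 36 individuals:
#'   nine lineages with 2-4 individuals each plus 6 outgroup individuals.
#' @param genome_length total reference length in bases.
#' @param n_contigs number of reference contigs the genome is split into.
#' @param autapomorphic_rate planted fixed-difference SNPs per kilobase per
#'   group.
#' @param shared_poly_rate non-diagnostic polymorphisms per kilobase,
#'   segregating in at least two groups.
#' @param within_group_rate rare within-group variants per kilobase
#'   (one heterozygous individual each).
#' @param repeat_fraction fraction of the genome flagged repetitive in the
#'   truth masks.
#' @param mtdna_contig include one mitochondrial-like contig (~16.6 kb),
#'   flagged in the masks.
#' @param paralog_rate fraction of contigs emulating a paralog-collapsed
#'   misassembly: dense apparent heterozygosity in every individual.
#' @param group_names optional group labels, length `n_groups`.
#' @param seed master random seed for the panel stream.
#' @return a `panel_config` list, validated.
#' @export
panel_config <- function(n_groups = 10,
                         individuals_per_group = c(4, 4, 2, 4, 4, 2, 4, 4, 2, 6),
                         genome_length = 2e6,
                         n_contigs = 50,
                         autapomorphic_rate = 0.2,
                         shared_poly_rate = 1.0,
                         within_group_rate = 0.5,
                         repeat_fraction = 0.10,
                         mtdna_contig = TRUE,
                         paralog_rate = 0.04,
                         group_names = NULL,
                         seed = 1L) {
  stopifnot_scalar_number(n_groups, "n_groups", min = 2, integerish = TRUE)
  if (length(individuals_per_group) == 1L)
    individuals_per_group <- rep(individuals_per_group, n_groups)
  if (length(individuals_per_group) != n_groups)
    config_error("individuals_per_group",
                 sprintf("length must be 1 or n_groups (%d)", n_groups))
  if (any(individuals_per_group < 1))
    config_error("individuals_per_group", "every group needs >= 1 individual")
  stopifnot_scalar_number(genome_length, "genome_length", min = 1)
  stopifnot_scalar_number(n_contigs, "n_contigs", min = 1, integerish = TRUE)
  if (genome_length < n_contigs)
    config_error("genome_length", "must be >= n_contigs")
  for (f in c("autapomorphic_rate", "shared_poly_rate", "within_group_rate"))
    stopifnot_scalar_number(get(f), f, min = 0)
  stopifnot_scalar_number(repeat_fraction, "repeat_fraction", min = 0, max = 1)
  stopifnot_scalar_number(paralog_rate, "paralog_rate", min = 0, max = 1)
  if (!is.logical(mtdna_contig) || length(mtdna_contig) != 1L)
    config_error("mtdna_contig", "must be TRUE or FALSE")
  stopifnot_scalar_number(seed, "seed", min = 0, integerish = TRUE)
  if (is.null(group_names)) {
    pool <- c("BearRiver", "Bonneville", "Coastal", "ColoradoRiver",
              "Greenback", "Lahontan", "RioGrande", "Westslope",
              "Yellowstone", "Rainbow")
    group_names <- if (n_groups <= length(pool)) {
      c(pool[seq_len(n_groups - 1L)], pool[length(pool)])
    } else sprintf("G%02d", seq_len(n_groups))
  }
  if (length(group_names) != n_groups || anyDuplicated(group_names))
    config_error("group_names", "must be n_groups unique labels")
  structure(list(
    n_groups = as.integer(n_groups),
    individuals_per_group = as.integer(individuals_per_group),
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    autapomorphic_rate = autapomorphic_rate,
    shared_poly_rate = shared_poly_rate,
    within_group_rate = within_group_rate,
    repeat_fraction = repeat_fraction,
    mtdna_contig = mtdna_contig,
    paralog_rate = paralog_rate,
    group_names = group_names,
    seed = as.integer(seed)
  ), class = "panel_config")
}

#' Simulate a lineage panel with full truth tables
#'
#' Builds a random multi-contig reference, assigns diploid individuals to
#' groups, and plants three classes of substitutions into their haplotypes:
#'
#' * autapomorphic: fixed (both haplotypes) in every individual of exactly one
#'   focal group, absent elsewhere -- the diagnostic markers the discovery
#'   pipeline is meant to find;
#' * shared: segregating at 50% per haplotype in 2+ groups;
#' * within: carried on one haplotype of one individual.
#'
#' Paralog-collapsed contigs additionally receive dense `psv` variants on one
#' haplotype of every individual, mimicking two co-assembled gene copies.
#' Repeat intervals covering ~`repeat_fraction` of the genome and the
#' mitochondrial-like contig make up the truth masks.
#'
#' @param config a [panel_config()].
#' @return a `truth_panel` list with elements `contigs` (named character),
#'   `contig_info`, `individuals`, `group_map`, `hap_variants`, `truth_snps`
#'   (data.table: contig, pos0, class, focal_group, ref, alt), and `masks`
#'   (a [mask_set()]).
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "panel_config")) config <- do.call(panel_config, config)
  set.seed(split_seed(config$seed, "panel"))

  ## --- contigs ------------------------------------------------------------
  n_contigs <- config$n_contigs
  ids <- sprintf("contig%03d", seq_len(n_contigs))
  mt_len <- 0L
  mt_id <- character(0)
  if (config$mtdna_contig) {
    mt_len <- min(16600L, max(1L, config$genome_length %/% 4L))
    mt_id <- "contigMT"
  }
  nuclear_len <- config$genome_length - mt_len
  if (nuclear_len < n_contigs) config_error("genome_length",
    "too short to fit the mtDNA contig plus nuclear contigs")
  # uneven contig sizes, at least 200 bp (or what fits) each
  w <- runif(n_contigs, 0.5, 1.5)
  lens <- pmax(1L, as.integer(round(nuclear_len * w / sum(w))))
  lens[1L] <- lens[1L] + (nuclear_len - sum(lens))
  contigs <- vapply(lens, random_dna, character(1))
  names(contigs) <- ids
  if (config$mtdna_contig) {
    contigs <- c(contigs, structure(random_dna(mt_len), names = mt_id))
    lens <- c(lens, mt_len)
    ids <- c(ids, mt_id)
  }
  paralog <- runif(length(ids)) < config$paralog_rate & ids != mt_id
  contig_info <- data.table(contig = ids, length = as.integer(lens),
                            mtdna = ids %in% mt_id, paralog = paralog)

  ## --- individuals --------------------------------------------------------
  groups <- rep(config$group_names, config$individuals_per_group)
  individuals <- sprintf("%s_%02d", groups,
                         unlist(lapply(config$individuals_per_group, seq_len)))
  group_map <- structure(groups, names = individuals)

  ## --- variant positions --------------------------------------------------
  kb <- config$genome_length / 1000
  n_auta <- round(config$autapomorphic_rate * kb)    # per group
  n_shared <- round(config$shared_poly_rate * kb)
  n_within <- round(config$within_group_rate * kb)
  n_total <- n_auta * config$n_groups + n_shared + n_within
  offsets <- c(0, cumsum(as.double(lens)))
  pick_positions <- function(n) {
    g <- sort(sample(config$genome_length, n))
    i <- findInterval(g - 1, offsets, rightmost.closed = FALSE)
    data.table(contig = ids[i], pos0 = as.integer(g - 1 - offsets[i]))
  }
  truth <- list()
  hapv <- list()
  ref_base <- function(contig, pos0)
    substring(contigs[contig], pos0 + 1L, pos0 + 1L)
  alt_base <- function(ref) {
    vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  }

  if (n_total > 0) {
    sites <- pick_positions(n_total)
    sites[, ref := ref_base(contig, pos0)]
    sites[, alt := alt_base(ref)]
    cls <- c(rep(config$group_names, each = n_auta),
             rep("shared", n_shared), rep("within", n_within))
    cls <- sample(cls)  # scatter classes over positions
    sites[, class := ifelse(cls %in% config$group_names, "autapomorphic",
                            cls)]
    sites[, focal_group := ifelse(class == "autapomorphic", cls, NA_character_)]

    for (k in seq_len(nrow(sites))) {
      s <- sites[k]
      if (s$class == "autapomorphic") {
        ind <- individuals[group_map == s$focal_group]
        hapv[[length(hapv) + 1L]] <- data.table(
          individual = rep(ind, each = 2L), hap = rep(1:2, length(ind)),
          contig = s$contig, pos0 = s$pos0, alt = s$alt)
      } else if (s$class == "shared") {
        ngrp <- sample(2:min(4L, config$n_groups), 1L)
        grp <- sample(config$group_names, ngrp)
        ind <- individuals[group_map %in% grp]
        carry <- matrix(runif(2L * length(ind)) < 0.5, nrow = 2L)
        # guarantee segregation in >= 2 groups
        first_of <- match(grp[1:2], group_map[ind])
        carry[1L, first_of] <- TRUE
        hh <- which(carry, arr.ind = TRUE)
        hapv[[length(hapv) + 1L]] <- data.table(
          individual = ind[hh[, 2L]], hap = as.integer(hh[, 1L]),
          contig = s$contig, pos0 = s$pos0, alt = s$alt)
        sites[k, focal_group := NA_character_]
      } else {  # within-group rare variant
        ind <- sample(individuals, 1L)
        hapv[[length(hapv) + 1L]] <- data.table(
          individual = ind, hap = sample(1:2, 1L),
          contig = s$contig, pos0 = s$pos0, alt = s$alt)
        sites[k, focal_group := group_map[[ind]]]
      }
    }
    truth[[length(truth) + 1L]] <- sites
  }

  ## --- paralog-collapsed contigs ------------------------------------------
  taken <- if (length(truth)) rbindlist(truth, fill = TRUE)[, paste(contig, pos0)]
           else character(0)
  for (pc in ids[paralog]) {
    clen <- lens[match(pc, ids)]
    npsv <- max(1L, round(10 * clen / 1000))  # ~10 PSV sites per kb
    pos0 <- sort(sample(clen, min(npsv, clen))) - 1L
    pos0 <- pos0[!paste(pc, pos0) %in% taken]
    if (!length(pos0)) next
    rb <- ref_base(rep(pc, length(pos0)), pos0)
    ab <- alt_base(rb)
    psv <- data.table(contig = pc, pos0 = as.integer(pos0), ref = rb, alt = ab,
                      class = "psv", focal_group = NA_character_)
    truth[[length(truth) + 1L]] <- psv
    # one "copy" of the collapsed paralog: hap 2 of every individual
    hapv[[length(hapv) + 1L]] <- data.table(
      individual = rep(individuals, each = length(pos0)), hap = 2L,
      contig = pc, pos0 = rep(as.integer(pos0), length(individuals)),
      alt = rep(ab, length(individuals)))
  }

  truth_snps <- if (length(truth)) {
    out <- rbindlist(truth, use.names = TRUE, fill = TRUE)
    setorder(out, contig, pos0)
    out[, .(contig, pos0, class, focal_group, ref, alt)]
  } else data.table(contig = character(), pos0 = integer(),
                    class = character(), focal_group = character(),
                    ref = character(), alt = character())
  hap_variants <- if (length(hapv)) {
    hv <- rbindlist(hapv, use.names = TRUE)
    hv <- hv[paste(contig, pos0) %in% truth_snps[, paste(contig, pos0)]]
    setorder(hv, individual, hap, contig, pos0)
    hv
  } else data.table(individual = character(), hap = integer(),
                    contig = character(), pos0 = integer(), alt = character())

  ## --- repeat masks -------------------------------------------------------
  target <- config$repeat_fraction * config$genome_length
  rep_iv <- list()
  covered <- 0
  nuclear_ids <- setdiff(ids, mt_id)
  while (covered < target && length(nuclear_ids)) {
    ci <- sample(nuclear_ids, 1L)
    clen <- lens[match(ci, ids)]
    w <- min(clen, max(50L, as.integer(round(stats::rexp(1, 1 / 500)))))
    st <- sample(max(1L, clen - w + 1L), 1L) - 1L
    rep_iv[[length(rep_iv) + 1L]] <- data.table(contig = ci, start = st,
                                                end = st + w)
    covered <- covered + w
  }
  rep_dt <- if (length(rep_iv)) rbindlist(rep_iv) else
    data.table(contig = character(), start = integer(), end = integer())
  masks <- mask_set(rep_dt, mtdna_contigs = mt_id)

  structure(list(contigs = contigs, contig_info = contig_info,
                 individuals = individuals, group_map = group_map,
                 hap_variants = hap_variants, truth_snps = truth_snps,
                 masks = masks, config = config),
            class = "truth_panel")
}

#' @export
print.truth_panel <- function(x, ...) {
  cat(sprintf(
    "truth_panel: %d contigs (%s bp), %d individuals in %d groups\n",
    length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
    length(x$individuals), length(unique(x$group_map))))
  cat(sprintf("  truth variants: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth_snps$class)),
                            table(x$truth_snps$class)), collapse = ", ")))
  invisible(x)
}

#' Materialise one haplotype sequence
#'
#' Applies an individual's planted substitutions to the reference contig.
#' Haplotypes have the same length as the reference (substitutions only).
#'
#' @param panel a `truth_panel`.
#' @param individual individual id.
#' @param contig contig id.
#' @param hap haplotype index, 1 or 2.
#' @param start,end optional 0-based half-open window; defaults to the whole
#'   contig.
#' @return a character string.
#' @export
panel_haplotype <- function(panel, individual, contig, hap,
                            start = 0L, end = NULL) {
  ref <- panel$contigs[[contig]]
  if (is.null(end)) end <- nchar(ref)
  s <- substring(ref, start + 1L, end)
  want <- list(ind = individual, hap = hap, contig = contig,
               from = start, to = end)
  hvdt <- panel$hap_variants
  hv <- hvdt[hvdt[["individual"]] == want$ind &
             hvdt[["hap"]] == want$hap &
             hvdt[["contig"]] == want$contig &
             hvdt[["pos0"]] >= want$from & hvdt[["pos0"]] < want$to, ]
  if (nrow(hv)) {
    v <- chars(s)
    v[hv$pos0 - start + 1L] <- hv$alt
    s <- paste(v, collapse = "")
  }
  s
}
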