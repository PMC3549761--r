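#' Genotype matrix container
#'
#' Individuals x loci genotype calls coded as copies of the panel-wide minor
#' allele: 0, 1, 2, or `NA` for missing.
#'
#' @param calls integer matrix (individuals x loci), values 0/1/2/NA;
#'   rownames are individual ids, colnames locus ids (supplied separately if
#'   absent).
#' @param group_of named character vector `individual -> group`.
#' @return a `genotype_matrix` list.
#' @export
genotype_matrix <- function(calls, group_of) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    config_error("calls", "needs individual ids as rownames")
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("locus%03d", seq_len(ncol(calls)))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad))
    config_error("calls", "codes must be 0, 1, 2 or NA")
  missing_grp <- setdiff(rownames(calls), names(group_of))
  if (length(missing_grp))
    config_error("group_of", paste("no group for:",
                                   paste(missing_grp, collapse = ", ")))
  structure(list(calls = calls,
                 group_of = group_of[rownames(calls)]),
            class = "genotype_matrix")
}

#' Read a genotype CSV (rows = individuals, columns = loci, codes 0/1/2/NA)
#' @param path CSV file with an `individual` first column.
#' @param group_of named character vector `individual -> group`.
#' @export
read_genotypes_csv <- function(path, group_of) {
  d <- fread(path)
  ind <- d[[1]]
  m <- as.matrix(d[, -1])
  rownames(m) <- ind
  genotype_matrix(m, group_of)
}

#' Per-group minor allele frequencies
#'
#' The minor allele is defined panel-wide (the allele whose overall
#' frequency across all individuals is <= 0.5, ties folded), then its
#' frequency is computed per group over that group's non-missing calls and
#' folded to <= 0.5. Groups with no genotyped individuals at a locus yield
#' `NA` with `valid_n = 0`.
#'
#' @param genotypes a [genotype_matrix()].
#' @return data.table: group, locus_id, maf (in `[0, 0.5]` or NA), valid_n.
#' @export
compute_maf <- function(genotypes) {
  calls <- genotypes$calls
  groups <- genotypes$group_of
  if (any(table(groups) == 0L))
    config_error("group_of", "empty group")
  # fold to the panel-wide minor allele: if the coded allele is the major
  # one overall, flip codes 0<->2
  overall <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(overall) & overall > 0.5
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  out <- list()
  for (g in unique(groups)) {
    sub <- calls[groups == g, , drop = FALSE]
    valid_n <- colSums(!is.na(sub))
    f <- colSums(sub, na.rm = TRUE) / (2 * valid_n)
    f[valid_n == 0L] <- NA_real_
    f <- pmin(f, 1 - f)  # folded: reported MAF never exceeds 0.5
    out[[g]] <- data.table(group = g, locus_id = colnames(calls),
                           maf = as.numeric(f),
                           valid_n = as.integer(valid_n))
  }
  rbindlist(out)
}

#' Per-group polymorphism summary
#'
#' For each group: the number of polymorphic loci (MAF > 0), the number of
#' highly polymorphic loci (MAF >= `high_threshold`), the average MAF, and
#' the MAF range over polymorphic loci. The average is reported under both
#' conventions -- over all loci including zeros (`avg_maf`, the default
#' reading of published per-group averages) and over polymorphic loci only
#' (`avg_maf_polymorphic`) -- since summary tables in the literature rarely
#' state which they use.
#'
#' @param maf a [compute_maf()] table.
#' @param high_threshold MAF at or above which a locus is called highly
#'   polymorphic (0.3 by convention).
#' @return data.table: group, n_loci, polymorphic, highly_polymorphic,
#'   avg_maf, avg_maf_polymorphic, maf_min, maf_max.
#' @export
summarize_polymorphism <- function(maf, high_threshold = 0.3) {
  maf <- as.data.table(maf)
  maf[, .(
    n_loci = .N,
    polymorphic = sum(maf > 0, na.rm = TRUE),
    highly_polymorphic = sum(maf >= high_threshold, na.rm = TRUE),
    avg_maf = mean(maf, na.rm = TRUE),
    avg_maf_polymorphic = if (any(maf > 0, na.rm = TRUE))
      mean(maf[maf > 0], na.rm = TRUE) else NA_real_,
    maf_min = if (any(maf > 0, na.rm = TRUE)) min(maf[maf > 0], na.rm = TRUE)
              else NA_real_,
    maf_max = if (any(maf > 0, na.rm = TRUE)) max(maf[maf > 0], na.rm = TRUE)
              else NA_real_
  ), by = group]
}

#' Allele-sharing distance between individuals
#'
#' `d(i, j) = 1 - shared / (2 * L)` where, per jointly genotyped locus, two
#' diploid genotypes share `2 - |g_i - g_j|` allele copies (with genotypes
#' coded as minor-allele counts) and `L` counts those loci. Identical
#' individuals get 0; opposite homozygotes at every locus get 1.
#'
#' @param genotypes a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(genotypes) {
  calls <- genotypes$calls
  n <- nrow(calls)
  if (n < 2L) config_error("genotypes", "need >= 2 individuals")
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    if (!any(ok))
      stop(sprintf("no jointly genotyped loci for pair (%s, %s)",
                   rownames(calls)[i], rownames(calls)[j]))
    dij <- mean(abs(calls[i, ok] - calls[j, ok])) / 2
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` with the centering projector, takes the symmetric
#' eigendecomposition, and scales eigenvectors by the square roots of the
#' positive eigenvalues. Variance explained is each positive eigenvalue over
#' the positive-eigenvalue total. Axis signs follow a fixed convention (the
#' first nonzero loading of each axis is made positive) so output is
#' reproducible across platforms.
#'
#' @param d square symmetric distance matrix, zero diagonal.
#' @param n_axes number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return list: `coordinates` (individuals x axes), `eigenvalues` (all, in
#'   decreasing order), `variance_explained` (percent, one per positive
#'   eigenvalue).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    config_error("d", "must be square symmetric with zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  if (!any(pos))
    stop("degenerate input: no positive eigenvalues")
  k <- min(n_axes, sum(pos))
  vals <- e$values[pos]
  vecs <- e$vectors[, pos, drop = FALSE]
  coords <- sweep(vecs[, seq_len(k), drop = FALSE], 2, sqrt(vals[seq_len(k)]),
                  `*`)
  for (a in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("PCo%d", seq_len(k))
  list(coordinates = coords,
       eigenvalues = e$values,
       variance_explained = 100 * vals / sum(vals))
}

#' Diagnostic-allele admixture index
#'
#' A lightweight, counts-based stand-in for model-based ancestry estimation:
#' for individual i and group G, the raw index is the fraction of
#' G-diagnostic allele copies carried at G's diagnostic loci, normalized
#' across groups to sum to 1. Individuals whose second-largest fraction
#' reaches `flag_threshold` are flagged as putative hybrids.
#'
#' @param genotypes a [genotype_matrix()] whose codes count copies of the
#'   locus's minor allele.
#' @param diagnostic_loci data.table mapping locus_id -> focal_group; the
#'   diagnostic allele is the coded (minor) allele.
#' @param flag_threshold hybrid flag threshold on the second-largest
#'   fraction.
#' @return data.table: individual, group columns (fractions), top_group,
#'   second_fraction, hybrid_flag.
#' @export
admixture_index <- function(genotypes, diagnostic_loci,
                            flag_threshold = 0.10) {
  dl <- as.data.table(diagnostic_loci)
  if (!all(c("locus_id", "focal_group") %in% names(dl)))
    config_error("diagnostic_loci", "needs columns locus_id, focal_group")
  dl <- dl[locus_id %in% colnames(genotypes$calls)]
  groups <- sort(unique(dl$focal_group))
  no_loci <- setdiff(unique(genotypes$group_of), groups)
  if (length(no_loci))
    warning(paste("no diagnostic loci for group(s):",
                  paste(no_loci, collapse = ", "), "- omitted"))
  calls <- genotypes$calls
  inds <- rownames(calls)
  raw <- matrix(NA_real_, length(inds), length(groups),
                dimnames = list(inds, groups))
  for (g in groups) {
    loci <- dl[focal_group == g, locus_id]
    sub <- calls[, loci, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    raw[, g] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / (2 * nn), NA)
  }
  tot <- rowSums(raw, na.rm = TRUE)
  frac <- raw / ifelse(tot > 0, tot, NA)
  all_missing <- apply(raw, 1L, function(x) all(is.na(x)))
  res <- data.table(individual = inds)
  for (g in groups) res[, (g) := frac[, g]]
  res[, top_group := apply(frac, 1L, function(x)
    if (all(is.na(x))) NA_character_ else groups[which.max(x)])]
  res[, second_fraction := apply(frac, 1L, function(x) {
    x <- sort(x[!is.na(x)], decreasing = TRUE)
    if (length(x) >= 2L) x[2L] else 0
  })]
  res[, hybrid_flag := !all_missing & second_fraction >= flag_threshold]
  res
}

#' Build a synthetic genotype matrix from a truth panel
#'
#' Collapses the panel's planted haplotypes at a set of loci into 0/1/2
#' genotype codes (copies of the alternate allele), optionally adding
#' verification individuals drawn from the same groups and simple F1
#' hybrids. A bridge from the discovery side of the package to the
#' genotype-based diversity summaries.
#'
#' @param panel a `truth_panel`.
#' @param loci validated locus table (contig, pos0, locus_id) or truth-table
#'   subset.
#' @param extra_per_group additional simulated individuals per group,
#'   emulating a verification panel drawn from the same lineages.
#' @param focal_allele_freq frequency at which verification individuals of
#'   the focal group carry a diagnostic allele (1 = perfectly fixed; values
#'   slightly below 1 emulate the near-fixation the 95%-identity criterion
#'   tolerates).
#' @param offtarget_allele_freq frequency at which verification individuals
#'   of *other* groups carry a diagnostic allele (0 = strict autapomorphy;
#'   small values emulate residual introgression in wild populations).
#' @param missing_rate per-call missing probability.
#' @param seed random seed.
#' @return a [genotype_matrix()].
#' @export
panel_genotypes <- function(panel, loci, extra_per_group = 0L,
                            focal_allele_freq = 1.0,
                            offtarget_allele_freq = 0.0,
                            missing_rate = 0, seed = 1L) {
  set.seed(split_seed(seed, "genotypes"))
  loci <- as.data.table(loci)
  if (!"locus_id" %in% names(loci))
    loci[, locus_id := sprintf("%s_%d", contig, pos0 + 1L)]
  hv <- panel$hap_variants
  key <- paste(loci$contig, loci$pos0)
  inds <- panel$individuals
  m <- matrix(0L, length(inds), nrow(loci),
              dimnames = list(inds, loci$locus_id))
  hit <- hv[paste(contig, pos0) %in% key]
  if (nrow(hit)) {
    hit[, locus_id := loci$locus_id[match(paste(contig, pos0), key)]]
    agg <- hit[, .(n = .N), by = .(individual, locus_id)]
    m[cbind(match(agg$individual, inds),
            match(agg$locus_id, loci$locus_id))] <- pmin(2L, agg$n)
  }
  group_of <- panel$group_map
  if (extra_per_group > 0L) {
    # verification individuals: same fixed autapomorphies as their group,
    # shared/within sites redrawn at the planted frequencies
    truth <- panel$truth_snps[paste(contig, pos0) %in% key]
    truth[, locus_id := loci$locus_id[match(paste(contig, pos0), key)]]
    for (g in unique(panel$group_map)) {
      for (k in seq_len(extra_per_group)) {
        nm <- sprintf("%s_v%02d", g, k)
        row <- integer(nrow(loci))
        fixed <- truth[class == "autapomorphic" & focal_group == g, locus_id]
        row[match(fixed, loci$locus_id)] <-
          stats::rbinom(length(fixed), 2L, focal_allele_freq)
        if (offtarget_allele_freq > 0) {
          other <- truth[class == "autapomorphic" & focal_group != g,
                         locus_id]
          row[match(other, loci$locus_id)] <-
            stats::rbinom(length(other), 2L, offtarget_allele_freq)
        }
        seg <- truth[class == "shared", locus_id]
        row[match(seg, loci$locus_id)] <-
          stats::rbinom(length(seg), 2L, 0.5)
        m <- rbind(m, matrix(row, 1L, dimnames = list(nm, NULL)))
        group_of <- c(group_of, structure(g, names = nm))
      }
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(length(m)) < missing_rate, nrow(m))
    m[drop] <- NA_integer_
  }
  genotype_matrix(m, group_of)
}
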