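# Independent brute-force re-derivation of the final locus set from a raw
# SAM file. Deliberately written with plain loops and arrays, sharing no
# code with the package implementation, so it can serve as an oracle on
# small panels.

oracle_pileup <- function(sam_path, contigs) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  counts <- list()   # counts[[contig]][[individual]]: 5 x len matrix
  indel <- list()    # indel[[contig]]: integer vector
  ambig <- list()
  for (cid in names(contigs)) {
    len <- nchar(contigs[[cid]])
    indel[[cid]] <- integer(len)
    ambig[[cid]] <- integer(len)
    counts[[cid]] <- list()
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), 4L) != 0L) next
    cid <- f[3]
    pos <- as.integer(f[4])          # 1-based
    cig <- f[6]
    seq <- f[10]
    rg <- grep("^RG:Z:", f, value = TRUE)
    ind <- if (length(rg)) sub("^RG:Z:", "", rg[1]) else sub("\\|.*", "", f[1])
    if (is.null(counts[[cid]][[ind]]))
      counts[[cid]][[ind]] <- matrix(0L, 5L, nchar(contigs[[cid]]))
    ops <- regmatches(cig, gregexpr("\\d+[A-Z]", cig))[[1]]
    rp <- pos; qp <- 1L
    for (o in ops) {
      l <- as.integer(sub("[A-Z]$", "", o))
      t <- sub("^\\d+", "", o)
      if (t == "M") {
        for (i in seq_len(l)) {
          b <- toupper(substr(seq, qp + i - 1L, qp + i - 1L))
          bi <- base_idx[[if (b %in% names(base_idx)) b else "N"]]
          counts[[cid]][[ind]][bi, rp + i - 1L] <-
            counts[[cid]][[ind]][bi, rp + i - 1L] + 1L
          if (bi == 5L) ambig[[cid]][rp + i - 1L] <-
            ambig[[cid]][rp + i - 1L] + 1L
        }
        rp <- rp + l; qp <- qp + l
      } else if (t == "D") {
        for (i in seq_len(l)) indel[[cid]][rp + i - 1L] <-
          indel[[cid]][rp + i - 1L] + 1L
        rp <- rp + l
      } else if (t == "I") {
        for (p in c(rp - 1L, rp))
          if (p >= 1L && p <= nchar(contigs[[cid]]))
            indel[[cid]][p] <- indel[[cid]][p] + 1L
        qp <- qp + l
      } else if (t == "S") {
        qp <- qp + l
      } else stop("oracle: unexpected CIGAR op ", t)
    }
  }
  list(counts = counts, indel = indel, ambig = ambig)
}

# Full criteria re-derivation. masks: list(intervals = data.frame(contig,
# start, end), mtdna_contigs = character). Returns the validated locus set
# as a data.frame(contig, pos0) plus the pass set before one-per-contig.
oracle_discover <- function(sam_path, contigs, group_of,
                            masks_intervals, mtdna_contigs,
                            min_depth = 8, flank = 50, clean = 20,
                            min_minor_reads = 3, min_minor_frac = 0.04,
                            min_identity = 0.95, radius = 20, reject = 6,
                            min_poly_reads = 2) {
  pl <- oracle_pileup(sam_path, contigs)
  weight_of <- function(d) if (d <= 5) 3 else if (d <= 10) 2 else if (d <= 20) 1 else 0
  pass <- list()
  for (cid in names(contigs)) {
    len <- nchar(contigs[[cid]])
    inds <- names(pl$counts[[cid]])
    if (!length(inds)) next
    pooled <- Reduce(`+`, pl$counts[[cid]])   # 5 x len
    acgt <- pooled[1:4, , drop = FALSE]
    # polymorphic guard set for the window filter
    n_guarded <- colSums(acgt >= min_poly_reads)
    poly_pos <- which(n_guarded >= 2L)        # 1-based
    cand_pos <- which(colSums(acgt >= 1L) >= 2L)
    for (p in cand_pos) {
      cnt <- acgt[, p]
      ord <- order(-cnt, seq_len(4))
      major <- c("A", "C", "G", "T")[ord[1]]
      minor <- c("A", "C", "G", "T")[ord[2]]
      minor_n <- cnt[ord[2]]
      depth_total <- sum(pooled[, p])
      # C1: minor allele unique to one group
      bi <- ord[2]
      per_group <- sapply(inds, function(i) pl$counts[[cid]][[i]][bi, p])
      gsum <- tapply(per_group, group_of[inds], sum)
      gsum[is.na(gsum)] <- 0
      carriers <- names(gsum)[gsum > 0]
      C1 <- length(carriers) == 1L
      focal <- if (C1) carriers else NA
      C2 <- depth_total >= min_depth
      dirty <- unique(c(which(pl$indel[[cid]] > 0), which(pl$ambig[[cid]] > 0)))
      C3 <- (p - 1) >= flank && (len - p) >= flank &&
        !any(abs(dirty - p) <= clean)
      C4 <- minor_n >= min_minor_reads &&
        minor_n / sum(cnt) >= min_minor_frac
      C5 <- NA
      if (C1) {
        gi <- inds[group_of[inds] == focal]
        gc <- Reduce(`+`, lapply(gi, function(i) pl$counts[[cid]][[i]][, p]))
        C5 <- gc[bi] / sum(gc[1:4]) >= min_identity
      }
      C6 <- !(cid %in% mtdna_contigs)
      if (C6 && nrow(masks_intervals)) {
        mi <- masks_intervals[masks_intervals$contig == cid, , drop = FALSE]
        if (nrow(mi) && any((p - 1) >= mi$start & (p - 1) < mi$end))
          C6 <- FALSE
      }
      nb <- poly_pos[poly_pos != p & abs(poly_pos - p) <= radius]
      W <- sum(vapply(abs(nb - p), weight_of, numeric(1))) < reject
      if (C1 && C2 && C3 && C4 && isTRUE(C5) && C6 && W)
        pass[[length(pass) + 1L]] <- data.frame(
          contig = cid, pos0 = p - 1L, depth = depth_total)
    }
  }
  pass <- if (length(pass)) do.call(rbind, pass) else
    data.frame(contig = character(), pos0 = integer(), depth = integer())
  # one per contig: max depth, then leftmost
  loci <- do.call(rbind, lapply(split(pass, pass$contig), function(d) {
    d <- d[order(-d$depth, d$pos0), , drop = FALSE]
    d[1, c("contig", "pos0")]
  }))
  if (is.null(loci)) loci <- data.frame(contig = character(), pos0 = integer())
  rownames(loci) <- NULL
  list(pass = pass, loci = loci[order(loci$contig, loci$pos0), , drop = FALSE])
}
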