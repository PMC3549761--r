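#' Generate unique MID barcodes for a set of individuals
#'
#' Synthetic multiplex-identifier barcodes: fixed-length, mutually distinct
#' (equal length makes them mutually prefix-free by construction).
#'
#' @param individuals character vector of individual ids.
#' @param length barcode length in bases.
#' @param seed random seed.
#' @return named character vector, `individual -> barcode`.
#' @export
make_barcodes <- function(individuals, length = 10L, seed = 1L) {
  set.seed(split_seed(seed, "reads"))
  n <- base::length(individuals)
  if (4^length < n)
    config_error("length", "too short to give every individual a unique barcode")
  bc <- character(0)
  while (base::length(bc) < n) {
    bc <- unique(c(bc, vapply(seq_len(n), function(i) random_dna(length),
                              character(1))))
  }
  structure(bc[seq_len(n)], names = individuals)
}

check_barcode_map <- function(barcode_map, individuals) {
  missing <- setdiff(individuals, names(barcode_map))
  if (length(missing))
    config_error("barcode_map",
                 paste("no barcode for individual(s):",
                       paste(missing, collapse = ", ")))
  bc <- unname(barcode_map)
  if (any(!nzchar(bc))) config_error("barcode_map", "empty barcode")
  if (anyDuplicated(bc)) config_error("barcode_map", "duplicate barcodes")
  for (i in seq_along(bc)) for (j in seq_along(bc)) {
    if (i != j && startsWith(bc[[j]], bc[[i]]))
      config_error("barcode_map", sprintf(
        "barcode collision: '%s' is a prefix of '%s'", bc[[i]], bc[[j]]))
  }
  invisible(TRUE)
}

# Apply 454-style errors to one read. Returns list(seq=, cigar=).
# Substitutions leave the cigar alone; each homopolymer run (length >= 2)
# suffers a +/-1 indel with probability `indel_rate`.
apply_read_errors <- function(v, sub_rate, indel_rate) {
  L <- length(v)
  if (sub_rate > 0) {
    hit <- which(runif(L) < sub_rate)
    if (length(hit))
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1L),
                       character(1), USE.NAMES = FALSE)
  }
  events <- NULL
  if (indel_rate > 0) {
    r <- rle(v)
    runs <- which(r$lengths >= 2L)
    if (length(runs)) {
      sel <- runs[runif(length(runs)) < indel_rate]
      if (length(sel)) {
        starts <- cumsum(c(1L, r$lengths))[sel]  # 1-based run starts
        type <- ifelse(runif(length(sel)) < 0.5, "I", "D")
        events <- data.frame(off = starts - 1L, type = type)  # 0-based
        events <- events[order(events$off), , drop = FALSE]
      }
    }
  }
  if (is.null(events) || nrow(events) == 0L)
    return(list(seq = paste(v, collapse = ""), cigar = sprintf("%dM", L)))
  out <- character(0)
  cig <- character(0)
  cur <- 0L  # reference offset consumed so far
  for (k in seq_len(nrow(events))) {
    off <- events$off[k]
    if (events$type[k] == "D") {
      m <- off - cur
      if (m > 0L) { out <- c(out, v[(cur + 1L):(cur + m)])
                    cig <- c(cig, sprintf("%dM", m)) }
      cig <- c(cig, "1D")       # reference base dropped from the read
      cur <- off + 1L
    } else {
      m <- off - cur + 1L       # match through the run's first base ...
      out <- c(out, v[(cur + 1L):(cur + m)], v[off + 1L])  # ... then repeat it
      cig <- c(cig, sprintf("%dM", m), "1I")
      cur <- off + 1L
    }
  }
  if (cur < L) { out <- c(out, v[(cur + 1L):L])
                 cig <- c(cig, sprintf("%dM", L - cur)) }
  # merge adjacent M ops
  ops <- regmatches(paste(cig, collapse = ""),
                    gregexpr("\\d+[MID]", paste(cig, collapse = "")))[[1]]
  lens <- as.integer(sub("[MID]$", "", ops))
  typ <- sub("^\\d+", "", ops)
  keep_len <- integer(0); keep_typ <- character(0)
  for (k in seq_along(ops)) {
    if (length(keep_typ) && keep_typ[length(keep_typ)] == typ[k])
      keep_len[length(keep_len)] <- keep_len[length(keep_len)] + lens[k]
    else { keep_len <- c(keep_len, lens[k]); keep_typ <- c(keep_typ, typ[k]) }
  }
  list(seq = paste(out, collapse = ""),
       cigar = paste0(keep_len, keep_typ, collapse = ""))
}

#' Simulate barcoded 454-like reads with truth alignments
#'
#' For every retained fragment and every individual, a negative-binomial
#' number of reads is drawn (over-dispersion reproduces the unequal
#' per-individual yields seen on real multiplexed runs). Each read starts at
#' one end of the fragment on one of the individual's two haplotypes (equal
#' probability), has approximately normal length, and is perturbed by
#' independent substitution errors and homopolymer-run +/-1 indels. Quality
#' strings are a constant Q30 symbol: the downstream filters never read
#' qualities.
#'
#' @param panel a `truth_panel`.
#' @param fragments retained fragments from [size_select()].
#' @param params a [read_sim_params()].
#' @param barcode_map named character vector `individual -> barcode`
#'   (see [make_barcodes()]); barcodes must be mutually prefix-free.
#' @return list with `reads` (data.table: read_id, individual, sequence
#'   [barcode-prefixed], quality) and `alignments` (data.table: qname, flag,
#'   rname, pos1 [1-based], cigar, seq [barcode-free], qual, individual),
#'   the error-free truth placement of every read.
#' @export
simulate_reads <- function(panel, fragments, params = read_sim_params(),
                           barcode_map = NULL) {
  if (is.null(barcode_map))
    barcode_map <- make_barcodes(panel$individuals,
                                 length = params$barcode_length,
                                 seed = params$seed)
  check_barcode_map(barcode_map, panel$individuals)
  set.seed(split_seed(params$seed, "reads"))

  empty <- list(
    reads = data.table(read_id = character(), individual = character(),
                       sequence = character(), quality = character()),
    alignments = data.table(qname = character(), flag = integer(),
                            rname = character(), pos1 = integer(),
                            cigar = character(), seq = character(),
                            qual = character(), individual = character()),
    barcode_map = barcode_map)
  if (nrow(fragments) == 0L || params$mean_depth == 0) return(empty)

  nfrag <- nrow(fragments)
  inds <- panel$individuals
  # pre-split variants per individual for fast window lookups
  hv <- panel$hap_variants
  setkey(hv, individual, contig, hap)

  reads_out <- vector("list", length(inds))
  aligns_out <- vector("list", length(inds))
  for (ii in seq_along(inds)) {
    ind <- inds[[ii]]
    k <- if (params$depth_dispersion > 0)
      rnbinom(nfrag, size = 1 / params$depth_dispersion,
              mu = params$mean_depth)
    else rpois(nfrag, params$mean_depth)
    total <- sum(k)
    if (total == 0L) next
    fidx <- rep(seq_len(nfrag), k)
    hap_pick <- sample(1:2, total, replace = TRUE)
    from_left <- runif(total) < 0.5
    L <- pmax(30L, as.integer(round(rnorm(total, params$mean_read_length,
                                          params$read_length_sd))))
    fstart <- fragments$start[fidx]
    fend <- fragments$end[fidx]
    L <- pmin(L, fend - fstart)
    wstart <- ifelse(from_left, fstart, fend - L)
    wend <- wstart + L
    ctg <- fragments$contig[fidx]
    ivars <- hv[.(ind), nomatch = NULL]
    seqs <- character(total)
    cigs <- character(total)
    for (r in seq_len(total)) {
      ref <- panel$contigs[[ctg[r]]]
      s <- substring(ref, wstart[r] + 1L, wend[r])
      ctg_r <- ctg[r]; hap_r <- hap_pick[r]; ws_r <- wstart[r]; we_r <- wend[r]
      vv <- ivars[contig == ctg_r & hap == hap_r &
                  pos0 >= ws_r & pos0 < we_r]
      v <- chars(s)
      if (nrow(vv)) v[vv$pos0 - ws_r + 1L] <- vv$alt
      e <- apply_read_errors(v, params$sub_error_rate,
                             params$homopolymer_indel_rate)
      seqs[r] <- e$seq
      cigs[r] <- e$cigar
    }
    qual <- vapply(nchar(seqs), function(n)
      strrep("?", n), character(1))  # constant Q30
    rid <- sprintf("%s|%06d", ind, seq_len(total))
    reads_out[[ii]] <- data.table(
      read_id = rid, individual = ind,
      sequence = paste0(barcode_map[[ind]], seqs),
      quality = paste0(strrep("?", nchar(barcode_map[[ind]])), qual))
    aligns_out[[ii]] <- data.table(
      qname = rid, flag = 0L, rname = ctg, pos1 = as.integer(wstart + 1L),
      cigar = cigs, seq = seqs, qual = qual, individual = ind)
  }
  out <- list(reads = rbindlist(reads_out),
              alignments = rbindlist(aligns_out),
              barcode_map = barcode_map)
  if (nrow(out$reads) == 0L) return(empty)
  out
}
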