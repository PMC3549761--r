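## Readers/writers for the plain-text formats the pipeline touches.
## Coordinates are 0-based half-open internally; SAM (1-based) and BED
## (0-based) are converted at the boundary.

#' Write/read reference contigs as FASTA
#' @param contigs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(as.character(x), names = names(x))
}

#' Write/read reads as FASTQ
#' @param reads data.table with read_id, sequence, quality.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.table(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)))
}

#' Write truth alignments as plain SAM
#'
#' Emits a minimal SAM 1.6 file: `@HD`/`@SQ` header lines per contig and one
#' record per mapped read with an `RG:Z:` tag carrying the individual id.
#'
#' @param alignments data.table from [simulate_reads()].
#' @param contigs named character vector of reference sequences (for `@SQ`).
#' @param path output file.
#' @export
write_sam <- function(alignments, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                 alignments$qname, alignments$flag, alignments$rname,
                 alignments$pos1, alignments$cigar, alignments$seq,
                 alignments$qual, alignments$individual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Parse a SAM stream into placed reads
#'
#' Reads plain SAM (the binary formats are out of scope at desk scale),
#' keeping only mapped records. Individual identity is taken from the
#' `RG:Z:` tag, with a `<individual>|<serial>` read-name fallback.
#' Coordinates are converted to 0-based.
#'
#' @param path SAM file.
#' @param reference named character vector of contigs; every alignment must
#'   name one of them.
#' @return list with `placed` (data.table: read_id, individual, contig,
#'   start [0-based], cigar, seq) and `n_skipped_unmapped`.
#' @export
parse_alignments <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(list(placed = data.table(read_id = character(),
                                    individual = character(),
                                    contig = character(), start = integer(),
                                    cigar = character(), seq = character()),
                n_skipped_unmapped = 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    format_error(sprintf("malformed SAM record (fewer than 11 fields): %s",
                         f[[which(nf < 11L)[1]]][1]))
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  f_m <- f[!unmapped]
  if (!length(f_m))
    return(list(placed = data.table(read_id = character(),
                                    individual = character(),
                                    contig = character(), start = integer(),
                                    cigar = character(), seq = character()),
                n_skipped_unmapped = sum(unmapped)))
  rname <- vapply(f_m, `[[`, character(1), 3L)
  bad <- !(rname %in% names(reference))
  if (any(bad))
    format_error(sprintf("alignment of read '%s' names unknown contig '%s'",
                         f_m[[which(bad)[1]]][1], rname[which(bad)[1]]))
  rg <- vapply(f_m, function(x) {
    tags <- x[-(1:11)]
    hit <- tags[startsWith(tags, "RG:Z:")]
    if (length(hit)) substring(hit[[1]], 6L) else NA_character_
  }, character(1))
  qname <- vapply(f_m, `[[`, character(1), 1L)
  fallback <- sub("\\|.*$", "", qname)
  ind <- ifelse(is.na(rg), ifelse(grepl("|", qname, fixed = TRUE),
                                  fallback, NA_character_), rg)
  if (anyNA(ind))
    format_error(sprintf(
      "cannot recover individual id for read '%s' (no RG tag, no '|' name)",
      qname[which(is.na(ind))[1]]))
  list(placed = data.table(
         read_id = qname, individual = ind, contig = rname,
         start = as.integer(vapply(f_m, `[[`, character(1), 4L)) - 1L,
         cigar = vapply(f_m, `[[`, character(1), 6L),
         seq = vapply(f_m, `[[`, character(1), 10L)),
       n_skipped_unmapped = sum(unmapped))
}

#' Repeat/mtDNA mask set
#'
#' Normalises repeat intervals (sorts and merges overlaps per contig) and
#' records which contigs are mitochondrial.
#'
#' @param intervals data.frame/data.table with columns contig, start, end
#'   (0-based half-open).
#' @param mtdna_contigs character vector of mtDNA contig ids.
#' @return a `mask_set` list.
#' @export
mask_set <- function(intervals = NULL, mtdna_contigs = character(0)) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    iv <- data.table(contig = character(), start = integer(),
                     end = integer())
  } else {
    iv <- as.data.table(intervals)[, .(contig, start = as.integer(start),
                                       end = as.integer(end))]
    if (any(iv$start < 0 | iv$end <= iv$start))
      config_error("intervals", "need 0 <= start < end")
    # merge per contig with IRanges (half-open -> closed and back)
    iv <- iv[, {
      r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
      .(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
    }, by = contig]
    setorder(iv, contig, start)
  }
  structure(list(intervals = iv,
                 mtdna_contigs = unique(as.character(mtdna_contigs))),
            class = "mask_set")
}

#' Test positions against a mask set
#' @param masks a [mask_set()].
#' @param contig,pos0 parallel vectors of positions.
#' @return logical: TRUE where masked (repeat overlap or mtDNA contig).
#' @export
in_mask <- function(masks, contig, pos0) {
  out <- contig %in% masks$mtdna_contigs
  iv <- masks$intervals
  if (nrow(iv)) {
    for (ci in unique(contig[!out])) {
      civ <- iv[iv$contig == ci, ]
      if (!nrow(civ)) next
      sel <- which(contig == ci & !out)
      for (s in sel)
        out[s] <- any(pos0[s] >= civ$start & pos0[s] < civ$end)
    }
  }
  out
}

#' Write/read masks as BED
#'
#' Repeat intervals get the name `repeat`; mtDNA contigs are emitted as one
#' whole-contig interval named `mtDNA` (contig lengths required to write).
#'
#' @param masks a [mask_set()].
#' @param path BED file.
#' @param contigs named character vector (needed to span mtDNA contigs).
#' @export
write_bed <- function(masks, path, contigs = NULL) {
  rows <- character(0)
  iv <- masks$intervals
  if (nrow(iv))
    rows <- sprintf("%s\t%d\t%d\trepeat", iv$contig, iv$start, iv$end)
  for (mt in masks$mtdna_contigs) {
    len <- if (!is.null(contigs) && mt %in% names(contigs))
      nchar(contigs[[mt]]) else 1L
    rows <- c(rows, sprintf("%s\t0\t%d\tmtDNA", mt, len))
  }
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) return(mask_set())
  f <- strsplit(raw, "\t", fixed = TRUE)
  dt <- data.table(contig = vapply(f, `[[`, character(1), 1L),
                   start = as.integer(vapply(f, `[[`, character(1), 2L)),
                   end = as.integer(vapply(f, `[[`, character(1), 3L)),
                   name = vapply(f, function(x)
                     if (length(x) >= 4L) x[[4L]] else "repeat", character(1)))
  mask_set(dt[name != "mtDNA", .(contig, start, end)],
           mtdna_contigs = dt[name == "mtDNA", unique(contig)])
}

#' Demultiplex barcoded reads
#'
#' Assigns a read to an individual iff its sequence starts with exactly one
#' of the MID barcodes; matching is an exact prefix match (no mismatch
#' tolerance), and the barcode is trimmed from assigned reads.
#'
#' @param reads data.table with read_id, sequence, quality.
#' @param barcode_map named character vector `individual -> barcode`,
#'   mutually prefix-free.
#' @return list with `assigned` (reads plus `individual`, barcode trimmed),
#'   `unassigned`, and `counts` (per-individual plus `unassigned`).
#' @export
demultiplex <- function(reads, barcode_map) {
  check_barcode_map(barcode_map, names(barcode_map))
  reads <- as.data.table(reads)
  malformed <- is.na(reads$sequence) | !nzchar(reads$sequence)
  if (any(malformed))
    warning(sprintf("%d malformed read record(s) routed to unassigned",
                    sum(malformed)))
  ind <- rep(NA_character_, nrow(reads))
  nb <- nchar(barcode_map)
  for (k in seq_along(barcode_map)) {
    hit <- !malformed & is.na(ind) &
      substr(reads$sequence, 1L, nb[[k]]) == barcode_map[[k]]
    ind[hit] <- names(barcode_map)[[k]]
  }
  assigned <- reads[!is.na(ind)]
  trim <- nb[match(ind[!is.na(ind)], names(barcode_map))]
  assigned[, individual := ind[!is.na(ind)]]
  assigned[, sequence := substring(sequence, trim + 1L)]
  assigned[, quality := substring(quality, trim + 1L)]
  counts <- c(table(factor(ind[!is.na(ind)], levels = names(barcode_map))),
              unassigned = sum(is.na(ind)))
  list(assigned = assigned, unassigned = reads[is.na(ind)], counts = counts)
}

#' Export validated loci as an assay design sheet
#'
#' One row per locus with the 50-bp flanks composed into bracket context
#' (`ACGT...[A/G]...TTCA`) plus any per-group minor-allele-frequency columns
#' supplied. Rows whose flanks are shorter than `flank_len` are refused with
#' a warning naming the locus.
#'
#' @param loci data.table of validated loci (locus_id, contig, pos0,
#'   focal_group, major, minor, left_flank, right_flank).
#' @param path CSV output.
#' @param maf optional MAF table (group, locus_id, maf) spread into columns.
#' @param flank_len required flank length.
#' @return the data.frame written, invisibly.
#' @export
write_assay_sheet <- function(loci, path, maf = NULL, flank_len = 50L) {
  loci <- as.data.table(loci)
  if (nrow(loci)) {
    short <- nchar(loci$left_flank) < flank_len |
             nchar(loci$right_flank) < flank_len
    if (any(short)) {
      warning(sprintf("refusing %d locus/loci with short flanks: %s",
                      sum(short),
                      paste(loci$locus_id[short], collapse = ", ")))
      loci <- loci[!short]
    }
  }
  setorder(loci, contig, pos0)
  out <- loci[, .(locus_id, contig, pos0, focal_group,
                  bracket_context = paste0(left_flank, "[", major, "/",
                                           minor, "]", right_flank))]
  if (!is.null(maf) && nrow(loci)) {
    maf <- as.data.table(maf)
    wide <- data.table::dcast(maf, locus_id ~ group, value.var = "maf")
    setnames(wide, setdiff(names(wide), "locus_id"),
             paste0("maf_", setdiff(names(wide), "locus_id")))
    out <- merge(out, wide, by = "locus_id", all.x = TRUE, sort = FALSE)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write validated loci as minimal VCF v4.2
#'
#' CHROM/POS/ID/REF/ALT plus per-group allele-frequency INFO keys
#' (`AF_<group>=` pooled-minor-allele frequency) -- enough for downstream
#' consumption, not a full VCF implementation.
#'
#' @param loci validated locus table (contig, pos0, locus_id, major, minor).
#' @param path output file.
#' @param group_af optional data.table (locus_id, group, af).
#' @export
write_vcf_minimal <- function(loci, path, group_af = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF_GRP,Number=.,Type=String,Description=\"Per-group minor allele frequency as group:af pairs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  loci <- as.data.table(loci)
  setorder(loci, contig, pos0)
  info <- rep(".", nrow(loci))
  if (!is.null(group_af)) {
    ga <- as.data.table(group_af)
    info <- vapply(loci$locus_id, function(id) {
      g <- ga[ga$locus_id == id, ]
      if (!nrow(g)) return(".")
      paste0("AF_GRP=", paste(sprintf("%s:%.4g", g$group, g$af),
                              collapse = ","))
    }, character(1))
  }
  rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                 loci$contig, loci$pos0 + 1L, loci$locus_id,
                 loci$major, loci$minor, info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write the truth SNP table as TSV
#' @param truth_snps data.table from [simulate_panel()].
#' @param path output file.
#' @export
write_truth_tsv <- function(truth_snps, path) {
  fwrite(truth_snps, path, sep = "\t")
  invisible(path)
}
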