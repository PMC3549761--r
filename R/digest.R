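#' Restriction enzymes used by the in-silico genome reduction
#'
#' Recognition sites and cut offsets follow the standard REBASE definitions:
#' EcoRI cuts G^AATTC (offset 1 into the site), BfaI cuts C^TAG (offset 1).
#' @keywords internal
ENZYMES <- list(
  EcoRI = list(site = "GAATTC", cut = 1L),
  BfaI  = list(site = "CTAG",   cut = 1L)
)

#' Double-digest a contig sequence
#'
#' Cuts the sequence at every EcoRI (G^AATTC) and BfaI (C^TAG) recognition
#' site and returns the resulting fragments, which tile the sequence exactly.
#' Each fragment records which enzyme (or the sequence terminus) produced
#' each of its ends.
#'
#' @param sequence a nucleotide string (A/C/G/T/N).
#' @param contig_id id attached to the emitted fragments.
#' @return a data.table with columns `contig`, `start`, `end` (0-based
#'   half-open) and `left_end`, `right_end` in `{"EcoRI","BfaI","terminus"}`.
#'   Empty sequence gives zero rows.
#' @examples
#' digest_genome("AAAGAATTCAAACTAGAAA", "c1")
#' @export
digest_genome <- function(sequence, contig_id = "contig") {
  empty <- data.table(contig = character(), start = integer(),
                      end = integer(), left_end = character(),
                      right_end = character())
  if (is.null(sequence) || !nzchar(sequence)) return(empty)
  if (grepl("[^ACGTN]", sequence))
    config_error("sequence", "contains characters outside A/C/G/T/N")
  cuts <- integer(0)
  labels <- character(0)
  subj <- Biostrings::DNAString(sequence)
  for (enz in names(ENZYMES)) {
    hits <- Biostrings::matchPattern(ENZYMES[[enz]]$site, subj, fixed = TRUE)
    if (length(hits)) {
      # cut position in 0-based coordinates: site start + offset
      cp <- BiocGenerics::start(hits) - 1L + ENZYMES[[enz]]$cut
      cuts <- c(cuts, cp)
      labels <- c(labels, rep(enz, length(cp)))
    }
  }
  o <- order(cuts)
  cuts <- cuts[o]; labels <- labels[o]
  keep <- cuts > 0L & cuts < nchar(sequence)
  cuts <- cuts[keep]; labels <- labels[keep]
  bounds <- c(0L, cuts, nchar(sequence))
  data.table(
    contig = contig_id,
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    left_end = c("terminus", labels),
    right_end = c(labels, "terminus")
  )
}

#' Digest every contig of a panel
#' @param panel a `truth_panel` (or any named character vector of sequences).
#' @return combined fragment table.
#' @export
digest_panel <- function(panel) {
  contigs <- if (inherits(panel, "truth_panel")) panel$contigs else panel
  rbindlist(lapply(names(contigs), function(id)
    digest_genome(contigs[[id]], id)))
}

#' Read-simulation and size-selection parameters
#'
#' Defaults emulate the sequencing conditions of a 454 Titanium run on a
#' double-digest reduced library: mean read length 379 bp and a 450-600 bp
#' fragment size-selection window. Only fragments carrying one EcoRI and one
#' BfaI end survive the reduction by default, mirroring selective adapter
#' capture; set `mixed_ends_only = FALSE` to disable.
#'
#' @param mean_read_length mean read length in bases.
#' @param read_length_sd standard deviation of read length.
#' @param mean_depth mean reads per retained fragment per individual.
#' @param depth_dispersion negative-binomial over-dispersion (0 = Poisson).
#' @param sub_error_rate per-base substitution error probability.
#' @param homopolymer_indel_rate per-homopolymer-run +/-1 indel probability
#'   (the dominant 454 error mode).
#' @param size_min,size_max inclusive size-selection bounds in bases.
#' @param mixed_ends_only retain only EcoRI/BfaI mixed-end fragments.
#' @param barcode_length length of the synthetic MID barcodes.
#' @param seed seed for the read stream.
#' @return a validated `read_sim_params` list.
#' @export
read_sim_params <- function(mean_read_length = 379,
                            read_length_sd = 60,
                            mean_depth = 6,
                            depth_dispersion = 0.5,
                            sub_error_rate = 0.002,
                            homopolymer_indel_rate = 0.002,
                            size_min = 450,
                            size_max = 600,
                            mixed_ends_only = TRUE,
                            barcode_length = 10L,
                            seed = 1L) {
  stopifnot_scalar_number(mean_read_length, "mean_read_length", min = 1)
  stopifnot_scalar_number(read_length_sd, "read_length_sd", min = 0)
  stopifnot_scalar_number(mean_depth, "mean_depth", min = 0)
  stopifnot_scalar_number(depth_dispersion, "depth_dispersion", min = 0)
  stopifnot_scalar_number(sub_error_rate, "sub_error_rate", min = 0, max = 1)
  stopifnot_scalar_number(homopolymer_indel_rate, "homopolymer_indel_rate",
                          min = 0, max = 1)
  stopifnot_scalar_number(size_min, "size_min", min = 0)
  stopifnot_scalar_number(size_max, "size_max", min = 0)
  if (size_min > size_max)
    config_error("size_min", "must be <= size_max")
  stopifnot_scalar_number(barcode_length, "barcode_length", min = 1,
                          integerish = TRUE)
  stopifnot_scalar_number(seed, "seed", min = 0, integerish = TRUE)
  structure(list(mean_read_length = mean_read_length,
                 read_length_sd = read_length_sd,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 sub_error_rate = sub_error_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 size_min = size_min, size_max = size_max,
                 mixed_ends_only = mixed_ends_only,
                 barcode_length = as.integer(barcode_length),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Size-select digestion fragments
#'
#' Emulates gel size selection plus selective adapter capture: keeps
#' fragments whose length lies in `[size_min, size_max]` (inclusive) and --
#' unless `mixed_ends_only` is disabled -- whose two ends were produced by
#' different enzymes (one EcoRI, one BfaI). Input order is preserved.
#'
#' @param fragments fragment table from [digest_genome()].
#' @param params a [read_sim_params()].
#' @return the retained subset of `fragments`.
#' @export
size_select <- function(fragments, params = read_sim_params()) {
  len <- fragments$end - fragments$start
  keep <- len >= params$size_min & len <= params$size_max
  if (isTRUE(params$mixed_ends_only)) {
    mixed <- (fragments$left_end == "EcoRI" & fragments$right_end == "BfaI") |
             (fragments$left_end == "BfaI" & fragments$right_end == "EcoRI")
    keep <- keep & mixed
  }
  fragments[keep]
}
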