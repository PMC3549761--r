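#' @importFrom data.table data.table as.data.table setorder setnames := .N .SD rbindlist fwrite fread setkey
#' @importFrom stats rnorm rpois rnbinom runif
#' @importFrom utils write.csv head modifyList
NULL

# Fixed base order used by every tie-break in the package.
BASES <- c("A", "C", "G", "T")

#' Signal a configuration error
#'
#' All user-input validation funnels through here so that callers can catch
#' a single condition class (`rrsnp_config_error`) and so that every message
#' names the offending field.
#'
#' @param field name of the offending field.
#' @param msg human-readable description.
#' @keywords internal
config_error <- function(field, msg) {
  stop(structure(
    class = c("rrsnp_config_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = sys.call(-1))
  ))
}

format_error <- function(msg) {
  stop(structure(
    class = c("rrsnp_format_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar_number <- function(x, field, min = -Inf, max = Inf,
                                    integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    config_error(field, "must be a single non-missing number")
  if (x < min || x > max)
    config_error(field, sprintf("must be in [%s, %s], got %s", min, max, x))
  if (integerish && x != as.integer(x))
    config_error(field, "must be a whole number")
  invisible(x)
}

#' Derive per-stage random seeds from one master seed
#'
#' A single integer seed governs every stochastic stage; stages draw from
#' separate streams split in a documented order (panel -> digest -> reads ->
#' genotypes) so that changing read-simulation settings never perturbs the
#' simulated panel. Derived seeds stay below 2^31.
#'
#' @param seed master seed (non-negative integer).
#' @param stage one of "panel", "digest", "reads", "genotypes".
#' @return an integer seed.
#' @export
split_seed <- function(seed, stage = c("panel", "digest", "reads", "genotypes")) {
  stage <- match.arg(stage)
  stopifnot_scalar_number(seed, "seed", min = 0, integerish = TRUE)
  offset <- c(panel = 1L, digest = 2L, reads = 3L, genotypes = 4L)[[stage]]
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# Random DNA of length n as a single string.
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Vector of single characters -> string and back.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
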