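#' Decoding specification for bitstring genotypes
#'
#' A genotype is a fixed-length vector of bits encoding every connection
#' weight of the neural controller, 8 bits per weight.  Each consecutive
#' 8-bit group, most-significant bit first, is read as an unsigned integer
#' `v` in 0..255 and mapped linearly onto
#' `weight_min + v/255 * (weight_max - weight_min)`, so both bounds are
#' exactly reachable.
#'
#' @param has_memory logical; `TRUE` selects the 191-weight topology with a
#'   memory input neuron, `FALSE` the 182-weight memoryless topology.
#' @param weight_min,weight_max decoded weight range.  The default
#'   `[-5, 5]` spans both the saturating and the near-linear regime of the
#'   logistic activation.
#' @return An object of class `decoding_spec`.
#' @export
decoding_spec <- function(has_memory = FALSE, weight_min = -5,
                          weight_max = 5) {
  stopifnot(is.logical(has_memory), length(has_memory) == 1L,
            is.numeric(weight_min), is.numeric(weight_max))
  if (weight_min >= weight_max) stop("weight_min must be < weight_max")
  structure(list(n_weights = if (has_memory) 191L else 182L,
                 bits_per_weight = 8L,
                 weight_min = as.numeric(weight_min),
                 weight_max = as.numeric(weight_max),
                 has_memory = has_memory),
            class = "decoding_spec")
}

#' @export
print.decoding_spec <- function(x, ...) {
  cat(sprintf("Decoding spec: %d weights x %d bits, range [%g, %g]%s\n",
              x$n_weights, x$bits_per_weight, x$weight_min, x$weight_max,
              if (x$has_memory) ", memory topology" else ""))
  invisible(x)
}

new_genome <- function(bits, spec) {
  structure(as.integer(bits), spec = spec, class = "genome")
}

validate_genome <- function(genome) {
  if (!inherits(genome, "genome")) stop("not a genome object")
  spec <- attr(genome, "spec")
  n <- spec$n_weights * spec$bits_per_weight
  if (length(genome) != n)
    stop(sprintf("invalid genome: expected %d bits, got %d", n,
                 length(genome)))
  if (anyNA(genome) || !all(genome == 0L | genome == 1L))
    stop("invalid genome: bits must all be 0 or 1")
  invisible(genome)
}

#' Random genotype
#'
#' Bits are i.i.d. fair coin flips, the initialization used for founding
#' populations ("robots with random connection weights").
#'
#' @param spec a [decoding_spec()].
#' @return A `genome` object.
#' @export
random_genome <- function(spec = decoding_spec()) {
  n <- spec$n_weights * spec$bits_per_weight
  new_genome(sample(0:1, n, replace = TRUE), spec)
}

#' Decode a genotype into connection weights
#'
#' @param genome a `genome` object.
#' @return Numeric vector of `n_weights` connection weights, each within
#'   the spec's `[weight_min, weight_max]`.
#' @examples
#' g <- random_genome()
#' range(decode_genome(g))
#' @export
decode_genome <- function(genome) {
  validate_genome(genome)
  spec <- attr(genome, "spec")
  m <- matrix(unclass(genome), nrow = spec$bits_per_weight)
  v <- as.vector(2^((spec$bits_per_weight - 1):0) %*% m)
  spec$weight_min + v / (2^spec$bits_per_weight - 1) *
    (spec$weight_max - spec$weight_min)
}

#' Mutate a genotype
#'
#' Each bit flips independently with probability `per_bit_rate`
#' (default 1e-2, the rate used throughout the evolutionary experiments).
#'
#' @param genome a `genome` object.
#' @param per_bit_rate per-bit flip probability in `[0, 1]`.
#' @return A new `genome`; the input is not modified.
#' @export
mutate_genome <- function(genome, per_bit_rate = 1e-2) {
  validate_genome(genome)
  if (!is.numeric(per_bit_rate) || length(per_bit_rate) != 1L ||
      is.na(per_bit_rate) || per_bit_rate < 0 || per_bit_rate > 1)
    stop("per_bit_rate must be a probability in [0, 1]")
  flips <- stats::runif(length(genome)) < per_bit_rate
  bits <- unclass(genome)
  bits[flips] <- 1L - bits[flips]
  new_genome(bits, attr(genome, "spec"))
}

#' Number of differing weight loci between two genotypes
#'
#' Counts weight positions (8-bit groups), not bits, at which the two
#' genomes differ — the "locus" unit in which mutational distances between
#' strategies are expressed.
#'
#' @param a,b `genome` objects sharing the same decoding spec.
#' @return Integer count in `0..n_weights`.
#' @export
weight_distance <- function(a, b) {
  validate_genome(a); validate_genome(b)
  sa <- attr(a, "spec"); sb <- attr(b, "spec")
  if (!identical(sa, sb)) stop("incompatible genomes: decoding specs differ")
  diff <- matrix(unclass(a) != unclass(b), nrow = sa$bits_per_weight)
  sum(colSums(diff) > 0L)
}

#' @export
print.genome <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Genotype: %d bits (%d weights x %d)%s\n", length(x),
              spec$n_weights, spec$bits_per_weight,
              if (spec$has_memory) ", memory topology" else ""))
  invisible(x)
}

#' Write a genotype to a text file
#'
#' Format: one header line
#' `# n_weights=<int> bits_per_weight=8 weight_min=<real> weight_max=<real>
#' memory=<0|1>` followed by one line of '0'/'1' characters.  Round-trips
#' exactly through [read_genotype()].
#'
#' @param genome a `genome` object.
#' @param path output file path.
#' @export
write_genotype <- function(genome, path) {
  validate_genome(genome)
  spec <- attr(genome, "spec")
  header <- sprintf(
    "# n_weights=%d bits_per_weight=%d weight_min=%s weight_max=%s memory=%d",
    spec$n_weights, spec$bits_per_weight,
    format(spec$weight_min, digits = 17), format(spec$weight_max, digits = 17),
    as.integer(spec$has_memory))
  writeLines(c(header, paste(unclass(genome), collapse = "")), path)
  invisible(path)
}

#' Read a genotype from a text file
#'
#' @param path file written by [write_genotype()].
#' @return A `genome` object.
#' @export
read_genotype <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "#"))
    stop("malformed genotype file: ", path)
  kv <- regmatches(lines[1L], gregexpr("[a-z_]+=[-0-9.eE+]+", lines[1L]))[[1L]]
  fields <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  needed <- c("n_weights", "bits_per_weight", "weight_min", "weight_max",
              "memory")
  if (!all(needed %in% names(fields)))
    stop("genotype file header missing fields: ",
         paste(setdiff(needed, names(fields)), collapse = ", "))
  spec <- decoding_spec(has_memory = fields[["memory"]] == 1,
                        weight_min = fields[["weight_min"]],
                        weight_max = fields[["weight_max"]])
  if (spec$n_weights != fields[["n_weights"]])
    stop("genotype file n_weights inconsistent with memory flag")
  bits <- as.integer(strsplit(lines[2L], "")[[1L]])
  g <- new_genome(bits, spec)
  validate_genome(g)
  g
}
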