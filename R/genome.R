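# Genome encoding, decoding and mutation.
#
# A genome is a sequence of integer loci in 0..255. Genes start at the codon
# pair (42, 213) and encode, in fixed-width fields: gate type, arities i and
# o (1 + locus mod 4), four input and four output addresses (mod n_nodes;
# the first i / o are used), the probability payload, and for feedback types
# a block of (positive node, negative node, history length mod 4, three
# positive and three negative per-depth deltas scaled to [0, 0.5]).
# Payloads: deterministic gates take 2^i loci (locus mod 2^o = the chosen
# output pattern); decomposable types take 2^i * o factor loci (v / 255);
# non-decomposable probabilistic types take 2^i * 2^o loci, row-normalised
# with +1 smoothing.

.genome_len_min <- 1000L
.genome_len_max <- 20000L

.enabled_type_ids <- function(gate_set) {
  ids <- .gate_type_ids[gate_set]
  if (anyNA(ids)) stop("unknown gate type in gate_set")
  as.integer(unname(ids))
}

#' Default gate repertoire
#'
#' Deterministic, decomposable, and decomposable feedback gates. The
#' non-decomposable probabilistic and legacy feedback types can be enabled
#' explicitly, but break the factorisability that integrated-information
#' analysis requires.
#' @return character vector of gate type names.
#' @export
default_gate_set <- function() {
  c("deterministic", "decomposable", "decomposable_feedback")
}

#' Generate a random genome
#'
#' Uniform random loci plus `seeded_codons` start codons written at random
#' positions, so initial brains are rarely empty.
#'
#' @param length genome length (default 5000).
#' @param seeded_codons number of start codons to plant.
#' @return integer vector of loci in 0..255.
#' @export
random_genome <- function(length = 5000L, seeded_codons = 4L) {
  g <- sample(0:255, length, replace = TRUE)
  if (seeded_codons > 0 && length >= 2) {
    at <- sample(length - 1L, min(seeded_codons, length - 1L))
    g[at] <- 42L
    g[at + 1L] <- 213L
  }
  as.integer(g)
}

#' Mutation rate settings
#'
#' @param point per-locus probability of redrawing a locus uniformly.
#' @param duplication per-offspring probability of duplicating one random
#'   gene (codon plus body) at a random position.
#' @param deletion per-offspring probability of deleting one random gene.
#' @return a list of rates.
#' @export
mutation_rates <- function(point = 0.005, duplication = 0.05,
                           deletion = 0.05) {
  stopifnot(point >= 0, point <= 1, duplication >= 0, duplication <= 1,
            deletion >= 0, deletion <= 1)
  list(point = point, duplication = duplication, deletion = deletion)
}

#' Decode a genome into a Markov Brain
#'
#' Scans the genome for start codons and decodes each complete gene into a
#' gate; genes truncated by the genome end are skipped. Decoding is a pure
#' function of the genome: the same genome always yields an identical brain.
#'
#' @param genome integer vector of loci in 0..255.
#' @param n_nodes brain size (default 16).
#' @param gate_set character vector of enabled gate types; the type locus is
#'   interpreted modulo its length.
#' @param learning_enabled passed through to the brain.
#' @return a `markov_brain`.
#' @export
decode_genome <- function(genome, n_nodes = 16L,
                          gate_set = default_gate_set(),
                          learning_enabled = TRUE) {
  b <- cpp_decode_genome(as.integer(genome), as.integer(n_nodes),
                         .enabled_type_ids(gate_set), isTRUE(learning_enabled))
  b$gates <- lapply(b$gates, function(g) { class(g) <- "gate"; g })
  class(b) <- "markov_brain"
  b
}

#' Mutate a genome
#'
#' Point mutations redraw binomially-many loci uniformly on 0..255; with the
#' stated per-offspring probabilities one random gene is duplicated and one
#' deleted (skipped when the result would leave the 1000--20000 length
#' bounds).
#'
#' @param genome integer vector of loci.
#' @param rates a [mutation_rates()] list.
#' @param gate_set enabled gate types (gene boundaries depend on the type
#'   map).
#' @return the offspring genome.
#' @export
mutate_genome <- function(genome, rates = mutation_rates(),
                          gate_set = default_gate_set()) {
  cpp_mutate(as.integer(genome), .enabled_type_ids(gate_set),
             rates$point, rates$duplication, rates$deletion,
             .genome_len_min, .genome_len_max)
}

#' Hash a genome (FNV-1a, 32 bit)
#' @param genome integer vector of loci.
#' @return the hash as a double.
#' @export
genome_hash <- function(genome) {
  cpp_genome_hash(as.integer(genome))
}

#' Write genomes to a plain-text archive (one per line, comma-separated)
#' @param genomes a list of integer vectors.
#' @param path output file.
#' @export
write_genomes <- function(genomes, path) {
  writeLines(vapply(genomes, paste, character(1), collapse = ","), path)
}

#' Read genomes written by [write_genomes()]
#' @param path input file.
#' @return list of integer vectors.
#' @export
read_genomes <- function(path) {
  lapply(strsplit(readLines(path), ","), as.integer)
}
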