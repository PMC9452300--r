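#' Log partition weight of the constrained grammar
#'
#' Runs the inside algorithm and returns the log of the total derivation
#' weight summed over all nested structures compatible with the
#' constraints. Mostly useful for testing the engine against exhaustive
#' enumeration on short sequences.
#'
#' @param sequence RNA/DNA sequence string (alphabet A,C,G,U/T,N).
#' @param grammar an [scfg_grammar()].
#' @param constraints logical vector of `force_unpaired` flags (length of
#'   the sequence), or `NULL` for unconstrained.
#' @return Log total weight (natural log).
#' @export
inside_partition <- function(sequence, grammar = scfg_grammar(),
                             constraints = NULL) {
  codes <- .encode_sequence(sequence)
  constraints <- .check_constraints(constraints, length(codes))
  res <- .scfg_run(codes, constraints, .pair_matrix(grammar),
                   grammar$unpaired_weight, grammar$stack_bonus,
                   grammar$init_penalty, grammar$min_hairpin, 0L, 1L)
  res$logZ
}

.check_constraints <- function(constraints, L) {
  if (is.null(constraints)) return(rep(FALSE, L))
  if (is.numeric(constraints)) constraints <- constraints != 0
  stopifnot(is.logical(constraints))
  if (length(constraints) != L)
    .stopf("constraints have length %d but the sequence has length %d",
           length(constraints), L)
  constraints[is.na(constraints)] <- FALSE
  constraints
}

#' Sample secondary structures from the constrained grammar
#'
#' Draws pseudoknot-free structures by stochastic traceback of the inside
#' table, each with probability proportional to its derivation weight.
#' Positions flagged `force_unpaired` can only be emitted unpaired, so
#' every returned structure honours the constraints exactly. Output is
#' deterministic for a fixed seed.
#'
#' @inheritParams inside_partition
#' @param n_samples number of structures to draw.
#' @param seed integer seed for the sampler's own generator (independent of
#'   R's RNG state).
#' @return Character vector of `n_samples` dot-bracket strings.
#' @examples
#' sample_structures("GGGGAAAACCCC", n_samples = 5, seed = 1)
#' @export
sample_structures <- function(sequence, grammar = scfg_grammar(),
                              constraints = NULL, n_samples = 1L,
                              seed = 1L) {
  if (!.is_count(n_samples) || n_samples < 1)
    .stopf("n_samples must be a positive integer")
  if (!.is_count(seed)) .stopf("seed must be an integer")
  codes <- .encode_sequence(sequence)
  constraints <- .check_constraints(constraints, length(codes))
  res <- .scfg_run(codes, constraints, .pair_matrix(grammar),
                   grammar$unpaired_weight, grammar$stack_bonus,
                   grammar$init_penalty, grammar$min_hairpin,
                   as.integer(n_samples), as.integer(seed))
  res$structures
}

#' Derive single-strandedness constraints from one bit vector
#'
#' Mutation codes of 1 mark chemically modified, hence single-stranded,
#' nucleotides and become `force_unpaired`. Codes of 0 and masked positions
#' carry no evidence and stay unconstrained.
#'
#' @param codes integer vector over \{0, 1, NA\} (NA = masked).
#' @return Logical `force_unpaired` vector.
#' @export
constraints_from_codes <- function(codes) {
  !is.na(codes) & codes == 1L
}

#' Fold every molecule under its own constraints
#'
#' For each bit vector the mutation pattern is turned into hard
#' single-strandedness constraints and `samples_per_molecule` structures
#' are sampled. Child seeds are split off the root seed with a fixed
#' splitmix64 stream, so each molecule's draw is independent of processing
#' order and the whole result is reproducible.
#'
#' @param bitvectors a [bitvector_set] whose reference matches `sequence`.
#' @param sequence the reference sequence.
#' @param grammar an [scfg_grammar()].
#' @param samples_per_molecule structures to draw per molecule (default 1:
#'   one conformation per molecule; increase for highly diverse
#'   transcripts).
#' @param seed root integer seed.
#' @return A data.frame with columns `read_id`, `sample`, `db`.
#' @export
sample_per_molecule <- function(bitvectors, sequence,
                                grammar = scfg_grammar(),
                                samples_per_molecule = 1L, seed = 1L) {
  stopifnot(inherits(bitvectors, "bitvector_set"))
  L <- nchar(sequence)
  if (ncol(bitvectors$codes) != L)
    .stopf("bit vectors are length %d but the sequence is length %d",
           ncol(bitvectors$codes), L)
  n <- nrow(bitvectors$codes)
  if (n == 0L)
    return(data.frame(read_id = character(0), sample = integer(0),
                      db = character(0), stringsAsFactors = FALSE))
  seeds <- .derive_seeds(as.integer(seed), n)
  dbs <- vector("list", n)
  for (m in seq_len(n)) {
    cons <- constraints_from_codes(bitvectors$codes[m, ])
    dbs[[m]] <- sample_structures(sequence, grammar, cons,
                                  n_samples = samples_per_molecule,
                                  seed = seeds[m])
  }
  data.frame(read_id = rep(bitvectors$read_id, each = samples_per_molecule),
             sample = rep(seq_len(samples_per_molecule), times = n),
             db = unlist(dbs), stringsAsFactors = FALSE)
}

#' Unconstrained in-silico structural ensemble
#'
#' Samples an unconstrained Boltzmann-style ensemble from the grammar
#' (default 10,000 structures), so purely sequence-driven ensembles can be
#' fed through the same landscape stages as probing-derived structures.
#'
#' @inheritParams sample_structures
#' @export
in_silico_ensemble <- function(sequence, grammar = scfg_grammar(),
                               n_samples = 10000L, seed = 1L) {
  sample_structures(sequence, grammar, constraints = NULL,
                    n_samples = n_samples, seed = seed)
}
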