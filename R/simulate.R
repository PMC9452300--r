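#' Simulation configuration for synthetic probing data
#'
#' Describes a ground-truth conformational mixture and the per-position
#' Bernoulli modification model: in the treated channel, unpaired
#' positions of a molecule's conformation mutate with `p_unpaired_mod` and
#' paired positions with `p_paired_mod`; the control channel mutates
#' uniformly with `p_background`. The default rates emulate sparse
#' single-molecule SHAPE signal on high-accuracy long reads.
#'
#' @param sequence reference sequence.
#' @param conformations character vector of ground-truth dot-bracket
#'   strings (same length as the sequence).
#' @param weights mixture weights (must sum to 1).
#' @param n_molecules molecules per channel.
#' @param p_unpaired_mod treated-channel modification rate at unpaired
#'   positions (default 0.06).
#' @param p_paired_mod treated-channel rate at paired positions (default
#'   0.005; must be below `p_unpaired_mod`).
#' @param p_background control-channel rate at all positions (default
#'   0.002).
#' @param seed integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sequence, conformations, weights,
                              n_molecules = 1000L,
                              p_unpaired_mod = 0.06,
                              p_paired_mod = 0.005,
                              p_background = 0.002,
                              seed = 1L) {
  L <- nchar(sequence)
  stopifnot(length(conformations) >= 1L,
            length(weights) == length(conformations))
  if (any(nchar(conformations) != L))
    .stopf("conformations must match the sequence length (%d)", L)
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    .stopf("weights must be non-negative and sum to 1")
  if (!(p_paired_mod >= 0 && p_paired_mod < p_unpaired_mod &&
        p_unpaired_mod <= 1))
    .stopf("need 0 <= p_paired_mod < p_unpaired_mod <= 1")
  if (p_background < 0) .stopf("p_background must be >= 0")
  if (!.is_count(n_molecules) || n_molecules < 1)
    .stopf("n_molecules must be a positive integer")
  structure(list(sequence = sequence, conformations = conformations,
                 weights = weights, n_molecules = as.integer(n_molecules),
                 p_unpaired_mod = p_unpaired_mod,
                 p_paired_mod = p_paired_mod,
                 p_background = p_background,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate probing bit vectors from a conformational mixture
#'
#' Each molecule draws a ground-truth conformation from the mixture
#' weights, then mutates Bernoulli-independently per position according to
#' its pairedness. The control channel is an independent set of molecules
#' with uniform background mutation. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A list with `plus` and `minus` ([bitvector_set]s) and `truth`
#'   (data.frame `read_id`, `conformation`).
#' @export
simulate_probing <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- nchar(config$sequence)
  n <- config$n_molecules
  K <- length(config$conformations)
  paired <- t(vapply(config$conformations,
                     function(db) strsplit(db, "")[[1]] != ".",
                     logical(L), USE.NAMES = FALSE))
  withr::with_seed(config$seed, {
    z <- sample.int(K, n, replace = TRUE, prob = config$weights)
    rates <- matrix(config$p_unpaired_mod, n, L)
    rates[paired[z, , drop = FALSE]] <- config$p_paired_mod
    plus_codes <- matrix(rbinom(n * L, 1L, as.vector(rates)), n, L)
    minus_codes <- matrix(rbinom(n * L, 1L, config$p_background), n, L)
  })
  plus_ids <- sprintf("mol_%05d", seq_len(n))
  minus_ids <- sprintf("ctl_%05d", seq_len(n))
  list(plus = bitvector_set("ref", plus_ids, "plus", plus_codes),
       minus = bitvector_set("ref", minus_ids, "minus", minus_codes),
       truth = data.frame(read_id = plus_ids, conformation = z,
                          stringsAsFactors = FALSE))
}

#' Emit simulated bit vectors as SAM alignment records
#'
#' Writes one perfectly coordinated, full-length primary alignment per
#' molecule: code-1 positions are re-encoded as substitutions (a fixed
#' non-reference base per reference base), so extracting bit vectors from
#' the emitted SAM recovers the input exactly for mask-free bit vectors.
#'
#' @param bitvectors a mask-free [bitvector_set].
#' @param sequence the reference sequence.
#' @param path output `.sam` path.
#' @param reference_id reference name written to the header.
#' @return `path`, invisibly.
#' @export
emit_sam <- function(bitvectors, sequence, path, reference_id = NULL) {
  stopifnot(inherits(bitvectors, "bitvector_set"))
  if (anyNA(bitvectors$codes))
    .stopf("emit_sam requires mask-free bit vectors")
  if (is.null(reference_id)) reference_id <- bitvectors$reference_id
  refchars <- strsplit(toupper(sequence), "")[[1]]
  refchars[refchars == "U"] <- "T"
  L <- length(refchars)
  if (ncol(bitvectors$codes) != L)
    .stopf("sequence length does not match the bit vectors")
  # fixed non-reference substitution per base
  sub_map <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  n <- nrow(bitvectors$codes)
  recs <- character(n)
  for (m in seq_len(n)) {
    rd <- refchars
    mut <- which(bitvectors$codes[m, ] == 1L)
    rd[mut] <- sub_map[rd[mut]]
    recs[m] <- paste(bitvectors$read_id[m], 0L, reference_id, 1L, 60L,
                     paste0(L, "M"), "*", 0L, 0L,
                     paste(rd, collapse = ""), "*", sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", reference_id, L))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Three-conformation toy transcript
#'
#' A ~120-nt (125-nt) sequence built from six 20-nt blocks separated by
#' single adenine spacers, `A1 a B1 a C1 a A2 a B2 a C2`, with
#' `A2 = rc(A1)`, `B2 = rc(B1)`, `C2 = rc(C1)`. The three 20-pair helices
#' A1:A2, B1:B2 and C1:C2 are pairwise interleaved, so a pseudoknot-free
#' structure can hold pairs from at most one of them: the three
#' conformations are mutually exclusive by topology. Each helix closes 10
#' CG and 10 AU pairs with 19 stacking steps and leaves 85 unpaired
#' positions, so all three conformations carry identical grammar weight.
#' The block sequences were designed once, by annealing, to suppress
#' register slippage and cross-block parasitic helices: blocks A1 and C1
#' use only A/C, the middle block B1 only G/U (so that no two blocks other
#' than designed partners can form more than a few Watson-Crick pairs),
#' and the spacers prevent any helix from extending across a block
#' boundary.
#'
#' @return A list with `sequence`, `conformations` (3 named dot-bracket
#'   strings) and `blocks` (block coordinates).
#' @examples
#' toy <- toy_threeway()
#' nchar(toy$sequence)
#' @export
toy_threeway <- function() {
  rc <- function(s) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  a1 <- "CCACAAAAACCCCACACACA"
  b1 <- "UUGGGUGGGUUGUUUGGGUU"
  c1 <- "CCCAAACCAAACACAACCCA"
  seq <- paste0(a1, "A", b1, "A", c1, "A", rc(a1), "A", rc(b1), "A", rc(c1))
  helix_db <- function(open_start, close_start) {
    db <- rep(".", 125L)
    db[open_start:(open_start + 19L)] <- "("
    db[close_start:(close_start + 19L)] <- ")"
    paste(db, collapse = "")
  }
  list(sequence = seq,
       conformations = c(A = helix_db(1L, 64L),
                         B = helix_db(22L, 85L),
                         C = helix_db(43L, 106L)),
       blocks = data.frame(block = c("A1", "B1", "C1", "A2", "B2", "C2"),
                           start = c(1L, 22L, 43L, 64L, 85L, 106L),
                           end = c(20L, 41L, 62L, 83L, 104L, 125L)))
}
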