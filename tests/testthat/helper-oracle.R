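# Independent brute-force oracle for the SCFG sampler: exhaustively
# enumerates every pseudoknot-free structure (canonical pairs, hairpin
# loops >= min_hairpin) of a short sequence and scores each structure
# directly from its pair set. Written independently of the inside/
# traceback engine.

CANONICAL <- c("AU", "UA", "CG", "GC", "GU", "UG")

enum_structures <- function(seq, min_hairpin = 3) {
  chars <- strsplit(toupper(gsub("T", "U", seq)), "")[[1]]
  ok <- function(a, b) paste0(chars[a], chars[b]) %in% CANONICAL
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i + 1L, j)                     # i unpaired
    ks <- seq.int(i + min_hairpin + 1L, j)
    for (k in ks[ks <= j & ks >= i + min_hairpin + 1L]) {
      if (!ok(i, k)) next
      for (ins in rec(i + 1L, k - 1L))
        for (outr in rec(k + 1L, j))
          out[[length(out) + 1L]] <- rbind(c(i, k), ins, outr)
    }
    out
  }
  if (length(chars) == 0L) return(list())
  rec(1L, length(chars))
}

# direct structure weight: q_u^unpaired * prod pair weights
# * stack^(pairs with immediately enclosing pair) * init^(helices)
oracle_weight <- function(pairs, seq, grammar = scfg_grammar()) {
  chars <- strsplit(toupper(gsub("T", "U", seq)), "")[[1]]
  L <- length(chars)
  m <- nrow(pairs)
  w <- grammar$unpaired_weight^(L - 2L * m)
  if (m > 0L) {
    key <- paste0(chars[pairs[, 1L]], chars[pairs[, 2L]])
    w <- w * prod(grammar$pair_weights[key])
    pk <- paste(pairs[, 1L], pairs[, 2L])
    stacked <- sum(paste(pairs[, 1L] - 1L, pairs[, 2L] + 1L) %in% pk)
    w <- w * grammar$stack_bonus^stacked *
      grammar$init_penalty^(m - stacked)
  }
  w
}

# exact structure distribution of a short sequence: named probabilities
# keyed by dot-bracket
oracle_distribution <- function(seq, grammar = scfg_grammar(),
                                min_hairpin = grammar$min_hairpin) {
  structs <- enum_structures(seq, min_hairpin)
  w <- vapply(structs, oracle_weight, numeric(1), seq = seq,
              grammar = grammar)
  dbs <- vapply(structs, pairs_to_db, character(1), length = nchar(seq))
  stats::setNames(w / sum(w), dbs)
}

# short sequences used for exactness checks (all <= 14 nt)
sampler_fixtures <- function() {
  c("AAAA", "GCGAAACGC", "GGGGAAAACCCC", "GCAGCAAACUGCAA",
    "ACGUACGUACGU", "CCGGAAAAUUGG")
}

# simple SAM text writer for hand-built alignment fixtures
write_test_sam <- function(path, ref_id, ref_len, records) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_id, ref_len))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, rname, pos, cigar, seq, flag = 0L,
                       mapq = 60L, qual = "*") {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}
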