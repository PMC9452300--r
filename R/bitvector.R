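#' Per-molecule mutation bit vectors
#'
#' A `bitvector_set` holds one mutation bit vector per retained read:
#' an integer matrix with one row per read and one column per reference
#' position, coded 0 (match), 1 (mutation) or `NA` (masked /
#' uninformative). Masked positions never enter any rate denominator.
#'
#' @param reference_id reference identifier.
#' @param read_id character vector of read names.
#' @param channel `"plus"` (reagent-treated) or `"minus"` (control).
#' @param codes integer matrix over \{0, 1, NA\}, rows = reads.
#' @param n_insertions per-read insertion counts (QC only).
#' @return An object of class `bitvector_set`.
#' @export
bitvector_set <- function(reference_id, read_id, channel, codes,
                          n_insertions = rep(0L, nrow(codes))) {
  channel <- match.arg(channel, c("plus", "minus"))
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != length(read_id))
    .stopf("codes has %d rows but read_id has length %d",
           nrow(codes), length(read_id))
  if (!all(codes %in% c(0L, 1L, NA_integer_)))
    .stopf("codes must contain only 0, 1 or NA")
  structure(list(reference_id = reference_id,
                 read_id = as.character(read_id),
                 channel = channel,
                 codes = codes,
                 n_insertions = as.integer(n_insertions)),
            class = "bitvector_set")
}

#' @export
print.bitvector_set <- function(x, ...) {
  cat(sprintf("bitvector_set: %d reads x %d positions (%s channel, reference '%s')\n",
              nrow(x$codes), ncol(x$codes), x$channel, x$reference_id))
  invisible(x)
}

#' Read alignment records from SAM or BAM
#'
#' Thin wrapper around Rsamtools; plain-text SAM is converted to BAM in a
#' temporary directory first.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return A list of alignment fields as returned by
#'   [Rsamtools::scanBam()].
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) .stopf("alignment file not found: %s", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
}

#' Extract mutation bit vectors from aligned reads
#'
#' Converts primary alignments against one reference into per-molecule
#' mutation bit vectors. Mismatches and unambiguously aligned deletions
#' become 1; aligned matches become 0; soft-clipped or uncovered reference
#' positions stay masked (`NA`). A deletion is treated as ambiguous when
#' the deleted base sits in (or adjacent to) a reference homopolymer run of
#' length >= 2 of that base; the whole run is then masked, because the
#' deletion's placement within the run is arbitrary. Insertions carry no
#' reference coordinate and are only counted for QC.
#'
#' @param alignments a `.sam`/`.bam` path or the result of
#'   [read_alignments()].
#' @param reference named character vector of length 1 (name = reference
#'   id, value = sequence), or a `Biostrings::XStringSet` of length 1.
#' @param channel `"plus"` or `"minus"`.
#' @param min_coverage minimum fraction of reference positions a read must
#'   align across to be retained (default 0.9, so every bit vector informs
#'   full-length structure).
#' @param min_base_quality optional Phred threshold; aligned positions with
#'   lower read base quality are masked. Default `NULL`: no quality
#'   filter, appropriate for high-accuracy consensus long reads.
#' @return A [bitvector_set].
#' @export
extract_bitvectors <- function(alignments, reference, channel = "plus",
                               min_coverage = 0.9,
                               min_base_quality = NULL) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignments(alignments)
  ref <- .as_reference(reference)
  L <- nchar(ref$sequence)
  refchars <- strsplit(toupper(ref$sequence), "")[[1]]
  refchars[refchars == "U"] <- "T"  # SAM reads are in DNA alphabet
  hp_run <- .homopolymer_runs(refchars)

  n_aln <- length(alignments$qname)
  keep_rows <- list(); read_ids <- character(0); nins <- integer(0)
  if (n_aln > 0) {
    flags <- alignments$flag
    primary <- bitwAnd(flags, 0x904L) == 0L  # mapped, not secondary/supplementary
    rnames <- as.character(alignments$rname)
    wrong_ref <- primary & !is.na(rnames) & rnames != ref$id
    if (any(wrong_ref))
      .warnf("skipping %d read(s) aligned to a different reference",
             sum(wrong_ref))
    use <- which(primary & !wrong_ref & !is.na(alignments$pos))
    seqs <- as.character(alignments$seq)
    quals <- if (!is.null(min_base_quality)) as(alignments$qual, "IntegerList")
    for (a in use) {
      walk <- .walk_alignment(cigar = alignments$cigar[a],
                              pos = alignments$pos[a],
                              read = seqs[a],
                              refchars = refchars, hp_run = hp_run,
                              qual = if (!is.null(min_base_quality)) quals[[a]],
                              min_q = min_base_quality)
      if (is.null(walk)) next
      if (walk$covered / L < min_coverage) next
      keep_rows[[length(keep_rows) + 1L]] <- walk$codes
      read_ids <- c(read_ids, alignments$qname[a])
      nins <- c(nins, walk$n_ins)
    }
  }
  codes <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    matrix(NA_integer_, 0L, L)
  bitvector_set(ref$id, read_ids, channel, codes, nins)
}

.as_reference <- function(reference) {
  if (inherits(reference, "XStringSet")) {
    if (length(reference) != 1L)
      .stopf("supply exactly one reference record")
    return(list(id = names(reference)[1L],
                sequence = as.character(reference[[1L]])))
  }
  stopifnot(is.character(reference), length(reference) == 1L)
  if (is.null(names(reference)))
    .stopf("the reference must be named by its id")
  list(id = names(reference), sequence = unname(reference))
}

# run id per position of the maximal homopolymer run containing it
.homopolymer_runs <- function(refchars) {
  r <- rle(refchars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(start = rep(starts, r$lengths), end = rep(ends, r$lengths))
}

# Walk one CIGAR against the reference; returns codes, coverage and
# insertion count, or NULL for unusable records.
.walk_alignment <- function(cigar, pos, read, refchars, hp_run,
                            qual = NULL, min_q = NULL) {
  L <- length(refchars)
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  codes <- rep(NA_integer_, L)
  readchars <- strsplit(toupper(read), "")[[1]]
  readchars[readchars == "U"] <- "T"
  rp <- pos; qp <- 1L; covered <- 0L; n_ins <- 0L
  ambiguous <- integer(0)  # masked after the walk so later ops cannot unmask
  for (k in seq_along(ops)) {
    op <- ops[k]; n <- lens[k]
    if (op %in% c("M", "=", "X")) {
      idx <- rp:(rp + n - 1L)
      if (any(idx > L)) return(NULL)  # alignment runs off the reference
      codes[idx] <- ifelse(readchars[qp:(qp + n - 1L)] == refchars[idx], 0L, 1L)
      if (!is.null(min_q) && !is.null(qual)) {
        lowq <- qual[qp:(qp + n - 1L)] < min_q
        codes[idx][lowq] <- NA_integer_
      }
      covered <- covered + n
      rp <- rp + n; qp <- qp + n
    } else if (op == "D") {
      idx <- rp:(rp + n - 1L)
      if (any(idx > L)) return(NULL)
      for (p in idx) {
        rs <- hp_run$start[p]; re <- hp_run$end[p]
        if (re - rs + 1L >= 2L) {
          ambiguous <- c(ambiguous, rs:re)  # ambiguous placement: mask the run
        } else {
          codes[p] <- 1L
        }
      }
      covered <- covered + n
      rp <- rp + n
    } else if (op == "N") {
      rp <- rp + n  # skipped region: stays masked
    } else if (op == "I") {
      n_ins <- n_ins + n
      qp <- qp + n
    } else if (op == "S") {
      qp <- qp + n
    }
    # H and P consume neither sequence
  }
  codes[ambiguous] <- NA_integer_
  list(codes = codes, covered = covered, n_ins = n_ins)
}

#' Assign a read to its best-matching reference isoform
#'
#' @param scores named numeric vector of per-reference alignment scores.
#' @return The reference id with the maximal score (ties broken
#'   lexicographically), or `NA_character_` when no valid score exists.
#' @examples
#' assign_isoform(c(II.i = 540, II.ii = 310))
#' @export
assign_isoform <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) return(NA_character_)
  cand <- names(scores)[scores == max(scores)]
  sort(cand)[1L]
}

#' Read and write bit-vector tables
#'
#' The TSV dialect has columns `read_id`, `reference_id`, `channel` and
#' `codes`, the last being a string over `0`, `1` and `?` (masked).
#'
#' @param bitvectors a [bitvector_set].
#' @param path file path.
#' @export
write_bitvectors <- function(bitvectors, path) {
  stopifnot(inherits(bitvectors, "bitvector_set"))
  code_str <- apply(bitvectors$codes, 1L, function(r) {
    r <- as.character(r)
    r[is.na(r)] <- "?"
    paste(r, collapse = "")
  })
  n <- length(bitvectors$read_id)
  if (length(code_str) == 0L) code_str <- character(0)
  df <- data.frame(read_id = bitvectors$read_id,
                   reference_id = rep(bitvectors$reference_id, n),
                   channel = rep(bitvectors$channel, n),
                   codes = code_str, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bitvectors
#' @export
read_bitvectors <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  if (nrow(df) == 0L) .stopf("empty bit-vector table: %s", path)
  L <- nchar(df$codes[1L])
  codes <- t(vapply(strsplit(df$codes, ""), function(ch) {
    v <- suppressWarnings(as.integer(ch))
    v
  }, integer(L)))
  bitvector_set(df$reference_id[1L], df$read_id, df$channel[1L], codes)
}
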