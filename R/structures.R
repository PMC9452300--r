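#' Convert a dot-bracket string to a base-pair table
#'
#' @param db a single dot-bracket string over `.`, `(`, `)`.
#' @return Integer matrix with columns `i`, `j` (1-based, `i < j`), one row
#'   per pair, ordered by `i`.
#' @examples
#' db_to_pairs("((...))")
#' @export
db_to_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L, !is.na(db))
  chars <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad))
    .stopf("dot-bracket contains unsupported characters: %s",
           paste(bad, collapse = " "))
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  ii <- integer(length(chars)); jj <- integer(length(chars)); np <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) .stopf("unbalanced dot-bracket: ')' at position %d", k)
      np <- np + 1L
      ii[np] <- open[length(open)]
      jj[np] <- k
      open <- open[-length(open)]
    }
  }
  if (length(open))
    .stopf("unbalanced dot-bracket: %d unmatched '('", length(open))
  if (np > 0L) {
    out <- cbind(i = ii[seq_len(np)], j = jj[seq_len(np)])
    out <- out[order(out[, 1L]), , drop = FALSE]
  }
  out
}

#' Convert a base-pair table to a dot-bracket string
#'
#' @param pairs integer matrix with columns `i`, `j` (1-based); pairs must
#'   be nested and non-overlapping.
#' @param length sequence length.
#' @return A dot-bracket string.
#' @examples
#' pairs_to_db(cbind(i = c(1, 2), j = c(7, 6)), 7)
#' @export
pairs_to_db <- function(pairs, length) {
  stopifnot(.is_count(length), length >= 1)
  db <- rep(".", length)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(paste(db, collapse = ""))
  pairs <- as.matrix(pairs)
  i <- as.integer(pairs[, 1L]); j <- as.integer(pairs[, 2L])
  if (any(i >= j) || any(i < 1L) || any(j > length))
    .stopf("pairs must satisfy 1 <= i < j <= length")
  pos <- c(i, j)
  if (anyDuplicated(pos))
    .stopf("a position occurs in more than one pair")
  # nestedness: no i < i' < j < j'
  o <- order(i)
  i <- i[o]; j <- j[o]
  stack <- integer(0)
  for (k in seq_along(i)) {
    while (length(stack) && stack[length(stack)] < i[k])
      stack <- stack[-length(stack)]
    if (length(stack) && stack[length(stack)] < j[k])
      .stopf("pairs are not nested (pseudoknot at (%d,%d))", i[k], j[k])
    stack <- c(stack, j[k])
  }
  db[i] <- "("
  db[j] <- ")"
  paste(db, collapse = "")
}

#' Read or write multi-structure dot-bracket files
#'
#' The file format is Vienna-like: a `>id` header line followed by one
#' dot-bracket line per structure. An optional sequence line directly after
#' the header is recognised on read.
#'
#' @param path file path.
#' @return `read_dotbracket()` returns a named character vector of
#'   dot-bracket strings.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- character(0)
  id <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- sub("^>\\s*", "", ln)
    } else if (grepl("^[.()]+$", ln)) {
      nm <- if (is.null(id)) as.character(length(out) + 1L) else id
      out[nm] <- ln
      id <- NULL
    }
    # other lines (sequences) are skipped
  }
  out
}

#' @param structures named character vector of dot-bracket strings; names
#'   are written as headers.
#' @rdname read_dotbracket
#' @export
write_dotbracket <- function(structures, path) {
  ids <- names(structures)
  if (is.null(ids)) ids <- as.character(seq_along(structures))
  writeLines(as.vector(rbind(paste0(">", ids), structures)), path)
  invisible(path)
}

#' Write a connectivity-table (CT) file for one structure
#'
#' @param sequence RNA sequence string.
#' @param db dot-bracket string of the same length.
#' @param path output path.
#' @param title title line content.
#' @export
write_ct <- function(sequence, db, path, title = "structure") {
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(s)
  if (nchar(db) != L) .stopf("sequence and structure lengths differ")
  partner <- integer(L)
  p <- db_to_pairs(db)
  partner[p[, "i"]] <- p[, "j"]
  partner[p[, "j"]] <- p[, "i"]
  lines <- c(sprintf("%6d %s", L, title),
             sprintf("%6d %s %6d %6d %6d %6d",
                     seq_len(L), s, seq_len(L) - 1L,
                     c(seq_len(L - 1L) + 1L, 0L), partner, seq_len(L)))
  writeLines(lines, path)
  invisible(path)
}

# sequence string -> integer codes 0..4 for the engine (T treated as U)
.encode_sequence <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  s[s == "T"] <- "U"
  codes <- match(s, c("A", "C", "G", "U", "N")) - 1L
  if (anyNA(codes))
    .stopf("sequence contains characters outside {A,C,G,U/T,N}: %s",
           paste(unique(s[is.na(codes)]), collapse = " "))
  codes
}
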