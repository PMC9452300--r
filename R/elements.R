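#' Encode a structure as a structural-element string
#'
#' Classifies every position of a dot-bracket structure into one of six
#' element types: `s` stem (paired), `h` hairpin loop, `i` interior or
#' bulge loop, `m` multiloop, `f` 5' unpaired end, `t` 3' unpaired end.
#' An unpaired position takes its type from the loop it sits in, i.e. the
#' innermost pair enclosing it: no helix branching off that loop makes it
#' a hairpin loop, exactly one makes it an interior/bulge loop, two or
#' more make it a multiloop. Exterior unpaired positions are `f` before
#' the first helix, `t` after the last, and `m` between top-level helices.
#' A structure with no pairs is coded all-`f` by convention (the element
#' taxonomy is undefined for a pairless chain).
#'
#' @param db dot-bracket string (or a base-pair matrix together with
#'   `length`).
#' @param length sequence length, required when `db` is a pair matrix.
#' @return Element string of the same length as the structure.
#' @examples
#' to_elements("((((....))))")
#' to_elements(".((...)).")
#' @export
to_elements <- function(db, length = NULL) {
  if (is.character(db)) {
    L <- nchar(db)
    pairs <- db_to_pairs(db)
  } else {
    stopifnot(!is.null(length))
    L <- as.integer(length)
    pairs <- as.matrix(db)
  }
  out <- rep("f", L)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(paste(out, collapse = ""))
  partner <- integer(L)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  out[partner > 0L] <- "s"

  # innermost enclosing pair per position (0 = exterior)
  enclosing <- integer(L)
  stack <- integer(0)
  for (p in seq_len(L)) {
    if (partner[p] > p) {            # opening
      enclosing[p] <- if (length(stack)) stack[length(stack)] else 0L
      stack <- c(stack, p)
    } else if (partner[p] > 0L) {    # closing
      stack <- stack[-length(stack)]
      enclosing[p] <- if (length(stack)) stack[length(stack)] else 0L
    } else {
      enclosing[p] <- if (length(stack)) stack[length(stack)] else 0L
    }
  }

  # number of helices branching directly off each loop (keyed by the
  # opening position of the enclosing pair; 0 = exterior loop)
  opens <- which(partner > seq_len(L))
  branch <- table(factor(enclosing[opens], levels = 0:L))
  first_open <- min(opens)
  last_close <- max(which(partner > 0L & partner < seq_len(L)))
  unp <- which(partner == 0L)
  for (p in unp) {
    enc <- enclosing[p]
    if (enc == 0L) {
      out[p] <- if (p < first_open) "f" else if (p > last_close) "t" else "m"
    } else {
      k <- branch[[as.character(enc)]]
      out[p] <- if (k == 0L) "h" else if (k == 1L) "i" else "m"
    }
  }
  paste(out, collapse = "")
}

#' One-hot element matrix for landscape analysis
#'
#' Expands a collection of equal-length element strings into a numeric
#' matrix with one row per structure and, by default, a block of six
#' one-hot indicator columns per position (fixed element order
#' `f, t, s, h, i, m`). An ordinal encoding (integer code per position) is
#' available for sensitivity checks but imposes an arbitrary metric
#' between element types and is not the default.
#'
#' @param element_strings character vector of element strings, optionally
#'   named by read id.
#' @param encoding `"onehot"` or `"ordinal"`.
#' @return Numeric matrix; rows keep the input order and names.
#' @export
element_matrix <- function(element_strings, encoding = c("onehot", "ordinal")) {
  encoding <- match.arg(encoding)
  stopifnot(length(element_strings) >= 1L)
  L <- nchar(element_strings[1L])
  lens <- nchar(element_strings)
  if (any(lens != L)) {
    bad <- names(element_strings)[lens != L]
    if (is.null(bad) || !length(bad)) bad <- which(lens != L)
    .stopf("element strings differ in length (offending: %s)",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(element_strings, "")),
                  nrow = length(element_strings), byrow = TRUE)
  codes <- matrix(match(chars, .ELEMENTS), nrow = nrow(chars))
  if (anyNA(codes)) .stopf("element strings may only contain %s",
                           paste(.ELEMENTS, collapse = ""))
  if (encoding == "ordinal") {
    m <- codes
    colnames(m) <- paste0("pos", seq_len(L))
  } else {
    m <- matrix(0, nrow(chars), L * 6L)
    for (e in 1:6) {
      idx <- which(codes == e)  # column-major over positions
      cols <- ((idx - 1L) %/% nrow(chars)) * 6L + e
      rows <- ((idx - 1L) %% nrow(chars)) + 1L
      m[cbind(rows, cols)] <- 1
    }
    colnames(m) <- paste0("pos", rep(seq_len(L), each = 6L), "_",
                          rep(.ELEMENTS, L))
  }
  rownames(m) <- names(element_strings)
  m
}
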