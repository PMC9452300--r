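#' Base-pairing similarity between two structures
#'
#' Positive predictive value (fraction of predicted pairs present in the
#' reference) and sensitivity (fraction of reference pairs predicted),
#' with exact pair matching by default. A slip-tolerant mode, in which a
#' predicted pair \eqn{(i,j)} also matches \eqn{(i \pm 1, j)} or
#' \eqn{(i, j \pm 1)}, is available because some published PPV variants
#' allow it; it is off by default.
#'
#' @param predicted,reference dot-bracket strings of equal length (or
#'   base-pair matrices).
#' @param slip logical; allow one-nucleotide slipping.
#' @param length sequence length, required when pair matrices are given.
#' @return An object of class `pair_similarity`: list with `ppv`,
#'   `sensitivity`, `n_pred`, `n_ref`, `n_common`. `ppv` is `NA` with a
#'   message when the prediction has no pairs.
#' @examples
#' structure_ppv("((((...))))", "((((...))))")
#' @export
structure_ppv <- function(predicted, reference, slip = FALSE, length = NULL) {
  pp <- if (is.character(predicted)) db_to_pairs(predicted) else
    as.matrix(predicted)
  rp <- if (is.character(reference)) db_to_pairs(reference) else
    as.matrix(reference)
  if (is.character(predicted) && is.character(reference) &&
      nchar(predicted) != nchar(reference))
    .stopf("structures have different lengths")
  keys <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L]) else character(0)
  rk <- keys(rp)
  n_pred <- nrow(pp); n_ref <- nrow(rp)
  if (n_pred == 0L) {
    message("prediction has no base pairs; PPV undefined")
    return(structure(list(ppv = NA_real_, sensitivity = 0,
                          n_pred = 0L, n_ref = n_ref, n_common = 0L),
                     class = "pair_similarity"))
  }
  if (!slip) {
    n_common <- sum(keys(pp) %in% rk)
  } else {
    hit <- logical(n_pred)
    for (r in seq_len(n_pred)) {
      i <- pp[r, 1L]; j <- pp[r, 2L]
      cand <- rbind(c(i, j), c(i - 1L, j), c(i + 1L, j),
                    c(i, j - 1L), c(i, j + 1L))
      hit[r] <- any(paste(cand[, 1L], cand[, 2L]) %in% rk)
    }
    n_common <- sum(hit)
  }
  structure(list(ppv = n_common / n_pred,
                 sensitivity = if (n_ref > 0L) n_common / n_ref else NA_real_,
                 n_pred = n_pred, n_ref = n_ref, n_common = n_common),
            class = "pair_similarity")
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("pair similarity: PPV = %s, sensitivity = %s (%d/%d predicted, %d reference)\n",
              format(x$ppv, digits = 4), format(x$sensitivity, digits = 4),
              x$n_common, x$n_pred, x$n_ref))
  invisible(x)
}
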