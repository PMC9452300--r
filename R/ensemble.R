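#' Base-pair probabilities and positional statistics of an ensemble
#'
#' Treats a structure collection (a whole landscape or one cluster) as an
#' empirical ensemble: the probability of pair \eqn{(i,j)} is the fraction
#' of structures containing it. Derived per-position quantities follow the
#' printed definitions:
#' \deqn{P_i = \sum_j^J P_{ij}}
#' (summing over all of position i's pairing partners on either side), the
#' likelihood of single-strandedness \eqn{1 - P_i}, and the Shannon
#' entropy \deqn{E_i = \sum_j^J -P_{ij} \log_{10} P_{ij}.}
#' The entropy sums over pairing partners only; a position's unpaired
#' state contributes no term. Setting `extended_entropy = TRUE` adds the
#' unpaired state \eqn{-(1-P_i)\log_{10}(1-P_i)} as an extra term; this
#' extended definition is clearly non-standard here and off by default.
#'
#' @param structures character vector of equal-length dot-bracket strings.
#' @param extended_entropy include the unpaired state in the entropy.
#' @return An object of class `ensemble_stats`: list with `pairs`
#'   (data.frame `i`, `j`, `p`), `p_paired`, `single_strandedness`,
#'   `entropy` (all length-L vectors) and `n` (ensemble size).
#' @examples
#' es <- ensemble_stats(c("(...)", "(...)"))
#' es$p_paired
#' @export
ensemble_stats <- function(structures, extended_entropy = FALSE) {
  n <- length(structures)
  if (n == 0L) .stopf("empty structure collection")
  L <- nchar(structures[1L])
  if (any(nchar(structures) != L)) .stopf("structures differ in length")
  plist <- lapply(structures, db_to_pairs)
  all_pairs <- do.call(rbind, plist)
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    pairs <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
  } else {
    key <- paste(all_pairs[, 1L], all_pairs[, 2L])
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    pairs <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                        p = as.numeric(tab) / n)
    pairs <- pairs[order(pairs$i, pairs$j), ]
    rownames(pairs) <- NULL
  }
  p_paired <- numeric(L)
  entropy <- numeric(L)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]; p <- pairs$p[r]
    term <- if (p > 0) -p * log10(p) else 0
    p_paired[i] <- p_paired[i] + p
    p_paired[j] <- p_paired[j] + p
    entropy[i] <- entropy[i] + term
    entropy[j] <- entropy[j] + term
  }
  ss <- 1 - p_paired
  if (extended_entropy) {
    p0 <- pmin(pmax(ss, 0), 1)
    entropy <- entropy + ifelse(p0 > 0, -p0 * log10(p0), 0)
  }
  structure(list(pairs = pairs, p_paired = p_paired,
                 single_strandedness = ss, entropy = entropy, n = n),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble_stats: %d structures, %d distinct pairs, L = %d\n",
              x$n, nrow(x$pairs), length(x$p_paired)))
  invisible(x)
}

#' Per-cluster ensemble statistics
#'
#' [ensemble_stats()] restricted to each conformation of a landscape.
#'
#' @param landscape a [conformation_landscape()], or an integer label
#'   vector when `structures` is given.
#' @param structures dot-bracket strings matching the labels (defaults to
#'   the landscape's own structures).
#' @param ... passed to [ensemble_stats()].
#' @return Named list, one `ensemble_stats` per cluster.
#' @export
per_cluster_stats <- function(landscape, structures = NULL, ...) {
  if (inherits(landscape, "conformation_landscape")) {
    labels <- landscape$labels
    if (is.null(structures)) structures <- landscape$structures$db
  } else {
    labels <- as.integer(landscape)
    stopifnot(!is.null(structures))
  }
  if (length(labels) != length(structures))
    .stopf("labels do not cover the structure collection")
  out <- list()
  for (c in sort(unique(labels))) {
    idx <- which(labels == c)
    if (length(idx) == 0L) {
      .warnf("cluster %d is empty; skipped", c)
      next
    }
    out[[as.character(c)]] <- ensemble_stats(structures[idx], ...)
  }
  out
}

#' Write ensemble statistics as TSV tables
#'
#' @param stats an `ensemble_stats` object.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @export
write_ensemble_stats <- function(stats, dir, prefix = "ensemble") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_pair_probabilities.tsv"))
  write.table(stats$pairs, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_positional.tsv"))
  write.table(data.frame(position = seq_along(stats$p_paired),
                         p_paired = stats$p_paired,
                         single_strandedness = stats$single_strandedness,
                         shannon_entropy = stats$entropy),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
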