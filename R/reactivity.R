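#' Per-position mutation rates of a bit-vector collection
#'
#' The mutation rate at a position is the number of ones divided by the
#' number of zeroes and ones there; masked codes are excluded from the
#' denominator. Positions where every code is masked get `NA`.
#'
#' @param bitvectors a [bitvector_set].
#' @return A list with `rate` (numeric, `NA` where undefined) and
#'   `coverage` (integer count of informative reads per position).
#' @export
mutation_rates <- function(bitvectors) {
  stopifnot(inherits(bitvectors, "bitvector_set"))
  codes <- bitvectors$codes
  cov <- colSums(!is.na(codes))
  ones <- colSums(codes == 1L, na.rm = TRUE)
  rate <- ifelse(cov > 0L, ones / cov, NA_real_)
  list(rate = rate, coverage = as.integer(cov))
}

#' Raw SHAPE reactivity from channel mutation rates
#'
#' Implements the positive-likelihood-ratio estimate
#' \deqn{R = \frac{MR_{(+)} - MR_{(-)}}{1 - MR_{(-)}}}
#' where the denominator, the true-negative rate of the control channel,
#' is its specificity. Values where the treated rate falls below the
#' control rate are clamped to 0: the reactivity scale starts at 0 (no
#' reactivity) and downstream constraint logic only consumes non-negative
#' evidence. `NA` inputs, and positions with control rate 1, give `NA`.
#'
#' @param mr_plus,mr_minus mutation-rate vectors in `[0, 1]`.
#' @return Raw reactivity vector.
#' @examples
#' raw_reactivity(0.08, 0.02)  # (0.08 - 0.02) / 0.98
#' @export
raw_reactivity <- function(mr_plus, mr_minus) {
  stopifnot(length(mr_plus) == length(mr_minus))
  r <- (mr_plus - mr_minus) / (1 - mr_minus)
  r[!is.na(mr_minus) & mr_minus >= 1] <- NA_real_
  pmax(r, 0)
}

#' Normalize raw reactivities to a standard 0-to-~1 scale
#'
#' The default is the common 2%/8% rule: the top 2% of defined values
#' are set aside as outliers and every value is divided by the mean of the
#' next 8%. A boxplot variant (outliers above Q3 + 1.5 IQR excluded,
#' divisor the mean of the top 10% of the remainder) is available.
#' Undefined (`NA`) positions pass through unchanged.
#'
#' @param raw raw reactivity vector.
#' @param method `"percentile"` (2%/8%) or `"boxplot"`.
#' @param min_defined minimum number of defined positions required
#'   (default 20); below this the caller should skip normalization.
#' @return Normalized reactivity vector.
#' @export
normalize_reactivity <- function(raw, method = c("percentile", "boxplot"),
                                 min_defined = 20L) {
  method <- match.arg(method)
  defined <- which(!is.na(raw))
  if (length(defined) < min_defined)
    .stopf(paste("only %d defined positions (< %d): too few to normalize;",
                 "skip normalization for this profile"),
           length(defined), min_defined)
  v <- sort(raw[defined], decreasing = TRUE)
  n <- length(v)
  if (method == "percentile") {
    n_out <- max(1L, ceiling(0.02 * n))
    n_div <- max(1L, ceiling(0.08 * n))
    divisor <- mean(v[(n_out + 1L):min(n, n_out + n_div)])
  } else {
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    keep <- v[v <= q[2] + 1.5 * (q[2] - q[1])]
    divisor <- mean(head(keep, max(1L, ceiling(0.1 * length(keep)))))
  }
  if (!is.finite(divisor) || divisor <= 0)
    .stopf("normalization divisor is not positive; profile has no signal")
  raw / divisor
}

#' Full reactivity profile from the two probing channels
#'
#' Combines treated and control bit vectors into a per-position table of
#' mutation rates, coverages, raw and (optionally) normalized
#' reactivities. Positions with informative coverage below
#' `low_confidence_coverage` in either channel are reported but flagged.
#'
#' @param bv_plus,bv_minus [bitvector_set]s for the treated and control
#'   channels against the same reference.
#' @param sequence optional reference sequence (adds a `base` column).
#' @param normalize whether to attach normalized reactivities (skipped
#'   with a message when too few positions are defined).
#' @param low_confidence_coverage coverage floor for the flag column
#'   (default 50 informative reads).
#' @param ... passed to [normalize_reactivity()].
#' @return A data.frame of class `reactivity_profile` with columns
#'   `position`, `base`, `mr_plus`, `mr_minus`, `coverage_plus`,
#'   `coverage_minus`, `raw`, `normalized`, `low_confidence`.
#' @export
reactivity_profile <- function(bv_plus, bv_minus, sequence = NULL,
                               normalize = TRUE,
                               low_confidence_coverage = 50L, ...) {
  stopifnot(inherits(bv_plus, "bitvector_set"),
            inherits(bv_minus, "bitvector_set"))
  if (ncol(bv_plus$codes) != ncol(bv_minus$codes))
    .stopf("channel bit vectors have different lengths")
  mp <- mutation_rates(bv_plus)
  mm <- mutation_rates(bv_minus)
  raw <- raw_reactivity(mp$rate, mm$rate)
  normalized <- rep(NA_real_, length(raw))
  if (normalize) {
    normalized <- tryCatch(normalize_reactivity(raw, ...),
                           error = function(e) {
                             message("normalization skipped: ",
                                     conditionMessage(e))
                             rep(NA_real_, length(raw))
                           })
  }
  base <- if (!is.null(sequence)) strsplit(toupper(sequence), "")[[1]] else
    rep(NA_character_, length(raw))
  out <- data.frame(position = seq_along(raw),
                    base = base,
                    mr_plus = mp$rate, mr_minus = mm$rate,
                    coverage_plus = mp$coverage,
                    coverage_minus = mm$coverage,
                    raw = raw, normalized = normalized,
                    low_confidence = mp$coverage < low_confidence_coverage |
                      mm$coverage < low_confidence_coverage,
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- bv_plus$reference_id
  attr(out, "defined_fraction") <- mean(!is.na(raw))
  class(out) <- c("reactivity_profile", "data.frame")
  out
}

#' Pearson correlation between two reactivity profiles
#'
#' Computed over positions defined in both profiles; used to check the
#' reproducibility of biological replicates.
#'
#' @param profile_a,profile_b `reactivity_profile` objects (or numeric
#'   vectors).
#' @param value which column to correlate when profiles are supplied.
#' @return A list with `r`, `n` (positions used) and `p_value`; `r` is
#'   `NA` with a message when fewer than 3 joint positions exist.
#' @export
replicate_correlation <- function(profile_a, profile_b, value = "raw") {
  a <- if (is.numeric(profile_a)) profile_a else profile_a[[value]]
  b <- if (is.numeric(profile_b)) profile_b else profile_b[[value]]
  stopifnot(length(a) == length(b))
  joint <- !is.na(a) & !is.na(b)
  n <- sum(joint)
  if (n < 3L) {
    message("fewer than 3 jointly defined positions; correlation undefined")
    return(list(r = NA_real_, n = n, p_value = NA_real_))
  }
  ct <- stats::cor.test(a[joint], b[joint], method = "pearson")
  list(r = unname(ct$estimate), n = n, p_value = ct$p.value)
}

#' Write a SHAPE-map-style reactivity table
#'
#' Tab-separated export with `-999` encoding undefined values, plus a
#' two-column `.shape` dialect (position, reactivity) consumable by
#' standard folding tools.
#'
#' @param profile a [reactivity_profile()].
#' @param path output path.
#' @param dialect `"map"` (full table) or `"shape"` (position and
#'   normalized reactivity only).
#' @export
write_reactivity <- function(profile, path, dialect = c("map", "shape")) {
  dialect <- match.arg(dialect)
  enc <- function(x) ifelse(is.na(x), -999, x)
  if (dialect == "map") {
    df <- data.frame(position = profile$position, base = profile$base,
                     mr_plus = enc(profile$mr_plus),
                     mr_minus = enc(profile$mr_minus),
                     raw = enc(profile$raw),
                     normalized = enc(profile$normalized),
                     coverage_plus = profile$coverage_plus,
                     coverage_minus = profile$coverage_minus)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(position = profile$position,
                     reactivity = enc(profile$normalized))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
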